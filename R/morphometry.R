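#' Otsu's threshold for a grayscale image
#'
#' Histogram-based threshold maximizing the between-class variance over 256
#' bins spanning the image's intensity range. Because binning is relative to
#' the range, the resulting mask is invariant to multiplying the image by a
#' positive constant.
#'
#' @param image Numeric matrix.
#' @param n_bins Histogram resolution.
#' @return Threshold on the image's intensity scale.
#' @export
otsu_threshold <- function(image, n_bins = 256L) {
  v <- as.vector(image)
  rng <- range(v)
  if (diff(rng) == 0) return(rng[[1L]])
  breaks <- seq(rng[[1L]], rng[[2L]], length.out = n_bins + 1L)
  counts <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE), n_bins)
  p <- counts / sum(counts)
  mids <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  w1 <- cumsum(p)
  mu1 <- cumsum(p * mids)
  mu_total <- mu1[[n_bins]]
  between <- (mu_total * w1 - mu1)^2 / (w1 * (1 - w1))
  between[!is.finite(between)] <- 0
  breaks[[which.max(between) + 1L]]
}

# Connected-component labelling of a logical mask (4- or 8-connectivity)
# by BFS flood fill.
label_mask <- function(mask, connectivity = 8L) {
  h <- nrow(mask); w <- ncol(mask)
  labels <- matrix(0L, h, w)
  if (connectivity == 8L) {
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else {
    dr <- c(-1L, 0L, 0L, 1L); dc <- c(0L, -1L, 1L, 0L)
  }
  current <- 0L
  for (start in which(mask & labels == 0L)) {
    if (labels[[start]] != 0L) next
    current <- current + 1L
    queue <- start
    labels[[start]] <- current
    while (length(queue) > 0) {
      px <- queue[[1L]]; queue <- queue[-1L]
      r <- (px - 1L) %% h + 1L
      cc <- (px - 1L) %/% h + 1L
      nr <- r + dr; nc <- cc + dc
      ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
      nb <- (nc[ok] - 1L) * h + nr[ok]
      nb <- nb[mask[nb] & labels[nb] == 0L]
      labels[nb] <- current
      queue <- c(queue, nb)
    }
  }
  labels
}

#' Segment bright inclusions in a single-cell image
#'
#' Applies a global threshold (Otsu by default, or a fixed numeric value),
#' labels the foreground with 8-connectivity and discards regions smaller
#' than `min_area`. Inclusions are compact, bright and sparse; a normal
#' reticular ER fills a large, connected share of the cytoplasm, so a
#' foreground exceeding `max_fill` of the image is treated as reticular
#' texture rather than inclusions and yields zero regions.
#'
#' @param image Numeric matrix (8/16-bit intensities).
#' @param min_area Minimum region area in px^2 (default 4).
#' @param threshold_method `"otsu"` or a fixed numeric threshold.
#' @param max_fill Maximum foreground fraction accepted as inclusions.
#' @return Tibble of regions (`region_id`, `area`, `centroid_row`,
#'   `centroid_col`, `mean_intensity`) with the label matrix as attribute
#'   `labels`.
#' @export
segment_inclusions <- function(image, min_area = 4L, threshold_method = "otsu",
                               max_fill = 0.30) {
  stopifnot(is.matrix(image))
  empty <- tibble(region_id = integer(), area = integer(),
                  centroid_row = numeric(), centroid_col = numeric(),
                  mean_intensity = numeric())
  if (diff(range(image)) == 0) {
    rlang::warn("constant image: no inclusions segmented.")
    attr(empty, "labels") <- matrix(0L, nrow(image), ncol(image))
    return(empty)
  }
  thr <- if (identical(threshold_method, "otsu")) {
    otsu_threshold(image)
  } else if (is.numeric(threshold_method)) {
    threshold_method
  } else {
    stop_erfrag("`threshold_method` must be \"otsu\" or a numeric threshold.",
                "erfrag_parameter_error")
  }
  mask <- image > thr
  if (mean(mask) > max_fill) {
    # large connected foreground: reticular texture, not inclusions
    attr(empty, "labels") <- matrix(0L, nrow(image), ncol(image))
    return(empty)
  }
  labels <- label_mask(mask, connectivity = 8L)
  if (max(labels) == 0L) {
    attr(empty, "labels") <- labels
    return(empty)
  }
  px <- which(labels > 0L)
  lab <- labels[px]
  rows <- (px - 1L) %% nrow(image) + 1L
  cols <- (px - 1L) %/% nrow(image) + 1L
  regions <- tibble(label = lab, row = rows, col = cols,
                    intensity = image[px]) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(area = dplyr::n(),
                     centroid_row = mean(.data$row),
                     centroid_col = mean(.data$col),
                     mean_intensity = mean(.data$intensity),
                     .groups = "drop") |>
    dplyr::filter(.data$area >= min_area) |>
    dplyr::arrange(dplyr::desc(.data$area)) |>
    dplyr::mutate(region_id = dplyr::row_number(), .before = 1) |>
    dplyr::select(-"label")
  attr(regions, "labels") <- labels
  regions
}

#' Classify a cell's ER morphology from its segmented inclusions
#'
#' A cell with no inclusion regions is `normal`; otherwise its class is that
#' of its largest inclusion, assigned by three contiguous half-open area
#' bands `(0, b1]`, `(b1, b2]`, `(b2, Inf)` in px^2.
#'
#' @param regions Region tibble from [segment_inclusions()].
#' @param area_bands Two increasing band boundaries, default `c(80, 300)`.
#' @param cell_id Optional identifier carried into the output.
#' @return One-row tibble: `cell_id`, `n_inclusions`, `largest_area`,
#'   `size_class`.
#' @export
classify_cell <- function(regions, area_bands = c(80, 300), cell_id = NA_integer_) {
  if (length(area_bands) != 2L || any(diff(area_bands) <= 0) || any(area_bands <= 0)) {
    stop_erfrag("`area_bands` must be two increasing positive boundaries.",
                "erfrag_configuration_error")
  }
  n <- nrow(regions)
  if (n == 0L) {
    cls <- "normal"; largest <- NA_real_
  } else {
    largest <- max(regions$area)
    cls <- if (largest <= area_bands[[1L]]) "small"
           else if (largest <= area_bands[[2L]]) "medium"
           else "large"
  }
  tibble(cell_id = cell_id, n_inclusions = n, largest_area = largest,
         size_class = factor(cls, levels = c("normal", "small", "medium", "large")))
}

#' Population-level morphology summary with prevalence confidence interval
#'
#' Tabulates per-class percentages (summing to 100) and the inclusion
#' prevalence (1 - fraction normal) with an exact binomial 95% confidence
#' interval.
#'
#' @param cell_morphologies Row-bound output of [classify_cell()].
#' @return List with `class_summary` (tibble of counts and percentages),
#'   `prevalence`, `prevalence_ci` (exact 95% CI) and `n_cells`.
#' @export
population_summary <- function(cell_morphologies) {
  if (is.null(cell_morphologies) || nrow(cell_morphologies) == 0L) {
    stop_erfrag("at least one cell is required.", "erfrag_input_error")
  }
  n <- nrow(cell_morphologies)
  counts <- table(factor(cell_morphologies$size_class,
                         levels = c("normal", "small", "medium", "large")))
  class_summary <- tibble(
    size_class = names(counts),
    n_cells = as.integer(counts),
    percent = 100 * as.integer(counts) / n
  )
  k <- n - counts[["normal"]]
  ci <- stats::binom.test(k, n)$conf.int
  list(
    class_summary = class_summary,
    prevalence = k / n,
    prevalence_ci = c(lower = ci[[1L]], upper = ci[[2L]]),
    n_cells = n
  )
}

#' Generate a synthetic single-cell image population with known morphology
#'
#' Emulates confocal sections of GFP-KDEL-transfected hepatocyte-like cells:
#' a `normal` cell shows a smooth reticular texture filling the cytoplasm;
#' an inclusion-bearing cell additionally carries 1-5 bright disc inclusions
#' whose radii are drawn from its size class band (defaults small 2-4 px,
#' medium 5-8 px, large 9-14 px). Whether a cell bears inclusions is a
#' Bernoulli draw at `inclusion_prevalence`; the size class is drawn from
#' `size_class_probs`. Discs are placed without overlap; the truth table
#' records each cell's class and inclusion count.
#'
#' @param n_cells Number of cells (pages).
#' @param inclusion_prevalence Probability in \[0, 1\] a cell bears inclusions.
#' @param size_class_probs Probabilities of (small, medium, large), summing
#'   to 1.
#' @param image_size Side of the square image in px.
#' @param radius_bands List of integer radius ranges per class.
#' @param seed Integer seed.
#' @return List with `images` (list of 16-bit matrices) and `truth` (tibble
#'   `cell_id`, `class`, `n_inclusions`).
#' @export
generate_cell_population <- function(n_cells, inclusion_prevalence = 0.40,
                                     size_class_probs = c(1, 1, 1) / 3,
                                     image_size = 128L,
                                     radius_bands = list(small = 2:4,
                                                         medium = 5:8,
                                                         large = 9:14),
                                     seed) {
  n_cells <- assert_count(n_cells, "n_cells", min = 1L)
  assert_scalar_number(inclusion_prevalence, "inclusion_prevalence", 0, 1)
  if (length(size_class_probs) != 3L || any(size_class_probs < 0) ||
      abs(sum(size_class_probs) - 1) > 1e-8) {
    stop_erfrag("`size_class_probs` must be three probabilities summing to 1.",
                "erfrag_parameter_error")
  }
  image_size <- assert_count(image_size, "image_size", min = 8L)
  max_r <- max(unlist(radius_bands))
  if (image_size < 2L * (max_r + 2L)) {
    stop_erfrag("image too small for the largest inclusion disc.",
                "erfrag_parameter_error")
  }
  if (missing(seed)) stop_erfrag("`seed` must be supplied.", "erfrag_parameter_error")
  set.seed(as.integer(seed))

  coords_r <- matrix(rep(seq_len(image_size), image_size), image_size)
  coords_c <- t(coords_r)

  has_inclusion <- stats::runif(n_cells) < inclusion_prevalence
  classes <- character(n_cells)
  n_placed <- integer(n_cells)
  images <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    img <- 1000 + matrix(stats::rnorm(image_size^2, sd = 30), image_size)
    if (!has_inclusion[[i]]) {
      # smooth reticular field: a few random sinusoids, high fill fraction
      classes[[i]] <- "normal"
      for (w in 1:3) {
        fr <- stats::runif(1, 0.02, 0.08); fc <- stats::runif(1, 0.02, 0.08)
        ph <- stats::runif(1, 0, 2 * pi)
        img <- img + 250 * sin(2 * pi * (fr * coords_r + fc * coords_c) + ph)
      }
    } else {
      cls <- sample(c("small", "medium", "large"), 1L, prob = size_class_probs)
      classes[[i]] <- cls
      # dim residual texture so thresholding is driven by the discs
      fr <- stats::runif(1, 0.02, 0.08); ph <- stats::runif(1, 0, 2 * pi)
      img <- img + 100 * sin(2 * pi * fr * (coords_r + coords_c) + ph)
      n_target <- sample(1:5, 1L)
      centres <- matrix(numeric(0), 0, 2)
      radii <- integer(0)
      tries <- 0L
      while (length(radii) < n_target && tries < 200L) {
        tries <- tries + 1L
        r <- sample(radius_bands[[cls]], 1L)
        cr <- stats::runif(1, r + 2, image_size - r - 1)
        cc <- stats::runif(1, r + 2, image_size - r - 1)
        if (nrow(centres) > 0) {
          d <- sqrt((centres[, 1] - cr)^2 + (centres[, 2] - cc)^2)
          if (any(d < radii + r + 3)) next
        }
        centres <- rbind(centres, c(cr, cc))
        radii <- c(radii, r)
        disc <- (coords_r - cr)^2 + (coords_c - cc)^2 <= r^2
        img[disc] <- 4000 + stats::rnorm(sum(disc), sd = 50)
      }
      n_placed[[i]] <- length(radii)
    }
    images[[i]] <- matrix(as.integer(pmin(pmax(round(img), 0), 65535)), image_size)
  }
  truth <- tibble(
    cell_id = seq_len(n_cells),
    class = factor(classes, levels = c("normal", "small", "medium", "large")),
    n_inclusions = n_placed
  )
  list(images = images, truth = truth)
}

#' Segment and classify every cell of an image stack
#'
#' Convenience wrapper running [segment_inclusions()] and [classify_cell()]
#' over a list of images.
#'
#' @param images List of matrices (or a population from
#'   [generate_cell_population()]).
#' @inheritParams segment_inclusions
#' @inheritParams classify_cell
#' @return Tibble of per-cell morphologies.
#' @export
classify_population <- function(images, min_area = 4L, threshold_method = "otsu",
                                area_bands = c(80, 300)) {
  if (is.list(images) && !is.null(images$images)) images <- images$images
  purrr::map_dfr(seq_along(images), function(i) {
    regions <- segment_inclusions(images[[i]], min_area = min_area,
                                  threshold_method = threshold_method)
    classify_cell(regions, area_bands = area_bands, cell_id = i)
  })
}
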