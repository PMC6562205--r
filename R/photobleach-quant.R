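#' Normalize traces to 100% pre-bleach fluorescence
#'
#' Each ROI's intensities are divided by the mean of its pre-bleach frames
#' (all frames before the first bleach frame) and multiplied by 100, so the
#' pre-bleach level of the output is exactly 100%. The operation is idempotent
#' and invariant to multiplying the raw trace by any positive constant.
#'
#' @param traces Tibble with `time_s`, `frame`, `roi_id`, `intensity`,
#'   `is_bleach_frame` (the [simulate_photobleach()] dialect).
#' @return The same tibble with `intensity` rescaled to percent of pre-bleach.
#' @export
normalize_prebleach <- function(traces) {
  check_trace_columns(traces)
  traces |>
    dplyr::group_by(.data$roi_id) |>
    dplyr::group_modify(function(tr, key) {
      first_pulse <- which(tr$is_bleach_frame)[1]
      if (is.na(first_pulse)) {
        stop_erfrag("trace has no bleach frame; cannot locate pre-bleach window.",
                    "erfrag_protocol_error")
      }
      pre <- tr$intensity[seq_len(first_pulse - 1L)]
      if (length(pre) < 3L) {
        stop_erfrag("at least 3 pre-bleach frames are required for normalization.",
                    "erfrag_normalization_error")
      }
      m <- mean(pre)
      if (!is.finite(m) || m <= 0) {
        stop_erfrag("pre-bleach mean must be positive.", "erfrag_normalization_error")
      }
      tr$intensity <- tr$intensity / m * 100
      tr
    }) |>
    dplyr::ungroup() |>
    dplyr::relocate("time_s", "frame", "roi_id")
}

check_trace_columns <- function(traces) {
  need <- c("time_s", "frame", "roi_id", "intensity", "is_bleach_frame")
  missing <- setdiff(need, names(traces))
  if (length(missing) > 0) {
    stop_erfrag(paste0("trace table lacks column(s): ", paste(missing, collapse = ", ")),
                "erfrag_input_error")
  }
  invisible(traces)
}

#' Fit a FRAP recovery curve and estimate the mobile fraction
#'
#' Fits the single-exponential recovery model
#' \deqn{F(t) = F_0 + (plateau - F_0)(1 - e^{-k t})}
#' to the post-bleach frames of a normalized single-pulse (FRAP) trace by
#' least squares, with time measured from the first post-bleach frame. `F0`
#' is the observed first post-bleach level (the pulse frame, which this
#' pipeline's traces record immediately after the pulse); the asymptote and
#' rate are the fitted parameters. The
#' mobile fraction — the share of fluorophores free to exchange into the
#' bleached region — is `(plateau - F0) / (F_pre - F0)` with `F_pre = 100`.
#' Because the recovery plateau can also be read off the trace directly,
#' a model-free variant using the mean of the last three frames is reported
#' alongside, and the initial recovery slope is estimated model-free by
#' ordinary linear regression over the first `window` post-bleach frames.
#'
#' A non-convergent or unidentifiable fit is returned flagged
#' (`converged = FALSE`), never as an error; the mobile fraction is clipped
#' to \[0, 1.05\] with `clipped = TRUE` when clipping occurred.
#'
#' @param traces Normalized trace tibble (see [normalize_prebleach()]).
#' @param roi ROI to fit; defaults to `"bleach"` when present, otherwise the
#'   single ROI in the table.
#' @param window Number of early post-bleach frames for the slope regression.
#' @return An object of class `frap_fit`; see [tidy.frap_fit()].
#' @export
fit_frap <- function(traces, roi = NULL, window = 5L) {
  check_trace_columns(traces)
  rois <- unique(traces$roi_id)
  if (is.null(roi)) roi <- if ("bleach" %in% rois) "bleach" else rois[[1L]]
  if (length(rois) > 1L && !roi %in% rois) {
    stop_erfrag("requested ROI not present in trace table.", "erfrag_input_error")
  }
  tr <- dplyr::filter(traces, .data$roi_id == !!roi) |> dplyr::arrange(.data$frame)
  pulses <- which(tr$is_bleach_frame)
  if (length(pulses) != 1L) {
    stop_erfrag("FRAP fitting requires exactly one bleach event.", "erfrag_protocol_error")
  }
  # the pulse frame is acquired immediately after the (instantaneous) pulse,
  # so it is the first post-bleach sample
  post <- tr[tr$frame >= tr$frame[pulses], , drop = FALSE]
  if (nrow(post) < 5L) {
    stop_erfrag("at least 5 post-bleach frames are required.", "erfrag_input_error")
  }
  t_rel <- post$time_s - post$time_s[[1L]]
  y <- post$intensity
  # F0 is a data quantity: the first post-bleach level. Only the asymptote
  # and rate are fitted, which keeps the plateau estimate stable on
  # diffusion-shaped (multi-scale) recoveries.
  F0 <- y[[1L]]
  plateau_start <- mean(utils::tail(y, max(3L, nrow(post) %/% 10L)))
  span <- max(t_rel[length(t_rel)], 1e-6)

  fit <- NULL
  converged <- FALSE
  if (stats::sd(y) > 1e-10 && plateau_start > F0 + 1e-8) {
    fit <- tryCatch(
      stats::nls(y ~ F0 + (plateau - F0) * (1 - exp(-k * t_rel)),
                 start = list(plateau = plateau_start, k = 3 / span),
                 algorithm = "port",
                 lower = c(plateau = -Inf, k = 0),
                 control = stats::nls.control(maxiter = 200, warnOnly = TRUE)),
      error = function(e) NULL
    )
    converged <- !is.null(fit) && fit$convInfo$isConv
  }
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    plateau <- unname(cf[["plateau"]]); k <- unname(cf[["k"]])
    rss <- sum(stats::resid(fit)^2)
  } else {
    # flat or degenerate recovery: plateau = observed level, rate unidentified
    plateau <- mean(y); k <- NA_real_
    rss <- sum((y - mean(y))^2)
  }
  # a rate faster than the frame interval or slower than the window is
  # effectively unidentified from these frames
  k_identifiable <- converged && is.finite(k) && k > 1e-3 / span && k < 1e3 / span

  mf <- mobile_fraction_from(plateau, F0)
  plateau_last <- mean(utils::tail(y, 3L))
  mf_last <- mobile_fraction_from(plateau_last, F0)

  slope <- NA_real_
  if (nrow(post) >= window) {
    w <- seq_len(window)
    slope <- unname(stats::coef(stats::lm(y[w] ~ t_rel[w]))[[2L]])
  } else {
    rlang::warn(sprintf("fewer than %d post-bleach frames; initial slope omitted.", window))
  }

  structure(
    list(roi_id = roi, F_pre = 100, F0 = F0, plateau = plateau, k = k,
         initial_slope = slope, window = as.integer(window),
         mobile_fraction = mf$value, mobile_fraction_clipped = mf$clipped,
         plateau_last = plateau_last, mobile_fraction_last = mf_last$value,
         fit_rss = rss, converged = converged, k_identifiable = k_identifiable,
         n_post = nrow(post),
         data = tibble(t = t_rel, intensity = y)),
    class = "frap_fit"
  )
}

mobile_fraction_from <- function(plateau, F0, F_pre = 100) {
  denom <- F_pre - F0
  if (!is.finite(denom) || abs(denom) < 1e-12) {
    return(list(value = NA_real_, clipped = FALSE))
  }
  raw <- (plateau - F0) / denom
  clipped <- raw < 0 || raw > 1.05
  list(value = min(max(raw, 0), 1.05), clipped = clipped)
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf(
    paste0("<frap_fit> roi '%s': F0 = %.2f%%, plateau = %.2f%%, k = %s 1/s,\n",
           "  initial slope = %s %%/s, mobile fraction = %.3f%s\n"),
    x$roi_id, x$F0, x$plateau,
    ifelse(is.finite(x$k), sprintf("%.4f", x$k), "unidentified"),
    ifelse(is.finite(x$initial_slope), sprintf("%.3f", x$initial_slope), "NA"),
    x$mobile_fraction,
    if (x$mobile_fraction_clipped) " (clipped)" else ""
  ))
  invisible(x)
}

#' Tidy a FRAP fit
#'
#' @param x A `frap_fit`.
#' @param ... Unused.
#' @return One-row tibble of fitted quantities.
#' @export
tidy.frap_fit <- function(x, ...) {
  tibble(
    roi_id = x$roi_id, F_pre = x$F_pre, F0 = x$F0, plateau = x$plateau,
    k = x$k, initial_slope = x$initial_slope,
    mobile_fraction = x$mobile_fraction,
    mobile_fraction_last = x$mobile_fraction_last,
    clipped = x$mobile_fraction_clipped
  )
}

#' @rdname tidy.frap_fit
#' @return `glance()`: one-row tibble of fit diagnostics.
#' @export
glance.frap_fit <- function(x, ...) {
  tibble(fit_rss = x$fit_rss, converged = x$converged,
         k_identifiable = x$k_identifiable, n_post = x$n_post)
}

#' Plot a FRAP fit: observed post-bleach recovery and fitted curve
#'
#' @param object A `frap_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.frap_fit <- function(object, ...) {
  dat <- object$data
  curve <- tibble(t = seq(0, max(dat$t), length.out = 200))
  curve$fitted <- if (is.finite(object$k)) {
    object$F0 + (object$plateau - object$F0) * (1 - exp(-object$k * curve$t))
  } else {
    rep(object$plateau, nrow(curve))
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$t, y = .data$intensity)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = .data$fitted),
                       colour = "firebrick") +
    ggplot2::geom_hline(yintercept = 100, linetype = "dashed") +
    ggplot2::labs(x = "time after bleach (s)", y = "fluorescence (% pre-bleach)",
                  title = sprintf("FRAP recovery, mobile fraction %.2f",
                                  object$mobile_fraction)) +
    ggplot2::theme_minimal()
}

#' FLIP depletion statistics per monitored ROI
#'
#' For a repeated-bleach (FLIP) experiment, computes per ROI the depletion
#' fraction (mean of the last three frames divided by the 100% pre-bleach
#' level) and the mean inter-pulse recovery: within each gap between
#' consecutive pulses, the fractional rebound of intensity relative to the
#' drop at the preceding pulse. A connected lumen shares depletion with the
#' bleach region and shows small, consistent rebounds; an isolated cisterna
#' retains its fluorescence.
#'
#' @param traces Normalized trace tibble with at least two bleach frames.
#' @return A `flip_stats` tibble: `roi_id`, `depletion_fraction`,
#'   `interpulse_recovery`.
#' @export
flip_depletion <- function(traces) {
  check_trace_columns(traces)
  pulse_frames <- sort(unique(traces$frame[traces$is_bleach_frame]))
  if (length(pulse_frames) < 2L) {
    stop_erfrag("FLIP analysis requires at least two bleach pulses.",
                "erfrag_protocol_error")
  }
  out <- traces |>
    dplyr::group_by(.data$roi_id) |>
    dplyr::group_modify(function(tr, key) {
      tr <- dplyr::arrange(tr, .data$frame)
      depletion <- mean(utils::tail(tr$intensity, 3L)) / 100
      rebounds <- purrr::map_dbl(seq_along(pulse_frames), function(i) {
        p <- pulse_frames[[i]]
        gap_end <- if (i < length(pulse_frames)) pulse_frames[[i + 1L]] - 1L else max(tr$frame)
        before <- tr$intensity[tr$frame == p - 1L]
        at <- tr$intensity[tr$frame == p]
        gap <- tr$intensity[tr$frame > p & tr$frame <= gap_end]
        if (length(before) != 1L || length(at) != 1L || length(gap) < 1L) return(NA_real_)
        drop <- before - at
        if (drop <= 1e-9) return(NA_real_)
        (max(gap) - at) / drop
      })
      tibble(depletion_fraction = max(depletion, 0),
             interpulse_recovery = mean(rebounds, na.rm = TRUE))
    }) |>
    dplyr::ungroup()
  class(out) <- c("flip_stats", class(out))
  out
}

#' Classify luminal connectivity from FLIP depletion
#'
#' An ROI whose fluorescence is co-depleted with the bleach region
#' (depletion fraction at or below `deplete_below`) is called `connected`;
#' one retaining at least `preserve_above` of its pre-bleach level is
#' `isolated`; anything in between is `indeterminate`.
#'
#' @param flip_stats Output of [flip_depletion()].
#' @param deplete_below,preserve_above Ordered thresholds (defaults 0.25 and
#'   0.75) on the depletion fraction.
#' @return The input tibble with a `connectivity_call` factor column.
#' @export
classify_connectivity <- function(flip_stats, deplete_below = 0.25,
                                  preserve_above = 0.75) {
  if (!is.numeric(deplete_below) || !is.numeric(preserve_above) ||
      deplete_below >= preserve_above) {
    stop_erfrag("thresholds must satisfy deplete_below < preserve_above.",
                "erfrag_parameter_error")
  }
  if (!"depletion_fraction" %in% names(flip_stats)) {
    stop_erfrag("`flip_stats` must contain a depletion_fraction column.",
                "erfrag_input_error")
  }
  dplyr::mutate(
    flip_stats,
    connectivity_call = factor(
      dplyr::case_when(
        .data$depletion_fraction <= deplete_below ~ "connected",
        .data$depletion_fraction >= preserve_above ~ "isolated",
        TRUE ~ "indeterminate"
      ),
      levels = c("connected", "isolated", "indeterminate")
    )
  )
}

#' Two-group comparison by unpaired parametric t test
#'
#' Student's pooled-variance two-sample t test (the unpaired parametric t
#' test customary in imaging figure legends); Welch's correction is behind
#' `var_equal = FALSE`. Significance stars follow the figure-legend scheme
#' (see [significance_stars()]). Two groups with zero variance and equal
#' means return t = 0, p = 1 rather than NaN.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @param var_equal Use the pooled-variance statistic (default) or Welch.
#' @return One-row tibble: `t`, `df`, `p`, `stars`, group means and ns.
#' @export
#' @examples
#' compare_groups(c(1, 2, 3, 4), c(2, 3, 4, 5))
compare_groups <- function(values_a, values_b, var_equal = TRUE) {
  if (length(values_a) < 2L || length(values_b) < 2L ||
      any(!is.finite(values_a)) || any(!is.finite(values_b))) {
    stop_erfrag("each group needs >= 2 finite values.", "erfrag_input_error")
  }
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0 &&
      mean(values_a) == mean(values_b)) {
    res <- list(statistic = 0, parameter = length(values_a) + length(values_b) - 2L,
                p.value = 1)
  } else {
    res <- stats::t.test(values_a, values_b, var.equal = var_equal)
  }
  tibble(
    t = unname(res$statistic), df = unname(res$parameter),
    p = res$p.value, stars = significance_stars(res$p.value),
    mean_a = mean(values_a), mean_b = mean(values_b),
    n_a = length(values_a), n_b = length(values_b)
  )
}
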