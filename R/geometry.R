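#' ER lattice geometries
#'
#' The endoplasmic reticulum lumen is represented as a 2D lattice graph:
#' each luminal site is a (row, col) cell (0-based), and sites at Manhattan
#' distance 1 are joined by an undirected edge (4-neighbour adjacency).
#' A connected reticulum is a single connected component; fragmented ER is a
#' set of walled-off cisternae, i.e. several components with no edges between
#' them. Luminal probes can only diffuse along edges, so connectivity fully
#' determines which regions a photobleaching protocol can deplete.
#'
#' An `er_geometry` is a list with
#' * `sites`: tibble with `site_id`, `row`, `col`, `component_id`
#' * `edges`: tibble with `from`, `to` (site ids, `from < to`)
#' * `n_rows`, `n_cols`: bounding lattice dimensions
#'
#' @name er_geometry
NULL

new_er_geometry <- function(sites, edges, n_rows, n_cols) {
  structure(
    list(sites = sites, edges = edges,
         n_rows = as.integer(n_rows), n_cols = as.integer(n_cols)),
    class = "er_geometry"
  )
}

# 4-neighbour edges among an arbitrary site set; sites keyed by row/col.
lattice_edges <- function(sites) {
  key <- paste(sites$row, sites$col)
  idx <- stats::setNames(sites$site_id, key)
  right <- idx[paste(sites$row, sites$col + 1L)]
  down <- idx[paste(sites$row + 1L, sites$col)]
  tibble(
    from = rep(sites$site_id, 2L),
    to = c(unname(right), unname(down))
  ) |>
    dplyr::filter(!is.na(.data$to)) |>
    dplyr::mutate(
      lo = pmin(.data$from, .data$to),
      hi = pmax(.data$from, .data$to)
    ) |>
    dplyr::transmute(from = .data$lo, to = .data$hi) |>
    dplyr::arrange(.data$from, .data$to)
}

# Breadth-first flood fill over an edge list; returns per-site component id.
label_components_bfs <- function(n_sites, edges) {
  adj <- vector("list", n_sites)
  if (nrow(edges) > 0) {
    adj_from <- split(edges$to, edges$from)
    adj_to <- split(edges$from, edges$to)
    for (k in names(adj_from)) adj[[as.integer(k)]] <- c(adj[[as.integer(k)]], adj_from[[k]])
    for (k in names(adj_to)) adj[[as.integer(k)]] <- c(adj[[as.integer(k)]], adj_to[[k]])
  }
  comp <- integer(n_sites)
  current <- 0L
  for (s in seq_len(n_sites)) {
    if (comp[s] != 0L) next
    current <- current + 1L
    queue <- s
    comp[s] <- current
    while (length(queue) > 0) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- adj[[v]]
      nb <- nb[comp[nb] == 0L]
      comp[nb] <- current
      queue <- c(queue, nb)
    }
  }
  comp
}

finish_geometry <- function(sites, n_rows, n_cols) {
  sites$site_id <- seq_len(nrow(sites))
  edges <- lattice_edges(sites)
  sites$component_id <- label_components_bfs(nrow(sites), edges)
  new_er_geometry(sites[, c("site_id", "row", "col", "component_id")],
                  edges, n_rows, n_cols)
}

#' Construct a fully connected reticular ER geometry
#'
#' Builds a complete `n_rows` x `n_cols` lattice: every cell is a luminal
#' site and the 4-neighbour adjacency is complete, giving a single connected
#' component. This is the geometry of a normal, tubular reticulum in which
#' luminal probes can reach every region by diffusion.
#'
#' @param n_rows,n_cols Positive lattice dimensions.
#' @return An [er_geometry] with one connected component.
#' @export
#' @examples
#' g <- make_reticular_geometry(5, 8)
#' max(g$sites$component_id) # 1
make_reticular_geometry <- function(n_rows, n_cols) {
  n_rows <- assert_count(n_rows, "n_rows", min = 1L, class = "erfrag_dimension_error")
  n_cols <- assert_count(n_cols, "n_cols", min = 1L, class = "erfrag_dimension_error")
  sites <- tidyr::expand_grid(row = seq_len(n_rows) - 1L, col = seq_len(n_cols) - 1L)
  finish_geometry(as.data.frame(sites), n_rows, n_cols)
}

#' Construct a fragmented ER geometry of isolated inclusions
#'
#' Places `n_inclusions` square blocks of luminal sites in a column, separated
#' by at least one empty lattice row so no edge can join two blocks; each
#' block is therefore its own connected component (a walled-off cisterna).
#' Optionally a residual reticulum strip is appended below the inclusions as
#' one further component, emulating the leftover tubular network of an
#' inclusion-bearing cell.
#'
#' @param n_inclusions Number of inclusion blocks (>= 1).
#' @param inclusion_side_lengths Integer vector of block side lengths,
#'   recycled to `n_inclusions`.
#' @param include_residual_reticulum Append a connected residual strip?
#' @param residual_rows,residual_cols Size of the residual strip.
#' @return An [er_geometry] with `n_inclusions` (+1 if residual) components.
#' @export
#' @examples
#' g <- make_fragmented_geometry(3, c(2, 2, 2), include_residual_reticulum = TRUE)
#' max(g$sites$component_id) # 4
make_fragmented_geometry <- function(n_inclusions, inclusion_side_lengths,
                                     include_residual_reticulum = FALSE,
                                     residual_rows = 2L, residual_cols = 10L) {
  n_inclusions <- assert_count(n_inclusions, "n_inclusions", min = 1L)
  sides <- rep_len(as.integer(inclusion_side_lengths), n_inclusions)
  if (any(sides < 1L)) {
    stop_erfrag("inclusion side lengths must be >= 1.", "erfrag_placement_error")
  }
  blocks <- vector("list", n_inclusions)
  row0 <- 0L
  for (i in seq_len(n_inclusions)) {
    s <- sides[[i]]
    blocks[[i]] <- expand.grid(row = row0 + seq_len(s) - 1L, col = seq_len(s) - 1L)
    row0 <- row0 + s + 1L # >=1 empty row between blocks: no cross-block edge
  }
  if (include_residual_reticulum) {
    blocks[[n_inclusions + 1L]] <- expand.grid(
      row = row0 + seq_len(residual_rows) - 1L,
      col = seq_len(residual_cols) - 1L
    )
    row0 <- row0 + residual_rows
  }
  sites <- do.call(rbind, blocks)
  finish_geometry(sites, n_rows = row0, n_cols = max(sites$col) + 1L)
}

#' @export
print.er_geometry <- function(x, ...) {
  cat(sprintf(
    "<er_geometry> %d sites, %d edges, %d component(s) on a %d x %d lattice\n",
    nrow(x$sites), nrow(x$edges), max(x$sites$component_id), x$n_rows, x$n_cols
  ))
  invisible(x)
}

# Site ids inside a half-open ROI rectangle [r0, r1) x [c0, c1).
sites_in_roi <- function(geometry, roi) {
  with(geometry$sites,
       site_id[row >= roi[["r0"]] & row < roi[["r1"]] &
               col >= roi[["c0"]] & col < roi[["c1"]]])
}

#' Define a rectangular region of interest on the lattice
#'
#' ROIs are half-open rectangles `[r0, r1) x [c0, c1)` in 0-based lattice
#' coordinates, the same convention used throughout the trace files.
#'
#' @param r0,r1,c0,c1 Rectangle bounds, `r0 < r1`, `c0 < c1`.
#' @return Named numeric vector of class `er_roi`.
#' @export
roi_rect <- function(r0, r1, c0, c1) {
  if (r0 >= r1 || c0 >= c1) {
    stop_erfrag("ROI must satisfy r0 < r1 and c0 < c1.", "erfrag_geometry_error")
  }
  structure(c(r0 = r0, r1 = r1, c0 = c0, c1 = c1), class = "er_roi")
}
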