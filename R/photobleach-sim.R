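#' Photobleaching protocols
#'
#' A protocol declares the bleach region of interest, the pulse schedule and
#' the acquisition frame interval. FRAP uses a single pulse followed by
#' recovery monitoring; FLIP uses repeated pulses of the same region while
#' distant regions are monitored for shared depletion.
#'
#' @param roi Bleach region, from [roi_rect()].
#' @param mode `"FRAP"` (exactly one pulse) or `"FLIP"` (two or more pulses).
#' @param pulse_times Strictly increasing pulse times in seconds.
#' @param bleach_efficiency Probability in \[0, 1\] that a particle inside the
#'   ROI during a pulse is converted to the bleached (dark) state.
#' @param frame_interval Acquisition interval in seconds.
#' @return A `bleach_protocol` list.
#' @export
bleach_protocol <- function(roi, mode = c("FRAP", "FLIP"), pulse_times,
                            bleach_efficiency = 1, frame_interval = 0.5) {
  mode <- match.arg(mode)
  if (!inherits(roi, "er_roi")) stop_erfrag("`roi` must come from roi_rect().", "erfrag_geometry_error")
  if (length(pulse_times) < 1L || any(diff(pulse_times) <= 0) || any(pulse_times < 0)) {
    stop_erfrag("`pulse_times` must be non-negative and strictly increasing.",
                "erfrag_protocol_error")
  }
  if (mode == "FRAP" && length(pulse_times) != 1L) {
    stop_erfrag("FRAP protocols have exactly one pulse.", "erfrag_protocol_error")
  }
  if (mode == "FLIP" && length(pulse_times) < 2L) {
    stop_erfrag("FLIP protocols need at least two pulses.", "erfrag_protocol_error")
  }
  assert_scalar_number(bleach_efficiency, "bleach_efficiency", 0, 1)
  assert_scalar_number(frame_interval, "frame_interval", 1e-9, Inf)
  structure(
    list(roi = roi, mode = mode, pulse_times = as.numeric(pulse_times),
         bleach_efficiency = bleach_efficiency, frame_interval = frame_interval),
    class = "bleach_protocol"
  )
}

#' Simulate FLIP/FRAP photobleaching on an ER lattice
#'
#' Luminal fluorophores are modelled as discrete particles on the geometry's
#' lattice sites. A fraction (`immobile_fraction`) is immobile; mobile
#' particles perform a symmetric random walk on the 4-neighbour adjacency,
#' hopping to a uniformly chosen neighbour with probability `diffusion` per
#' frame. Bleach pulses convert particles inside the bleach ROI to a dark
#' state with probability `bleach_efficiency`; bleached particles keep
#' diffusing but no longer contribute signal. No particle is ever created or
#' destroyed, so total (bleached + unbleached) counts are conserved exactly,
#' and particles can never cross between connected components — the physical
#' content of the walled-off cisterna phenotype.
#'
#' Each monitored ROI yields one intensity trace: the per-frame sum of
#' unbleached particles inside the ROI plus additive Gaussian measurement
#' noise with standard deviation `noise_sd` times the ROI's expected
#' pre-bleach signal.
#'
#' @param geometry An [er_geometry].
#' @param protocol A [bleach_protocol()].
#' @param rois Named list of monitored ROIs ([roi_rect()]); the bleach ROI is
#'   monitored automatically as `"bleach"` unless a ROI named `"bleach"` is
#'   supplied.
#' @param total_time Total simulated time in seconds.
#' @param particles_per_site Initial fluorophore count per site.
#' @param diffusion Hop probability per frame in \[0, 1\]. The default 0.8 is
#'   deliberately below 1: at exactly 1 the walk on the bipartite lattice is
#'   periodic and its long-run occupancies deviate from the lazy-walk
#'   stationary distribution.
#' @param immobile_fraction Fraction of particles that never move.
#' @param noise_sd Measurement noise sd, relative to pre-bleach ROI signal.
#' @param seed Integer seed; required for reproducibility.
#' @return A tibble with columns `time_s`, `frame`, `roi_id`, `intensity`,
#'   `is_bleach_frame`, carrying attributes `truth` (ground-truth metadata)
#'   and `conservation` (per-frame particle totals).
#' @export
simulate_photobleach <- function(geometry, protocol, rois = list(),
                                 total_time, particles_per_site = 20L,
                                 diffusion = 0.8, immobile_fraction = 0,
                                 noise_sd = 0, seed) {
  stopifnot(inherits(geometry, "er_geometry"), inherits(protocol, "bleach_protocol"))
  if (missing(seed)) stop_erfrag("`seed` must be supplied.", "erfrag_parameter_error")
  assert_scalar_number(diffusion, "diffusion", 0, 1)
  assert_scalar_number(immobile_fraction, "immobile_fraction", 0, 1)
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop_erfrag("`noise_sd` must be >= 0.", "erfrag_parameter_error")
  }
  particles_per_site <- assert_count(particles_per_site, "particles_per_site", min = 1L)

  if (!("bleach" %in% names(rois))) rois <- c(list(bleach = protocol$roi), rois)
  roi_sites <- lapply(rois, function(r) sites_in_roi(geometry, r))
  if (any(lengths(roi_sites) == 0L)) {
    stop_erfrag("every ROI must contain at least one lattice site.", "erfrag_geometry_error")
  }

  n_sites <- nrow(geometry$sites)
  # neighbour table: row = site, up to 4 neighbours
  deg <- integer(n_sites)
  nbr <- matrix(NA_integer_, n_sites, 4L)
  if (nrow(geometry$edges) > 0) {
    for (i in seq_len(nrow(geometry$edges))) {
      a <- geometry$edges$from[[i]]; b <- geometry$edges$to[[i]]
      deg[a] <- deg[a] + 1L; nbr[a, deg[a]] <- b
      deg[b] <- deg[b] + 1L; nbr[b, deg[b]] <- a
    }
  }

  set.seed(as.integer(seed))
  n_particles <- n_sites * particles_per_site
  site <- rep(geometry$sites$site_id, each = particles_per_site)
  bleached <- rep(FALSE, n_particles)
  mobile <- stats::runif(n_particles) >= immobile_fraction

  frame_times <- seq(0, total_time, by = protocol$frame_interval)
  n_frames <- length(frame_times)
  # a pulse fires at the first frame whose time >= the pulse time
  pulse_frame <- vapply(protocol$pulse_times,
                        function(tp) which(frame_times >= tp - 1e-12)[1L], integer(1))
  if (anyNA(pulse_frame)) {
    stop_erfrag("every pulse time must fall within `total_time`.", "erfrag_protocol_error")
  }
  is_pulse <- seq_len(n_frames) %in% pulse_frame
  bleach_sites <- roi_sites[["bleach"]]
  in_bleach <- rep(FALSE, n_sites); in_bleach[bleach_sites] <- TRUE

  roi_masks <- lapply(roi_sites, function(s) { m <- rep(FALSE, n_sites); m[s] <- TRUE; m })
  signal <- matrix(0, n_frames, length(rois), dimnames = list(NULL, names(rois)))
  conservation <- matrix(0L, n_frames, 2L, dimnames = list(NULL, c("unbleached", "bleached")))

  movable <- which(mobile & deg[site] > 0L)
  for (f in seq_len(n_frames)) {
    if (f > 1L) { # diffusion step between frames
      u <- stats::runif(length(movable))
      movers <- movable[u < diffusion]
      if (length(movers) > 0) {
        s <- site[movers]
        pick <- 1L + as.integer(floor(stats::runif(length(movers)) * deg[s]))
        site[movers] <- nbr[cbind(s, pick)]
      }
    }
    if (is_pulse[[f]]) {
      hit <- in_bleach[site] & !bleached
      if (protocol$bleach_efficiency >= 1) {
        bleached[hit] <- TRUE
      } else {
        idx <- which(hit)
        bleached[idx[stats::runif(length(idx)) < protocol$bleach_efficiency]] <- TRUE
      }
    }
    for (j in seq_along(rois)) {
      signal[f, j] <- sum(roi_masks[[j]][site] & !bleached)
    }
    conservation[f, 1L] <- sum(!bleached)
    conservation[f, 2L] <- sum(bleached)
  }

  traces <- tidyr::expand_grid(roi_id = names(rois), frame = seq_len(n_frames)) |>
    dplyr::mutate(
      time_s = frame_times[.data$frame],
      intensity = signal[cbind(.data$frame, match(.data$roi_id, colnames(signal)))],
      is_bleach_frame = is_pulse[.data$frame]
    )
  if (noise_sd > 0) {
    pre_signal <- particles_per_site * lengths(roi_sites)[traces$roi_id]
    traces$intensity <- traces$intensity +
      stats::rnorm(nrow(traces), sd = noise_sd * pre_signal)
  }
  traces <- traces[, c("time_s", "frame", "roi_id", "intensity", "is_bleach_frame")]

  attr(traces, "truth") <- list(
    immobile_fraction = immobile_fraction,
    diffusion = diffusion,
    particles_per_site = particles_per_site,
    component_id = geometry$sites$component_id,
    roi_components = lapply(roi_sites, function(s)
      sort(unique(geometry$sites$component_id[s]))),
    seed = as.integer(seed),
    protocol = protocol
  )
  attr(traces, "conservation") <- tibble(
    frame = seq_len(n_frames),
    unbleached = conservation[, 1L],
    bleached = conservation[, 2L]
  )
  traces
}
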