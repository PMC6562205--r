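# Plain-text interchange: TSV tables and JSON reports. Coordinates in all
# files are 0-based; ROIs are half-open rectangles [r0, r1) x [c0, c1).

#' Write and read photobleach traces as TSV
#'
#' Columns `time_s`, `frame`, `roi_id`, `intensity`, `is_bleach_frame`; a
#' JSON sidecar (same path with extension `.json`) records the seed,
#' protocol and ground-truth metadata when the traces carry them.
#'
#' @param traces Trace tibble from [simulate_photobleach()].
#' @param path Output TSV path.
#' @param sidecar Write the metadata sidecar?
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path, sidecar = TRUE) {
  readr::write_tsv(traces, path)
  truth <- attr(traces, "truth")
  if (sidecar && !is.null(truth)) {
    meta <- list(
      seed = truth$seed,
      immobile_fraction = truth$immobile_fraction,
      diffusion = truth$diffusion,
      particles_per_site = truth$particles_per_site,
      protocol = list(
        mode = truth$protocol$mode,
        roi = as.list(unclass(truth$protocol$roi)),
        pulse_times = truth$protocol$pulse_times,
        bleach_efficiency = truth$protocol$bleach_efficiency,
        frame_interval = truth$protocol$frame_interval
      ),
      coordinate_convention = "0-based; ROI half-open [r0,r1)x[c0,c1)"
    )
    jsonlite::write_json(meta, sub("\\.tsv$", ".json", path),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_traces
#' @return `read_traces()`: the trace tibble.
#' @export
read_traces <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    time_s = "d", frame = "i", roi_id = "c",
                    intensity = "d", is_bleach_frame = "l"
                  ))
}

#' Write a counts table and its group assignment as TSV
#'
#' @param counts Tibble with `gene_id` + sample columns.
#' @param groups Tibble with `sample_id`, `condition`.
#' @param path Counts TSV path; groups are written next to it with suffix
#'   `_groups.tsv`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, groups, path) {
  readr::write_tsv(counts, path)
  readr::write_tsv(groups, sub("\\.tsv$", "_groups.tsv", path))
  invisible(path)
}

#' @rdname write_counts
#' @return `read_counts()`: list of `counts` and `groups` tibbles.
#' @export
read_counts <- function(path) {
  list(
    counts = readr::read_tsv(path, show_col_types = FALSE),
    groups = readr::read_tsv(sub("\\.tsv$", "_groups.tsv", path),
                             show_col_types = FALSE)
  )
}

#' Write a JSON report
#'
#' Scalars are unboxed and numbers written at full precision.
#'
#' @param report Named list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
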