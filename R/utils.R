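#' @importFrom rlang .data abort warn
#' @importFrom tibble tibble as_tibble
#' @keywords internal
"_PACKAGE"

# Stop with a classed condition so callers can test on the error class.
stop_erfrag <- function(msg, class) {
  rlang::abort(msg, class = c(class, "erfrag_error"))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 class = "erfrag_parameter_error") {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop_erfrag(
      sprintf("`%s` must be a single finite number in [%s, %s].", name, lower, upper),
      class
    )
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0L, class = "erfrag_parameter_error") {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != as.integer(x) || x < min) {
    stop_erfrag(sprintf("`%s` must be an integer >= %d.", name, min), class)
  }
  invisible(as.integer(x))
}

#' Map a p value to the significance-star convention used in the figures
#'
#' The mapping is n.s. for p >= 0.05, `*` for p < 0.05, `**` for p <= 0.01,
#' `***` for p < 0.001 and `****` for p <= 0.0001, evaluated from the most
#' stringent level down.
#'
#' @param p Numeric vector of p values in \[0, 1\].
#' @return Character vector of star labels.
#' @export
#' @examples
#' significance_stars(c(0.2, 0.03, 0.009, 5e-4, 1e-5))
significance_stars <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop_erfrag("p values must lie in [0, 1].", "erfrag_input_error")
  }
  dplyr::case_when(
    p <= 1e-4 ~ "****",
    p < 1e-3 ~ "***",
    p <= 1e-2 ~ "**",
    p < 5e-2 ~ "*",
    TRUE ~ "n.s."
  )
}

#' Round a proportion to an integer percentage, half away from zero
#'
#' Reported percentages use round-half-away-from-zero (so 29.5 -> 30,
#' -29.5 -> -30), matching how the summary tables round, e.g. 5/17 -> 29%.
#'
#' @param x Numeric vector of proportions (1 = 100%).
#' @return Integer percentages.
#' @export
#' @examples
#' percent_round(5 / 17) # 29
percent_round <- function(x) {
  pct <- 100 * x
  as.integer(sign(pct) * floor(abs(pct) + 0.5))
}

# Derive a reproducible sub-seed (< 2^31) from a master seed and a stage tag,
# so pipeline stages can be toggled without perturbing one another's draws.
derive_seed <- function(seed, tag) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}
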