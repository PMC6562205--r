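test_that("pre-bleach normalization rescales to 100% and is idempotent", {
  tr <- tibble::tibble(
    time_s = c(0, 1, 2, 3), frame = 1:4, roi_id = "r1",
    intensity = c(200, 200, 50, 100),
    is_bleach_frame = c(FALSE, FALSE, FALSE, TRUE)
  )
  # needs >= 3 pre-bleach frames: shift bleach to frame 4
  tr$intensity <- c(200, 200, 200, 200)
  expect_equal(normalize_prebleach(tr)$intensity, c(100, 100, 100, 100))

  tr2 <- tibble::tibble(
    time_s = 0:4, frame = 1:5, roi_id = "r1",
    intensity = c(200, 200, 200, 50, 100),
    is_bleach_frame = c(FALSE, FALSE, FALSE, TRUE, FALSE)
  )
  expect_equal(normalize_prebleach(tr2)$intensity, c(100, 100, 100, 25, 50))

  once <- normalize_prebleach(tr2)
  expect_equal(normalize_prebleach(once)$intensity, once$intensity)

  # scale invariance under any positive constant
  for (const in c(0.25, 3, 1700)) {
    scaled <- dplyr::mutate(tr2, intensity = intensity * const)
    expect_equal(normalize_prebleach(scaled)$intensity, once$intensity)
  }

  bad <- dplyr::mutate(tr2, intensity = 0)
  expect_error(normalize_prebleach(bad), class = "erfrag_normalization_error")
  short <- tr2[3:5, ]
  expect_error(normalize_prebleach(short), class = "erfrag_normalization_error")
})

test_that("recovery fit reproduces closed-form parameters and mobile fraction", {
  tr <- make_exp_frap_trace(F0 = 20, plateau = 92, k = 0.5)
  fit <- fit_frap(normalize_prebleach(tr))
  expect_equal(fit$F0, 20, tolerance = 1e-6)
  expect_equal(fit$plateau, 92, tolerance = 1e-6)
  expect_equal(fit$k, 0.5, tolerance = 1e-6)
  expect_equal(fit$mobile_fraction, (92 - 20) / (100 - 20), tolerance = 1e-6)
  expect_false(fit$mobile_fraction_clipped)
  td <- tidy(fit)
  expect_equal(td$plateau, fit$plateau)
  expect_true(glance(fit)$converged)
})

test_that("a flat post-bleach trace yields zero mobile fraction and a flagged rate", {
  tr <- make_exp_frap_trace(F0 = 20, plateau = 92, k = 0.5)
  flat <- dplyr::mutate(tr, intensity = ifelse(frame >= 4, 20, intensity))
  fit <- suppressWarnings(fit_frap(normalize_prebleach(flat)))
  expect_equal(fit$mobile_fraction, 0, tolerance = 1e-9)
  expect_false(fit$k_identifiable)
})

test_that("the estimator recovers the generator's mobile fraction on lattice traces", {
  g <- make_reticular_geometry(24, 24)
  proto <- bleach_protocol(roi_rect(4, 8, 4, 8), "FRAP", pulse_times = 3,
                           frame_interval = 0.5)
  est <- vapply(1:10, function(s) {
    tr <- simulate_photobleach(g, proto, total_time = 500,
                               particles_per_site = 20,
                               immobile_fraction = 0.65, noise_sd = 0.02,
                               seed = 300 + s)
    fit_frap(normalize_prebleach(tr))$mobile_fraction
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.35), 0.05)
})

test_that("mobile-fraction error stays within 0.05 across an immobile-fraction grid", {
  g <- make_reticular_geometry(24, 24)
  proto <- bleach_protocol(roi_rect(4, 8, 4, 8), "FRAP", pulse_times = 3,
                           frame_interval = 0.5)
  for (im in c(0, 0.25, 0.5, 0.65, 0.9)) {
    est <- vapply(1:2, function(s) {
      tr <- simulate_photobleach(g, proto, total_time = 500,
                                 particles_per_site = 20,
                                 immobile_fraction = im, noise_sd = 0.02,
                                 seed = 1000 * s + round(100 * im))
      fit_frap(normalize_prebleach(tr))$mobile_fraction
    }, numeric(1))
    expect_lt(abs(mean(est) - (1 - im)), 0.05)
  }
})

test_that("initial recovery slope discriminates connected from fragmented ER", {
  conn <- make_reticular_geometry(16, 16)
  frag <- make_fragmented_geometry(1, 6, include_residual_reticulum = TRUE)
  proto_conn <- bleach_protocol(roi_rect(3, 6, 3, 6), "FRAP", pulse_times = 3,
                                frame_interval = 0.5)
  proto_frag <- bleach_protocol(roi_rect(0, 3, 0, 3), "FRAP", pulse_times = 3,
                                frame_interval = 0.5)
  slope_of <- function(geometry, proto, immobile, seed) {
    tr <- simulate_photobleach(geometry, proto, total_time = 80,
                               particles_per_site = 20,
                               immobile_fraction = immobile, noise_sd = 0.02,
                               seed = seed)
    fit_frap(normalize_prebleach(tr))$initial_slope
  }
  s_conn <- vapply(1:10, function(s) slope_of(conn, proto_conn, 0.10, 40 + s),
                   numeric(1))
  s_frag <- vapply(1:10, function(s) slope_of(frag, proto_frag, 0.65, 80 + s),
                   numeric(1))
  expect_gt(mean(s_conn), mean(s_frag))
})

test_that("group comparison matches the pooled-variance formula and star scheme", {
  res <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_equal(res$stars, "n.s.")

  res2 <- compare_groups(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_equal(res2$t, -1.095, tolerance = 1e-3)
  expect_equal(res2$df, 6)

  expect_equal(significance_stars(0.009), "**")
  expect_equal(significance_stars(c(0.2, 0.04, 0.0009, 0.00005)),
               c("n.s.", "*", "***", "****"))

  # oracle equivalence: hand pooled-variance t on 100 random inputs
  set.seed(7)
  for (i in 1:100) {
    a <- rnorm(sample(2:10, 1)); b <- rnorm(sample(2:10, 1), mean = runif(1, -1, 1))
    res <- compare_groups(a, b)
    na <- length(a); nb <- length(b)
    sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
    t_oracle <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    p_oracle <- 2 * pt(abs(t_oracle), na + nb - 2, lower.tail = FALSE)
    expect_equal(res$t, t_oracle, tolerance = 1e-10)
    expect_equal(res$p, p_oracle, tolerance = 1e-10)
  }

  expect_error(compare_groups(1, c(1, 2)), class = "erfrag_input_error")
})
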