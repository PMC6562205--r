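test_that("fate fractions are rate shares that always sum to one", {
  expect_equal(fate_fractions(0.70, 0.15, 0.15),
               tibble::tibble(f_deg = 0.70, f_sec = 0.15, f_ret = 0.15))
  expect_equal(fate_fractions(1, 0, 0),
               tibble::tibble(f_deg = 1, f_sec = 0, f_ret = 0))
  expect_error(fate_fractions(0, 0, 0), class = "erfrag_parameter_error")

  set.seed(2)
  for (i in 1:1000) {
    r <- runif(3, 0, 5)
    fr <- fate_fractions(r[1], r[2], r[3])
    expect_equal(fr$f_deg + fr$f_sec + fr$f_ret, 1, tolerance = 1e-12)
  }
})

test_that("the generator matches the analytic solution and conserves mass", {
  pc <- generate_pulse_chase(0.70, 0.15, 0.15, label0 = 100,
                             chase_times = c(0, 0.5, 1, 2, 4, 8, 20))
  expect_equal(pc$lysate_signal[1], 100)
  expect_equal(pc$supernatant_signal[1], 0)

  # independent RK4 integration of the ODE system
  for (j in c(2, 4, 6)) {
    y <- rk4_pulse_chase(0.70, 0.15, 0.15, 100, pc$time_h[j])
    expect_equal(pc$lysate_signal[j], unname(y["free"] + y["ret"]),
                 tolerance = 1e-8)
    expect_equal(pc$supernatant_signal[j], unname(y["sec"]), tolerance = 1e-8)
    expect_equal(pc$degraded_unobserved[j], unname(y["deg"]), tolerance = 1e-8)
  }
  # mass balance at every time point
  total <- pc$lysate_signal + pc$supernatant_signal + pc$degraded_unobserved
  expect_equal(total, rep(100, nrow(pc)), tolerance = 1e-9)

  # long-time pools approach the analytic fate partition
  late <- generate_pulse_chase(0.70, 0.15, 0.15, chase_times = c(0, 50, 100))
  expect_equal(late$supernatant_signal[3] / 100, 0.15, tolerance = 1e-9)
  expect_equal(late$lysate_signal[3] / 100, 0.15, tolerance = 1e-9)
  expect_equal(late$degraded_unobserved[3] / 100, 0.70, tolerance = 1e-9)

  expect_error(generate_pulse_chase(0, 0, 0), class = "erfrag_parameter_error")
  expect_error(generate_pulse_chase(1, 1, 1, chase_times = c(2, 1)),
               class = "erfrag_parameter_error")
})

test_that("the fitter recovers rates and fractions from noiseless data", {
  pc <- generate_pulse_chase(0.70, 0.15, 0.15, label0 = 100,
                             chase_times = c(0, 0.5, 1, 1.5, 2, 3, 4, 6))
  fit <- fit_pulse_chase(pc)
  expect_lt(abs(fit$f_deg - 0.70), 1e-6)
  expect_lt(abs(fit$f_sec - 0.15), 1e-6)
  expect_lt(abs(fit$f_ret - 0.15), 1e-6)
  expect_true(fit$identifiable)
  expect_equal(fit$f_deg + fit$f_sec + fit$f_ret, 1, tolerance = 1e-9)

  # fitted model obeys mass balance at the observed times
  cur <- erfrag:::pulse_chase_curves(pc$time_h, fit$label0, fit$k_deg,
                                     fit$k_sec, fit$k_ret)
  expect_equal(cur$lysate + cur$supernatant + cur$degraded,
               rep(fit$label0, nrow(pc)), tolerance = 1e-9)

  no_sec <- generate_pulse_chase(0.5, 0, 0.2, chase_times = c(0, 1, 2, 4))
  expect_true(all(no_sec$supernatant_signal == 0))
  fit2 <- fit_pulse_chase(no_sec)
  expect_equal(fit2$f_sec, 0, tolerance = 1e-6)
})

test_that("fractions are recovered within 0.05 at 2% noise on the 0-4 h schedule", {
  est <- purrr::map_dfr(1:20, function(s) {
    pc <- generate_pulse_chase(0.70, 0.15, 0.15, chase_times = c(0, 1, 2, 4),
                               noise_sd = 0.02, seed = 900 + s)
    tidy(fit_pulse_chase(pc))
  })
  expect_lt(abs(mean(est$f_deg) - 0.70), 0.05)
  expect_lt(abs(mean(est$f_sec) - 0.15), 0.05)
  expect_lt(abs(mean(est$f_ret) - 0.15), 0.05)
})

test_that("a non-decaying lysate is flagged non-identifiable", {
  flat <- tibble::tibble(time_h = c(0, 1, 2, 4),
                         lysate_signal = c(100, 101, 99, 100),
                         supernatant_signal = c(0, 0.1, 0.2, 0.1))
  fit <- fit_pulse_chase(flat)
  expect_false(fit$identifiable)
  expect_error(fit_pulse_chase(flat[1:2, ]), class = "erfrag_input_error")
})
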