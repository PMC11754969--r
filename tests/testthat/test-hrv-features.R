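test_that("time-domain features match hand-computed values", {
  const <- rep(800, 375)
  td <- time_domain_features(const)
  expect_equal(td$mean_rri, 0.8)
  expect_equal(td$sdnn, 0)
  expect_equal(td$rmssd, 0)
  expect_equal(td$pnn50, 0)
  expect_equal(td$tri, 1)

  alt10 <- rep(c(800, 810), 100)
  td10 <- time_domain_features(alt10)
  expect_equal(td10$rmssd, 10)
  expect_equal(td10$pnn50, 0)

  alt60 <- rep(c(800, 860), 100)
  expect_equal(time_domain_features(alt60)$pnn50, 100)

  expect_error(time_domain_features(800), "at least 2")
})

test_that("triangular index and TINN behave on known histograms", {
  # all mass in one 1/128-s bin: TRI = 1, degenerate TINN = 0
  expect_equal(time_domain_features(rep(800, 50))$tinn, 0)
  # a symmetric triangular histogram has TINN close to its base width
  set.seed(3)
  x <- 800 + round(rnorm(5000, 0, 25))
  td <- time_domain_features(x)
  expect_gt(td$tinn, 50)
  expect_lt(td$tinn, 250)
  expect_gt(td$tri, 1)
})

test_that("spectral features localise oscillator power in the right bands", {
  cfg <- cohort_config(noise_sd_ms = 0)
  st <- list(participant_id = "P1", group = "HC", base = 850, a_lf = 0,
             a_hf = 30, f_lf = 0.095, f_hf = 0.25,
             reactivity = list(rri = 0, hf = 0, lf = 0))
  set.seed(2)
  hf_only <- simulate_phase_rri(st, 0, 1, "rest1", cfg)$intervals_ms
  sp <- spectral_features(hf_only)
  expect_gt(sp$hf_nu, 90)
  expect_lt(sp$lf_hf, 0.1)

  st$a_lf <- 40
  st$a_hf <- 0
  set.seed(2)
  lf_only <- simulate_phase_rri(st, 0, 1, "rest1", cfg)$intervals_ms
  sp2 <- spectral_features(lf_only)
  expect_gt(sp2$lf_nu, 90)

  # normalised units are complementary on any input
  st$a_hf <- 25
  for (seed in 1:5) {
    set.seed(seed)
    s <- simulate_phase_rri(st, 0, 1, "rest1", cohort_config(noise_sd_ms = 10))
    spx <- spectral_features(s$intervals_ms)
    expect_equal(spx$lf_nu + spx$hf_nu, 100, tolerance = 1e-9)
  }
  expect_error(spectral_features(rep(800, 20)), "60 s")
})

test_that("log total power responds to overall variability", {
  cfg <- cohort_config(noise_sd_ms = 5)
  mk <- function(scale, seed) {
    set.seed(seed)
    st <- list(participant_id = "P1", group = "HC", base = 850,
               a_lf = 40 * scale, a_hf = 30 * scale, f_lf = 0.095, f_hf = 0.25,
               reactivity = list(rri = 0, hf = 0, lf = 0))
    simulate_phase_rri(st, 0, 1, "rest1", cfg)$intervals_ms
  }
  for (seed in 1:3) {
    expect_gt(spectral_features(mk(2, seed))$log_tot,
              spectral_features(mk(1, seed))$log_tot)
  }
})

test_that("Poincare descriptors satisfy their algebraic identities", {
  pc <- poincare(rep(800, 50))
  expect_equal(pc$sd1, 0)
  expect_equal(pc$sd2, 0)

  alt <- rep(c(800, 810), 100)
  expect_equal(poincare(alt)$sd1, 10 / sqrt(2), tolerance = 1e-9)

  set.seed(7)
  for (i in 1:10) {
    x <- 800 + cumsum(rnorm(200, 0, 10))
    pc <- poincare(x)
    td <- time_domain_features(x)
    expect_equal(pc$sd1, td$rmssd / sqrt(2), tolerance = 1e-9)
    expect_equal(pc$sd1^2 + pc$sd2^2, 2 * td$sdnn^2, tolerance = 1e-6)
  }
})

test_that("the full battery is complete, canonical and deterministic", {
  cfg <- cohort_config(n_per_group = c(MDD = 0, PD = 0, HC = 1), n_visits = 1,
                       retention_prob = 1, seed = 31)
  s <- generate_cohort(cfg)[[1]]
  f1 <- extract_features(s)
  f2 <- extract_features(s)
  expect_identical(f1, f2)
  expect_identical(names(f1), hrv_feature_names())
  expect_length(f1, 20L)
  expect_true(all(is.finite(f1)))

  fc <- extract_features(rep(800, 375))
  expect_equal(unname(fc[c("apen", "sampen", "sd1", "sd2", "cordim")]),
               rep(0, 5))
  expect_equal(unname(fc["tri"]), 1)
})

test_that("sample entropy does not decrease with beat-to-beat noise", {
  sampen_at <- function(noise, seed) {
    set.seed(seed)
    st <- list(participant_id = "P1", group = "HC", base = 850, a_lf = 40,
               a_hf = 30, f_lf = 0.095, f_hf = 0.25,
               reactivity = list(rri = 0, hf = 0, lf = 0))
    cfg <- cohort_config(noise_sd_ms = noise, phase_duration_s = 150)
    sample_entropy(simulate_phase_rri(st, 0, 1, "rest1", cfg)$intervals_ms)
  }
  noises <- c(2, 5, 10, 20, 40)
  rhos <- vapply(1:20, function(seed) {
    se <- vapply(noises, sampen_at, 0, seed = seed)
    cor(noises, se, method = "spearman")
  }, 0)
  expect_gt(mean(rhos), 0)
  expect_gt(mean(rhos > 0), 0.8)
})

test_that("cohort-level extraction tags failures and yields one row per series", {
  cfg <- cohort_config(n_per_group = c(MDD = 1, PD = 1, HC = 1), n_visits = 1,
                       retention_prob = 1, seed = 17)
  co <- generate_cohort(cfg)
  ft <- extract_cohort_features(co)
  expect_identical(nrow(ft), length(co))
  expect_identical(names(ft), c("participant", "group", "visit", "phase",
                                hrv_feature_names()))
  # short series abort with the offending series named
  co[[2]]$intervals_ms <- co[[2]]$intervals_ms[1:20]
  expect_error(suppressWarnings(extract_cohort_features(co)),
               co[[2]]$participant_id)
})
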