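test_that("cohort generation respects structure, keys and determinism", {
  cfg <- cohort_config(n_per_group = c(MDD = 1, PD = 0, HC = 0), n_visits = 1,
                       phase_duration_s = 60, retention_prob = 1, seed = 5)
  co <- generate_cohort(cfg)
  expect_length(co, 5L)
  expect_setequal(vapply(co, function(s) s$phase, ""), PHASES <- c("rest1", "stress", "rest2", "relaxation", "rest3"))
  expect_length(unique(vapply(co, function(s) s$participant_id, "")), 1L)

  cfg2 <- cohort_config(n_per_group = c(MDD = 3, PD = 2, HC = 4), n_visits = 3,
                        phase_duration_s = 40, retention_prob = 0.7, seed = 9)
  co2 <- generate_cohort(cfg2)
  keys <- vapply(co2, function(s) paste(s$participant_id, s$visit, s$phase), "")
  expect_false(anyDuplicated(keys) > 0)
  # every retained session has exactly its 5 phases
  sess <- table(vapply(co2, function(s) paste(s$participant_id, s$visit), ""))
  expect_true(all(sess == 5L))
  # bit-identical reproduction from the same config + seed
  co2b <- generate_cohort(cfg2)
  expect_identical(as.data.frame(co2), as.data.frame(co2b))
  # cumulative time lands within 2 s of the nominal phase duration
  durs <- vapply(co2, function(s) sum(s$intervals_ms) / 1000, 0)
  expect_true(all(durs >= 40 - 2 & durs <= 40 + 2))
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(cohort_config(phase_duration_s = 0), "phase_duration_s")
  expect_error(cohort_config(retention_prob = 1.2), "retention_prob")
  expect_error(cohort_config(reactivity = list(rri = c(MDD = -1.5, PD = 0, HC = 0),
                                               hf = c(MDD = 0, PD = 0, HC = 0),
                                               lf = c(MDD = 0, PD = 0, HC = 0))),
               "reactivity")
  expect_error(cohort_config(n_per_group = c(MDD = -1, PD = 2, HC = 2)),
               "non-negative")
})

test_that("phase simulation follows the oscillator model and reactivity signs", {
  cfg <- cohort_config(noise_sd_ms = 0, phase_duration_s = 60)
  st <- list(participant_id = "P1", group = "HC", base = 850, a_lf = 0, a_hf = 0,
             f_lf = 0.095, f_hf = 0.25,
             reactivity = list(rri = -0.08, hf = -0.3, lf = 0.3))
  s <- simulate_phase_rri(st, 0, 1, "rest1", cfg)
  expect_true(all(abs(s$intervals_ms - 850) < 1e-9)) # constant when A = noise = 0

  # negative-RR parameter sets are refused with a diagnostic
  st_bad <- st
  st_bad$a_lf <- 2000
  expect_error(simulate_phase_rri(st_bad, 0, 1, "rest1", cfg), "non-positive")

  # stress phase shortens the mean interval relative to relaxation (HC config)
  cfg2 <- cohort_config(phase_duration_s = 120)
  diffs <- vapply(1:100, function(seed) {
    set.seed(seed)
    st2 <- list(participant_id = "P1", group = "HC", base = 850, a_lf = 40,
                a_hf = 30, f_lf = 0.095, f_hf = 0.25,
                reactivity = list(rri = -0.08, hf = -0.35, lf = 0.35))
    mean(simulate_phase_rri(st2, 0, 1, "stress", cfg2)$intervals_ms) -
      mean(simulate_phase_rri(st2, 0, 1, "relaxation", cfg2)$intervals_ms)
  }, 0)
  expect_lt(mean(diffs), 0)
})

test_that("missingness keeps visit 1, prunes whole sessions, matches the binomial mean", {
  cfg <- cohort_config(n_per_group = c(MDD = 41, PD = 47, HC = 59), n_visits = 5,
                       phase_duration_s = 20, retention_prob = 1, seed = 2)
  co <- generate_cohort(cfg)
  expect_length(co, 147 * 5 * 5)

  expect_identical(length(apply_missingness(co, 1, seed = 3)), length(co))
  only1 <- apply_missingness(co, 0, seed = 3)
  expect_true(all(vapply(only1, function(s) s$visit, 0L) == 1L))
  expect_length(only1, 147 * 5)

  kept <- vapply(1:500, function(seed) {
    nrow(cohort_sessions(apply_missingness(co, 0.85, seed = seed)))
  }, 0)
  expected <- 147 + 147 * 4 * 0.85
  se <- sqrt(147 * 4 * 0.85 * 0.15 / 500)
  expect_lt(abs(mean(kept) - expected), 3 * se)

  # exact-count retention mode
  co650 <- apply_missingness(co, seed = 11,
                             retain_counts = c(MDD = 181, PD = 191, HC = 278))
  sess <- cohort_sessions(co650)
  expect_identical(nrow(sess), 650L)
  expect_identical(as.integer(table(sess$group)[c("MDD", "PD", "HC")]),
                   c(181L, 191L, 278L))
  expect_true(all(table(sess$participant[sess$visit == 1]) == 1))
  expect_error(apply_missingness(co, retain_counts = c(MDD = 20, PD = 191, HC = 278)),
               "cannot retain")
})

test_that("group-mean reactivity is negative everywhere and largest for controls", {
  cfg <- cohort_config(phase_duration_s = 60, seed = 21)
  co <- generate_cohort(cfg)
  df <- as.data.frame(co)
  df <- df[df$phase %in% c("stress", "relaxation"), ]
  m <- aggregate(rri_ms ~ participant + group + visit + phase, df, mean)
  w <- reshape(m, idvar = c("participant", "group", "visit"),
               timevar = "phase", direction = "wide")
  w$delta <- w$rri_ms.stress - w$rri_ms.relaxation
  gmeans <- tapply(w$delta, w$group, mean)
  expect_true(all(gmeans < 0))
  expect_true(abs(gmeans[["HC"]]) > abs(gmeans[["MDD"]]))
  expect_true(abs(gmeans[["HC"]]) > abs(gmeans[["PD"]]))
})

test_that("strong visit drift dominates the within-visit task contrast", {
  cfg <- cohort_config(n_per_group = c(MDD = 0, PD = 0, HC = 12), n_visits = 4,
                       phase_duration_s = 60, visit_drift_sd = 200,
                       reactivity = list(rri = c(MDD = 0, PD = 0, HC = -0.02),
                                         hf = c(MDD = 0, PD = 0, HC = -0.1),
                                         lf = c(MDD = 0, PD = 0, HC = 0.1)),
                       retention_prob = 1, seed = 8)
  co <- generate_cohort(cfg)
  df <- as.data.frame(co)
  m <- aggregate(rri_ms ~ participant + visit + phase, df, mean)
  per_part <- split(m, m$participant)
  dominated <- vapply(per_part, function(d) {
    visit_means <- tapply(d$rri_ms, d$visit, mean)
    task_diff <- mean(abs(d$rri_ms[d$phase == "stress"] -
                            d$rri_ms[d$phase == "relaxation"]))
    var(visit_means) > task_diff^2
  }, TRUE)
  expect_gt(mean(dominated), 0.75)
})
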