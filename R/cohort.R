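#' Configuration for a synthetic longitudinal RRI cohort
#'
#' Builds the parameter set for [generate_cohort()]. The simulator emulates a
#' three-group (MDD, PD, HC) longitudinal protocol: up to `n_visits` visits per
#' participant, each visit comprising five consecutive 5-minute phases
#' (rest1, stress, rest2, relaxation, rest3) of beat-to-beat RR intervals.
#' Beat intervals follow a two-oscillator model,
#' `RR(t) = base + A_LF sin(2 pi f_LF t + phi) + A_HF sin(2 pi f_HF t + psi) + eps`,
#' whose parameters map one-to-one onto the spectral and variability features
#' analysed downstream. The stress phase perturbs a participant's mean RRI
#' (down), HF amplitude (down) and LF amplitude (up) by group-specific
#' fractions; healthy controls default to the largest reactivity.
#'
#' @param n_per_group named integer vector of participants per group
#'   (default `c(MDD = 41, PD = 47, HC = 59)`).
#' @param n_visits number of scheduled visits per participant.
#' @param phase_duration_s duration of each phase in seconds.
#' @param base_rri_ms population mean RR interval (ms).
#' @param group_offsets list with `rri_ms` (additive shift to the mean RRI per
#'   group, ms) and `amp` (multiplicative shift to both oscillation amplitudes
#'   per group); patient groups default below HC, giving them lower overall HRV.
#' @param reactivity list of per-group fractional stress-phase changes:
#'   `rri` (mean RRI, negative), `hf` (HF amplitude, negative), `lf`
#'   (LF amplitude, positive). All fractions must lie in (-1, 1).
#' @param amp_lf_ms,amp_hf_ms population LF / HF oscillation amplitudes (ms).
#' @param subject_sd between-participant SD of the baseline RRI (ms).
#' @param subject_amp_sd log-scale SD of the per-participant amplitude
#'   multiplier (one lognormal draw per participant and band).
#' @param reactivity_jitter_sd log-scale SD of the per-participant reactivity
#'   multiplier (one draw per participant, shared by the three channels).
#' @param visit_drift_sd SD (ms) of the per-visit baseline offset shared by all
#'   five phases of that visit ("daily state" drift).
#' @param noise_sd_ms SD of white beat-to-beat noise (ms).
#' @param f_lf,f_hf centre frequencies (Hz) of the two oscillators.
#' @param freq_jitter_sd SD (Hz) of small per-participant frequency jitter.
#' @param retention_prob probability that each visit after the first is
#'   attended; the default 0.884 yields approximately 650 of 735 expected
#'   sessions for the default group sizes.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return An object of class `cohort_config`.
#' @seealso [generate_cohort()], [apply_missingness()]
#' @export
cohort_config <- function(n_per_group = c(MDD = 41L, PD = 47L, HC = 59L),
                          n_visits = 5L,
                          phase_duration_s = 300,
                          base_rri_ms = 850,
                          group_offsets = list(
                            rri_ms = c(MDD = -40, PD = -40, HC = 0),
                            amp = c(MDD = 0.7, PD = 0.7, HC = 1)
                          ),
                          reactivity = list(
                            rri = c(MDD = -0.04, PD = -0.04, HC = -0.08),
                            hf = c(MDD = -0.15, PD = -0.15, HC = -0.35),
                            lf = c(MDD = 0.15, PD = 0.15, HC = 0.35)
                          ),
                          amp_lf_ms = 40,
                          amp_hf_ms = 30,
                          subject_sd = 70,
                          subject_amp_sd = 0.35,
                          reactivity_jitter_sd = 0.3,
                          visit_drift_sd = 50,
                          noise_sd_ms = 15,
                          f_lf = 0.095,
                          f_hf = 0.25,
                          freq_jitter_sd = 0.01,
                          retention_prob = 0.884,
                          seed = 1L) {
  n_per_group <- as.integer(n_per_group)
  if (length(n_per_group) != 3L) {
    stop("`n_per_group` must give counts for the three groups MDD, PD, HC",
         call. = FALSE)
  }
  names(n_per_group) <- GROUPS
  if (any(is.na(n_per_group)) || any(n_per_group < 0L)) {
    stop("group counts must be non-negative integers", call. = FALSE)
  }
  if (!is.numeric(phase_duration_s) || phase_duration_s <= 0) {
    stop("`phase_duration_s` must be > 0", call. = FALSE)
  }
  if (retention_prob < 0 || retention_prob > 1) {
    stop("`retention_prob` must lie in [0, 1]", call. = FALSE)
  }
  for (ch in c("rri", "hf", "lf")) {
    rc <- reactivity[[ch]]
    if (is.null(rc) || length(rc) != 3L || any(abs(rc) >= 1)) {
      stop("reactivity fractions for '", ch, "' must lie in (-1, 1), one per group",
           call. = FALSE)
    }
    names(reactivity[[ch]]) <- GROUPS
  }
  names(group_offsets$rri_ms) <- GROUPS
  names(group_offsets$amp) <- GROUPS
  if (n_visits < 1L) stop("`n_visits` must be >= 1", call. = FALSE)
  structure(list(
    n_per_group = n_per_group, n_visits = as.integer(n_visits),
    phase_duration_s = phase_duration_s, base_rri_ms = base_rri_ms,
    group_offsets = group_offsets, reactivity = reactivity,
    amp_lf_ms = amp_lf_ms, amp_hf_ms = amp_hf_ms,
    subject_sd = subject_sd, subject_amp_sd = subject_amp_sd,
    reactivity_jitter_sd = reactivity_jitter_sd,
    visit_drift_sd = visit_drift_sd, noise_sd_ms = noise_sd_ms,
    f_lf = f_lf, f_hf = f_hf, freq_jitter_sd = freq_jitter_sd,
    retention_prob = retention_prob, seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Single-phase RRI series
#'
#' Lightweight container for one phase's beat-interval sequence with its
#' participant / visit / phase metadata.
#'
#' @param participant_id identifier, coerced to character.
#' @param group one of `"MDD"`, `"PD"`, `"HC"`.
#' @param visit visit number (integer).
#' @param phase one of `"rest1"`, `"stress"`, `"rest2"`, `"relaxation"`,
#'   `"rest3"`.
#' @param intervals_ms numeric vector of RR intervals in milliseconds, all > 0.
#' @return An object of class `rri_series`.
#' @export
rri_series <- function(participant_id, group, visit, phase, intervals_ms) {
  group <- match.arg(group, GROUPS)
  phase <- match.arg(phase, PHASES)
  intervals_ms <- as.numeric(intervals_ms)
  if (length(intervals_ms) == 0L || any(!is.finite(intervals_ms)) ||
      any(intervals_ms <= 0)) {
    stop("RR intervals must be finite and strictly positive", call. = FALSE)
  }
  structure(list(participant_id = as.character(participant_id), group = group,
                 visit = as.integer(visit), phase = phase,
                 intervals_ms = intervals_ms),
            class = "rri_series")
}

#' @export
print.rri_series <- function(x, ...) {
  cat(sprintf("<rri_series> %s [%s] visit %d, %s: %d beats, %.1f s\n",
              x$participant_id, x$group, x$visit, x$phase,
              length(x$intervals_ms), sum(x$intervals_ms) / 1000))
  invisible(x)
}

new_cohort <- function(series, config = NULL) {
  structure(series, class = "hrv_cohort", config = config)
}

#' @export
print.hrv_cohort <- function(x, ...) {
  keys <- vapply(x, function(s) paste(s$participant_id, s$visit), "")
  cat(sprintf("<hrv_cohort> %d series, %d sessions, %d participants\n",
              length(x), length(unique(keys)),
              length(unique(vapply(x, function(s) s$participant_id, "")))))
  invisible(x)
}

#' Simulate one phase of RR intervals
#'
#' Generates beats iteratively: `t[k+1] = t[k] + RR(t[k]) / 1000` with
#' `RR(t) = base + A_LF sin(2 pi f_LF t + phi_LF) + A_HF sin(2 pi f_HF t +
#' phi_HF) + eps`, stopping at the first beat whose cumulative time exceeds
#' `config$phase_duration_s`. In the stress phase the participant's reactivity
#' fractions scale the base (down), HF amplitude (down) and LF amplitude (up)
#' relative to the other phases. Oscillator phases are drawn uniformly per
#' series and the white noise per beat, so call this inside a seeded context
#' ([generate_cohort()] does).
#'
#' @param participant_state list with `participant_id`, `group`, `base`
#'   (ms), `a_lf`, `a_hf` (ms), `f_lf`, `f_hf` (Hz) and `reactivity` (list of
#'   fractions `rri`, `hf`, `lf`).
#' @param visit_drift additive baseline offset (ms) for this visit.
#' @param visit visit number.
#' @param phase phase name.
#' @param config a [cohort_config()].
#' @return An [rri_series()].
#' @export
simulate_phase_rri <- function(participant_state, visit_drift, visit, phase,
                               config) {
  phase <- match.arg(phase, PHASES)
  st <- participant_state
  base <- st$base + visit_drift
  a_lf <- st$a_lf
  a_hf <- st$a_hf
  if (phase == "stress") {
    base <- base * (1 + st$reactivity$rri)
    a_hf <- a_hf * (1 + st$reactivity$hf)
    a_lf <- a_lf * (1 + st$reactivity$lf)
  }
  dur <- config$phase_duration_s
  phi_lf <- runif(1, 0, 2 * pi)
  phi_hf <- runif(1, 0, 2 * pi)
  # upper bound on beats: intervals cannot undershoot base minus amplitudes by
  # much, so budget generously and pre-draw the noise once
  n_max <- max(ceiling(dur * 1000 / max(base - a_lf - a_hf - 6 * config$noise_sd_ms, 200)) + 10L, 20L)
  eps <- if (config$noise_sd_ms > 0) rnorm(n_max, 0, config$noise_sd_ms) else numeric(n_max)
  rr <- numeric(n_max)
  t <- 0
  k <- 0L
  while (t <= dur) {
    k <- k + 1L
    if (k > n_max) { # pathological parameters; extend the noise budget once
      eps <- c(eps, rnorm(n_max, 0, config$noise_sd_ms))
      rr <- c(rr, numeric(n_max))
      n_max <- 2L * n_max
    }
    val <- base + a_lf * sin(2 * pi * st$f_lf * t + phi_lf) +
      a_hf * sin(2 * pi * st$f_hf * t + phi_hf) + eps[k]
    if (!is.finite(val) || val <= 0) {
      stop(sprintf(paste0("simulated RR interval became non-positive at beat %d ",
                          "(base = %.1f ms, A_LF = %.1f, A_HF = %.1f, noise SD = %.1f)"),
                   k, base, a_lf, a_hf, config$noise_sd_ms), call. = FALSE)
    }
    rr[k] <- val
    t <- t + val / 1000
  }
  rri_series(st$participant_id, st$group, visit, phase, rr[seq_len(k)])
}

draw_participant_state <- function(id, group, config) {
  amp_g <- config$group_offsets$amp[[group]]
  list(
    participant_id = id, group = group,
    base = config$base_rri_ms + config$group_offsets$rri_ms[[group]] +
      rnorm(1, 0, config$subject_sd),
    a_lf = config$amp_lf_ms * amp_g * exp(rnorm(1, 0, config$subject_amp_sd)),
    a_hf = config$amp_hf_ms * amp_g * exp(rnorm(1, 0, config$subject_amp_sd)),
    f_lf = min(max(config$f_lf + rnorm(1, 0, config$freq_jitter_sd), 0.05), 0.14),
    f_hf = min(max(config$f_hf + rnorm(1, 0, config$freq_jitter_sd), 0.16), 0.39),
    reactivity = {
      m <- exp(rnorm(1, 0, config$reactivity_jitter_sd))
      list(rri = max(config$reactivity$rri[[group]] * m, -0.9),
           hf = max(config$reactivity$hf[[group]] * m, -0.9),
           lf = min(config$reactivity$lf[[group]] * m, 0.9))
    }
  )
}

#' Generate a synthetic RRI cohort
#'
#' Draws each participant's latent state (baseline RRI, oscillation amplitudes,
#' reactivity multiplier) once and reuses it across visits; draws one baseline
#' drift offset per visit, shared by that visit's five phases; then simulates
#' every phase with [simulate_phase_rri()] and applies visit missingness with
#' [apply_missingness()] at `config$retention_prob`. Fully reproducible from
#' `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return An object of class `hrv_cohort`: a list of [rri_series()] with the
#'   config attached as an attribute.
#' @examples
#' cfg <- cohort_config(n_per_group = c(MDD = 1, PD = 0, HC = 1), n_visits = 1,
#'                      phase_duration_s = 60)
#' cohort <- generate_cohort(cfg)
#' length(cohort) # 2 participants x 1 visit x 5 phases
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop("`config` must be created by cohort_config()", call. = FALSE)
  }
  series <- with_seed(config$seed, {
    out <- vector("list", sum(config$n_per_group) * config$n_visits * 5L)
    idx <- 0L
    pnum <- 0L
    for (g in GROUPS) {
      for (i in seq_len(config$n_per_group[[g]])) {
        pnum <- pnum + 1L
        id <- sprintf("P%03d", pnum)
        st <- draw_participant_state(id, g, config)
        drifts <- rnorm(config$n_visits, 0, config$visit_drift_sd)
        for (v in seq_len(config$n_visits)) {
          for (ph in PHASES) {
            idx <- idx + 1L
            out[[idx]] <- simulate_phase_rri(st, drifts[v], v, ph, config)
          }
        }
      }
    }
    out
  })
  cohort <- new_cohort(series, config)
  apply_missingness(cohort, config$retention_prob, seed = config$seed + 1L)
}

#' Drop missed visits from a cohort
#'
#' Visit 1 is always retained; every later participant-visit is retained
#' independently with probability `retention_prob`, and all five phases of a
#' dropped visit are removed together. Alternatively `retain_counts` requests
#' exact per-group retained-session totals (e.g. `c(MDD = 181, PD = 191,
#' HC = 278)` for a 650-of-735 cohort): each participant keeps visit 1 and the
#' remaining sessions are sampled uniformly from the later visits.
#'
#' @param cohort an `hrv_cohort`.
#' @param retention_prob per-visit retention probability in `[0, 1]` for
#'   visits after the first.
#' @param seed integer seed for the retention draws.
#' @param retain_counts optional named vector of exact retained session counts
#'   per group; overrides `retention_prob`.
#' @return The pruned `hrv_cohort`.
#' @export
apply_missingness <- function(cohort, retention_prob, seed = 1L,
                              retain_counts = NULL) {
  if (is.null(retain_counts) &&
      (retention_prob < 0 || retention_prob > 1)) {
    stop("`retention_prob` must lie in [0, 1]", call. = FALSE)
  }
  meta <- data.frame(
    participant = vapply(cohort, function(s) s$participant_id, ""),
    group = vapply(cohort, function(s) s$group, ""),
    visit = vapply(cohort, function(s) s$visit, 0L),
    stringsAsFactors = FALSE
  )
  sess <- unique(meta)
  keep_key <- with_seed(seed, {
    if (is.null(retain_counts)) {
      keep <- sess$visit == 1L | runif(nrow(sess)) < retention_prob
      sess[keep, , drop = FALSE]
    } else {
      kept <- sess[sess$visit == 1L, , drop = FALSE]
      later <- sess[sess$visit != 1L, , drop = FALSE]
      for (g in unique(sess$group)) {
        want <- retain_counts[[g]] - sum(kept$group == g)
        pool <- which(later$group == g)
        if (want < 0 || want > length(pool)) {
          stop(sprintf("cannot retain %d '%s' sessions: %d first visits and %d later sessions available",
                       retain_counts[[g]], g, sum(kept$group == g), length(pool)),
               call. = FALSE)
        }
        kept <- rbind(kept, later[sample(pool, want), , drop = FALSE])
      }
      kept
    }
  })
  key <- function(d) paste(d$participant, d$visit, sep = "\r")
  keep_idx <- key(meta) %in% key(keep_key)
  new_cohort(unclass(cohort)[keep_idx], attr(cohort, "config"))
}

#' Session table of a cohort
#'
#' @param cohort an `hrv_cohort`.
#' @return data.frame with one row per retained (participant, visit) session.
#' @export
cohort_sessions <- function(cohort) {
  meta <- data.frame(
    participant = vapply(cohort, function(s) s$participant_id, ""),
    group = vapply(cohort, function(s) s$group, ""),
    visit = vapply(cohort, function(s) s$visit, 0L),
    stringsAsFactors = FALSE
  )
  out <- unique(meta)
  rownames(out) <- NULL
  out
}
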