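# Synthetic CTG fixture generator.
#
# Emulates the statistical structure the classifier assumes: a fetal heart
# rate (FHR) channel with a per-record baseline in the normal 110-160 bpm
# band, short-term variability (sinusoidal plus band-limited noise), a
# uterine-contraction (UC) channel made of periodic Gaussian pressure bumps,
# and -- in the abnormal class -- late decelerations: Gaussian FHR dips
# lagged ~30 s behind contraction peaks.  Invalid points (dropouts, spikes,
# jumps, UC spikes) are injected with ground-truth masks so the invalid-point
# detectors can be scored against a known answer.  Maternal metadata is
# label-coupled: the abnormal class has a higher gestational-diabetes
# prevalence and a higher mean age.

#' Synthetic dataset configuration
#'
#' @param n_records number of records to generate.
#' @param abnormal_fraction fraction of records labeled abnormal (class 1).
#' @param seed integer seed; identical configurations are bit-reproducible.
#' @param segment_length samples per channel (default 7200 = 30 min at 4 Hz).
#' @param sample_rate sampling rate in Hz.
#' @param baseline_mean,baseline_sd per-record FHR baseline distribution (bpm).
#' @param variability_amplitude short-term FHR variability scale (bpm).
#' @param contraction_period average spacing of UC contractions (seconds).
#' @param uc_amplitude mean contraction bump height (pressure units).
#' @param decel_depth mean depth of abnormal-class decelerations (bpm); the
#'   abnormal-class effect size.
#' @param decel_lag lag of the deceleration nadir behind the contraction peak
#'   (seconds); decelerations are "late" by construction.
#' @param decel_width Gaussian width (sd, seconds) of a deceleration.
#' @param artifact_rates named per-sample probabilities for the three FHR
#'   artifact types (`dropout`, `spike`, `jump`); UC receives `spike` only.
#' @param gravidity_missing_rate probability that gravidity is missing, to
#'   exercise mean imputation (cohorts of this kind report ~0.7% missing).
#' @param age_mean,age_sd,age_shift maternal age model: normal class
#'   `N(age_mean, age_sd)`, abnormal class shifted up by `age_shift` years.
#' @param diabetes_prob length-2 vector of gestational-diabetes probabilities
#'   for the (normal, abnormal) classes.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_records = 100,
                             abnormal_fraction = 0.6,
                             seed = 1L,
                             segment_length = 7200L,
                             sample_rate = 4,
                             baseline_mean = 140,
                             baseline_sd = 10,
                             variability_amplitude = 5,
                             contraction_period = 180,
                             uc_amplitude = 40,
                             decel_depth = 30,
                             decel_lag = 30,
                             decel_width = 20,
                             artifact_rates = c(dropout = 0.01, spike = 0.005, jump = 0.005),
                             gravidity_missing_rate = 0.007,
                             age_mean = 27,
                             age_sd = 4,
                             age_shift = 5,
                             diabetes_prob = c(0.08, 0.45)) {
  check_number(abnormal_fraction, "abnormal_fraction", 0, 1)
  check_number(segment_length, "segment_length", 1)
  check_number(sample_rate, "sample_rate", 0.1)
  rates <- artifact_rates
  for (nm in c("dropout", "spike", "jump")) {
    if (is.na(rates[nm])) rates[nm] <- 0
    check_number(unname(rates[nm]), paste0("artifact_rates['", nm, "']"), 0, 1)
  }
  check_number(gravidity_missing_rate, "gravidity_missing_rate", 0, 1)
  structure(list(
    n_records = as.integer(n_records), abnormal_fraction = abnormal_fraction,
    seed = as.integer(seed), segment_length = as.integer(segment_length),
    sample_rate = sample_rate, baseline_mean = baseline_mean,
    baseline_sd = baseline_sd, variability_amplitude = variability_amplitude,
    contraction_period = contraction_period, uc_amplitude = uc_amplitude,
    decel_depth = decel_depth, decel_lag = decel_lag, decel_width = decel_width,
    artifact_rates = rates[c("dropout", "spike", "jump")],
    gravidity_missing_rate = gravidity_missing_rate,
    age_mean = age_mean, age_sd = age_sd, age_shift = age_shift,
    diabetes_prob = diabetes_prob
  ), class = "synthetic_config")
}

#' Construct a CTG record
#'
#' @param record_id identifier string.
#' @param fhr,uc equal-length numeric channels (FHR in bpm, UC in arbitrary
#'   pressure units) sampled at `sample_rate` Hz.
#' @param metadata a `maternal_metadata` object (or list with fields `age`,
#'   `gravidity`, `parity`, `diabetes`).
#' @param label 0 = normal, 1 = abnormal.
#' @param sample_rate sampling rate in Hz.
#' @export
ctg_record <- function(record_id, fhr, uc, metadata, label, sample_rate = 4) {
  if (length(fhr) != length(uc)) abort_input("fhr and uc must have identical length")
  if (!is.na(label) && !label %in% c(0, 1)) {
    abort_input("label must be 0 or 1 (NA = unlabeled)")
  }
  structure(list(record_id = as.character(record_id),
                 fhr = as.numeric(fhr), uc = as.numeric(uc),
                 metadata = metadata, label = as.integer(label),
                 sample_rate = sample_rate),
            class = "ctg_record")
}

#' Maternal metadata vector
#'
#' Age (years), gravidity and parity (counts, may be `NA`), and a binary
#' gestational-diabetes indicator.
#' @param age,gravidity,parity,diabetes see description.
#' @export
maternal_metadata <- function(age, gravidity, parity, diabetes) {
  if (!is.na(diabetes) && !diabetes %in% c(0, 1)) {
    abort_input("diabetes must be 0 or 1")
  }
  for (v in c(gravidity, parity)) {
    if (!is.na(v) && v < 0) abort_input("counts must be non-negative")
  }
  structure(list(age = age, gravidity = gravidity, parity = parity,
                 diabetes = diabetes),
            class = "maternal_metadata")
}

#' Per-sample validity mask
#'
#' @param flags logical vector, `TRUE` = invalid sample.
#' @param reasons character vector of the same length with reason codes in
#'   `{"range", "jump", "sigma", "injected", "none"}`.
#' @export
validity_mask <- function(flags, reasons = NULL) {
  if (is.null(reasons)) reasons <- ifelse(flags, "injected", "none")
  if (length(flags) != length(reasons)) {
    abort_input("flags and reasons must have the same length")
  }
  structure(list(flags = as.logical(flags), reasons = as.character(reasons)),
            class = "validity_mask")
}

#' Inject artifacts into a clean signal
#'
#' Corrupts a signal with out-of-range dropouts (value 0), large spikes
#' (+40 bpm) and medium jumps (+/-35 bpm, i.e. just above the 25 bpm
#' adjacent-sample rule), returning the corrupted signal together with the
#' ground-truth mask of injected positions.  For the UC channel only spikes
#' are injected (large deviations the sliding-window 3-sigma rule should
#' flag).  The corrupted signal differs from the input only at masked
#' positions.
#'
#' @param signal numeric vector.
#' @param rates named vector with entries `dropout`, `spike`, `jump` in [0,1].
#' @param seed optional seed; when `NULL` the current RNG stream is used.
#' @param channel `"fhr"` or `"uc"`.
#' @return list with elements `signal` (corrupted) and `mask`
#'   (`validity_mask` with reason `"injected"` at corrupted positions).
#' @export
inject_artifacts <- function(signal, rates, seed = NULL,
                             channel = c("fhr", "uc")) {
  channel <- match.arg(channel)
  run <- function() {
    n <- length(signal)
    out <- signal
    hit <- logical(n)
    get_rate <- function(nm) if (is.na(rates[nm])) 0 else unname(rates[nm])
    if (channel == "fhr") {
      drop_pos <- which(stats::runif(n) < get_rate("dropout"))
      out[drop_pos] <- 0
      hit[drop_pos] <- TRUE
      spike_pos <- setdiff(which(stats::runif(n) < get_rate("spike")), which(hit))
      out[spike_pos] <- out[spike_pos] + 40
      hit[spike_pos] <- TRUE
      jump_pos <- setdiff(which(stats::runif(n) < get_rate("jump")), which(hit))
      out[jump_pos] <- out[jump_pos] +
        35 * sample(c(-1, 1), length(jump_pos), replace = TRUE)
      hit[jump_pos] <- TRUE
    } else {
      amp <- max(8 * stats::sd(signal), 30)
      spike_pos <- which(stats::runif(n) < get_rate("spike"))
      out[spike_pos] <- out[spike_pos] + amp
      hit[spike_pos] <- TRUE
    }
    list(signal = out, mask = validity_mask(hit, ifelse(hit, "injected", "none")))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# Gaussian bump helper
gauss_bump <- function(t, center, width) exp(-((t - center)^2) / (2 * width^2))

# Contraction peak times covering [0, dur]; always at least one peak placed
# so that a lagged deceleration still fits inside the segment.
contraction_peaks <- function(dur, period, lag, width) {
  first <- stats::runif(1, 0.25, 0.75) * period
  base <- if (first > dur) numeric(0) else seq(first, dur, by = period)
  peaks <- base + stats::rnorm(length(base), 0, period * 0.05)
  peaks <- peaks[peaks > 0.05 * dur & peaks < 0.95 * dur]
  guard <- dur - lag - 2 * width
  if (!any(peaks + lag + 2 * width < dur) && guard > 0) {
    peaks <- c(peaks, min(0.45 * dur, guard))
  }
  sort(peaks)
}

synth_record <- function(cfg, id, label) {
  L <- cfg$segment_length
  fs <- cfg$sample_rate
  t <- (seq_len(L) - 1) / fs
  dur <- L / fs

  # uterine activity: low baseline + periodic Gaussian bumps + noise
  peaks <- contraction_peaks(dur, cfg$contraction_period,
                             cfg$decel_lag, cfg$decel_width)
  uc <- rep(10, L)
  for (pk in peaks) {
    amp <- stats::rnorm(1, cfg$uc_amplitude, cfg$uc_amplitude * 0.12)
    uc <- uc + amp * gauss_bump(t, pk, 25)
  }
  uc <- uc + stats::rnorm(L, 0, 1.5)

  # fetal heart rate: baseline + sinusoidal variability + band-limited noise
  baseline <- stats::rnorm(1, cfg$baseline_mean, cfg$baseline_sd)
  phase <- stats::runif(1, 0, 2 * pi)
  fhr <- baseline +
    cfg$variability_amplitude * sin(2 * pi * 0.04 * t + phase) +
    rolling_mean(stats::rnorm(L, 0, cfg$variability_amplitude), 9L)
  if (label == 1L) {
    # late decelerations: dips lagged behind contraction peaks
    fit <- peaks[peaks + cfg$decel_lag + 2 * cfg$decel_width < dur]
    for (pk in fit) {
      depth <- stats::rnorm(1, cfg$decel_depth, cfg$decel_depth * 0.15)
      fhr <- fhr - depth * gauss_bump(t, pk + cfg$decel_lag, cfg$decel_width)
    }
  }

  fhr_art <- inject_artifacts(fhr, cfg$artifact_rates, channel = "fhr")
  uc_art <- inject_artifacts(uc, cfg$artifact_rates, channel = "uc")

  p_dia <- cfg$diabetes_prob[label + 1L]
  age <- round(stats::rnorm(1, cfg$age_mean + label * cfg$age_shift, cfg$age_sd))
  age <- min(max(age, 16), 50)
  gravidity <- 1 + stats::rpois(1, 0.8)
  parity <- min(gravidity - 1, stats::rpois(1, 0.6))
  diabetes <- stats::rbinom(1, 1, p_dia)
  if (stats::runif(1) < cfg$gravidity_missing_rate) gravidity <- NA_integer_

  rec <- ctg_record(id, fhr_art$signal, uc_art$signal,
                    maternal_metadata(age, gravidity, parity, diabetes),
                    label, fs)
  rec$truth <- list(fhr_mask = fhr_art$mask, uc_mask = uc_art$mask,
                    clean_fhr = fhr, clean_uc = uc)
  rec
}

#' Generate a synthetic CTG dataset
#'
#' Produces exactly `n_records` records, `round(n_records * abnormal_fraction)`
#' of them labeled abnormal.  Abnormal records contain at least one late
#' deceleration time-locked to a contraction peak by construction.  Identical
#' configurations yield bit-identical datasets; the caller's RNG state is left
#' untouched.
#'
#' @param config a [synthetic_config()].
#' @return list of `ctg_record` objects, each carrying a `truth` element with
#'   the clean signals and ground-truth artifact masks.
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    abort_input("config must be a synthetic_config")
  }
  if (config$n_records <= 0L) abort_input("n_records must be positive")
  with_seed(config$seed, {
    n <- config$n_records
    n_ab <- round(n * config$abnormal_fraction)
    labels <- integer(n)
    if (n_ab > 0) labels[sample.int(n, n_ab)] <- 1L
    lapply(seq_len(n), function(i) {
      synth_record(config, sprintf("syn-%04d", i), labels[i])
    })
  })
}

#' @export
print.ctg_record <- function(x, ...) {
  cat(sprintf("<ctg_record %s> %d samples @ %g Hz, label=%d (%s)\n",
              x$record_id, length(x$fhr), x$sample_rate, x$label,
              if (x$label == 1L) "abnormal" else "normal"))
  invisible(x)
}
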