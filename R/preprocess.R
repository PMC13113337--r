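# Signal cleaning: invalid-point detection, linear interpolation, smoothing.
#
# FHR invalid points are (1) samples outside the physiologically plausible
# 50-220 bpm range and (2) abrupt changes exceeding 25 bpm between adjacent
# samples.  UC invalid points follow the Pauta (3-sigma) rule computed over a
# centered sliding window.  Invalid points are treated as missing and
# reconstructed by linear interpolation between valid samples, then a light
# moving-average smoother is applied.

#' Preprocessing configuration
#'
#' @param fhr_min,fhr_max physiologically plausible FHR range in bpm.
#' @param fhr_jump maximum allowed change between adjacent samples (bpm).
#' @param uc_window sliding-window size (samples) for the UC 3-sigma rule.
#' @param uc_sigma_k deviation threshold in local standard deviations.
#' @param smooth_window moving-average width in samples (odd).
#' @param max_loss_rate records with a signal-loss rate at or above this
#'   fraction are ineligible (strict `<` comparison for eligibility).
#' @export
preprocess_config <- function(fhr_min = 50, fhr_max = 220, fhr_jump = 25,
                              uc_window = 500L, uc_sigma_k = 3,
                              smooth_window = 5L, max_loss_rate = 0.5) {
  if (fhr_min >= fhr_max) abort_input("fhr_min must be < fhr_max")
  if (uc_window < 2) abort_input("uc_window must be >= 2")
  if (uc_sigma_k <= 0) abort_input("uc_sigma_k must be > 0")
  if (smooth_window < 1 || smooth_window %% 2 == 0) {
    abort_input("smooth_window must be odd and >= 1")
  }
  structure(list(fhr_min = fhr_min, fhr_max = fhr_max, fhr_jump = fhr_jump,
                 uc_window = as.integer(uc_window), uc_sigma_k = uc_sigma_k,
                 smooth_window = as.integer(smooth_window),
                 max_loss_rate = max_loss_rate),
            class = "preprocess_config")
}

#' Detect invalid FHR samples
#'
#' A sample is flagged when it lies outside `[fhr_min, fhr_max]` (reason
#' `"range"`), or when it differs by more than `fhr_jump` bpm from the most
#' recent preceding in-range sample (reason `"jump"`; the later sample of the
#' offending pair is the one flagged).  Jump comparisons skip range-invalid
#' neighbours so that a single out-of-range excursion does not condemn the
#' in-range sample that follows it, while an in-range spike flags only itself
#' plus at most its immediate successor.
#'
#' @param fhr numeric vector of bpm values.
#' @param config a [preprocess_config()].
#' @return a [validity_mask()].
#' @export
detect_invalid_fhr <- function(fhr, config = preprocess_config()) {
  n <- length(fhr)
  if (n == 0L) abort_input("empty signal")
  reasons <- rep("none", n)
  in_range <- is.finite(fhr) & fhr >= config$fhr_min & fhr <= config$fhr_max
  reasons[!in_range] <- "range"
  last_ref <- NA_real_
  for (i in seq_len(n)) {
    if (!in_range[i]) next
    if (!is.na(last_ref) && abs(fhr[i] - last_ref) > config$fhr_jump) {
      reasons[i] <- "jump"
    }
    last_ref <- fhr[i]
  }
  validity_mask(reasons != "none", reasons)
}

#' Detect invalid UC samples (sliding-window 3-sigma rule)
#'
#' A sample is flagged when it deviates from its local mean by more than
#' `uc_sigma_k` local standard deviations, with local statistics computed over
#' a centered window of `uc_window` samples truncated at the boundaries
#' (sequences shorter than the window use the whole sequence).  Windows with
#' zero local standard deviation flag nothing.
#'
#' @param uc numeric pressure sequence.
#' @param config a [preprocess_config()].
#' @return a [validity_mask()].
#' @export
detect_invalid_uc <- function(uc, config = preprocess_config()) {
  n <- length(uc)
  if (n == 0L) abort_input("empty signal")
  st <- rolling_mean_sd(uc, config$uc_window)
  flag <- st$sd > 0 & abs(uc - st$mean) > config$uc_sigma_k * st$sd
  flag[!is.finite(uc)] <- TRUE
  validity_mask(flag, ifelse(flag, "sigma", "none"))
}

#' Reconstruct invalid samples by linear interpolation
#'
#' Invalid runs are replaced by the straight line between the nearest valid
#' neighbours; leading/trailing invalid runs take the nearest valid value.
#' Valid samples pass through unchanged.
#'
#' @param signal numeric vector.
#' @param mask a [validity_mask()] (or logical vector) of the same length.
#' @export
interpolate_invalid <- function(signal, mask) {
  flags <- if (inherits(mask, "validity_mask")) mask$flags else as.logical(mask)
  if (length(flags) != length(signal)) abort_input("mask length mismatch")
  if (!any(flags)) return(signal)
  valid <- which(!flags)
  if (length(valid) == 0L) {
    stop("unrecoverable record: all samples invalid", call. = FALSE)
  }
  out <- signal
  out[flags] <- stats::approx(valid, signal[valid], xout = which(flags),
                              method = "linear", rule = 2)$y
  out
}

#' Centered moving-average smoother
#'
#' Width `smooth_window` (odd); boundary windows are truncated so the output
#' has the input's length.  Width 1 is the identity.
#'
#' @param signal numeric vector.
#' @param config a [preprocess_config()].
#' @export
smooth_signal <- function(signal, config = preprocess_config()) {
  if (length(signal) == 0L) abort_input("empty signal")
  if (config$smooth_window == 1L) return(signal)
  rolling_mean(signal, config$smooth_window)
}

#' Fraction of flagged samples
#'
#' @param mask a [validity_mask()] or logical vector.
#' @return proportion in [0, 1].
#' @export
signal_loss_rate <- function(mask) {
  flags <- if (inherits(mask, "validity_mask")) mask$flags else as.logical(mask)
  if (length(flags) == 0L) abort_input("empty mask")
  mean(flags)
}

#' Is a record eligible given its signal-loss rate?
#'
#' Eligibility requires a loss rate strictly below `max_loss_rate` ("less
#' than 50%" at the default).
#' @param mask a [validity_mask()] or logical vector.
#' @param config a [preprocess_config()].
#' @export
is_eligible <- function(mask, config = preprocess_config()) {
  signal_loss_rate(mask) < config$max_loss_rate
}

#' Clean a CTG record
#'
#' Applies detect -> interpolate -> smooth to the FHR channel (range + jump
#' rules) and the UC channel (sliding-window 3-sigma rule) independently.
#'
#' @param record a [ctg_record()].
#' @param config a [preprocess_config()].
#' @return list with elements `record` (cleaned), `fhr_mask`, `uc_mask`
#'   (masks detected on the raw channels), `loss_rates` and `eligible`
#'   (based on the FHR mask).
#' @export
preprocess_record <- function(record, config = preprocess_config()) {
  if (length(record$fhr) != length(record$uc)) {
    abort_input("record channels must have equal length")
  }
  fhr_mask <- detect_invalid_fhr(record$fhr, config)
  uc_mask <- detect_invalid_uc(record$uc, config)
  fhr <- smooth_signal(interpolate_invalid(record$fhr, fhr_mask), config)
  uc <- smooth_signal(interpolate_invalid(record$uc, uc_mask), config)
  cleaned <- record
  cleaned$fhr <- fhr
  cleaned$uc <- uc
  list(record = cleaned, fhr_mask = fhr_mask, uc_mask = uc_mask,
       loss_rates = c(fhr = signal_loss_rate(fhr_mask),
                      uc = signal_loss_rate(uc_mask)),
       eligible = is_eligible(fhr_mask, config))
}
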