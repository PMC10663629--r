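#' Per-sample dilation speed
#'
#' Speed at each sample is the larger of the absolute backward and forward
#' first differences divided by the sampling interval; endpoints (and samples
#' with one missing neighbour) use the single available difference.
#'
#' @param trace Pupil diameter series (px); `NA` allowed.
#' @param dt Sampling interval (s).
#' @return Speed series (px/s), same length as `trace`.
#' @export
dilation_speed <- function(trace, dt) {
  if (length(trace) < 3)
    stop("trace must have at least 3 samples", call. = FALSE)
  stopifnot(dt > 0)
  d <- abs(diff(trace))
  back <- c(NA, d)
  fwd <- c(d, NA)
  pmax(back, fwd, na.rm = TRUE) / dt
}

#' Detect blinks and dilation-speed outliers
#'
#' Samples are flagged when (i) the diameter is missing, non-positive, or
#' below `zero_frac` of the median valid diameter (device blink coding), or
#' (ii) the dilation speed exceeds `median(speed) + k_mad * MAD(speed)`.
#' Flagged regions are dilated by a guard margin on each side. When the speed
#' MAD is zero (e.g. a constant trace) the speed rule flags nothing.
#'
#' @param trace Diameter series (px).
#' @param sampling_rate Hz.
#' @param k_mad Robust multiplier for the speed threshold.
#' @param guard_ms Guard margin added around flagged regions (ms per side).
#' @param zero_frac Near-zero criterion as a fraction of the median valid
#'   diameter.
#' @return Logical artifact mask, same length as `trace`.
#' @export
detect_artifacts <- function(trace, sampling_rate, k_mad = 16,
                             guard_ms = 50, zero_frac = 0.1) {
  n <- length(trace)
  invalid <- is.na(trace) | trace <= 0
  med_d <- stats::median(trace[!invalid])
  if (is.finite(med_d)) invalid <- invalid | (trace < zero_frac * med_d)
  x <- trace
  x[invalid] <- NA
  flag <- invalid
  if (n >= 3) {
    speed <- dilation_speed(x, 1 / sampling_rate)
    med_s <- stats::median(speed, na.rm = TRUE)
    mad_s <- stats::mad(speed, na.rm = TRUE)
    if (is.finite(mad_s) && mad_s > 0)
      flag <- flag | (!is.na(speed) & speed > med_s + k_mad * mad_s)
  }
  g <- round(guard_ms / 1000 * sampling_rate)
  if (g > 0 && any(flag)) {
    idx <- which(flag)
    idx <- unique(pmin(n, pmax(1L, rep(idx, each = 2 * g + 1) +
                                 rep(-g:g, times = length(idx)))))
    flag[idx] <- TRUE
  }
  flag
}

#' Fill artifact gaps by linear interpolation
#'
#' Interior masked runs are replaced by linear interpolation between the
#' nearest valid neighbours; leading and trailing runs are extended with the
#' nearest valid value.
#'
#' @param trace Diameter series (px).
#' @param mask Logical mask of samples to replace (same length).
#' @return A list with `trace` (filled series) and `interpolated` (logical
#'   per-sample flag of replaced samples, including originally missing ones).
#' @export
interpolate_gaps <- function(trace, mask) {
  stopifnot(length(mask) == length(trace))
  bad <- mask | is.na(trace)
  if (all(bad)) stop("all samples masked: trace cannot be interpolated",
                     call. = FALSE)
  if (!any(bad)) return(list(trace = trace, interpolated = bad))
  idx <- seq_along(trace)
  filled <- stats::approx(idx[!bad], trace[!bad], xout = idx,
                          method = "linear", rule = 2)$y
  list(trace = filled, interpolated = bad)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Forward-backward filtering (no phase shift, DC gain 1), third-order
#' Butterworth design.
#'
#' @param trace Series to filter.
#' @param cutoff Cutoff frequency (Hz), must be below Nyquist.
#' @param sampling_rate Hz.
#' @param order Filter order of the one-pass design.
#' @return Filtered series.
#' @export
lowpass <- function(trace, cutoff = 10, sampling_rate = 120, order = 3) {
  if (cutoff >= sampling_rate / 2)
    stop("cutoff must be below the Nyquist frequency", call. = FALSE)
  bf <- signal::butter(order, cutoff / (sampling_rate / 2), type = "low")
  zero_phase_filter(bf, trace, pad = round(3 * sampling_rate / cutoff))
}

# forward-backward filtering with odd-reflection padding at both ends, so
# edge transients fall on the discarded padding (a constant input comes back
# unchanged); pad should cover a few time constants of the slowest pole
zero_phase_filter <- function(bf, x, pad = 100) {
  n <- length(x)
  pad <- min(n - 1, pad)
  m <- mean(x)  # filter around the mean so a constant input is exact
  x <- x - m
  head_pad <- 2 * x[1] - x[seq(pad + 1, 2)]
  tail_pad <- 2 * x[n] - x[seq(n - 1, n - pad)]
  y <- as.numeric(signal::filtfilt(bf, c(head_pad, x, tail_pad)))
  g <- (sum(bf$b) / sum(bf$a))^2  # squared DC gain of the two passes
  y[pad + seq_len(n)] + m * g
}

#' Epoch a cleaned pupil trace around trial onsets
#'
#' Extracts a fixed window (default -0.5 to +3.0 s, i.e. 420 samples at
#' 120 Hz) around each trial onset, records the fraction of interpolated
#' samples per epoch, and rejects trials whose interpolated fraction exceeds
#' the threshold (default 25%). Trials whose window falls outside the
#' recording are rejected with reason `"out_of_range"`.
#'
#' @param trace Cleaned diameter series (px).
#' @param interpolated Per-sample logical interpolation flags.
#' @param schedule Schedule tibble with session-relative `onset` (s) and
#'   `trial_label`.
#' @param sampling_rate Hz.
#' @param window Epoch window in seconds relative to first-sound onset.
#' @param trial_reject_threshold Maximum tolerated interpolated fraction.
#' @param baseline_window Window used later for baseline correction.
#' @param t0 Time of the first trace sample on the schedule's clock (s);
#'   recordings usually start a little before the first trial.
#' @param include_habituation Keep the block-initial habituation trials
#'   (labelled GS) in the epochs.
#' @return An object of class `pupil_epochs`: trial x sample `data` and
#'   `interp` matrices, relative `times`, per-trial `labels`,
#'   `interp_fraction`, `rejected`, `reject_reason`, and window metadata.
#' @export
epoch_pupil <- function(trace, interpolated, schedule, sampling_rate = 120,
                        window = c(-0.5, 3.0), trial_reject_threshold = 0.25,
                        baseline_window = c(-0.5, 0), t0 = 0,
                        include_habituation = TRUE) {
  stopifnot(length(interpolated) == length(trace), window[1] < window[2])
  if (!include_habituation && "is_habituation" %in% names(schedule))
    schedule <- schedule[!schedule$is_habituation, ]
  fs <- sampling_rate
  n_samp <- round((window[2] - window[1]) * fs)
  offsets <- round(window[1] * fs) + seq_len(n_samp) - 1L
  times <- offsets / fs
  n_trials <- nrow(schedule)
  data <- matrix(NA_real_, n_trials, n_samp)
  interp <- matrix(NA, n_trials, n_samp)
  reason <- rep(NA_character_, n_trials)
  for (i in seq_len(n_trials)) {
    idx <- round((schedule$onset[i] - t0) * fs) + 1L + offsets
    if (idx[1] < 1 || idx[n_samp] > length(trace)) {
      reason[i] <- "out_of_range"
      next
    }
    data[i, ] <- trace[idx]
    interp[i, ] <- interpolated[idx]
  }
  interp_fraction <- rowMeans(interp)
  rejected <- !is.na(reason) |
    (!is.na(interp_fraction) & interp_fraction > trial_reject_threshold)
  reason[is.na(reason) & rejected] <- "interpolated_fraction"
  structure(list(data = data, interp = interp, times = times,
                 labels = schedule$trial_label,
                 is_habituation = schedule$is_habituation %||% rep(FALSE, n_trials),
                 interp_fraction = interp_fraction,
                 rejected = rejected, reject_reason = reason,
                 sampling_rate = fs, window = window,
                 baseline_window = baseline_window,
                 baseline_corrected = FALSE),
            class = "pupil_epochs")
}

#' Baseline-correct pupil epochs
#'
#' Subtracts each trial's mean diameter over the baseline window (default
#' -0.5 to 0 s before the first sound). Trials whose baseline is entirely
#' interpolated are flagged in `baseline_all_interp`.
#'
#' @param epochs A `pupil_epochs` object.
#' @return The epochs with corrected `data` and `baseline_corrected = TRUE`.
#' @export
baseline_correct <- function(epochs) {
  stopifnot(inherits(epochs, "pupil_epochs"))
  bw <- epochs$baseline_window
  in_bl <- epochs$times >= bw[1] & epochs$times < bw[2]
  if (!any(in_bl)) stop("baseline window lies outside the epoch",
                        call. = FALSE)
  bl <- rowMeans(epochs$data[, in_bl, drop = FALSE])
  epochs$data <- epochs$data - bl
  epochs$baseline_all_interp <-
    rowMeans(epochs$interp[, in_bl, drop = FALSE]) == 1
  epochs$baseline_corrected <- TRUE
  epochs
}

#' Grade a patient's pupillometry dataset quality
#'
#' The dataset is `excluded` when more than `exclude_threshold` of trials are
#' rejected, `poor` when the rejection rate exceeds `poor_threshold` (but not
#' `exclude_threshold`), and `correct` otherwise.
#'
#' @param epochs A `pupil_epochs` object.
#' @param poor_threshold,exclude_threshold Rejection-rate thresholds.
#' @return A list of class `pupil_quality` with `label` and `rejection_rate`.
#' @export
assess_dataset_quality <- function(epochs, poor_threshold = 0.25,
                                   exclude_threshold = 0.50) {
  stopifnot(inherits(epochs, "pupil_epochs"),
            poor_threshold <= exclude_threshold)
  rate <- mean(epochs$rejected)
  label <- if (rate > exclude_threshold) "excluded"
           else if (rate > poor_threshold) "poor" else "correct"
  structure(list(label = label, rejection_rate = rate),
            class = "pupil_quality")
}

#' Choose which eye's dataset to analyse
#'
#' With an asymmetric pupillary light reflex the most reactive eye is used;
#' otherwise the eye with the lower trial rejection rate, ties going to the
#' right eye by convention. If both eyes are excluded the dataset is
#' unusable.
#'
#' @param left_quality,right_quality `pupil_quality` objects for each eye.
#' @param reflex `"symmetric"`, or `"left"` / `"right"` naming the most
#'   reactive eye when the light reflex is asymmetric.
#' @return `"left"` or `"right"`.
#' @export
select_eye <- function(left_quality, right_quality,
                       reflex = c("symmetric", "left", "right")) {
  reflex <- match.arg(reflex)
  if (reflex != "symmetric") return(reflex)
  if (left_quality$label == "excluded" && right_quality$label == "excluded")
    stop("both eyes excluded: dataset unusable", call. = FALSE)
  if (left_quality$label == "excluded") return("right")
  if (right_quality$label == "excluded") return("left")
  if (left_quality$rejection_rate < right_quality$rejection_rate) "left"
  else "right"
}

#' Full per-eye pupil preprocessing
#'
#' Artifact detection, linear gap interpolation and 10 Hz zero-phase
#' low-pass, in that order.
#'
#' @inheritParams detect_artifacts
#' @inheritParams lowpass
#' @return A list with `trace` (cleaned, filtered) and `interpolated`
#'   (per-sample flags).
#' @export
preprocess_pupil <- function(trace, sampling_rate = 120, cutoff = 10,
                             k_mad = 16, guard_ms = 50, zero_frac = 0.1) {
  mask <- detect_artifacts(trace, sampling_rate, k_mad = k_mad,
                           guard_ms = guard_ms, zero_frac = zero_frac)
  gi <- interpolate_gaps(trace, mask)
  list(trace = lowpass(gi$trace, cutoff, sampling_rate),
       interpolated = gi$interpolated)
}

#' End-to-end pupil preprocessing for a binocular recording
#'
#' Preprocesses both eyes, epochs them, grades each eye's quality, selects
#' the analysis eye, and returns its baseline-corrected epochs.
#'
#' @param recording Tibble with `time_s`, `left_px`, `right_px`.
#' @param schedule Schedule tibble.
#' @param reflex Pupillary-light-reflex symmetry, see [select_eye()].
#' @param ... Passed to [preprocess_pupil()] and [epoch_pupil()].
#' @inheritParams epoch_pupil
#' @return A list of class `pupil_dataset`: `epochs` (baseline-corrected,
#'   selected eye), `eye`, `quality` (selected eye's `pupil_quality`), and
#'   `per_eye` quality list.
#' @export
pupil_pipeline <- function(recording, schedule, sampling_rate = 120,
                           reflex = "symmetric", window = c(-0.5, 3.0),
                           trial_reject_threshold = 0.25, ...) {
  eyes <- list(left = recording$left_px, right = recording$right_px)
  prep <- purrr::map(eyes, preprocess_pupil, sampling_rate = sampling_rate,
                     ...)
  ep <- purrr::map(prep, ~ epoch_pupil(.x$trace, .x$interpolated, schedule,
                                       sampling_rate = sampling_rate,
                                       window = window,
                                       trial_reject_threshold =
                                         trial_reject_threshold,
                                       t0 = recording$time_s[1]))
  qual <- purrr::map(ep, assess_dataset_quality)
  eye <- select_eye(qual$left, qual$right, reflex = reflex)
  structure(list(epochs = baseline_correct(ep[[eye]]), eye = eye,
                 quality = qual[[eye]], per_eye = qual),
            class = "pupil_dataset")
}
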