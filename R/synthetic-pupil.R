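#' Pupil simulation parameters
#'
#' Defaults describe a bedside recording: 120 Hz binocular sampling, a
#' baseline diameter of ~50 px, a unit-peak gamma dilation kernel peaking
#' 1.3 s after trial onset, a generic 1-px dilation to any trial, an extra
#' 0.5-px dilation to global deviants, stationary AR(1) measurement noise of
#' 0.5 px, and a handful of blinks per minute.
#'
#' @param sampling_rate Samples per second (Hz).
#' @param baseline_diameter Resting pupil diameter (px).
#' @param kernel_peak_latency Peak latency of the dilation kernel (s).
#' @param kernel_shape Shape parameter of the gamma kernel (dimensionless).
#' @param amp_generic Dilation amplitude added on every trial (px).
#' @param amp_local Additional amplitude on local-deviant trials (px).
#' @param amp_global Additional amplitude on global-deviant trials (px).
#' @param noise_sd Stationary standard deviation of the AR(1) noise (px).
#' @param noise_ar1 Lag-1 autocorrelation of the noise, in `[0, 1)`.
#' @param blink_rate Expected blinks per minute.
#' @param blink_duration Mean near-zero plateau duration of a blink (s).
#' @param drift_amp Amplitude of an optional slow anticipatory ramp from
#'   trial onset to the fifth sound (px); a CNV-like nuisance, default off.
#'
#' @return A list of class `pupil_sim_params`.
#' @export
pupil_sim_params <- function(sampling_rate = 120, baseline_diameter = 50,
                             kernel_peak_latency = 1.3, kernel_shape = 2,
                             amp_generic = 1, amp_local = 0, amp_global = 0.5,
                             noise_sd = 0.5, noise_ar1 = 0.9,
                             blink_rate = 4, blink_duration = 0.3,
                             drift_amp = 0) {
  stopifnot(sampling_rate > 0, baseline_diameter > 0,
            kernel_peak_latency > 0, kernel_shape > 0,
            noise_sd >= 0, noise_ar1 >= 0, noise_ar1 < 1,
            blink_rate >= 0, blink_duration > 0)
  structure(as.list(environment()), class = "pupil_sim_params")
}

#' Unit-peak gamma dilation kernel
#'
#' `k(t) = (t / tp)^s * exp(s * (1 - t / tp))`, which rises from 0 at stimulus
#' onset to 1 at `t = tp` and decays smoothly afterwards — the conventional
#' impulse-response shape for event-related pupil dilation.
#'
#' @param t Time since trial onset (s); values `< 0` return 0.
#' @param peak_latency Peak time `tp` (s), must be positive.
#' @param shape Shape `s` (dimensionless), must be positive.
#' @return Kernel weights in `[0, 1]`, same length as `t`.
#' @export
pdr_kernel <- function(t, peak_latency = 1.3, shape = 2) {
  if (peak_latency <= 0) stop("peak_latency must be positive", call. = FALSE)
  if (shape <= 0) stop("shape must be positive", call. = FALSE)
  k <- ifelse(t <= 0, 0, (t / peak_latency)^shape *
                exp(shape * (1 - t / peak_latency)))
  k
}

trial_amplitude <- function(label, params) {
  params$amp_generic +
    params$amp_local * grepl("^LD", label) +
    params$amp_global * grepl("GD$", label)
}

# AR(1) noise with stationary sd `sd` and lag-1 correlation `rho`.
ar1_noise <- function(n, sd, rho) {
  if (sd == 0 || n == 0) return(numeric(n))
  innov_sd <- sd * sqrt(1 - rho^2)
  as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), rho,
                           method = "recursive",
                           init = stats::rnorm(1, 0, sd)))
}

# Blink profile: linear fall over 50 ms, near-zero plateau, linear recovery
# over 150 ms; plateau duration ~ N(blink_duration, blink_duration/4)
# truncated at 50 ms.
insert_blinks <- function(trace, fs, rate_per_min, mean_dur) {
  n <- length(trace)
  total_min <- n / fs / 60
  n_blinks <- stats::rpois(1, rate_per_min * total_min)
  intervals <- tibble::tibble(start = numeric(0), end = numeric(0))
  if (n_blinks == 0) return(list(trace = trace, intervals = intervals))
  fall <- round(0.050 * fs)
  recover <- round(0.150 * fs)
  starts <- sort(stats::runif(n_blinks, 0, n / fs))
  durs <- pmax(0.05, stats::rnorm(n_blinks, mean_dur, mean_dur / 4))
  floor_px <- 0.02 * stats::median(trace)
  for (b in seq_len(n_blinks)) {
    i0 <- max(1L, round(starts[b] * fs))
    plateau <- round(durs[b] * fs)
    idx_fall <- i0:min(n, i0 + fall)
    idx_plat <- min(n, i0 + fall):min(n, i0 + fall + plateau)
    idx_rec <- min(n, i0 + fall + plateau):min(n, i0 + fall + plateau + recover)
    from <- trace[idx_fall[1]]
    trace[idx_fall] <- seq(from, floor_px, length.out = length(idx_fall))
    trace[idx_plat] <- floor_px
    to <- trace[min(n, max(idx_rec) + 1)]
    trace[idx_rec] <- seq(floor_px, to, length.out = length(idx_rec))
    intervals <- dplyr::bind_rows(intervals, tibble::tibble(
      start = (idx_fall[1] - 1) / fs, end = (max(idx_rec) - 1) / fs))
  }
  list(trace = trace, intervals = intervals)
}

#' Simulate a binocular pupil recording for a stimulus schedule
#'
#' Each trial adds `(amp_generic + amp_local * 1[LD] + amp_global * 1[GD])`
#' times the dilation kernel to the baseline diameter. Both eyes share the
#' event-related signal and blinks but receive independent AR(1) noise.
#'
#' @param schedule A schedule tibble from [build_session()].
#' @param params A [pupil_sim_params()].
#' @param seed Optional integer seed; fixed seeds reproduce the recording.
#'
#' @return A list of class `pupil_sim` with elements
#'   `recording` (tibble: `time_s`, `left_px`, `right_px`),
#'   `truth` (per-trial tibble with onset, label and injected amplitude),
#'   `blinks` (tibble of blink start/end times, s) and `params`.
#' @export
simulate_pupil_session <- function(schedule, params = pupil_sim_params(),
                                   seed = NULL) {
  run <- function() {
    fs <- params$sampling_rate
    t_start <- -2  # pre-roll before the first trial (baseline exists)
    t_end <- max(schedule$onset) + 4  # room for the last trial's response
    n <- ceiling((t_end - t_start) * fs)
    time_s <- t_start + (seq_len(n) - 1) / fs
    signal_px <- rep(0, n)
    amps <- trial_amplitude(schedule$trial_label, params)
    for (i in seq_len(nrow(schedule))) {
      rel <- time_s - schedule$onset[i]
      live <- rel > 0 & rel < 6
      signal_px[live] <- signal_px[live] + amps[i] *
        pdr_kernel(rel[live], params$kernel_peak_latency, params$kernel_shape)
      if (params$drift_amp != 0) {
        ramp <- rel > 0 & rel <= 0.6
        signal_px[ramp] <- signal_px[ramp] +
          params$drift_amp * rel[ramp] / 0.6
      }
    }
    clean <- params$baseline_diameter + signal_px
    left <- clean + ar1_noise(n, params$noise_sd, params$noise_ar1)
    right <- clean + ar1_noise(n, params$noise_sd, params$noise_ar1)
    bl <- insert_blinks(left, fs, params$blink_rate, params$blink_duration)
    if (nrow(bl$intervals) > 0)  # report intervals on the recording clock
      bl$intervals <- dplyr::mutate(bl$intervals,
                                    start = .data$start + t_start,
                                    end = .data$end + t_start)
    # binocular blinks: apply the same occlusion profile to the right eye
    right2 <- right
    if (nrow(bl$intervals) > 0) {
      occl <- bl$trace / pmax(left, 1e-9)
      right2 <- right * occl
    }
    structure(list(
      recording = tibble::tibble(time_s = time_s, left_px = bl$trace,
                                 right_px = right2),
      truth = dplyr::mutate(schedule, amplitude_px = amps),
      blinks = bl$intervals,
      params = params), class = "pupil_sim")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Read and write delimited pupil exports
#'
#' The device export format is delimited text with columns `time_s`,
#' `left_px`, `right_px`; zero or empty diameters encode missing samples and
#' are read as `NA`.
#'
#' @param path File path.
#' @param recording Tibble with columns `time_s`, `left_px`, `right_px`.
#' @param delim Field delimiter.
#' @return `read_pupil_delim()` returns the recording tibble with zeros
#'   replaced by `NA`; `write_pupil_delim()` returns `path` invisibly.
#' @export
read_pupil_delim <- function(path, delim = ",") {
  rec <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  stopifnot(all(c("time_s", "left_px", "right_px") %in% names(rec)))
  dplyr::mutate(rec, dplyr::across(c("left_px", "right_px"),
                                   ~ dplyr::if_else(.x <= 0, NA_real_, .x)))
}

#' @rdname read_pupil_delim
#' @export
write_pupil_delim <- function(recording, path, delim = ",") {
  readr::write_delim(recording, path, delim = delim)
  invisible(path)
}
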