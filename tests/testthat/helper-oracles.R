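# Independent brute-force oracles used to cross-check the package's
# statistical primitives.

# Benjamini-Hochberg step-up, straight from the definition.
bh_oracle <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  ok <- which(ps <= seq_len(m) * q / m)
  mask <- rep(FALSE, m)
  if (length(ok) > 0) mask[p <= ps[max(ok)]] <- TRUE
  mask
}

# BH adjusted p-values: running minimum of m * p_(k) / k from the top.
bh_adjust_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- rev(cummin(rev(pmin(1, m * ps / seq_len(m)))))
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Two-sided Fisher exact p by full enumeration with choose().
fisher_oracle <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  xs <- max(0, k - n):min(k, m)
  pr <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
  obs <- choose(m, tab[1, 1]) * choose(n, k - tab[1, 1]) / choose(m + n, k)
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# Exact Clopper-Pearson coverage by enumeration over the binomial support.
cp_exact_coverage <- function(p, n, alpha = 0.05) {
  covered <- vapply(0:n, function(k) {
    ci <- clopper_pearson(k, n, alpha)
    ci[["low"]] <= p && p <= ci[["high"]]
  }, logical(1))
  sum(stats::dbinom(0:n, n, p)[covered])
}

# A small schedule with widely spaced trials: pupil responses do not overlap,
# so epochs reproduce the injected kernel exactly.
sparse_schedule <- function(n_trials = 12, soa_s = 14,
                            labels = rep(c("LSGS", "LDGD"), length.out = n_trials)) {
  tibble::tibble(
    trial = seq_len(n_trials),
    onset = (seq_len(n_trials) - 1) * soa_s + 2,
    duration = 0.65,
    series = "AAAAA",
    trial_label = labels,
    block_type = "AAAAA",
    is_habituation = FALSE)
}

# Epochs built directly from a trial x sample matrix (already clean).
matrix_pupil_epochs <- function(data, labels, sampling_rate = 120,
                                window = c(-0.5, 3.0)) {
  ep <- structure(list(
    data = data,
    interp = matrix(FALSE, nrow(data), ncol(data)),
    times = (round(window[1] * sampling_rate) + seq_len(ncol(data)) - 1) /
      sampling_rate,
    labels = labels,
    is_habituation = rep(FALSE, nrow(data)),
    interp_fraction = rep(0, nrow(data)),
    rejected = rep(FALSE, nrow(data)),
    reject_reason = rep(NA_character_, nrow(data)),
    sampling_rate = sampling_rate, window = window,
    baseline_window = c(-0.5, 0), baseline_corrected = FALSE),
    class = "pupil_epochs")
  baseline_correct(ep)
}

# ERP epochs of pure white noise plus an optional boxcar effect injected on
# given channels/samples of condition-A trials.
noise_erp_epochs <- function(n_a = 20, n_b = 20, montage = grid_montage(),
                             noise_sd = 1, effect = 0,
                             effect_channels = integer(0),
                             effect_samples = integer(0)) {
  n_ch <- nrow(montage$channels)
  n_samp <- 386
  n <- n_a + n_b
  arr <- array(stats::rnorm(n * n_ch * n_samp, 0, noise_sd),
               c(n, n_ch, n_samp))
  if (effect != 0)
    arr[seq_len(n_a), effect_channels, effect_samples] <-
      arr[seq_len(n_a), effect_channels, effect_samples] + effect
  erp_epochs(arr, rep(c("LDGD", "LSGS"), c(n_a, n_b)), montage)
}
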