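#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward band-pass (default 0.5-45 Hz), applied per channel.
#'
#' @param data Numeric vector or channel x time matrix (µV).
#' @param low,high Band edges (Hz), `0 < low < high < Nyquist`.
#' @param sampling_rate Hz.
#' @param order One-pass Butterworth order.
#' @return Filtered data, same shape.
#' @export
bandpass <- function(data, low = 0.5, high = 45, sampling_rate = 250,
                     order = 3) {
  if (!(low > 0 && low < high && high < sampling_rate / 2))
    stop("band must satisfy 0 < low < high < Nyquist", call. = FALSE)
  bf <- signal::butter(order, c(low, high) / (sampling_rate / 2),
                       type = "pass")
  pad <- round(3 * sampling_rate / low)
  if (is.matrix(data)) {
    t(apply(data, 1, function(ch) zero_phase_filter(bf, ch, pad = pad)))
  } else {
    zero_phase_filter(bf, data, pad = pad)
  }
}

#' Epoch a continuous EEG recording around trial onsets
#'
#' Extracts a fixed window (default -0.200 to +1.344 s from first-sound
#' onset; 386 samples at 250 Hz) per trial. Trials whose window exceeds the
#' recording are dropped and counted in `n_dropped`.
#'
#' @param data Channel x time matrix (µV).
#' @param schedule Schedule tibble with session-relative `onset` (s) and
#'   `trial_label`.
#' @param montage The recording montage.
#' @param sampling_rate Hz.
#' @param window Epoch window (s) relative to first-sound onset.
#' @param t0 Time of the first data column on the schedule's clock (s).
#' @return An object of class `erp_epochs`: `data`
#'   (trial x channel x sample array), `times`, `labels`, logical
#'   `valid_channels` / `valid_epochs` masks, `interpolated_channels`,
#'   `montage`, `sampling_rate`, `n_dropped`.
#' @export
epoch_eeg <- function(data, schedule, montage, sampling_rate = 250,
                      window = c(-0.200, 1.344), t0 = 0) {
  stopifnot(is.matrix(data), window[1] < window[2])
  fs <- sampling_rate
  n_samp <- round((window[2] - window[1]) * fs)
  offsets <- round(window[1] * fs) + seq_len(n_samp) - 1L
  onset_idx <- round((schedule$onset - t0) * fs) + 1L
  ok <- onset_idx + offsets[1] >= 1 & onset_idx + offsets[n_samp] <= ncol(data)
  n_dropped <- sum(!ok)
  sched <- schedule[ok, ]
  n_trials <- nrow(sched)
  n_ch <- nrow(data)
  arr <- array(NA_real_, c(n_trials, n_ch, n_samp))
  for (i in seq_len(n_trials)) {
    idx <- round((sched$onset[i] - t0) * fs) + 1L + offsets
    arr[i, , ] <- data[, idx]
  }
  ch_names <- montage$channels$channel
  structure(list(data = arr, times = offsets / fs,
                 labels = sched$trial_label,
                 valid_channels = stats::setNames(rep(TRUE, n_ch), ch_names),
                 valid_epochs = rep(TRUE, n_trials),
                 interpolated_channels = character(0),
                 montage = montage, sampling_rate = fs,
                 n_dropped = n_dropped), class = "erp_epochs")
}

#' Construct an ERP epochs object from an array
#'
#' Assembles a `trial x channel x sample` array, trial labels and a montage
#' into the epochs container used throughout the ERP pipeline — convenient
#' for simulation studies that build epochs directly rather than cutting
#' them from a continuous recording.
#'
#' @param data Trial x channel x sample array (µV).
#' @param labels Per-trial labels (length = first dimension).
#' @param montage The montage (channel count = second dimension).
#' @param sampling_rate Hz.
#' @param window Epoch window (s) relative to first-sound onset; sample
#'   times are derived from it.
#' @return An `erp_epochs` object with all channels and epochs valid.
#' @export
erp_epochs <- function(data, labels, montage, sampling_rate = 250,
                       window = c(-0.200, 1.344)) {
  stopifnot(length(dim(data)) == 3, length(labels) == dim(data)[1],
            nrow(montage$channels) == dim(data)[2])
  n_samp <- dim(data)[3]
  offsets <- round(window[1] * sampling_rate) + seq_len(n_samp) - 1L
  structure(list(data = data, times = offsets / sampling_rate,
                 labels = labels,
                 valid_channels = stats::setNames(rep(TRUE, dim(data)[2]),
                                                  montage$channels$channel),
                 valid_epochs = rep(TRUE, dim(data)[1]),
                 interpolated_channels = character(0),
                 montage = montage, sampling_rate = sampling_rate,
                 n_dropped = 0L), class = "erp_epochs")
}

# per-channel variance over currently valid epochs, concatenated samples
channel_variances <- function(epochs) {
  keep <- epochs$valid_epochs
  vapply(seq_along(epochs$valid_channels), function(ch) {
    stats::var(as.vector(epochs$data[keep, ch, ]))
  }, numeric(1))
}

epoch_variances <- function(epochs) {
  keep_ch <- epochs$valid_channels
  vapply(seq_along(epochs$valid_epochs), function(i) {
    stats::var(as.vector(epochs$data[i, keep_ch, ]))
  }, numeric(1))
}

#' Iterative bad-channel rejection
#'
#' First removes channels whose absolute voltage exceeds `amp_thresh`
#' (100 µV) in more than `amp_epoch_frac` (50%) of the epochs. Then, for
#' `n_iter` passes, computes each remaining channel's voltage variance over
#' valid epochs and removes channels whose variance Z-score (across the
#' currently valid channels) exceeds `z_thresh`; removed channels stay
#' removed.
#'
#' @param epochs An `erp_epochs` object.
#' @param amp_thresh Absolute amplitude criterion (µV).
#' @param amp_epoch_frac Fraction of epochs that must exceed it (strictly).
#' @param z_thresh Variance Z-score criterion (strictly exceeded).
#' @param n_iter Number of variance-rejection passes.
#' @return The epochs with `valid_channels` updated.
#' @export
reject_channels <- function(epochs, amp_thresh = 100, amp_epoch_frac = 0.5,
                            z_thresh = 4, n_iter = 4) {
  stopifnot(inherits(epochs, "erp_epochs"))
  if (sum(epochs$valid_channels) < 2)
    stop("need at least 2 valid channels", call. = FALSE)
  n_ch <- length(epochs$valid_channels)
  # amplitude rule: fraction of epochs in which the channel ever exceeds
  frac <- vapply(seq_len(n_ch), function(ch) {
    mean(apply(abs(epochs$data[, ch, , drop = FALSE]), 1, max) > amp_thresh)
  }, numeric(1))
  epochs$valid_channels <- epochs$valid_channels & !(frac > amp_epoch_frac)
  for (it in seq_len(n_iter)) {
    v <- channel_variances(epochs)
    v[!epochs$valid_channels] <- NA
    z <- (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
    bad <- !is.na(z) & z > z_thresh
    if (!any(bad)) next
    epochs$valid_channels <- epochs$valid_channels & !bad
  }
  if (!any(epochs$valid_channels))
    stop("all channels removed by rejection rules", call. = FALSE)
  epochs
}

# Thin-plate-spline interpolation weights: value at target point as a linear
# combination of the valid channels' values (exact for constant and linear
# fields).
tps_weights <- function(xy_valid, xy_target) {
  n <- nrow(xy_valid)
  r2 <- as.matrix(stats::dist(xy_valid))^2
  U <- ifelse(r2 == 0, 0, r2 * log(sqrt(r2)))
  P <- cbind(1, xy_valid)
  K <- rbind(cbind(U, P), cbind(t(P), matrix(0, 3, 3)))
  d2 <- rowSums(sweep(xy_valid, 2, xy_target)^2)
  u0 <- ifelse(d2 == 0, 0, d2 * log(sqrt(d2)))
  phi <- c(u0, 1, xy_target)
  # value(target) = phi^T K^{-1} [values; 0]; weights are the first n entries
  as.numeric(phi %*% solve(K))[seq_len(n)]
}

#' Interpolate bad channels from the montage geometry
#'
#' Reconstructs each invalid channel by thin-plate-spline interpolation over
#' the valid channels (the planar analogue of spherical-spline scalp
#' interpolation). A bad channel with fewer than `min_neighbors` valid
#' montage neighbours is left invalid.
#'
#' @param epochs An `erp_epochs` object.
#' @param min_neighbors Minimum valid adjacent channels required.
#' @return The epochs with bad channels reconstructed, marked valid and
#'   listed in `interpolated_channels`.
#' @export
interpolate_channels <- function(epochs, min_neighbors = 3) {
  stopifnot(inherits(epochs, "erp_epochs"))
  mont <- epochs$montage
  ch_names <- mont$channels$channel
  bad <- which(!epochs$valid_channels)
  if (length(bad) == 0) return(epochs)
  good <- which(epochs$valid_channels)
  if (length(good) < 3)
    stop("need at least 3 valid channels to interpolate", call. = FALSE)
  xy <- as.matrix(mont$channels[, c("x", "y")])
  for (ch in bad) {
    nbrs <- mont$adjacency[[ch_names[ch]]]
    if (sum(nbrs %in% ch_names[good]) < min_neighbors) next
    w <- tps_weights(xy[good, , drop = FALSE], xy[ch, ])
    # data[, good, ] is trial x good x sample; contract over channels
    n_tr <- dim(epochs$data)[1]
    for (i in seq_len(n_tr)) {
      epochs$data[i, ch, ] <-
        as.numeric(w %*% epochs$data[i, good, , drop = TRUE])
    }
    epochs$valid_channels[ch] <- TRUE
    epochs$interpolated_channels <- union(epochs$interpolated_channels,
                                          ch_names[ch])
  }
  epochs
}

#' Iterative bad-epoch rejection
#'
#' Discards epochs whose voltage exceeds `amp_thresh` (100 µV) on strictly
#' more than `chan_frac` (10%) of the valid electrodes, then runs `n_iter`
#' passes removing epochs whose voltage variance Z-score across the
#' remaining epochs exceeds `z_thresh`.
#'
#' @inheritParams reject_channels
#' @param chan_frac Fraction of valid electrodes that must exceed the
#'   amplitude criterion (strictly).
#' @return The epochs with `valid_epochs` updated.
#' @export
reject_epochs <- function(epochs, amp_thresh = 100, chan_frac = 0.1,
                          z_thresh = 4, n_iter = 4) {
  stopifnot(inherits(epochs, "erp_epochs"))
  if (sum(epochs$valid_epochs) < 2)
    stop("need at least 2 valid epochs", call. = FALSE)
  keep_ch <- epochs$valid_channels
  frac <- vapply(seq_along(epochs$valid_epochs), function(i) {
    exceed <- apply(abs(epochs$data[i, keep_ch, , drop = FALSE]), 2, max) >
      amp_thresh
    mean(exceed)
  }, numeric(1))
  epochs$valid_epochs <- epochs$valid_epochs & !(frac > chan_frac)
  for (it in seq_len(n_iter)) {
    v <- epoch_variances(epochs)
    v[!epochs$valid_epochs] <- NA
    z <- (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
    bad <- !is.na(z) & z > z_thresh
    if (!any(bad)) next
    epochs$valid_epochs <- epochs$valid_epochs & !bad
  }
  if (!any(epochs$valid_epochs))
    stop("all epochs removed by rejection rules", call. = FALSE)
  epochs
}

#' Re-reference epochs to the average of valid channels
#'
#' Subtracts, at every trial and sample, the mean over valid channels.
#' Idempotent; between-channel differences are unchanged.
#'
#' @param epochs An `erp_epochs` object.
#' @return The re-referenced epochs (`reference = "average"`).
#' @export
rereference_average <- function(epochs) {
  stopifnot(inherits(epochs, "erp_epochs"))
  keep <- epochs$valid_channels
  n_tr <- dim(epochs$data)[1]
  for (i in seq_len(n_tr)) {
    m <- colMeans(epochs$data[i, keep, , drop = TRUE])
    epochs$data[i, , ] <- sweep(epochs$data[i, , , drop = TRUE], 2, m)
  }
  epochs$reference <- "average"
  epochs
}

#' Baseline-correct ERP epochs up to the fifth-sound onset
#'
#' Subtracts, per trial and channel, the mean voltage over the 800-ms window
#' ending at the fifth-sound onset (+600 ms after the first sound at default
#' tone timing), i.e. (-0.200, +0.600) s.
#'
#' @param epochs An `erp_epochs` object.
#' @param window Baseline window (s) relative to first-sound onset.
#' @return The baseline-corrected epochs.
#' @export
baseline_erp <- function(epochs, window = c(-0.200, 0.600)) {
  stopifnot(inherits(epochs, "erp_epochs"))
  in_bl <- epochs$times >= window[1] & epochs$times < window[2]
  if (!any(in_bl)) stop("baseline window outside the epoch", call. = FALSE)
  n_tr <- dim(epochs$data)[1]
  for (i in seq_len(n_tr)) {
    bl <- rowMeans(epochs$data[i, , in_bl, drop = TRUE])
    epochs$data[i, , ] <- epochs$data[i, , , drop = TRUE] - bl
  }
  epochs$baseline_window <- window
  epochs
}

#' Grade an EEG dataset's quality
#'
#' `correct` requires at least 75% valid channels and at least 30% valid
#' epochs; otherwise `poor`.
#'
#' @param epochs An `erp_epochs` object.
#' @param min_channel_frac,min_epoch_frac Validity thresholds.
#' @return `"correct"` or `"poor"`.
#' @export
erp_quality <- function(epochs, min_channel_frac = 0.75,
                        min_epoch_frac = 0.30) {
  stopifnot(inherits(epochs, "erp_epochs"))
  ch <- mean(epochs$valid_channels)
  ep <- mean(epochs$valid_epochs)
  if (ch >= min_channel_frac && ep >= min_epoch_frac) "correct" else "poor"
}

welch_t_map <- function(a, b) {
  # a, b: trial x channel x sample arrays
  n1 <- dim(a)[1]; n2 <- dim(b)[1]
  m1 <- colMeans(a); m2 <- colMeans(b)
  v1 <- (colMeans(a^2) - m1^2) * n1 / (n1 - 1)
  v2 <- (colMeans(b^2) - m2^2) * n2 / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  p[se2 == 0] <- ifelse((m1 - m2)[se2 == 0] == 0, 1, 0)
  list(t = t, p = p)
}

#' Triple-threshold spatio-temporal ERP effect
#'
#' Runs an unpaired Welch t-test at every (channel, sample) between two trial
#' sets, thresholds the p-map at `alpha`, and declares the effect significant
#' only if, inside the expected time window, some run of at least
#' `min_samples` consecutive samples shares a set of at least `min_channels`
#' electrodes that (a) are below threshold throughout the run and (b) form a
#' connected subgraph of the montage adjacency. `mode = "component"` relaxes
#' the constant-channel-set requirement to a single connected
#' spatio-temporal component spanning the same extents.
#'
#' @param epochs A preprocessed `erp_epochs` object.
#' @param spec A [contrast_spec()] (`"local"`, `"global"` or `"mve"`).
#' @param window Time window (s) in which the effect is expected. Defaults
#'   (when `NULL`) anchor to the fifth-sound onset at +0.6 s: local 0.7 s to
#'   epoch end, global/mve 0.8 s to epoch end.
#' @param alpha Per-test significance threshold.
#' @param min_samples Minimum consecutive significant samples.
#' @param min_channels Minimum contiguous significant electrodes.
#' @param mode `"strict"` (constant channel set over the run) or
#'   `"component"` (connected spatio-temporal component).
#' @return A list of class `erp_cluster_result`: `significant`, `clusters`
#'   (tibble: channel count, start/end time, minimum p), `window`, and the
#'   per-(channel, sample) `t` and `p` maps.
#' @export
triple_threshold_effect <- function(epochs, spec, window = NULL,
                                    alpha = 0.05, min_samples = 5,
                                    min_channels = 10,
                                    mode = c("strict", "component")) {
  mode <- match.arg(mode)
  stopifnot(inherits(epochs, "erp_epochs"), inherits(spec, "contrast_spec"))
  if (is.null(epochs$montage$adjacency))
    stop("montage adjacency is required for the contiguity criterion",
         call. = FALSE)
  if (is.null(window)) {
    window <- if (spec$name == "local") c(0.7, max(epochs$times))
              else c(0.8, max(epochs$times))
  }
  keep_ep <- epochs$valid_epochs
  sel <- function(labels) keep_ep & epochs$labels %in% labels
  ia <- sel(spec$condition_a); ib <- sel(spec$condition_b)
  if (sum(ia) < 2 || sum(ib) < 2)
    stop("need at least 2 valid epochs per condition", call. = FALSE)
  tm <- welch_t_map(epochs$data[ia, , , drop = FALSE],
                    epochs$data[ib, , , drop = FALSE])
  sig <- tm$p < alpha
  sig[!epochs$valid_channels, ] <- FALSE
  in_win <- epochs$times >= window[1] & epochs$times <= window[2]
  sig[, !in_win] <- FALSE
  g <- montage_graph(epochs$montage)
  ch_names <- epochs$montage$channels$channel
  clusters <- tibble::tibble(n_channels = integer(0), t_start = numeric(0),
                             t_end = numeric(0), min_p = numeric(0))
  found <- FALSE
  win_idx <- which(in_win)
  if (mode == "strict") {
    for (s in win_idx) {
      if (s + min_samples - 1 > max(win_idx)) break
      run <- s:(s + min_samples - 1)
      common <- which(rowSums(sig[, run, drop = FALSE]) == length(run))
      if (length(common) < min_channels) next
      sub <- igraph::induced_subgraph(g, ch_names[common])
      comp <- igraph::components(sub)
      if (max(comp$csize) >= min_channels) {
        big_names <- igraph::V(sub)$name[comp$membership ==
                                           which.max(comp$csize)]
        big <- match(big_names, ch_names)
        # extend the run while the component stays jointly significant
        e <- max(run)
        while (e + 1 <= max(win_idx) && all(sig[big, e + 1])) e <- e + 1
        clusters <- dplyr::bind_rows(clusters, tibble::tibble(
          n_channels = max(comp$csize),
          t_start = epochs$times[s], t_end = epochs$times[e],
          min_p = min(tm$p[big, s:e])))
        found <- TRUE
      }
    }
    clusters <- dplyr::distinct(clusters, .data$n_channels, .data$t_end,
                                .keep_all = TRUE)
  } else {
    # connected components over (channel, sample) nodes: channel adjacency
    # at equal samples, plus same-channel consecutive samples
    nodes <- which(sig, arr.ind = TRUE)
    if (nrow(nodes) > 0) {
      id <- function(ch, s) paste0(ch, "_", s)
      adj_idx <- purrr::map(ch_names, ~ match(epochs$montage$adjacency[[.x]],
                                              ch_names))
      edges <- list()
      node_set <- new.env(hash = TRUE)
      for (r in seq_len(nrow(nodes)))
        assign(id(nodes[r, 1], nodes[r, 2]), TRUE, envir = node_set)
      for (r in seq_len(nrow(nodes))) {
        ch <- nodes[r, 1]; s <- nodes[r, 2]
        if (exists(id(ch, s + 1), envir = node_set, inherits = FALSE))
          edges[[length(edges) + 1]] <- c(id(ch, s), id(ch, s + 1))
        for (nb in adj_idx[[ch]])
          if (nb > ch && exists(id(nb, s), envir = node_set,
                                inherits = FALSE))
            edges[[length(edges) + 1]] <- c(id(ch, s), id(nb, s))
      }
      vnames <- apply(nodes, 1, function(r) id(r[1], r[2]))
      if (length(edges) > 0) {
        gg <- igraph::graph_from_edgelist(do.call(rbind, edges),
                                          directed = FALSE)
        gg <- gg + igraph::vertices(setdiff(vnames, igraph::V(gg)$name))
      } else {
        gg <- igraph::make_empty_graph(directed = FALSE) +
          igraph::vertices(vnames)
      }
      comp <- igraph::components(gg)
      for (k in seq_len(comp$no)) {
        mem <- igraph::V(gg)$name[comp$membership == k]
        parts <- do.call(rbind, strsplit(mem, "_"))
        chs <- unique(as.integer(parts[, 1]))
        ss <- sort(unique(as.integer(parts[, 2])))
        runs <- rle(diff(ss) == 1)
        max_run <- if (length(ss) == 1) 1 else
          max(runs$lengths[runs$values], 0) + 1
        if (length(chs) >= min_channels && max_run >= min_samples) {
          clusters <- dplyr::bind_rows(clusters, tibble::tibble(
            n_channels = length(chs),
            t_start = epochs$times[min(ss)], t_end = epochs$times[max(ss)],
            min_p = min(tm$p[cbind(as.integer(parts[, 1]),
                                   as.integer(parts[, 2]))])))
          found <- TRUE
        }
      }
    }
  }
  structure(list(significant = found, clusters = clusters, window = window,
                 t = tm$t, p = tm$p, times = epochs$times,
                 channels = ch_names, contrast = spec$name, mode = mode),
            class = "erp_cluster_result")
}

#' Standard ERP preprocessing chain
#'
#' Band-pass, epoch, channel rejection, spline interpolation of bad
#' channels, epoch rejection, average re-reference and baseline correction,
#' in the conventional order.
#'
#' @param data Channel x time matrix (µV).
#' @param schedule Schedule tibble.
#' @param montage The montage.
#' @param sampling_rate Hz.
#' @param t0 Time of the first data column on the schedule's clock (s).
#' @return A list of class `erp_dataset`: `epochs` (preprocessed) and
#'   `quality` (`"correct"` / `"poor"`).
#' @export
erp_pipeline <- function(data, schedule, montage, sampling_rate = 250,
                         t0 = 0) {
  filtered <- bandpass(data, sampling_rate = sampling_rate)
  ep <- epoch_eeg(filtered, schedule, montage, sampling_rate, t0 = t0)
  ep <- reject_channels(ep)
  ep <- interpolate_channels(ep)
  ep <- reject_epochs(ep)
  ep <- rereference_average(ep)
  ep <- baseline_erp(ep)
  structure(list(epochs = ep, quality = erp_quality(ep)),
            class = "erp_dataset")
}
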