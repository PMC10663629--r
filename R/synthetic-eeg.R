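#' Planar grid montage with rook adjacency
#'
#' A synthetic electrode layout: `nrow x ncol` channels on a unit-spaced
#' planar grid, each channel adjacent to its horizontal and vertical
#' neighbours. The adjacency is an explicit graph, serialisable to JSON.
#'
#' @param nrow,ncol Grid dimensions (default 4 x 8 = 32 channels).
#' @return A list of class `montage` with `channels` (tibble: `channel`,
#'   `x`, `y`) and `adjacency` (named list of neighbour channel names).
#' @export
grid_montage <- function(nrow = 4, ncol = 8) {
  stopifnot(nrow >= 1, ncol >= 1)
  ch <- tibble::tibble(
    row = rep(seq_len(nrow), each = ncol),
    col = rep(seq_len(ncol), times = nrow))
  ch <- dplyr::mutate(ch,
                      channel = sprintf("E%02d", dplyr::row_number()),
                      x = .data$col - 1, y = .data$row - 1)
  adj <- purrr::map(seq_len(nrow(ch)), function(i) {
    d <- abs(ch$row - ch$row[i]) + abs(ch$col - ch$col[i])
    ch$channel[d == 1]
  })
  names(adj) <- ch$channel
  structure(list(channels = ch[c("channel", "x", "y")], adjacency = adj),
            class = "montage")
}

#' @rdname grid_montage
#' @param montage A `montage` object.
#' @param path File path for the montage JSON (one record per channel with
#'   name, position and neighbour list).
#' @export
write_montage_json <- function(montage, path) {
  recs <- purrr::pmap(montage$channels, function(channel, x, y) {
    list(channel = channel, x = x, y = y,
         neighbors = montage$adjacency[[channel]])
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname grid_montage
#' @export
read_montage_json <- function(path) {
  recs <- jsonlite::read_json(path)
  ch <- purrr::map_dfr(recs, ~ tibble::tibble(channel = .x$channel,
                                              x = .x$x, y = .x$y))
  adj <- purrr::map(recs, ~ as.character(unlist(.x$neighbors)))
  names(adj) <- ch$channel
  structure(list(channels = ch, adjacency = adj), class = "montage")
}

montage_graph <- function(montage) {
  edges <- purrr::imap_dfr(montage$adjacency, function(nbrs, ch) {
    if (length(nbrs) == 0) return(tibble::tibble())
    tibble::tibble(from = ch, to = nbrs)
  })
  igraph::graph_from_data_frame(edges[edges$from < edges$to, ],
                                directed = FALSE,
                                vertices = montage$channels$channel)
}

#' EEG simulation parameters
#'
#' Scalp EEG around the local-global paradigm: 250 Hz sampling, an MMN-like
#' negativity on local-deviant trials and a P3b-like positivity on
#' global-deviant trials, both time-locked to the fifth sound (600 ms after
#' trial onset at default tone timing), with Gaussian spatial profiles on the
#' montage, white sensor noise, and configurable rates of bad channels and
#' high-amplitude artifact epochs.
#'
#' @param sampling_rate Hz.
#' @param montage A [grid_montage()]-style montage.
#' @param mmn_amp MMN amplitude (µV, applied as a negativity).
#' @param mmn_latency,mmn_width Gaussian latency and SD (s) relative to the
#'   fifth-sound onset.
#' @param p3b_amp P3b amplitude (µV, positivity).
#' @param p3b_latency,p3b_width Latency and SD (s) relative to fifth sound.
#' @param mmn_center,p3b_center Channel names at the centre of each spatial
#'   profile (defaults: grid centre-front and centre-back).
#' @param profile_sd Spatial Gaussian SD in grid units.
#' @param noise_sd Sensor noise SD (µV).
#' @param bad_channel_rate Fraction of channels rendered high-variance.
#' @param artifact_epoch_rate Fraction of trials given >100 µV excursions.
#'
#' @return A list of class `eeg_sim_params`.
#' @export
eeg_sim_params <- function(sampling_rate = 250, montage = grid_montage(),
                           mmn_amp = 3, mmn_latency = 0.15, mmn_width = 0.05,
                           p3b_amp = 5, p3b_latency = 0.4, p3b_width = 0.1,
                           mmn_center = NULL, p3b_center = NULL,
                           profile_sd = 2.5, noise_sd = 5,
                           bad_channel_rate = 0, artifact_epoch_rate = 0) {
  stopifnot(sampling_rate > 0, inherits(montage, "montage"),
            noise_sd >= 0, bad_channel_rate >= 0, bad_channel_rate <= 1,
            artifact_epoch_rate >= 0, artifact_epoch_rate <= 1)
  ch <- montage$channels
  if (is.null(mmn_center))
    mmn_center <- ch$channel[which.min((ch$x - stats::median(ch$x))^2 + ch$y^2)]
  if (is.null(p3b_center))
    p3b_center <- ch$channel[which.min((ch$x - stats::median(ch$x))^2 +
                                         (ch$y - max(ch$y))^2)]
  structure(list(sampling_rate = sampling_rate, montage = montage,
                 mmn_amp = mmn_amp, mmn_latency = mmn_latency,
                 mmn_width = mmn_width, p3b_amp = p3b_amp,
                 p3b_latency = p3b_latency, p3b_width = p3b_width,
                 mmn_center = mmn_center, p3b_center = p3b_center,
                 profile_sd = profile_sd, noise_sd = noise_sd,
                 bad_channel_rate = bad_channel_rate,
                 artifact_epoch_rate = artifact_epoch_rate),
            class = "eeg_sim_params")
}

spatial_profile <- function(montage, center, sd) {
  ch <- montage$channels
  c0 <- ch[ch$channel == center, ]
  exp(-((ch$x - c0$x)^2 + (ch$y - c0$y)^2) / (2 * sd^2))
}

#' Simulate a continuous multichannel EEG recording for a schedule
#'
#' Local-deviant trials receive an MMN-like negativity and global-deviant
#' trials a P3b-like positivity, each a temporal Gaussian at its configured
#' latency after the fifth-sound onset (trial onset + 4 x SOA), scaled by a
#' spatial profile over the montage. Bad channels get 10x noise; artifact
#' trials get a 150 µV low-frequency excursion on all channels.
#'
#' @param schedule Schedule tibble with session-relative `onset` (s).
#' @param params An [eeg_sim_params()].
#' @param seed Optional integer seed.
#' @param soa_ms Tone SOA used to place the fifth-sound onset (ms).
#'
#' @return A list of class `eeg_sim`: `data` (channel x time matrix, µV),
#'   `times` (s), `sampling_rate`, `montage`, `truth` (schedule plus injected
#'   flags), `bad_channels`, `artifact_trials`.
#' @export
simulate_eeg_session <- function(schedule, params = eeg_sim_params(),
                                 seed = NULL, soa_ms = 150) {
  run <- function() {
    fs <- params$sampling_rate
    mont <- params$montage
    n_ch <- nrow(mont$channels)
    t_start <- -1  # pre-roll so the first epoch's baseline exists
    t_end <- max(schedule$onset) + 3
    n <- ceiling((t_end - t_start) * fs)
    times <- t_start + (seq_len(n) - 1) / fs
    data <- matrix(stats::rnorm(n_ch * n, 0, params$noise_sd), n_ch, n)
    bad <- sample(mont$channels$channel,
                  round(params$bad_channel_rate * n_ch))
    if (length(bad) > 0) {
      idx <- match(bad, mont$channels$channel)
      data[idx, ] <- data[idx, , drop = FALSE] * 20
    }
    prof_mmn <- params$mmn_amp * spatial_profile(mont, params$mmn_center,
                                                 params$profile_sd)
    prof_p3b <- params$p3b_amp * spatial_profile(mont, params$p3b_center,
                                                 params$profile_sd)
    fifth <- 4 * soa_ms / 1000
    art <- sample(seq_len(nrow(schedule)),
                  round(params$artifact_epoch_rate * nrow(schedule)))
    for (i in seq_len(nrow(schedule))) {
      rel <- times - schedule$onset[i] - fifth
      if (grepl("^LD", schedule$trial_label[i])) {
        w <- exp(-(rel - params$mmn_latency)^2 / (2 * params$mmn_width^2))
        live <- which(abs(rel - params$mmn_latency) < 4 * params$mmn_width)
        data[, live] <- data[, live] - prof_mmn %o% w[live]
      }
      if (grepl("GD$", schedule$trial_label[i])) {
        w <- exp(-(rel - params$p3b_latency)^2 / (2 * params$p3b_width^2))
        live <- which(abs(rel - params$p3b_latency) < 4 * params$p3b_width)
        data[, live] <- data[, live] + prof_p3b %o% w[live]
      }
      if (i %in% art) {
        # movement-like burst well inside the 0.5-45 Hz band
        rel2 <- times - schedule$onset[i]
        live <- which(rel2 >= 0 & rel2 < 0.5)
        data[, live] <- data[, live] +
          matrix(150 * sin(2 * pi * 4 * rel2[live]), n_ch, length(live),
                 byrow = TRUE)
      }
    }
    structure(list(data = data, times = times, sampling_rate = fs,
                   montage = mont,
                   truth = dplyr::mutate(schedule,
                                         artifact = dplyr::row_number() %in% art),
                   bad_channels = bad,
                   artifact_trials = sort(art)), class = "eeg_sim")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
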