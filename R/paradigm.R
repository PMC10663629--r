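#' Auditory local-global stimulus schedules
#'
#' The local-global paradigm crosses two auditory regularities. Each trial is
#' a series of five 50-ms tones (low-pitched `A` or high-pitched `B`) with a
#' 150-ms stimulus-onset asynchrony: the fifth tone either repeats the first
#' four (local standard, LS) or differs from them (local deviant, LD). Within
#' a block one series is presented frequently (~80% of trials) and establishes
#' the global regularity; trials repeating it are global standards (GS) and
#' the rare alternative series are global deviants (GD). Four block types are
#' used, one per possible frequent series (AAAAA, BBBBB, AAAAB, BBBBA), so
#' that local and global deviance are fully crossed over a session.
#'
#' @name paradigm
#' @keywords internal
NULL

#' Timing and structure parameters for the local-global paradigm
#'
#' @param tone_duration_ms Duration of each tone in milliseconds.
#' @param soa_ms Sound-onset asynchrony between consecutive tones (ms).
#' @param trial_soa_ms Onset-to-onset asynchrony between consecutive trials
#'   (ms). The default of 3000 ms makes a 30-trial block last 90 s.
#' @param n_trials Trials per block.
#' @param n_habituation Number of initial frequent-series trials that
#'   establish the global regularity before any deviant may occur.
#' @param deviant_range Inclusive integer range from which the per-block
#'   number of global deviants is drawn uniformly.
#'
#' @return A list of class `paradigm_config`.
#' @export
paradigm_config <- function(tone_duration_ms = 50, soa_ms = 150,
                            trial_soa_ms = 3000, n_trials = 30,
                            n_habituation = 5, deviant_range = c(4L, 7L)) {
  stopifnot(tone_duration_ms > 0, soa_ms >= tone_duration_ms,
            trial_soa_ms > 0, n_trials >= 1,
            n_habituation >= 0, n_habituation < n_trials,
            length(deviant_range) == 2, deviant_range[1] <= deviant_range[2])
  structure(list(tone_duration_ms = tone_duration_ms, soa_ms = soa_ms,
                 trial_soa_ms = trial_soa_ms, n_trials = n_trials,
                 n_habituation = n_habituation,
                 deviant_range = as.integer(deviant_range)),
            class = "paradigm_config")
}

block_types <- function() c("AAAAA", "BBBBB", "AAAAB", "BBBBA")

validate_series <- function(series, arg = "series") {
  if (!is.character(series) || length(series) != 1 || is.na(series))
    stop(arg, " must be a single string of five tones", call. = FALSE)
  tones <- strsplit(series, "")[[1]]
  if (length(tones) != 5)
    stop(arg, " must contain exactly 5 tones, got ", length(tones),
         call. = FALSE)
  if (!all(tones %in% c("A", "B")))
    stop(arg, " may only contain tones 'A' and 'B'", call. = FALSE)
  if (length(unique(tones[1:4])) != 1)
    stop(arg, " must have four identical leading tones", call. = FALSE)
  tones
}

#' Label a five-tone series relative to a block's frequent series
#'
#' A series is a local deviant (LD) when its fifth tone differs from the first
#' four, and a global deviant (GD) when it is not the series that the block
#' presents frequently. The four combinations give the trial types LSGS,
#' LDGS, LSGD and LDGD.
#'
#' @param series Five-character string such as `"AAAAB"`; the first four
#'   tones must be identical.
#' @param frequent The block's frequent (global standard) series, same format.
#'
#' @return One of `"LSGS"`, `"LDGS"`, `"LSGD"`, `"LDGD"`.
#' @examples
#' label_trial("AAAAA", frequent = "AAAAA") # LSGS
#' label_trial("AAAAB", frequent = "AAAAA") # LDGD
#' @export
label_trial <- function(series, frequent) {
  tones <- validate_series(series, "series")
  validate_series(frequent, "frequent")
  local <- if (tones[5] != tones[1]) "LD" else "LS"
  global <- if (series != frequent) "GD" else "GS"
  paste0(local, global)
}

deviant_series_for <- function(block_type) {
  tones <- strsplit(block_type, "")[[1]]
  tones[5] <- setdiff(c("A", "B"), tones[5])
  paste(tones, collapse = "")
}

# Uniform draw over deviant placements that respect the habituation period,
# forbid adjacent deviants and keep the final trial a standard. Rejection
# sampling keeps the draw uniform over admissible sets.
draw_deviant_positions <- function(n_deviant, config) {
  slots <- seq(config$n_habituation + 1L, config$n_trials - 1L)
  n_free <- length(slots) - (n_deviant - 1L)  # non-adjacency feasibility
  if (n_deviant > 0 && n_free < n_deviant)
    stop("cannot place ", n_deviant, " non-adjacent deviants after ",
         config$n_habituation, " habituation trials in ", config$n_trials,
         " trials", call. = FALSE)
  if (n_deviant == 0) return(integer(0))
  repeat {
    pos <- sort(sample(slots, n_deviant))
    if (n_deviant == 1 || all(diff(pos) >= 2)) return(pos)
  }
}

#' Build one local-global block
#'
#' A block opens with `n_habituation` presentations of its frequent series,
#' then mixes frequent trials with 4-7 infrequent (global deviant) trials.
#' Every infrequent trial is immediately followed by a frequent one, so no
#' block ends on a deviant.
#'
#' @param block_type One of `"AAAAA"`, `"BBBBB"`, `"AAAAB"`, `"BBBBA"` — the
#'   frequent series that defines the block.
#' @param seed Optional integer; identical seeds give identical blocks.
#' @param config A [paradigm_config()].
#' @param n_deviant Optional fixed number of global deviants; by default drawn
#'   uniformly from `config$deviant_range`.
#'
#' @return A tibble with one row per trial: `trial`, `onset` (s, block-local),
#'   `duration` (s, sound footprint of the series), `series`, `trial_label`,
#'   `block_type`, `is_habituation`.
#' @export
build_block <- function(block_type, seed = NULL, config = paradigm_config(),
                        n_deviant = NULL) {
  block_type <- match.arg(block_type, block_types())
  build <- function() {
    if (is.null(n_deviant)) {
      n_dev <- sample(seq(config$deviant_range[1], config$deviant_range[2]), 1L)
    } else {
      n_dev <- as.integer(n_deviant)
    }
    pos <- draw_deviant_positions(n_dev, config)
    series <- rep(block_type, config$n_trials)
    series[pos] <- deviant_series_for(block_type)
    tibble::tibble(
      trial = seq_len(config$n_trials),
      onset = (seq_len(config$n_trials) - 1) * config$trial_soa_ms / 1000,
      duration = (4 * config$soa_ms + config$tone_duration_ms) / 1000,
      series = series,
      trial_label = purrr::map_chr(series, label_trial, frequent = block_type),
      block_type = block_type,
      is_habituation = seq_len(config$n_trials) <= config$n_habituation
    )
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Build a full four-block session schedule
#'
#' One block of each type, in a seed-determined random order, with onsets
#' measured from session start. At default timing each block lasts 90 s and
#' the session 360 s (120 trials).
#'
#' @inheritParams build_block
#' @return A tibble of 4 x `n_trials` trials with a `block` index column and
#'   session-relative `onset` in seconds.
#' @export
build_session <- function(seed = NULL, config = paradigm_config()) {
  build <- function() {
    order <- sample(block_types())
    block_dur <- config$n_trials * config$trial_soa_ms / 1000
    purrr::imap_dfr(order, function(bt, i) {
      dplyr::mutate(build_block(bt, seed = NULL, config = config),
                    block = i, onset = .data$onset + (i - 1) * block_dur,
                    .before = 1)
    })
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Read and write BIDS-events-like schedule files
#'
#' Schedules are stored as tab-separated text with columns `onset` (s from
#' session start), `duration` (s), `trial_label`, `block_type` and
#' `is_habituation` (0/1).
#'
#' @param schedule A schedule tibble from [build_session()] or [build_block()].
#' @param path File path.
#' @return `read_events_tsv()` returns the schedule tibble;
#'   `write_events_tsv()` returns `path` invisibly.
#' @export
write_events_tsv <- function(schedule, path) {
  out <- dplyr::transmute(schedule,
                          onset = .data$onset, duration = .data$duration,
                          trial_label = .data$trial_label,
                          block_type = .data$block_type,
                          is_habituation = as.integer(.data$is_habituation))
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           onset = readr::col_double(),
                           duration = readr::col_double(),
                           trial_label = readr::col_character(),
                           block_type = readr::col_character(),
                           is_habituation = readr::col_integer()))
  dplyr::mutate(out, is_habituation = .data$is_habituation == 1L)
}
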