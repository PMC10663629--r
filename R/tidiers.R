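#' Tidy pupil epochs into a long tibble
#'
#' @param x A `pupil_epochs` object.
#' @param ... Unused.
#' @return A tibble with one row per trial-sample: `trial`, `trial_label`,
#'   `time`, `diameter`, `interpolated`, `rejected`.
#' @method tidy pupil_epochs
#' @export
tidy.pupil_epochs <- function(x, ...) {
  n_trial <- nrow(x$data)
  n_samp <- ncol(x$data)
  tibble::tibble(
    trial = rep(seq_len(n_trial), each = n_samp),
    trial_label = rep(x$labels, each = n_samp),
    time = rep(x$times, times = n_trial),
    diameter = as.vector(t(x$data)),
    interpolated = as.vector(t(x$interp)),
    rejected = rep(x$rejected, each = n_samp))
}

#' @rdname tidy.pupil_epochs
#' @method glance pupil_epochs
#' @export
glance.pupil_epochs <- function(x, ...) {
  tibble::tibble(n_trials = nrow(x$data),
                 n_rejected = sum(x$rejected),
                 rejection_rate = mean(x$rejected),
                 n_samples = ncol(x$data),
                 sampling_rate = x$sampling_rate,
                 baseline_corrected = x$baseline_corrected)
}

#' Tidy a PDR effect result
#'
#' @param x A `pdr_effect` object.
#' @param ... Unused.
#' @return `tidy()`: the per-sample tibble (`time`, `t`, `p`, `p_adjusted`,
#'   `in_window`, `significant`, `trend`). `glance()`: one row with the
#'   contrast name, level, label, the number of surviving samples and the
#'   minimum adjusted p.
#' @method tidy pdr_effect
#' @export
tidy.pdr_effect <- function(x, ...) x$samples

#' @rdname tidy.pdr_effect
#' @method glance pdr_effect
#' @export
glance.pdr_effect <- function(x, ...) {
  tibble::tibble(
    contrast = x$name, level = x$level, label = x$label,
    n_significant = sum(x$samples$significant),
    n_trend = sum(x$samples$trend),
    min_p_adjusted = suppressWarnings(
      min(x$samples$p_adjusted, na.rm = TRUE)),
    alpha = x$alpha, trend_alpha = x$trend_alpha)
}

#' Tidy an ERP cluster result
#'
#' @param x An `erp_cluster_result` object.
#' @param ... Unused.
#' @return `tidy()`: the cluster tibble. `glance()`: one row with contrast,
#'   significance and the tested window.
#' @method tidy erp_cluster_result
#' @export
tidy.erp_cluster_result <- function(x, ...) x$clusters

#' @rdname tidy.erp_cluster_result
#' @method glance erp_cluster_result
#' @export
glance.erp_cluster_result <- function(x, ...) {
  tibble::tibble(contrast = x$contrast, significant = x$significant,
                 n_clusters = nrow(x$clusters),
                 window_start = x$window[1], window_end = x$window[2],
                 mode = x$mode)
}

#' Tidy a contingency table
#'
#' @param x A `contingency_table` object.
#' @param ... Unused.
#' @return A one-row tibble of counts and metadata.
#' @method tidy contingency_table
#' @export
tidy.contingency_table <- function(x, ...) {
  tibble::tibble(marker = x$marker, truth = x$truth, positive = x$positive,
                 tp = x$tp, fp = x$fp, fn = x$fn, tn = x$tn)
}

#' @export
print.pdr_effect <- function(x, ...) {
  cat("<pdr_effect> ", x$name, " (", x$level, " level): ", x$label, "\n",
      sep = "")
  cat("  ", sum(x$samples$significant), " samples significant at q = ",
      x$alpha, " in [", x$window[1], ", ", x$window[2], "] s\n", sep = "")
  invisible(x)
}

#' @export
print.pupil_quality <- function(x, ...) {
  cat("<pupil_quality> ", x$label, " (rejection rate ",
      round(100 * x$rejection_rate, 1), "%)\n", sep = "")
  invisible(x)
}

#' @export
print.patient_report <- function(x, ...) {
  cat("<patient_report> ", nrow(x$patients), " patients\n", sep = "")
  if (nrow(x$summary) > 0) {
    counts <- dplyr::distinct(x$summary, .data$marker, .data$truth,
                              .data$tp, .data$fp, .data$fn, .data$tn,
                              .data$fisher_p)
    print(counts, n = Inf)
  }
  invisible(x)
}
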