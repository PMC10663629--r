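#' The packaged 24-patient DoC cohort table
#'
#' A plain-text transcription of the study cohort's characteristics and
#' per-patient marker labels: diagnosis (VS/UWS or MCS), demographics,
#' CRS-R subscales, drugs affecting the pupil, behavioural startle, ERP and
#' PDR effect labels (sound, maximal-violation, local, global; each
#' `significant` / `trend` / `ns`, `NA` when not available), dataset quality
#' labels, and the six-month outcome.
#'
#' @return A tibble with 24 rows, one per patient, with `crs_r_total`
#'   computed as the sum of the six subscales.
#' @export
doc_patients <- function() {
  path <- system.file("extdata", "doc_patients.csv", package = "pupildoc")
  label_lvls <- c("significant", "trend", "ns")
  rec <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           id = readr::col_integer(),
                           age = readr::col_integer(),
                           delay_days = readr::col_integer(),
                           .default = readr::col_character()))
  rec <- dplyr::mutate(
    rec,
    dplyr::across(dplyr::starts_with("crs_"), as.integer),
    dplyr::across(c("erp_sound", "erp_mve", "erp_local", "erp_global",
                    "pdr_sound", "pdr_mve", "pdr_local", "pdr_global"),
                  ~ factor(.x, levels = label_lvls)))
  dplyr::mutate(rec, crs_r_total = .data$crs_auditory + .data$crs_visual +
                  .data$crs_motor + .data$crs_oromotor +
                  .data$crs_communication + .data$crs_arousal,
                .after = "crs_arousal")
}

#' Build a 2x2 contingency table for a marker against a reference truth
#'
#' Rows with a missing marker label or missing truth are excluded pairwise.
#' The reference condition is either the clinical diagnosis (MCS positive)
#' or recovery of consciousness at six months (outcome `"Conscious"`
#' positive; any other non-missing outcome negative).
#'
#' @param records Patient tibble as returned by [doc_patients()].
#' @param marker Name of the label column (e.g. `"pdr_mve"`).
#' @param positive Which labels count as marker-positive:
#'   `"significant_or_trend"` or `"significant_only"`.
#' @param truth `"diagnosis_mcs"` or `"outcome_recovered"`.
#' @return A list of class `contingency_table` with counts `tp`, `fp`,
#'   `fn`, `tn` (marker x truth).
#' @export
build_contingency <- function(records, marker,
                              positive = c("significant_or_trend",
                                           "significant_only"),
                              truth = c("diagnosis_mcs",
                                        "outcome_recovered")) {
  positive <- match.arg(positive)
  truth <- match.arg(truth)
  lab <- as.character(records[[marker]])
  pos_set <- if (positive == "significant_only") "significant"
             else c("significant", "trend")
  truth_val <- if (truth == "diagnosis_mcs") {
    records$diagnosis == "MCS"
  } else {
    ifelse(is.na(records$outcome_6m) | records$outcome_6m == "NA", NA,
           records$outcome_6m == "Conscious")
  }
  keep <- !is.na(lab) & !is.na(truth_val)
  if (!any(keep)) stop("no records left after pairwise exclusion",
                       call. = FALSE)
  mpos <- lab[keep] %in% pos_set
  tval <- truth_val[keep]
  structure(list(tp = sum(mpos & tval), fp = sum(mpos & !tval),
                 fn = sum(!mpos & tval), tn = sum(!mpos & !tval),
                 marker = marker, positive = positive, truth = truth),
            class = "contingency_table")
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' The equal-tailed exact interval from beta quantiles; the lower bound is 0
#' when `k = 0` and the upper bound 1 when `k = n`.
#'
#' @param k Successes, `0 <= k <= n`.
#' @param n Trials, `n >= 1`.
#' @param alpha Two-sided error level (default 95% interval).
#' @return Numeric `c(low, high)` on the proportion scale.
#' @export
clopper_pearson <- function(k, n, alpha = 0.05) {
  if (n < 1 || k < 0 || k > n) stop("need 0 <= k <= n, n >= 1",
                                    call. = FALSE)
  low <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  high <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  c(low = low, high = high)
}

# logit-transformed interval for predictive values (Mercaldo et al.)
logit_ci <- function(k, n, alpha = 0.05) {
  if (k == 0 || k == n) return(clopper_pearson(k, n, alpha))
  p <- k / n
  lo <- log(p / (1 - p))
  se <- sqrt(1 / k + 1 / (n - k))
  z <- stats::qnorm(1 - alpha / 2)
  inv <- function(x) exp(x) / (1 + exp(x))
  c(low = inv(lo - z * se), high = inv(lo + z * se))
}

#' Diagnostic metrics with confidence intervals
#'
#' Sensitivity, specificity, positive and negative predictive value from a
#' 2x2 table, as percentages with confidence intervals (Clopper-Pearson by
#' default; `"logit"` gives the Mercaldo logit-transformed interval, often
#' used for predictive values). Metrics with a zero denominator are
#' returned as `NA` and flagged.
#'
#' @param table A `contingency_table`.
#' @param ci_method `"clopper-pearson"` or `"logit"`.
#' @param alpha Two-sided CI error level.
#' @return A tibble of class `diag_metrics`: `metric`, `estimate` (%),
#'   `ci_low`, `ci_high` (%), `k`, `n`, `undefined`.
#' @export
diag_metrics <- function(table, ci_method = c("clopper-pearson", "logit"),
                         alpha = 0.05) {
  ci_method <- match.arg(ci_method)
  stopifnot(inherits(table, "contingency_table"))
  ci_fun <- if (ci_method == "logit") logit_ci else clopper_pearson
  one <- function(metric, k, n) {
    if (n == 0)
      return(tibble::tibble(metric = metric, estimate = NA_real_,
                            ci_low = NA_real_, ci_high = NA_real_,
                            k = k, n = n, undefined = TRUE))
    ci <- ci_fun(k, n, alpha)
    tibble::tibble(metric = metric, estimate = 100 * k / n,
                   ci_low = 100 * ci[["low"]], ci_high = 100 * ci[["high"]],
                   k = k, n = n, undefined = FALSE)
  }
  out <- dplyr::bind_rows(
    one("se", table$tp, table$tp + table$fn),
    one("sp", table$tn, table$tn + table$fp),
    one("ppv", table$tp, table$tp + table$fp),
    one("npv", table$tn, table$tn + table$fn))
  class(out) <- c("diag_metrics", class(out))
  out
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Enumerates all tables with the observed margins and sums the
#' hypergeometric probabilities of those no more probable than the observed
#' table (with a small relative tolerance for ties, as is conventional).
#'
#' @param table A `contingency_table` or a 2x2 matrix
#'   `rbind(c(tp, fn), c(fp, tn))`.
#' @return The two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  if (inherits(table, "contingency_table"))
    table <- rbind(c(table$tp, table$fn), c(table$fp, table$tn))
  stopifnot(is.matrix(table), all(dim(table) == 2), all(table >= 0))
  if (sum(table) == 0) stop("all-zero table", call. = FALSE)
  m <- sum(table[1, ]); n <- sum(table[2, ]); k <- sum(table[, 1])
  x_obs <- table[1, 1]
  support <- max(0, k - n):min(k, m)
  d <- stats::dhyper(support, m, n, k)
  d_obs <- stats::dhyper(x_obs, m, n, k)
  sum(d[d <= d_obs * (1 + 1e-7)])
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two groups: exact for small samples
#' without ties, normal approximation with tie correction otherwise.
#'
#' @param group_a,group_b Numeric vectors.
#' @return A list with `u` (the U statistic for `group_a`) and `p`.
#' @export
mann_whitney <- function(group_a, group_b) {
  stopifnot(length(group_a) > 0, length(group_b) > 0)
  wt <- suppressWarnings(stats::wilcox.test(group_a, group_b,
                                            alternative = "two.sided"))
  list(u = unname(wt$statistic), p = wt$p.value)
}

marker_defaults <- function() {
  tibble::tribble(
    ~marker, ~positive,
    "pdr_sound", "significant_only",
    "pdr_mve", "significant_or_trend",
    "pdr_local", "significant_or_trend",
    "pdr_global", "significant_or_trend",
    "erp_sound", "significant_only",
    "erp_mve", "significant_only",
    "erp_local", "significant_only",
    "erp_global", "significant_only")
}

#' Full per-patient and summary diagnostic report
#'
#' One row per patient (diagnosis, quality labels, marker labels, outcome)
#' plus, for every marker and both reference truths, the 2x2 counts,
#' Se/Sp/PPV/NPV with exact CIs, and the two-sided Fisher exact p. The
#' marker-positivity convention follows the study: the PDR maximal-violation
#' contrast counts trends as positive, ERP markers count `significant` only.
#'
#' @param records Patient tibble as from [doc_patients()]; an empty tibble
#'   yields an empty report.
#' @param markers Optional tibble with columns `marker`, `positive`
#'   overriding the defaults.
#' @return A list of class `patient_report`: `patients` (tibble) and
#'   `summary` (tibble: marker, truth, tp/fp/fn/tn, fisher_p, and one row
#'   per metric with CI).
#' @export
patient_report <- function(records, markers = marker_defaults()) {
  if (nrow(records) == 0)
    return(structure(list(patients = records,
                          summary = tibble::tibble()),
                     class = "patient_report"))
  summ <- purrr::pmap_dfr(markers, function(marker, positive) {
    purrr::map_dfr(c("diagnosis_mcs", "outcome_recovered"), function(tr) {
      tab <- tryCatch(build_contingency(records, marker, positive, tr),
                      error = function(e) NULL)
      if (is.null(tab)) return(tibble::tibble())
      met <- diag_metrics(tab)
      dplyr::mutate(met, marker = marker, truth = tr, positive = positive,
                    tp = tab$tp, fp = tab$fp, fn = tab$fn, tn = tab$tn,
                    fisher_p = fisher_exact_2x2(tab), .before = 1)
    })
  })
  structure(list(patients = records, summary = summ),
            class = "patient_report")
}
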