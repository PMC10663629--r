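#' Contrast specifications for PDR effects
#'
#' The four contrasts studied on the pupil dilation response:
#' * `generic` — LSGS trials against the pre-trial baseline (a response to
#'   any sound);
#' * `local` — local deviants (LDGD, LDGS) vs local standards (LSGS, LSGD);
#' * `global` — global deviants (LSGD, LDGD) vs global standards (LSGS,
#'   LDGS);
#' * `mve` — the maximal violation effect, doubly deviant LDGD vs doubly
#'   standard LSGS trials.
#'
#' @param name One of `"generic"`, `"local"`, `"global"`, `"mve"`.
#' @return A list of class `contrast_spec` with `name` and disjoint
#'   trial-label sets `condition_a`, `condition_b` (`condition_b` is
#'   `"baseline"` for the generic contrast).
#' @export
contrast_spec <- function(name = c("generic", "local", "global", "mve")) {
  name <- match.arg(name)
  sets <- switch(name,
    generic = list(a = "LSGS", b = "baseline"),
    local = list(a = c("LDGD", "LDGS"), b = c("LSGS", "LSGD")),
    global = list(a = c("LSGD", "LDGD"), b = c("LSGS", "LDGS")),
    mve = list(a = "LDGD", b = "LSGS"))
  structure(list(name = name, condition_a = sets$a, condition_b = sets$b),
            class = "contrast_spec")
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up FDR over a family of p-values: reject all `p <= p_(k*)` where
#' `k*` is the largest rank with `p_(k) <= k * q / m`.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param q FDR level.
#' @return A list with `mask` (logical rejections) and `p_adjusted`
#'   (monotone step-up adjusted p-values). Empty input gives empty output.
#' @export
fdr_bh <- function(p, q = 0.05) {
  if (length(p) == 0)
    return(list(mask = logical(0), p_adjusted = numeric(0)))
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  adj <- stats::p.adjust(p, method = "BH")
  list(mask = !is.na(adj) & adj <= q, p_adjusted = adj)
}

# Vectorised sample-wise t statistics. `a`, `b` are observation x sample
# matrices. Returns per-sample t and two-sided p. Zero-variance samples get
# p = 1 when the means agree and p = 0 otherwise.
samplewise_t_stats <- function(a, b = NULL, mu = 0,
                               design = c("one-sample", "paired",
                                          "two-sample")) {
  design <- match.arg(design)
  if (design == "paired") {
    stopifnot(!is.null(b), nrow(a) == nrow(b))
    a <- a - b
    b <- NULL
    design <- "one-sample"
  }
  if (design == "one-sample") {
    n <- nrow(a)
    if (n < 2) stop("need at least 2 observations", call. = FALSE)
    m <- colMeans(a)
    v <- colSums(sweep(a, 2, m)^2) / (n - 1)
    se <- sqrt(v / n)
    df <- n - 1
    delta <- m - mu
  } else {
    stopifnot(!is.null(b))
    n1 <- nrow(a); n2 <- nrow(b)
    if (n1 < 2 || n2 < 2) stop("need at least 2 observations per group",
                               call. = FALSE)
    m1 <- colMeans(a); m2 <- colMeans(b)
    v1 <- colSums(sweep(a, 2, m1)^2) / (n1 - 1)
    v2 <- colSums(sweep(b, 2, m2)^2) / (n2 - 1)
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    delta <- m1 - m2
  }
  t <- ifelse(se > 0, delta / se, ifelse(delta == 0, 0, Inf * sign(delta)))
  p <- ifelse(se > 0, 2 * stats::pt(-abs(delta / se), df),
              ifelse(delta == 0, 1, 0))
  list(t = t, p = p, df = df)
}

#' Sample-wise Student t-tests
#'
#' Applies a t-test independently at every time sample of trial x sample
#' matrices: one-sample against a constant, paired, or pooled-variance
#' two-sample (the classical Student form).
#'
#' @param data_a Observations x samples matrix for condition A.
#' @param data_b Matrix for condition B (`NULL` for one-sample).
#' @param mu Null value for the one-sample design.
#' @param design `"one-sample"`, `"paired"` or `"two-sample"`.
#' @return A tibble with one row per sample: `t`, `p`, `df`.
#' @export
samplewise_t <- function(data_a, data_b = NULL, mu = 0,
                         design = c("one-sample", "paired", "two-sample")) {
  res <- samplewise_t_stats(as.matrix(data_a),
                            if (!is.null(data_b)) as.matrix(data_b),
                            mu = mu, design = design)
  tibble::tibble(sample = seq_along(res$t), t = res$t, p = res$p,
                 df = res$df)
}

usable_trials <- function(epochs, labels) {
  keep <- !epochs$rejected & epochs$labels %in% labels
  epochs$data[keep, , drop = FALSE]
}

make_effect_result <- function(stat, times, in_window, name, level,
                               alpha = 0.05, trend_alpha = 0.10,
                               min_run = 1) {
  p_win <- stat$p[in_window]
  f05 <- fdr_bh(p_win, alpha)
  f10 <- fdr_bh(p_win, trend_alpha)
  q_mask <- rep(FALSE, length(times))
  q_mask[in_window] <- f05$mask
  trend_mask <- rep(FALSE, length(times))
  trend_mask[in_window] <- f10$mask
  p_adj <- rep(NA_real_, length(times))
  p_adj[in_window] <- f05$p_adjusted
  has_run <- function(mask) {
    r <- rle(mask)
    any(r$values & r$lengths >= min_run)
  }
  label <- if (has_run(q_mask)) "significant"
           else if (has_run(trend_mask)) "trend" else "ns"
  structure(list(
    name = name, level = level,
    samples = tibble::tibble(time = times, t = stat$t, p = stat$p,
                             p_adjusted = p_adj, in_window = in_window,
                             significant = q_mask, trend = trend_mask),
    label = label, alpha = alpha, trend_alpha = trend_alpha,
    min_run = min_run,
    window = range(times[in_window])), class = "pdr_effect")
}

#' Generic PDR to sounds
#'
#' Tests whether LSGS trials evoke any pupil dilation at all. At the
#' individual level the baseline-corrected LSGS trials are tested against 0
#' with a one-sample t at each time point; at the group level the test runs
#' across patients' mean LSGS traces. P-values are FDR-corrected over the
#' samples of the analysis window, and the effect is labelled `significant`
#' (some sample survives at `q = 0.05`), `trend` (at `q = 0.10`), or `ns`.
#'
#' @param epochs For `level = "individual"`, a baseline-corrected
#'   `pupil_epochs` object; for `level = "group"`, a list of such objects
#'   (one per patient).
#' @param level `"individual"` or `"group"`.
#' @param analysis_window Seconds relative to first-sound onset over which
#'   the FDR family is formed (default 0-3 s).
#' @param alpha,trend_alpha Significance and trend FDR levels.
#' @param min_run Minimum number of consecutive surviving samples required
#'   for a label.
#' @return A `pdr_effect` object; see [tidy.pdr_effect()].
#' @export
generic_pdr_test <- function(epochs, level = c("individual", "group"),
                             analysis_window = c(0, 3), alpha = 0.05,
                             trend_alpha = 0.10, min_run = 1) {
  level <- match.arg(level)
  if (level == "individual") {
    stopifnot(inherits(epochs, "pupil_epochs"), epochs$baseline_corrected)
    a <- usable_trials(epochs, "LSGS")
    if (nrow(a) < 2) stop("fewer than 2 usable LSGS trials", call. = FALSE)
    times <- epochs$times
  } else {
    stopifnot(is.list(epochs), length(epochs) >= 2)
    times <- epochs[[1]]$times
    a <- t(vapply(epochs, function(e) {
      stopifnot(e$baseline_corrected)
      colMeans(usable_trials(e, "LSGS"))
    }, numeric(length(times))))
  }
  stat <- samplewise_t_stats(a, design = "one-sample")
  in_win <- times >= analysis_window[1] & times <= analysis_window[2]
  make_effect_result(stat, times, in_win, "generic", level, alpha,
                     trend_alpha, min_run)
}

#' Local, global and maximal-violation PDR effects
#'
#' At the individual level the two trial sets are compared with a
#' pooled-variance two-sample Student t at each time point; at the group
#' level each patient contributes a mean trace per condition and the test is
#' a paired t across patients. FDR correction and labelling as in
#' [generic_pdr_test()].
#'
#' @param epochs A baseline-corrected `pupil_epochs` object
#'   (individual level) or a list of them (group level).
#' @param spec A [contrast_spec()] other than `"generic"`.
#' @inheritParams generic_pdr_test
#' @return A `pdr_effect` object.
#' @export
contrast_effect <- function(epochs, spec, level = c("individual", "group"),
                            analysis_window = c(0, 3), alpha = 0.05,
                            trend_alpha = 0.10, min_run = 1) {
  level <- match.arg(level)
  stopifnot(inherits(spec, "contrast_spec"))
  if (identical(spec$condition_b, "baseline"))
    stop("use generic_pdr_test() for the generic contrast", call. = FALSE)
  if (level == "individual") {
    stopifnot(inherits(epochs, "pupil_epochs"), epochs$baseline_corrected)
    a <- usable_trials(epochs, spec$condition_a)
    b <- usable_trials(epochs, spec$condition_b)
    if (nrow(a) < 2)
      stop("condition ", paste(spec$condition_a, collapse = "/"),
           " has fewer than 2 usable trials", call. = FALSE)
    if (nrow(b) < 2)
      stop("condition ", paste(spec$condition_b, collapse = "/"),
           " has fewer than 2 usable trials", call. = FALSE)
    times <- epochs$times
    stat <- samplewise_t_stats(a, b, design = "two-sample")
  } else {
    stopifnot(is.list(epochs), length(epochs) >= 2)
    times <- epochs[[1]]$times
    a <- t(vapply(epochs, function(e)
      colMeans(usable_trials(e, spec$condition_a)),
      numeric(length(times))))
    b <- t(vapply(epochs, function(e)
      colMeans(usable_trials(e, spec$condition_b)),
      numeric(length(times))))
    stat <- samplewise_t_stats(a, b, design = "paired")
  }
  in_win <- times >= analysis_window[1] & times <= analysis_window[2]
  make_effect_result(stat, times, in_win, spec$name, level, alpha,
                     trend_alpha, min_run)
}

#' Classify one patient's PDR effects
#'
#' Runs the generic test and the local, global and maximal-violation
#' contrasts at the individual level and returns the patient's effect-label
#' row. Refuses excluded-quality datasets.
#'
#' @param dataset A `pupil_dataset` from [pupil_pipeline()], or a
#'   baseline-corrected `pupil_epochs` object (quality then assessed here).
#' @inheritParams generic_pdr_test
#' @return A one-row tibble: `quality`, `sound`, `mve`, `local`, `global`
#'   (labels in `significant` / `trend` / `ns`).
#' @export
classify_patient_effects <- function(dataset, analysis_window = c(0, 3),
                                     alpha = 0.05, trend_alpha = 0.10,
                                     min_run = 1) {
  if (inherits(dataset, "pupil_dataset")) {
    epochs <- dataset$epochs
    quality <- dataset$quality
  } else {
    epochs <- dataset
    quality <- assess_dataset_quality(epochs)
  }
  if (quality$label == "excluded")
    stop("dataset excluded (trial rejection rate ",
         round(100 * quality$rejection_rate), "%): effects not computed",
         call. = FALSE)
  lab <- function(eff) eff$label
  tibble::tibble(
    quality = quality$label,
    sound = lab(generic_pdr_test(epochs, "individual", analysis_window,
                                 alpha, trend_alpha, min_run)),
    mve = lab(contrast_effect(epochs, contrast_spec("mve"), "individual",
                              analysis_window, alpha, trend_alpha, min_run)),
    local = lab(contrast_effect(epochs, contrast_spec("local"), "individual",
                                analysis_window, alpha, trend_alpha,
                                min_run)),
    global = lab(contrast_effect(epochs, contrast_spec("global"),
                                 "individual", analysis_window, alpha,
                                 trend_alpha, min_run)))
}
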