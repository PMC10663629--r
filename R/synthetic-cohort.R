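#' Cohort simulation specification
#'
#' Describes a synthetic DoC cohort: group sizes, per-group prevalence of the
#' true underlying effects (generic auditory response, local, global), and an
#' outcome model giving the probability of recovering consciousness at six
#' months as a function of group and of a true global effect.
#'
#' @param n_vs,n_mcs Number of VS/UWS and MCS patients (defaults mirror a
#'   24-patient cohort of 10 + 14).
#' @param prev_generic,prev_local,prev_global Named two-element vectors
#'   (`vs`, `mcs`) of true-effect prevalences.
#' @param p_recover Named probabilities of six-month recovery:
#'   `vs`, `mcs` baseline rates and `global_boost` added when the patient
#'   truly carries a global effect (capped at 1).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_vs = 10, n_mcs = 14,
                        prev_generic = c(vs = 0.9, mcs = 0.95),
                        prev_local = c(vs = 0, mcs = 0.05),
                        prev_global = c(vs = 0.05, mcs = 0.3),
                        p_recover = c(vs = 0.1, mcs = 0.4,
                                      global_boost = 0.4)) {
  probs <- c(prev_generic, prev_local, prev_global, p_recover)
  stopifnot(n_vs >= 0, n_mcs >= 0, all(probs >= 0), all(probs <= 1))
  structure(list(n_vs = n_vs, n_mcs = n_mcs, prev_generic = prev_generic,
                 prev_local = prev_local, prev_global = prev_global,
                 p_recover = p_recover), class = "cohort_spec")
}

#' Simulate a DoC patient cohort
#'
#' Draws per-patient true effect flags from the group prevalences, CRS-R-like
#' subscale scores from group-typical ranges, and a six-month outcome from
#' the outcome model. With `recordings = TRUE` each patient additionally gets
#' a simulated pupil session whose injected amplitudes reflect the true
#' flags, so the full pipeline can be run per patient.
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional integer seed.
#' @param recordings If `TRUE`, attach a list-column `pupil` of
#'   [simulate_pupil_session()] results (slower).
#' @param params Pupil simulation parameters used when `recordings = TRUE`;
#'   `amp_local` / `amp_global` are zeroed for patients lacking the
#'   corresponding true effect.
#' @return A tibble, one row per patient: `id`, `diagnosis`, `crs_*`
#'   subscales, `crs_r_total`, true-effect flags `true_generic`,
#'   `true_local`, `true_global`, and `outcome_6m`
#'   (`"Conscious"` or `"Not recovered"`).
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = NULL,
                            recordings = FALSE,
                            params = pupil_sim_params()) {
  run <- function() {
    n <- spec$n_vs + spec$n_mcs
    grp <- rep(c("VS/UWS", "MCS"), c(spec$n_vs, spec$n_mcs))
    key <- ifelse(grp == "VS/UWS", "vs", "mcs")
    draw <- function(prev) stats::runif(n) < prev[key]
    true_generic <- draw(spec$prev_generic)
    true_local <- draw(spec$prev_local)
    true_global <- draw(spec$prev_global)
    p_rec <- pmin(1, spec$p_recover[key] +
                    spec$p_recover[["global_boost"]] * true_global)
    outcome <- ifelse(stats::runif(n) < p_rec, "Conscious", "Not recovered")
    # CRS-R-like subscales: VS/UWS low-range, MCS mid-range draws
    lo <- grp == "VS/UWS"
    subs <- cbind(
      crs_auditory = ifelse(lo, sample(0:2, n, TRUE), sample(1:4, n, TRUE)),
      crs_visual = ifelse(lo, sample(0:1, n, TRUE), sample(1:5, n, TRUE)),
      crs_motor = ifelse(lo, sample(0:2, n, TRUE), sample(1:5, n, TRUE)),
      crs_oromotor = ifelse(lo, sample(0:2, n, TRUE), sample(1:2, n, TRUE)),
      crs_communication = ifelse(lo, 0L, sample(0:1, n, TRUE)),
      crs_arousal = ifelse(lo, sample(1:2, n, TRUE), sample(1:3, n, TRUE)))
    out <- tibble::tibble(
      id = seq_len(n), diagnosis = grp,
      tibble::as_tibble(subs),
      crs_r_total = rowSums(subs),
      true_generic = true_generic, true_local = true_local,
      true_global = true_global, outcome_6m = outcome)
    if (recordings) {
      out$pupil <- purrr::pmap(
        list(true_generic, true_local, true_global),
        function(g, l, gl) {
          p <- params
          p$amp_generic <- params$amp_generic * g
          p$amp_local <- params$amp_local * l
          p$amp_global <- params$amp_global * gl
          sched <- build_session(seed = NULL)
          simulate_pupil_session(sched, p, seed = NULL)
        })
    }
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
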