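#' Generate a behavioral trial table from model detectability
#'
#' Emulates buried-prey search trials: for each condition in `params_grid`
#' (one row per condition, matched 1:1 with a [detect_onset()] result), trial
#' success is Bernoulli with probability `encounter_prob` when the model says
#' the condition is detectable within the trial, and `false_rate` (default 0:
#' control capsules are never found) otherwise.
#'
#' @param params_grid data.frame of conditions; must have the same number of
#'   rows as `model_results` (columns `c0` and `depth` are conventional;
#'   extra columns such as `species` or `label` are carried through).
#' @param model_results list of `detectability_result` objects (e.g. a
#'   [detectability_map()]), one per grid row.
#' @param encounter_prob probability a detectable condition yields success,
#'   in (0, 1].
#' @param n_trials trials per condition (default 10).
#' @param seed integer RNG seed.
#' @param false_rate success probability for undetectable conditions.
#' @return a `trial_table` data.frame with one row per trial: the condition
#'   columns, `detected` (model flag), `trial`, `success` and `seed`.
#' @export
gen_trials <- function(params_grid, model_results, encounter_prob = 0.8,
                       n_trials = 10, seed = 1L, false_rate = 0) {
  if (encounter_prob <= 0 || encounter_prob > 1)
    stop("gen_trials: encounter_prob must be in (0, 1]")
  if (false_rate < 0 || false_rate > 1)
    stop("gen_trials: false_rate must be in [0, 1]")
  if (nrow(params_grid) != length(model_results))
    stop("gen_trials: params_grid rows and model_results length differ")
  if (!all(vapply(model_results, inherits, logical(1),
                  "detectability_result")))
    stop("gen_trials: model_results must be detectability_result objects")
  set.seed(as.integer(seed))
  out <- do.call(rbind, lapply(seq_len(nrow(params_grid)), function(i) {
    det <- model_results[[i]]$detected_within_t_max
    p <- if (det) encounter_prob else false_rate
    cbind(params_grid[rep(i, n_trials), , drop = FALSE],
          data.frame(detected = det, trial = seq_len(n_trials),
                     success = rbinom(n_trials, 1L, p),
                     seed = as.integer(seed)))
  }))
  rownames(out) <- NULL
  class(out) <- c("trial_table", "data.frame")
  out
}

#' Per-condition success rates with exact binomial confidence intervals
#'
#' Groups a trial table by every condition column (all columns except
#' `detected`, `trial`, `success`, `seed`) and reports the success rate with
#' its Clopper-Pearson 95% interval.
#'
#' @param table a `trial_table` (or any data.frame with a `success` column).
#' @return data.frame with the condition columns, `n`, `successes`, `rate`,
#'   `ci_lo`, `ci_hi`.
#' @export
summarize_trials <- function(table) {
  if (!nrow(table)) stop("summarize_trials: empty trial table")
  cond_cols <- setdiff(names(table), c("detected", "trial", "success",
                                       "seed"))
  if (!length(cond_cols)) {
    table$condition <- "all"
    cond_cols <- "condition"
  }
  key <- interaction(table[cond_cols], drop = TRUE, lex.order = TRUE)
  out <- do.call(rbind, lapply(levels(key), function(k) {
    sub <- table[key == k, , drop = FALSE]
    n <- nrow(sub)
    s <- sum(sub$success)
    ci <- binom.test(s, n)$conf.int
    cbind(sub[1L, cond_cols, drop = FALSE],
          data.frame(n = n, successes = s, rate = s / n,
                     ci_lo = ci[1L], ci_hi = ci[2L]))
  }))
  rownames(out) <- NULL
  out
}
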