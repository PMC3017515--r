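# Spectral-counting quantification: unweighted protein-by-run count
# matrices, a Poisson-Gamma conjugate Bayes factor for two-condition
# differential abundance (decision rule BF > 10), normalized fold
# changes and Monte-Carlo FDR calibration of the decision threshold.

#' Build an unweighted spectral count matrix
#'
#' Counts accepted spectra per protein and run. When a parsimony
#' grouping is supplied, every spectrum whose references intersect a
#' group is counted once for that group's representative, so shared
#' peptides are never counted multiply.
#'
#' @param psms Accepted PSM data.frame (`spectrum_id`, `run_id`,
#'   `condition`, `protein_refs` semicolon-joined).
#' @param groups Optional grouping data.frame from [parsimony_group()].
#' @param runs Optional character vector fixing the run order (runs
#'   with zero accepted spectra are then kept as all-zero columns).
#' @return list with `counts` (integer matrix, proteins x runs),
#'   `runs`, `conditions` (per run), `run_totals` (column sums).
#' @export
count_spectra <- function(psms, groups = NULL, runs = NULL) {
  refs <- .split_refs(psms$protein_refs)
  if (!is.null(groups)) {
    member2rep <- unlist(lapply(seq_len(nrow(groups)), function(i) {
      m <- strsplit(groups$members[i], ";", fixed = TRUE)[[1]]
      stats::setNames(rep(groups$representative[i], length(m)), m)
    }))
    assigned <- vapply(refs, function(r) {
      reps <- unique(unname(member2rep[r[r %in% names(member2rep)]]))
      if (length(reps) == 0L) NA_character_ else sort(reps)[1L]
    }, character(1))
  } else {
    # unambiguous assignment: first (smallest) referenced protein
    assigned <- vapply(refs, function(r) sort(r)[1L], character(1))
  }
  keep <- !is.na(assigned)
  run_levels <- if (is.null(runs)) sort(unique(psms$run_id)) else runs
  prot_levels <- sort(unique(assigned[keep]))
  counts <- table(factor(assigned[keep], levels = prot_levels),
                  factor(psms$run_id[keep], levels = run_levels))
  counts <- matrix(as.integer(counts), nrow = length(prot_levels),
                   ncol = length(run_levels),
                   dimnames = list(prot_levels, run_levels))
  cond <- psms$condition[match(run_levels, psms$run_id)]
  list(counts = counts, runs = run_levels, conditions = cond,
       run_totals = colSums(counts))
}

# log marginal likelihood of counts y with exposures t under a
# Gamma(shape, rate) prior on the Poisson rate; the Poisson factors
# prod(t^y / y!) are omitted as they cancel in the Bayes factor
.log_marginal <- function(sum_y, sum_t, shape, rate) {
  shape * log(rate) - lgamma(shape) +
    lgamma(shape + sum_y) - (shape + sum_y) * log(rate + sum_t)
}

#' Poisson-Gamma Bayes factor for two-condition count data
#'
#' Compares the model with distinct Poisson rates per condition
#' (independent conjugate Gamma priors) against a shared-rate model,
#' with run totals as exposure offsets. Exposures are normalized to
#' mean 1 so rates are on the per-run count scale. The prior is
#' Gamma(`prior_shape`, `prior_rate`); by default `prior_rate` is set
#' to `prior_shape / m`, where `m` is the protein's mean rate over all
#' runs, centring the prior on the observed overall abundance. The
#' Bayes factor is finite and positive for all finite counts and is
#' invariant under swapping the condition labels.
#'
#' @param y Integer vector of spectral counts, one per run.
#' @param condition Character/factor vector of condition labels (two
#'   levels) parallel to `y`.
#' @param exposure Optional positive exposures per run (e.g. run
#'   totals); default all equal.
#' @param prior_shape Gamma prior shape (default 0.5).
#' @param prior_rate Gamma prior rate; default `prior_shape / m` (see
#'   above). The same prior is used in both models.
#' @return Positive scalar Bayes factor (alternative over null).
#' @export
sc_bayes_factor <- function(y, condition, exposure = NULL,
                            prior_shape = 0.5, prior_rate = NULL) {
  condition <- as.character(condition)
  lev <- sort(unique(condition))
  stopifnot(length(lev) == 2L, length(y) == length(condition))
  if (is.null(exposure)) exposure <- rep(1, length(y))
  stopifnot(all(exposure > 0))
  t_norm <- exposure / mean(exposure)
  if (is.null(prior_rate)) {
    m <- max(sum(y) / sum(t_norm), 1e-8)
    prior_rate <- prior_shape / m
  }
  a <- condition == lev[1]
  lm1 <- .log_marginal(sum(y[a]), sum(t_norm[a]), prior_shape, prior_rate) +
    .log_marginal(sum(y[!a]), sum(t_norm[!a]), prior_shape, prior_rate)
  lm0 <- .log_marginal(sum(y), sum(t_norm), prior_shape, prior_rate)
  exp(lm1 - lm0)
}

#' Normalized spectral-count fold change
#'
#' Ratio of mean normalized counts (count over normalized run
#' exposure) between the two conditions, with a pseudocount added to
#' both means for robustness to zeros:
#' `(mean_A + pseudocount) / (mean_B + pseudocount)`. Swapping the
#' condition labels yields the exact reciprocal.
#'
#' @inheritParams sc_bayes_factor
#' @param pseudocount Added to both condition means (default 0.5).
#' @return Positive scalar; condition A is the first label in sort
#'   order.
#' @export
sc_fold_change <- function(y, condition, exposure = NULL, pseudocount = 0.5) {
  condition <- as.character(condition)
  lev <- sort(unique(condition))
  stopifnot(length(lev) == 2L)
  if (is.null(exposure)) exposure <- rep(1, length(y))
  t_norm <- exposure / mean(exposure)
  z <- y / t_norm
  a <- condition == lev[1]
  (mean(z[a]) + pseudocount) / (mean(z[!a]) + pseudocount)
}

#' Direction call from a Bayes factor and fold change
#'
#' `+1` if the Bayes factor strictly exceeds the threshold and the fold
#' change is above 1; `-1` if it exceeds the threshold and the fold
#' change is below 1; `0` otherwise. A Bayes factor of exactly the
#' threshold is not significant. A significant protein with fold change
#' exactly 1 is degenerate and called 0 with a warning.
#'
#' @param bayes_factor,fold_change Numeric vectors (recycled to common
#'   length).
#' @param bf_threshold Decision threshold (default 10, strict `>`).
#' @return Integer vector of directions in `{-1, 0, +1}`.
#' @export
call_sc_trend <- function(bayes_factor, fold_change, bf_threshold = 10) {
  n <- max(length(bayes_factor), length(fold_change))
  bf <- rep_len(bayes_factor, n)
  fc <- rep_len(fold_change, n)
  dir <- integer(n)
  sig <- bf > bf_threshold
  if (any(sig & fc == 1))
    warning("significant Bayes factor with fold change exactly 1; direction 0")
  dir[sig & fc > 1] <- 1L
  dir[sig & fc < 1] <- -1L
  dir
}

#' Spectral-counting differential abundance over a count matrix
#'
#' Applies [sc_bayes_factor()], [sc_fold_change()] and
#' [call_sc_trend()] to every protein of a count matrix.
#'
#' @param cm Count matrix object from [count_spectra()] or
#'   [read_count_matrix()].
#' @param bf_threshold Bayes-factor decision threshold (default 10).
#' @param pseudocount Fold-change pseudocount (default 0.5).
#' @param prior_shape Gamma prior shape (default 0.5).
#' @param normalize Use run totals as exposures (default TRUE).
#' @return data.frame `internal_id`, `bayes_factor`, `fold_change`,
#'   `direction`, `n_spectra`.
#' @export
sc_test <- function(cm, bf_threshold = 10, pseudocount = 0.5,
                    prior_shape = 0.5, normalize = TRUE) {
  exposure <- if (normalize && all(cm$run_totals > 0)) cm$run_totals else NULL
  res <- lapply(seq_len(nrow(cm$counts)), function(i) {
    y <- cm$counts[i, ]
    bf <- sc_bayes_factor(y, cm$conditions, exposure, prior_shape)
    fc <- sc_fold_change(y, cm$conditions, exposure, pseudocount)
    data.frame(internal_id = rownames(cm$counts)[i], bayes_factor = bf,
               fold_change = fc, n_spectra = sum(y),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$direction <- call_sc_trend(out$bayes_factor, out$fold_change,
                                 bf_threshold)
  rownames(out) <- NULL
  out[, c("internal_id", "bayes_factor", "fold_change", "direction",
          "n_spectra")]
}

#' Monte-Carlo false-positive calibration of the Bayes-factor threshold
#'
#' Simulates null proteins (equal Poisson rates in both conditions) and
#' reports the fraction whose Bayes factor exceeds the threshold,
#' with an exact binomial confidence interval. The fraction is
#' non-increasing in the threshold and tends to zero as the threshold
#' grows.
#'
#' @param rate Expected spectra per run under the null.
#' @param n_runs_per_condition Runs per condition (default 5).
#' @param bf_threshold Decision threshold (default 10).
#' @param n_sims Number of simulated null proteins (>= 1000).
#' @param prior_shape Gamma prior shape (default 0.5).
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return list with `fraction`, `conf_int` (length 2), `n_sims`,
#'   `bf_threshold`.
#' @export
calibrate_sc_fdr <- function(rate, n_runs_per_condition = 5,
                             bf_threshold = 10, n_sims = 1000,
                             prior_shape = 0.5, conf_level = 0.95) {
  stopifnot(n_sims >= 1000)
  cond <- rep(c("A", "B"), each = n_runs_per_condition)
  hits <- 0L
  for (i in seq_len(n_sims)) {
    y <- stats::rpois(2 * n_runs_per_condition, rate)
    if (sc_bayes_factor(y, cond, prior_shape = prior_shape) > bf_threshold)
      hits <- hits + 1L
  }
  ci <- stats::binom.test(hits, n_sims, conf.level = conf_level)$conf.int
  list(fraction = hits / n_sims, conf_int = as.numeric(ci),
       n_sims = n_sims, bf_threshold = bf_threshold)
}
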