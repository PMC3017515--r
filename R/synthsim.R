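# Seeded synthetic-data generator: EST collections with planted
# substring redundancy, LC-MS feature tables with planted fold changes
# and retention-time shifts, spectral-count matrices with planted rate
# ratios, and PSM tables with planted target/decoy score
# distributions. All outputs carry truth tables sufficient to score
# every downstream stage, and identical seeds give identical output.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# evaluate expr under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulation configuration
#'
#' Collects the knobs of the synthetic-data generator. Defaults encode
#' the emulated study design: five technical repeats per condition,
#' planted protein fold changes cycling through
#' `{0.25, 0.5, 1, 2, 4}`, multiplicative log-normal intensity noise
#' with sigma 0.3 on log areas, per-run retention-time shifts within
#' one minute plus 0.2 min uniform jitter, sub-threshold noise
#' features, and Poisson spectral counts at an expected depth of 10
#' spectra per run.
#'
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @param n_proteins Number of simulated proteins.
#' @param n_est Number of ESTs for [simulate_est_collection()].
#' @param redundancy_rate Fraction of ESTs emitted as exact substrings
#'   of a parent coding sequence.
#' @param short_rate Fraction of ESTs coding for products shorter than
#'   50 amino acids.
#' @param n_runs_per_condition Technical repeats per condition.
#' @param fold_changes Planted per-protein fold changes (condition A
#'   over B), recycled over proteins.
#' @param peptides_range Range of peptides per protein.
#' @param noise_sigma Log-normal noise sigma on log intensities.
#' @param rt_shifts Per-run RT shifts in minutes, recycled; `NULL`
#'   draws them uniformly from +/- 1 min under the seed.
#' @param rt_jitter Uniform per-feature RT jitter half-width (min).
#' @param n_noise_features Sub-threshold noise features per run pool.
#' @param count_depth Expected spectra per run for a null protein.
#' @param rate_ratios Planted count rate ratios (A over B), recycled.
#' @param n_psms Simulated PSMs for [simulate_psms()].
#' @param decoy_fraction Fraction of decoy PSMs.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_proteins = 50L, n_est = 100L,
                       redundancy_rate = 0.2, short_rate = 0.1,
                       n_runs_per_condition = 5L,
                       fold_changes = c(0.25, 0.5, 1, 2, 4),
                       peptides_range = c(2L, 6L), noise_sigma = 0.3,
                       rt_shifts = NULL, rt_jitter = 0.2,
                       n_noise_features = 200L, count_depth = 10,
                       rate_ratios = c(1, 5, 1, 0.2, 1),
                       n_psms = 2000L, decoy_fraction = 0.3) {
  cfg <- list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
              n_est = as.integer(n_est), redundancy_rate = redundancy_rate,
              short_rate = short_rate,
              n_runs_per_condition = as.integer(n_runs_per_condition),
              fold_changes = fold_changes, peptides_range = peptides_range,
              noise_sigma = noise_sigma, rt_shifts = rt_shifts,
              rt_jitter = rt_jitter,
              n_noise_features = as.integer(n_noise_features),
              count_depth = count_depth, rate_ratios = rate_ratios,
              n_psms = as.integer(n_psms), decoy_fraction = decoy_fraction)
  stopifnot(cfg$n_proteins >= 1, cfg$n_runs_per_condition >= 2,
            cfg$redundancy_rate >= 0, cfg$redundancy_rate < 1,
            cfg$short_rate >= 0, cfg$redundancy_rate + cfg$short_rate < 1,
            all(cfg$fold_changes > 0), all(cfg$rate_ratios > 0),
            cfg$decoy_fraction >= 0, cfg$decoy_fraction < 1)
  class(cfg) <- "sim_config"
  cfg
}

.run_design <- function(cfg) {
  n <- cfg$n_runs_per_condition
  data.frame(run_id = c(paste0("A", seq_len(n)), paste0("B", seq_len(n))),
             condition = rep(c("A", "B"), each = n),
             stringsAsFactors = FALSE)
}

# reverse-translate an amino-acid string with uniformly random
# synonymous codons (standard code, no stop)
.reverse_translate <- function(aa) {
  code <- standard_genetic_code()
  by_aa <- split(names(code), unname(code))
  paste(vapply(strsplit(aa, "")[[1]], function(a) {
    cands <- by_aa[[a]]
    cands[sample.int(length(cands), 1L)]
  }, character(1)), collapse = "")
}

.random_aa <- function(len) paste(sample(AA20, len, replace = TRUE),
                                  collapse = "")

#' Simulate an EST collection with planted redundancy
#'
#' Emits parent ESTs coding full-length proteins (60-250 aa), redundant
#' ESTs whose coding sequence reverse-translates an exact internal
#' substring (>= 50 aa, strictly shorter) of a parent protein, and
#' short ESTs coding products of 15-49 aa. Each EST is the coding
#' codons followed by one stop codon, so its `+1` frame carries exactly
#' the planted product. The truth table records each EST's kind, its
#' parent, and the candidate accession the database build derives from
#' its `+1` frame, which is the generator-side oracle for the
#' length-filter and redundancy-removal stages.
#'
#' @param cfg A [sim_config()].
#' @return list with `records` (data.frame `accession`, `source`,
#'   `sequence`) and `truth` (data.frame `accession`, `kind`,
#'   `parent`, `candidate`, `product_length`, `expected_removed`,
#'   `expected_reason`).
#' @export
simulate_est_collection <- function(cfg) {
  .with_seed(cfg$seed + 101L, {
    n_red <- floor(cfg$redundancy_rate * cfg$n_est)
    n_short <- floor(cfg$short_rate * cfg$n_est)
    n_parent <- cfg$n_est - n_red - n_short
    stopifnot(n_parent >= 1, n_red <= n_parent * 5)
    parent_aa <- vapply(seq_len(n_parent),
                        function(i) .random_aa(sample(60:250, 1L)),
                        character(1))
    parent_acc <- sprintf("EST%05d", seq_len(n_parent))
    rows <- data.frame(accession = parent_acc,
                       source = "assembly",
                       sequence = vapply(parent_aa, function(a)
                         paste0(.reverse_translate(a), "TAA"), character(1),
                         USE.NAMES = FALSE),
                       stringsAsFactors = FALSE)
    truth <- data.frame(accession = parent_acc, kind = "parent",
                        parent = NA_character_,
                        candidate = paste0(parent_acc, "|+1.1"),
                        product_length = nchar(parent_aa),
                        expected_removed = FALSE,
                        expected_reason = "none",
                        stringsAsFactors = FALSE)
    if (n_red > 0) {
      pid <- sample.int(n_parent, n_red, replace = TRUE)
      red_acc <- sprintf("RED%05d", seq_len(n_red))
      red_aa <- vapply(pid, function(p) {
        full <- parent_aa[p]
        len <- sample(50:(nchar(full) - 1L), 1L)
        start <- sample.int(nchar(full) - len + 1L, 1L)
        substr(full, start, start + len - 1L)
      }, character(1))
      rows <- rbind(rows, data.frame(
        accession = red_acc, source = "unigene",
        sequence = vapply(red_aa, function(a)
          paste0(.reverse_translate(a), "TGA"), character(1),
          USE.NAMES = FALSE),
        stringsAsFactors = FALSE))
      truth <- rbind(truth, data.frame(
        accession = red_acc, kind = "redundant",
        parent = parent_acc[pid],
        candidate = paste0(red_acc, "|+1.1"),
        product_length = nchar(red_aa),
        expected_removed = TRUE, expected_reason = "redundant",
        stringsAsFactors = FALSE))
    }
    if (n_short > 0) {
      short_acc <- sprintf("SHT%05d", seq_len(n_short))
      short_aa <- vapply(seq_len(n_short),
                         function(i) .random_aa(sample(15:49, 1L)),
                         character(1))
      rows <- rbind(rows, data.frame(
        accession = short_acc, source = "unigene",
        sequence = vapply(short_aa, function(a)
          paste0(.reverse_translate(a), "TAG"), character(1),
          USE.NAMES = FALSE),
        stringsAsFactors = FALSE))
      truth <- rbind(truth, data.frame(
        accession = short_acc, kind = "short", parent = NA_character_,
        candidate = paste0(short_acc, "|+1.1"),
        product_length = nchar(short_aa),
        expected_removed = TRUE, expected_reason = "too-short",
        stringsAsFactors = FALSE))
    }
    rownames(rows) <- rownames(truth) <- NULL
    list(records = rows, truth = truth)
  })
}

#' Simulate LC-MS feature tables with planted fold changes
#'
#' Each protein carries 2-6 peptide ions at distinct m/z positions and
#' random retention times; condition A intensities are the planted fold
#' change times the base intensity, with multiplicative log-normal
#' noise, per-run RT shifts, uniform RT jitter and small m/z jitter.
#' Sub-threshold noise features (intensity below the 50,000 seed
#' threshold) are sprinkled over every run.
#'
#' @param cfg A [sim_config()].
#' @return list with `features` (data.frame `run_id`, `condition`,
#'   `mz`, `rt`, `intensity`), `ids` (data.frame `mz`, `peptide`,
#'   `protein_refs`), `truth` (data.frame `protein`, `fold_change`,
#'   `direction`, `n_peptides`) and `rt_shifts` (named per run).
#' @export
simulate_features <- function(cfg) {
  .with_seed(cfg$seed + 202L, {
    design <- .run_design(cfg)
    n_runs <- nrow(design)
    shifts <- if (is.null(cfg$rt_shifts))
      stats::runif(n_runs, -1, 1) else rep_len(cfg$rt_shifts, n_runs)
    names(shifts) <- design$run_id
    shifts[1] <- 0  # reference run is unshifted
    folds <- rep_len(cfg$fold_changes, cfg$n_proteins)
    prot <- sprintf("%d", seq_len(cfg$n_proteins))
    n_pep <- sample(cfg$peptides_range[1]:cfg$peptides_range[2],
                    cfg$n_proteins, replace = TRUE)
    mz_pool <- sample(seq(301, 1399, by = 0.07), sum(n_pep))
    ids <- data.frame(
      mz = mz_pool,
      peptide = sprintf("PEP%05d", seq_len(sum(n_pep))),
      protein_refs = rep(prot, n_pep),
      stringsAsFactors = FALSE
    )
    pep_rt <- stats::runif(nrow(ids), 10, 100)
    pep_base <- exp(stats::rnorm(nrow(ids), log(5e5), 0.5))
    pep_base <- pmax(pep_base, 1e5)
    pep_fold <- rep(folds, n_pep)
    rows <- lapply(seq_len(n_runs), function(r) {
      is_a <- design$condition[r] == "A"
      mu <- pep_base * (if (is_a) pep_fold else rep(1, length(pep_fold)))
      data.frame(
        run_id = design$run_id[r], condition = design$condition[r],
        mz = ids$mz + stats::runif(nrow(ids), -0.003, 0.003),
        rt = pep_rt + shifts[r] +
          stats::runif(nrow(ids), -cfg$rt_jitter, cfg$rt_jitter),
        intensity = mu * exp(stats::rnorm(nrow(ids), 0, cfg$noise_sigma)),
        stringsAsFactors = FALSE
      )
    })
    noise <- lapply(seq_len(n_runs), function(r) {
      k <- cfg$n_noise_features
      if (k == 0L) return(NULL)
      data.frame(run_id = design$run_id[r], condition = design$condition[r],
                 mz = stats::runif(k, 300, 1400),
                 rt = stats::runif(k, 5, 110),
                 intensity = stats::runif(k, 1e3, 49999),
                 stringsAsFactors = FALSE)
    })
    features <- do.call(rbind, c(rows, noise))
    rownames(features) <- NULL
    direction <- ifelse(folds >= 2, 1L, ifelse(folds <= 0.5, -1L, 0L))
    truth <- data.frame(protein = prot, fold_change = folds,
                        direction = direction, n_peptides = n_pep,
                        stringsAsFactors = FALSE)
    list(features = features, ids = ids, truth = truth, rt_shifts = shifts)
  })
}

#' Simulate a spectral count matrix with planted rate ratios
#'
#' Counts are Poisson with per-run exposure equal to the configured
#' depth; a protein with rate ratio r has expected counts
#' `depth * sqrt(r)` in condition A and `depth / sqrt(r)` in condition
#' B, so the planted A/B ratio is exactly r. Null proteins (r = 1) are
#' included by the default ratio cycle for calibration.
#'
#' @param cfg A [sim_config()].
#' @return list with `cm` (count matrix object as for
#'   [count_spectra()]) and `truth` (data.frame `protein`,
#'   `rate_ratio`, `direction`).
#' @export
simulate_counts <- function(cfg) {
  .with_seed(cfg$seed + 303L, {
    design <- .run_design(cfg)
    ratios <- rep_len(cfg$rate_ratios, cfg$n_proteins)
    prot <- sprintf("%d", seq_len(cfg$n_proteins))
    lam <- matrix(rep(cfg$count_depth, cfg$n_proteins * nrow(design)),
                  nrow = cfg$n_proteins)
    lam <- lam * ifelse(matrix(rep(design$condition == "A",
                                   each = cfg$n_proteins),
                               nrow = cfg$n_proteins),
                        sqrt(ratios), 1 / sqrt(ratios))
    counts <- matrix(stats::rpois(length(lam), lam), nrow = cfg$n_proteins,
                     dimnames = list(prot, design$run_id))
    cm <- list(counts = counts, runs = design$run_id,
               conditions = design$condition, run_totals = colSums(counts))
    truth <- data.frame(protein = prot, rate_ratio = ratios,
                        direction = ifelse(ratios > 1, 1L,
                                           ifelse(ratios < 1, -1L, 0L)),
                        stringsAsFactors = FALSE)
    list(cm = cm, truth = truth)
  })
}

#' Simulate PSMs with separated target/decoy score distributions
#'
#' Target Xcorr scores are drawn one unit above the charge-dependent
#' threshold (sd 0.6) and decoy scores 1.2 units below it (sd 0.5),
#' both truncated at zero; peptide probabilities are high for targets
#' and low for decoys. Target PSMs reference the simulated proteins in
#' round-robin over a per-protein peptide repertoire, so downstream
#' acceptance and counting can be exercised end to end. The decoy flag
#' is the planted truth.
#'
#' @param cfg A [sim_config()].
#' @param thresholds Charge-dependent Xcorr thresholds used to centre
#'   the score distributions.
#' @return data.frame of PSMs (`spectrum_id`, `run_id`, `condition`,
#'   `peptide`, `charge`, `xcorr`, `peptide_probability`,
#'   `protein_refs`, `is_decoy`).
#' @export
simulate_psms <- function(cfg, thresholds = c("1" = 1.5, "2" = 2.2,
                                              "3" = 3.3)) {
  .with_seed(cfg$seed + 404L, {
    design <- .run_design(cfg)
    n <- cfg$n_psms
    n_decoy <- floor(cfg$decoy_fraction * n)
    is_decoy <- c(rep(TRUE, n_decoy), rep(FALSE, n - n_decoy))
    charge <- sample(as.integer(names(thresholds)), n, replace = TRUE)
    thr <- unname(thresholds[as.character(charge)])
    xcorr <- ifelse(is_decoy,
                    pmax(0, stats::rnorm(n, thr - 1.2, 0.5)),
                    pmax(0, stats::rnorm(n, thr + 1.0, 0.6)))
    pep_prob <- ifelse(is_decoy, stats::runif(n, 0, 0.6),
                       stats::runif(n, 0.7, 1))
    # per-protein peptide repertoire of 3, cycled over target PSMs
    n_target <- n - n_decoy
    prot_idx <- (seq_len(n_target) - 1L) %% cfg$n_proteins + 1L
    pep_idx <- ((seq_len(n_target) - 1L) %/% cfg$n_proteins) %% 3L + 1L
    run_row <- (seq_len(n) - 1L) %% nrow(design) + 1L
    psms <- data.frame(
      spectrum_id = sprintf("scan%06d", seq_len(n)),
      run_id = design$run_id[run_row],
      condition = design$condition[run_row],
      peptide = NA_character_, charge = charge, xcorr = xcorr,
      peptide_probability = pep_prob,
      protein_refs = NA_character_, is_decoy = is_decoy,
      stringsAsFactors = FALSE
    )
    psms$peptide[!is_decoy] <- sprintf("TPEP%d_%d", prot_idx, pep_idx)
    psms$protein_refs[!is_decoy] <- sprintf("%d", prot_idx)
    psms$peptide[is_decoy] <- sprintf("XPEP%06d", seq_len(n_decoy))
    psms$protein_refs[is_decoy] <- sprintf("DECOY_%d",
                                           (seq_len(n_decoy) - 1L) %%
                                             cfg$n_proteins + 1L)
    rownames(psms) <- NULL
    psms
  })
}
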