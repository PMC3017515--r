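# Independent oracles and fixture builders shared across the suite.
# Each oracle is deliberately coded along a different route than the
# package implementation it checks.

NT_PLAIN <- c("A", "C", "G", "T")
NT_AMBIG <- c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

random_nt <- function(len, ambig_prob = 0) {
  pool <- sample(NT_PLAIN, len, replace = TRUE)
  if (ambig_prob > 0 && len > 0) {
    flip <- stats::runif(len) < ambig_prob
    pool[flip] <- sample(NT_AMBIG, sum(flip), replace = TRUE)
  }
  paste(pool, collapse = "")
}

random_aa <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}

# six-frame translation through Biostrings (fuzzy codons solved to a
# unique residue where possible, otherwise X)
oracle_six_frames <- function(sequence) {
  fwd <- Biostrings::DNAString(sequence)
  rc <- Biostrings::reverseComplement(fwd)
  one <- function(s, off) {
    if (length(s) < off + 3) return("")
    sub <- Biostrings::subseq(s, start = off + 1)
    sub <- Biostrings::subseq(sub, start = 1, end = 3 * (length(sub) %/% 3))
    as.character(suppressWarnings(
      Biostrings::translate(sub, if.fuzzy.codon = "solve",
                            no.init.codon = TRUE)))
  }
  out <- c(one(fwd, 0), one(fwd, 1), one(fwd, 2),
           one(rc, 0), one(rc, 1), one(rc, 2))
  names(out) <- c("+1", "+2", "+3", "-1", "-2", "-3")
  out
}

# all-pairs O(n^2) substring-redundancy oracle: an entry is removed iff
# its sequence occurs inside a strictly longer sequence of the input,
# or an equal sequence belongs to an entry winning the tie-break
oracle_redundant_removed <- function(entries) {
  n <- nrow(entries)
  rank <- match(entries$source, c("assembly", "unigene", "protein-set"))
  removed <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      li <- nchar(entries$sequence[i]); lj <- nchar(entries$sequence[j])
      contained <- lj >= li &&
        grepl(entries$sequence[i], entries$sequence[j], fixed = TRUE)
      if (!contained) next
      if (lj > li) { removed[i] <- TRUE; break }
      # equal length: identical sequences, keep the tie-break winner
      if (entries$sequence[i] == entries$sequence[j] &&
          (rank[j] < rank[i] ||
             (rank[j] == rank[i] &&
                entries$accession[j] < entries$accession[i]))) {
        removed[i] <- TRUE; break
      }
    }
  }
  # an entry removed for containment in a removed duplicate chain is
  # still contained in the surviving copy, so the flags above are final
  sort(entries$accession[removed])
}

# independent reimplementation of the parsimony grouping rule using
# bitmask encodings of peptide sets
oracle_parsimony_owner <- function(evidence) {
  ids <- sort(names(evidence))
  peps <- sort(unique(unlist(evidence)))
  masks <- lapply(ids, function(id) peps %in% evidence[[id]])
  names(masks) <- ids
  size <- vapply(masks, sum, integer(1))
  owner <- vapply(ids, function(i) {
    supersets <- ids[vapply(ids, function(j) {
      j != i && all(masks[[i]] <= masks[[j]])
    }, logical(1))]
    if (length(supersets) == 0) return(i)
    strict <- supersets[size[supersets] > size[i]]
    if (length(strict) > 0) {
      strict[order(-size[strict], strict)][1]
    } else {
      min(c(i, supersets[vapply(supersets, function(j)
        identical(masks[[j]], masks[[i]]), logical(1))]))
    }
  }, character(1))
  # resolve chains: a subset absorbed by a duplicate follows its winner
  repeat {
    nxt <- owner[owner]
    if (identical(unname(nxt), unname(owner))) break
    owner <- nxt
  }
  owner
}

# exhaustive minimum number of proteins explaining all peptides
oracle_min_cover_size <- function(evidence) {
  ids <- names(evidence)
  peps <- sort(unique(unlist(evidence)))
  for (k in seq_along(ids)) {
    combos <- utils::combn(ids, k, simplify = FALSE)
    for (cb in combos) {
      if (all(peps %in% unlist(evidence[cb]))) return(k)
    }
  }
  length(ids)
}

# numerical-integration marginal likelihood oracle for the
# Poisson-Gamma Bayes factor (includes the constant Poisson factors,
# which cancel in the ratio)
oracle_bf <- function(y, condition, exposure = NULL,
                      prior_shape = 0.5, prior_rate = NULL) {
  if (is.null(exposure)) exposure <- rep(1, length(y))
  t_norm <- exposure / mean(exposure)
  if (is.null(prior_rate)) prior_rate <- prior_shape / (sum(y) / sum(t_norm))
  marg <- function(yy, tt) {
    logf <- function(li) {
      stats::dgamma(li, prior_shape, rate = prior_rate, log = TRUE) +
        sum(stats::dpois(yy, li * tt, log = TRUE))
    }
    # integrate the scaled integrand over the posterior's support
    lo <- stats::qgamma(1e-12, prior_shape + sum(yy),
                        rate = prior_rate + sum(tt))
    hi <- stats::qgamma(1 - 1e-12, prior_shape + sum(yy),
                        rate = prior_rate + sum(tt))
    peak <- logf(max((prior_shape + sum(yy) - 1) /
                       (prior_rate + sum(tt)), lo))
    val <- stats::integrate(function(l) {
      vapply(l, function(li) exp(logf(li) - peak), numeric(1))
    }, lo, hi, rel.tol = 1e-10)$value
    exp(peak) * val
  }
  lev <- sort(unique(as.character(condition)))
  a <- as.character(condition) == lev[1]
  marg(y[a], t_norm[a]) * marg(y[!a], t_norm[!a]) / marg(y, t_norm)
}

make_psms <- function(charge, xcorr, is_decoy = FALSE, peptide = NULL,
                      peptide_probability = NA_real_, protein_refs = "1",
                      run_id = "A1", condition = "A") {
  n <- max(lengths(list(charge, xcorr, is_decoy, peptide,
                        peptide_probability, protein_refs, run_id,
                        condition)))
  data.frame(spectrum_id = sprintf("s%03d", seq_len(n)),
             run_id = rep_len(run_id, n), condition = rep_len(condition, n),
             peptide = if (is.null(peptide)) sprintf("PEP%d", seq_len(n))
                       else rep_len(peptide, n),
             charge = rep_len(charge, n), xcorr = rep_len(xcorr, n),
             peptide_probability = rep_len(peptide_probability, n),
             protein_refs = rep_len(protein_refs, n),
             is_decoy = rep_len(is_decoy, n), stringsAsFactors = FALSE)
}
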