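# Peptide-spectrum-match filtering: charge-dependent Xcorr thresholds,
# reversed-decoy FDR estimation, peptide/protein probability acceptance
# and parsimony protein grouping.

.split_refs <- function(protein_refs) strsplit(protein_refs, ";", fixed = TRUE)

#' Filter PSMs by charge-dependent Xcorr thresholds
#'
#' Retains a PSM iff its Xcorr is at least the threshold for its charge
#' state (a PSM scoring exactly the threshold is retained). Charges
#' above the highest thresholded state use the highest state's
#' threshold. The filter is idempotent.
#'
#' @param psms PSM data.frame with `charge` and `xcorr` columns.
#' @param thresholds Named numeric vector, names are charge states
#'   (default `c("1" = 1.5, "2" = 2.2, "3" = 3.3)`).
#' @return The retained subset of `psms`.
#' @export
xcorr_filter <- function(psms, thresholds = c("1" = 1.5, "2" = 2.2, "3" = 3.3)) {
  ch <- sort(as.integer(names(thresholds)))
  stopifnot(!anyNA(ch), all(diff(ch) >= 1))
  idx <- pmin(pmax(psms$charge, ch[1]), ch[length(ch)])
  thr <- unname(thresholds[as.character(idx)])
  psms[psms$xcorr >= thr, , drop = FALSE]
}

#' Estimate the false discovery rate from decoy matches
#'
#' The classic reversed-database estimate FDR = D / T (number of decoy
#' PSMs over number of target PSMs). The alternative concatenated-search
#' convention 2D / (T + D) is available via `method`.
#'
#' @param psms PSM data.frame with an `is_decoy` logical column.
#' @param method `"ratio"` for D/T (default) or `"concatenated"` for
#'   2D/(T+D).
#' @return FDR estimate in `[0, 1]` (0 when there are targets but no
#'   decoys). Zero target PSMs is an error: the estimate is undefined.
#' @export
estimate_decoy_fdr <- function(psms, method = c("ratio", "concatenated")) {
  method <- match.arg(method)
  d <- sum(psms$is_decoy)
  t <- sum(!psms$is_decoy)
  if (t == 0L) stop("no target PSMs: decoy FDR is undefined")
  if (method == "ratio") d / t else 2 * d / (t + d)
}

#' Accept proteins by peptide/protein probability and peptide count
#'
#' Peptides are accepted at probability strictly greater than
#' `pep_min`. Protein probabilities are either supplied per protein or
#' computed from the accepted peptides' probabilities as
#' `1 - prod(1 - p)` (independence rule, one term per distinct
#' peptide using its best probability). A protein is accepted iff its
#' probability is strictly greater than `prot_min` and it carries at
#' least `min_peptides` distinct accepted peptides.
#'
#' @param psms PSM data.frame with `peptide`, `peptide_probability` and
#'   `protein_refs` (semicolon-joined ids) columns.
#' @param pep_min Peptide probability threshold (default 0.80, strict).
#' @param prot_min Protein probability threshold (default 0.95, strict).
#' @param min_peptides Minimum distinct accepted peptides (default 2).
#' @param protein_probs Optional named numeric vector of externally
#'   supplied protein probabilities (names are protein ids).
#' @return data.frame `protein`, `protein_probability`, `n_peptides`,
#'   `peptides` (semicolon-joined), one row per accepted protein.
#' @export
probability_filter <- function(psms, pep_min = 0.80, prot_min = 0.95,
                               min_peptides = 2, protein_probs = NULL) {
  if (!"peptide_probability" %in% names(psms) ||
      all(is.na(psms$peptide_probability)))
    stop("peptide_probability column is required for probability filtering")
  acc <- psms[!is.na(psms$peptide_probability) &
                psms$peptide_probability > pep_min, , drop = FALSE]
  refs <- .split_refs(acc$protein_refs)
  long <- data.frame(
    protein = unlist(refs),
    peptide = rep(acc$peptide, lengths(refs)),
    p = rep(acc$peptide_probability, lengths(refs)),
    stringsAsFactors = FALSE
  )
  if (nrow(long) == 0L)
    return(data.frame(protein = character(), protein_probability = numeric(),
                      n_peptides = integer(), peptides = character(),
                      stringsAsFactors = FALSE))
  # best probability per (protein, peptide)
  best <- stats::aggregate(p ~ protein + peptide, data = long, FUN = max)
  out <- do.call(rbind, lapply(split(best, best$protein), function(b) {
    prob <- if (!is.null(protein_probs) && b$protein[1] %in% names(protein_probs))
      unname(protein_probs[b$protein[1]]) else 1 - prod(1 - b$p)
    data.frame(protein = b$protein[1],
               protein_probability = prob,
               n_peptides = nrow(b),
               peptides = paste(sort(b$peptide), collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  out <- out[out$protein_probability > prot_min &
               out$n_peptides >= min_peptides, , drop = FALSE]
  out <- out[order(out$protein), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group proteins that share indistinguishable peptide evidence
#'
#' Proteins with identical peptide sets are merged into one group;
#' proteins whose peptide set is a proper subset of another protein's
#' set are absorbed into that protein's group. When a subset protein is
#' contained in several maximal sets it is absorbed into the group with
#' the largest peptide set, ties broken by the lexicographically
#' smallest representative id, so the result is independent of input
#' order. Group representatives are the members with the largest
#' peptide sets (ties by smallest id).
#'
#' @param evidence Named list mapping protein id to a character vector
#'   of peptides, or a data.frame with `protein` and `peptide` columns.
#' @return data.frame `group_id`, `representative`, `members`
#'   (semicolon-joined), `peptides` (semicolon-joined union),
#'   `n_members`, `n_peptides`.
#' @export
parsimony_group <- function(evidence) {
  if (is.data.frame(evidence))
    evidence <- lapply(split(evidence$peptide, evidence$protein), unique)
  evidence <- lapply(evidence, function(p) sort(unique(p)))
  stopifnot(all(lengths(evidence) >= 1L))
  ids <- sort(names(evidence))
  sets <- evidence[ids]
  n <- length(ids)
  sizes <- lengths(sets)
  # maximal proteins: peptide set not a proper subset of any other set,
  # and winner among identical sets (smallest id; ids are sorted)
  keys <- vapply(sets, paste, "", collapse = "\r")
  owner <- character(n)
  for (i in seq_len(n)) {
    sup <- which(vapply(seq_len(n), function(j) {
      j != i && sizes[j] >= sizes[i] && all(sets[[i]] %in% sets[[j]])
    }, logical(1)))
    if (length(sup) == 0L) {
      owner[i] <- ids[i]
    } else {
      strict <- sup[sizes[sup] > sizes[i]]
      if (length(strict) == 0L) {
        # identical sets: group under the smallest id among them
        owner[i] <- min(c(ids[i], ids[sup][keys[sup] == keys[i]]))
      } else {
        best <- strict[order(-sizes[strict], ids[strict])][1L]
        owner[i] <- ids[best]
      }
    }
  }
  # subset proteins may point at a non-representative duplicate; chase
  # one step so every owner is itself an owner
  owner <- stats::setNames(owner, ids)
  owner <- ifelse(owner[owner] == owner, owner, owner[owner])
  reps <- sort(unique(unname(owner)))
  out <- do.call(rbind, lapply(seq_along(reps), function(g) {
    members <- ids[owner == reps[g]]
    union_p <- sort(unique(unlist(sets[members])))
    data.frame(group_id = g, representative = reps[g],
               members = paste(sort(members), collapse = ";"),
               peptides = paste(union_p, collapse = ";"),
               n_members = length(members), n_peptides = length(union_p),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Run the full PSM acceptance pipeline
#'
#' Applies the Xcorr filter, reports the decoy FDR among the retained
#' PSMs, drops decoys, applies the probability/min-peptide acceptance
#' and groups the accepted proteins by parsimony.
#'
#' @param psms PSM data.frame.
#' @inheritParams xcorr_filter
#' @inheritParams probability_filter
#' @return list with `psms` (accepted target PSMs), `fdr`, `proteins`
#'   (from [probability_filter()]) and `groups` (from
#'   [parsimony_group()]).
#' @export
filter_psms <- function(psms, thresholds = c("1" = 1.5, "2" = 2.2, "3" = 3.3),
                        pep_min = 0.80, prot_min = 0.95, min_peptides = 2) {
  kept <- xcorr_filter(psms, thresholds)
  fdr <- if (sum(!kept$is_decoy) > 0) estimate_decoy_fdr(kept) else NA_real_
  targets <- kept[!kept$is_decoy, , drop = FALSE]
  proteins <- probability_filter(targets, pep_min, prot_min, min_peptides)
  groups <- if (nrow(proteins) > 0) {
    ev <- lapply(stats::setNames(proteins$peptides, proteins$protein),
                 function(p) strsplit(p, ";", fixed = TRUE)[[1]])
    parsimony_group(ev)
  } else NULL
  list(psms = targets, fdr = fdr, proteins = proteins, groups = groups)
}
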