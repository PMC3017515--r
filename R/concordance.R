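# Per-protein agreement between the two label-free routes: direction
# pair classification (strong / weak / no match), class summaries and
# accession-level vs homolog-level identification overlap.

#' Classify a pair of direction calls
#'
#' `"strong"` when the dMS and SC directions are equal (U/U, D/D or
#' N/N), `"none"` when both are nonzero and opposite (U/D, D/U), and
#' `"weak"` when exactly one method calls no change (N/U, U/N, D/N,
#' N/D). Vectorized.
#'
#' @param dms_direction,sc_direction Integer vectors with values in
#'   `{-1, 0, 1}`.
#' @return Character vector in `{"strong", "weak", "none"}`.
#' @export
classify_pair <- function(dms_direction, sc_direction) {
  stopifnot(all(dms_direction %in% c(-1L, 0L, 1L)),
            all(sc_direction %in% c(-1L, 0L, 1L)))
  ifelse(dms_direction == sc_direction, "strong",
         ifelse(dms_direction != 0L & sc_direction != 0L, "none", "weak"))
}

#' Build per-protein concordance records for the shared proteins
#'
#' Joins the two result tables on `internal_id`; proteins quantified by
#' only one method are excluded here (they enter only the overlap
#' counts).
#'
#' @param dms_results data.frame with `internal_id` and `direction`.
#' @param sc_results data.frame with `internal_id` and `direction`.
#' @return data.frame `internal_id`, `dms_direction`, `sc_direction`,
#'   `match_class`.
#' @export
concordance_records <- function(dms_results, sc_results) {
  shared <- merge(dms_results[, c("internal_id", "direction")],
                  sc_results[, c("internal_id", "direction")],
                  by = "internal_id", suffixes = c("_dms", "_sc"))
  data.frame(internal_id = shared$internal_id,
             dms_direction = shared$direction_dms,
             sc_direction = shared$direction_sc,
             match_class = classify_pair(shared$direction_dms,
                                         shared$direction_sc),
             stringsAsFactors = FALSE)
}

#' Summarize concordance classes
#'
#' Class counts over the shared proteins and their percentages (one
#' decimal) of the shared total. An empty record set yields zero counts
#' and `NA` percentages with a warning.
#'
#' @param records data.frame from [concordance_records()].
#' @return list with `counts` (named integer vector strong/weak/none),
#'   `percentages` (same names), `total`.
#' @export
summarize_concordance <- function(records) {
  classes <- c("strong", "weak", "none")
  counts <- vapply(classes, function(cl) sum(records$match_class == cl),
                   integer(1))
  total <- sum(counts)
  if (total == 0L) {
    warning("no shared proteins: percentages undefined")
    pct <- stats::setNames(rep(NA_real_, 3), classes)
  } else {
    pct <- round(100 * counts / total, 1)
  }
  list(counts = counts, percentages = pct, total = total)
}

#' Map database entries to their best annotation homolog
#'
#' Uses only the rank-1 annotation hit of each entry (smallest e-value,
#' ties broken by lexicographically smallest hit accession, as encoded
#' in the annotation ranking). Entries without a hit are unmapped.
#'
#' @param annotations Annotation data.frame from [attach_annotations()].
#' @return Named character vector internal_id -> homolog accession.
#' @export
homolog_map <- function(annotations) {
  top <- annotations[annotations$rank == 1, , drop = FALSE]
  stats::setNames(top$hit_accession, as.character(top$internal_id))
}

#' Identification overlap between the two methods
#'
#' Venn triple (only-dMS, shared, only-SC) of the identified protein
#' sets. With a homolog map, ids are first collapsed to their homolog
#' accession (unmapped ids stay at accession level), which can only
#' shrink the counts.
#'
#' @param dms_ids,sc_ids Character vectors of identified protein ids.
#' @param homologs Optional named vector from [homolog_map()].
#' @return Named integer vector `c(only_dms, shared, only_sc)`.
#' @export
method_overlap <- function(dms_ids, sc_ids, homologs = NULL) {
  collapse <- function(ids) {
    ids <- as.character(ids)
    if (is.null(homologs)) return(unique(ids))
    mapped <- homologs[ids]
    unique(ifelse(is.na(mapped), ids, mapped))
  }
  a <- collapse(dms_ids)
  b <- collapse(sc_ids)
  c(only_dms = length(setdiff(a, b)),
    shared = length(intersect(a, b)),
    only_sc = length(setdiff(b, a)))
}
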