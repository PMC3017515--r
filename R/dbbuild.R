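# Construction of a non-redundant protein search database from mixed
# nucleotide (EST/unigene) and protein source collections: six-frame
# translation, stop-codon splitting, minimum-length filtering,
# 100%-identity (substring) redundancy removal, dense internal ids,
# annotation attachment and reversed-decoy generation.

SOURCE_LEVELS <- c("assembly", "unigene", "protein-set")

IUPAC_NT <- c(
  A = "A", C = "C", G = "G", T = "T", U = "T", N = "ACGT",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG"
)

#' Standard genetic code as a codon-indexed vector
#'
#' Returns the codon table used by [six_frame_translate()]: a named
#' character vector mapping each of the 64 unambiguous codons (DNA
#' alphabet, e.g. `"ATG"`) to a one-letter amino acid, with `"*"` for the
#' three stop codons. The default is the standard nuclear code, which is
#' appropriate for plant EST collections; any table with the same shape
#' (for example a plastid or mitochondrial variant) can be passed to the
#' translation functions instead.
#'
#' @return Named character vector of length 64.
#' @export
standard_genetic_code <- function() {
  code <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(code), names(code))
}

.check_nt <- function(sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% names(IUPAC_NT))
  if (length(bad) > 0) {
    stop(sprintf("non-IUPAC nucleotide '%s' at position %d",
                 chars[bad[1]], bad[1]), call. = FALSE)
  }
  chars
}

.revcomp_chars <- function(chars) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", D = "H", H = "D", V = "B")
  rev(unname(comp[chars]))
}

# Translate one codon given as a length-3 character vector. Ambiguity
# codes are expanded; if every compatible unambiguous codon encodes the
# same residue that residue is returned, otherwise "X".
.translate_codon <- function(codon, code) {
  key <- paste(codon, collapse = "")
  aa <- code[key]
  if (!is.na(aa)) return(unname(aa))
  alts <- expand.grid(strsplit(IUPAC_NT[codon[1]], "")[[1]],
                      strsplit(IUPAC_NT[codon[2]], "")[[1]],
                      strsplit(IUPAC_NT[codon[3]], "")[[1]],
                      stringsAsFactors = FALSE)
  aas <- unique(code[paste0(alts[[1]], alts[[2]], alts[[3]])])
  if (length(aas) == 1L) unname(aas) else "X"
}

.translate_chars <- function(chars, code) {
  n_codons <- length(chars) %/% 3L
  if (n_codons == 0L) return("")
  out <- character(n_codons)
  for (i in seq_len(n_codons)) {
    out[i] <- .translate_codon(chars[(3L * i - 2L):(3L * i)], code)
  }
  paste(out, collapse = "")
}

#' Translate a nucleotide sequence in all six reading frames
#'
#' Frames `+1`, `+2`, `+3` read the forward strand at offsets 0, 1, 2;
#' frames `-1`, `-2`, `-3` read the reverse complement at the same
#' offsets. Stop codons are rendered as `"*"`. `U` is treated as `T`;
#' IUPAC ambiguity codes are permitted, and a codon containing an
#' ambiguous base translates to `"X"` unless every compatible codon
#' encodes the same residue.
#'
#' @param sequence Nucleotide string (IUPAC alphabet, case-insensitive).
#' @param genetic_code Codon table, see [standard_genetic_code()].
#' @return Named character vector of the six translations, names
#'   `"+1"`, `"+2"`, `"+3"`, `"-1"`, `"-2"`, `"-3"`.
#' @examples
#' six_frame_translate("ATGAAATAA")[["+1"]]  # "MK*"
#' @export
six_frame_translate <- function(sequence, genetic_code = standard_genetic_code()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  fwd <- .check_nt(sequence)
  fwd[fwd == "U"] <- "T"
  rc <- .revcomp_chars(fwd)
  frames <- c("+1", "+2", "+3", "-1", "-2", "-3")
  out <- stats::setNames(character(6L), frames)
  for (off in 0:2) {
    out[[sprintf("+%d", off + 1L)]] <-
      .translate_chars(fwd[seq_len(length(fwd)) > off], genetic_code)
    out[[sprintf("-%d", off + 1L)]] <-
      .translate_chars(rc[seq_len(length(rc)) > off], genetic_code)
  }
  out
}

#' Split a translated sequence at stop codons
#'
#' Returns the ordered stop-free segments of a translation. Empty
#' segments arising from adjacent, leading or trailing stops are
#' dropped, so concatenating the segments with stops between and around
#' them reconstructs the input.
#'
#' @param translation Amino-acid string possibly containing `"*"`.
#' @return Character vector of stop-free segments (possibly empty).
#' @export
split_at_stop_codons <- function(translation) {
  stopifnot(is.character(translation), length(translation) == 1L)
  parts <- strsplit(translation, "*", fixed = TRUE)[[1]]
  parts[nzchar(parts)]
}

#' Enumerate stop-free protein candidates from a nucleotide record
#'
#' Translates the record in all six frames, splits each frame at stop
#' codons and returns one row per stop-free segment, with a derived
#' candidate accession `"<accession>|<frame>.<segment>"` so that every
#' candidate is individually traceable in the conversion table.
#'
#' @param accession,source,sequence Fields of the nucleotide record.
#' @param genetic_code Codon table.
#' @return data.frame with columns `accession`, `parent_accession`,
#'   `source`, `frame`, `segment_index`, `sequence`.
#' @export
translate_to_candidates <- function(accession, source, sequence,
                                    genetic_code = standard_genetic_code()) {
  frames <- six_frame_translate(sequence, genetic_code)
  rows <- lapply(names(frames), function(fr) {
    segs <- split_at_stop_codons(frames[[fr]])
    if (length(segs) == 0L) return(NULL)
    data.frame(
      accession = sprintf("%s|%s.%d", accession, fr, seq_along(segs)),
      parent_accession = accession,
      source = source,
      frame = fr,
      segment_index = seq_along(segs),
      sequence = segs,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(accession = character(), parent_accession = character(),
                      source = character(), frame = character(),
                      segment_index = integer(), sequence = character(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Filter protein candidates by minimum length
#'
#' Retains exactly the candidates whose sequence has at least `min_len`
#' residues, preserving order. The comparison is "shorter than
#' `min_len` is removed", i.e. a candidate of exactly `min_len`
#' residues is kept.
#'
#' @param candidates data.frame with a `sequence` column.
#' @param min_len Minimum retained length in amino acids (default 50).
#' @return The retained subset of `candidates`.
#' @export
length_filter <- function(candidates, min_len = 50) {
  stopifnot(min_len >= 1)
  candidates[nchar(candidates$sequence) >= min_len, , drop = FALSE]
}

.source_rank <- function(source) {
  r <- match(source, SOURCE_LEVELS)
  if (anyNA(r)) stop("unknown source tag: ",
                     paste(unique(source[is.na(r)]), collapse = ", "))
  r
}

#' Remove sequences contained at 100% identity in a longer sequence
#'
#' An entry is removed iff its sequence is an exact substring of a
#' strictly longer retained sequence, or an exact duplicate of another
#' entry that wins the tie-break (source rank assembly < unigene <
#' protein-set, then lexicographically smallest accession). The
#' retained set is substring-free and independent of input order; every
#' removal names the retained representative that subsumes it.
#'
#' @param entries data.frame with columns `accession`, `source`,
#'   `sequence` (stop-free amino-acid strings).
#' @return list with `retained` (subset of `entries`, deterministic
#'   order: decreasing length, then source rank, then accession) and
#'   `conversion` (data.frame `accession`, `removal_reason` in
#'   `{"none","redundant"}`, `representative` accession or `NA`).
#' @export
remove_redundant <- function(entries) {
  stopifnot(all(c("accession", "source", "sequence") %in% names(entries)))
  if (anyDuplicated(entries$accession))
    stop("candidate accessions must be unique")
  n <- nrow(entries)
  ord <- order(-nchar(entries$sequence),
               .source_rank(entries$source),
               entries$accession, method = "radix")
  e <- entries[ord, , drop = FALSE]
  keep <- logical(n)
  rep_acc <- rep(NA_character_, n)
  retained_seq <- character(0)
  retained_acc <- character(0)
  retained_len <- integer(0)
  for (i in seq_len(n)) {
    s <- e$sequence[i]
    hit <- which(retained_len >= nchar(s) &
                   grepl(s, retained_seq, fixed = TRUE))
    if (length(hit) > 0L) {
      # deterministic representative: the first retained container in
      # retained order (longest, then source rank, then accession)
      rep_acc[i] <- retained_acc[hit[1L]]
    } else {
      keep[i] <- TRUE
      retained_seq <- c(retained_seq, s)
      retained_acc <- c(retained_acc, e$accession[i])
      retained_len <- c(retained_len, nchar(s))
    }
  }
  conversion <- data.frame(
    accession = e$accession,
    removal_reason = ifelse(keep, "none", "redundant"),
    representative = rep_acc,
    stringsAsFactors = FALSE
  )
  list(retained = e[keep, , drop = FALSE],
       conversion = conversion[order(conversion$accession), , drop = FALSE])
}

#' Assign dense internal identifiers to retained database entries
#'
#' Orders retained entries by (source rank, accession) and numbers them
#' 1..N. The ordering is a reproducibility device: any run over the
#' same retained set yields the same numbering.
#'
#' @param retained data.frame with `accession`, `source`, `sequence`.
#' @return data.frame with columns `internal_id`, `source_accession`,
#'   `source`, `sequence`, `length`; the per-source provenance summary
#'   of [provenance_summary()] is attached as attribute `"provenance"`.
#' @export
assign_internal_ids <- function(retained) {
  ord <- order(.source_rank(retained$source), retained$accession,
               method = "radix")
  r <- retained[ord, , drop = FALSE]
  db <- data.frame(
    internal_id = seq_len(nrow(r)),
    source_accession = r$accession,
    source = r$source,
    sequence = r$sequence,
    length = nchar(r$sequence),
    stringsAsFactors = FALSE
  )
  counts <- vapply(SOURCE_LEVELS, function(s) sum(db$source == s), integer(1))
  attr(db, "provenance") <- provenance_summary(counts)
  db
}

#' Summarize database provenance
#'
#' Per-source entry counts and their total, the headline bookkeeping of
#' a merged multi-source database.
#'
#' @param per_source_counts Named or unnamed integer vector of entry
#'   counts per source collection.
#' @return list with `per_source` (named integer vector) and `total`.
#' @examples
#' provenance_summary(c(assembly = 41018, unigene = 20949,
#'                      `protein-set` = 448))$total  # 62415
#' @export
provenance_summary <- function(per_source_counts) {
  counts <- as.integer(per_source_counts)
  names(counts) <- if (is.null(names(per_source_counts)))
    SOURCE_LEVELS[seq_along(counts)] else names(per_source_counts)
  list(per_source = counts, total = sum(counts))
}

#' Build the merged non-redundant protein database
#'
#' Runs the full construction pipeline: six-frame translation and
#' stop-codon splitting of every nucleotide record, minimum-length
#' filtering of the translation-derived candidates, merging with the
#' protein-set entries, substring redundancy removal and dense id
#' assignment. The conversion table accounts for every candidate:
#' retained (with its internal id), removed as too short, or removed as
#' redundant (with its retained representative).
#'
#' @param nt_records data.frame of nucleotide records (`accession`,
#'   `source`, `sequence`), sources `"assembly"` or `"unigene"`.
#' @param prot_records Optional data.frame of protein records
#'   (`accession`, `sequence`); their source is `"protein-set"` and the
#'   length filter is not applied to them.
#' @param min_len Minimum candidate length (amino acids).
#' @param genetic_code Codon table.
#' @return list with `database` (see [assign_internal_ids()]),
#'   `conversion` (data.frame `accession`, `internal_id` or `NA`,
#'   `removal_reason` in `{"none","too-short","redundant"}`,
#'   `representative`), and `provenance`.
#' @export
build_protein_db <- function(nt_records, prot_records = NULL, min_len = 50,
                             genetic_code = standard_genetic_code()) {
  cand_list <- lapply(seq_len(nrow(nt_records)), function(i) {
    translate_to_candidates(nt_records$accession[i], nt_records$source[i],
                            nt_records$sequence[i], genetic_code)
  })
  cands <- do.call(rbind, c(cand_list, list(NULL)))
  if (is.null(cands)) cands <- translate_to_candidates("x", "assembly", "")[0, ]
  kept <- length_filter(cands, min_len)
  short <- cands[!cands$accession %in% kept$accession, , drop = FALSE]
  pool <- kept[, c("accession", "source", "sequence")]
  if (!is.null(prot_records) && nrow(prot_records) > 0) {
    pool <- rbind(pool, data.frame(accession = prot_records$accession,
                                   source = "protein-set",
                                   sequence = prot_records$sequence,
                                   stringsAsFactors = FALSE))
  }
  dedup <- remove_redundant(pool)
  db <- assign_internal_ids(dedup$retained)
  conv <- dedup$conversion
  conv$internal_id <- db$internal_id[match(conv$accession, db$source_accession)]
  if (nrow(short) > 0) {
    conv <- rbind(conv, data.frame(accession = short$accession,
                                   removal_reason = "too-short",
                                   representative = NA_character_,
                                   internal_id = NA_integer_,
                                   stringsAsFactors = FALSE))
  }
  conv <- conv[order(conv$accession),
               c("accession", "internal_id", "removal_reason", "representative")]
  rownames(conv) <- NULL
  list(database = db, conversion = conv, provenance = attr(db, "provenance"))
}

#' Attach tabular annotation hits to database entries
#'
#' Filters BLAST-style hits at an e-value cutoff and ranks the
#' surviving hits of each entry by ascending e-value (ties broken by
#' hit accession). Hits may reference entries by internal id or by
#' source accession (resolved through the database); a hit referencing
#' an unknown entry is skipped with a warning. An entry with no
#' surviving hit simply has no rows.
#'
#' @param db Database data.frame from [build_protein_db()].
#' @param hits data.frame with columns `query` (internal id or source
#'   accession), `hit_accession`, `e_value`, and optionally
#'   `description` and `go_terms`.
#' @param e_cutoff Maximum e-value retained (default `1e-4`).
#' @return data.frame `internal_id`, `hit_accession`, `e_value`,
#'   `rank`, `description`, `go_terms`.
#' @export
attach_annotations <- function(db, hits, e_cutoff = 1e-4) {
  if (!"description" %in% names(hits)) hits$description <- NA_character_
  if (!"go_terms" %in% names(hits)) hits$go_terms <- NA_character_
  id <- suppressWarnings(as.integer(hits$query))
  resolved <- ifelse(!is.na(id) & id %in% db$internal_id, id,
                     db$internal_id[match(as.character(hits$query),
                                          db$source_accession)])
  unknown <- is.na(resolved)
  if (any(unknown)) {
    warning(sprintf("%d annotation hit(s) reference unknown entries; skipped",
                    sum(unknown)))
  }
  keep <- !unknown & hits$e_value <= e_cutoff
  ann <- data.frame(internal_id = resolved[keep],
                    hit_accession = hits$hit_accession[keep],
                    e_value = hits$e_value[keep],
                    description = hits$description[keep],
                    go_terms = hits$go_terms[keep],
                    stringsAsFactors = FALSE)
  ann <- ann[order(ann$internal_id, ann$e_value, ann$hit_accession), ,
             drop = FALSE]
  ann$rank <- stats::ave(ann$e_value, ann$internal_id,
                         FUN = seq_along)
  rownames(ann) <- NULL
  ann[, c("internal_id", "hit_accession", "e_value", "rank",
          "description", "go_terms")]
}

#' Generate a reversed-sequence decoy database
#'
#' One decoy per target entry, with the amino-acid sequence reversed
#' and the id namespace kept disjoint by prefixing. A palindromic
#' target yields a decoy with an identical sequence; it is still
#' flagged as a decoy.
#'
#' @param db Database data.frame.
#' @param prefix Decoy id prefix (default `"DECOY_"`).
#' @return data.frame with `decoy_id`, `target_id`, `sequence`,
#'   `length`, `is_decoy`.
#' @export
make_decoy_db <- function(db, prefix = "DECOY_") {
  rev_one <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
  data.frame(
    decoy_id = paste0(prefix, db$internal_id),
    target_id = db$internal_id,
    sequence = vapply(db$sequence, rev_one, character(1), USE.NAMES = FALSE),
    length = db$length,
    is_decoy = TRUE,
    stringsAsFactors = FALSE
  )
}
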