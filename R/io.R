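# File-format plumbing: FASTA via Biostrings, tab-separated tables via
# base utils. All tables round-trip: writing and re-reading reproduces
# identical in-memory content.

#' Read a nucleotide FASTA as a record table
#'
#' @param path FASTA file (wrapped or unwrapped).
#' @param source Source collection tag applied to every record, one of
#'   `"assembly"`, `"unigene"`.
#' @return data.frame `accession`, `source`, `sequence`. The accession
#'   is the first whitespace-delimited token of the header.
#' @export
read_nt_fasta <- function(path, source) {
  x <- Biostrings::readDNAStringSet(path)
  data.frame(accession = sub("\\s.*$", "", names(x)),
             source = source,
             sequence = as.character(x),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read a protein FASTA as a record table
#'
#' @param path FASTA file.
#' @return data.frame `accession`, `sequence`.
#' @export
read_protein_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  data.frame(accession = sub("\\s.*$", "", names(x)),
             sequence = as.character(x),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write the merged database as protein FASTA
#'
#' Headers follow `lcl|<internal_id> <source_accession> <source>`.
#'
#' @param db Database data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_db_fasta <- function(db, path) {
  aa <- Biostrings::AAStringSet(db$sequence)
  names(aa) <- sprintf("lcl|%d %s %s", db$internal_id, db$source_accession,
                       db$source)
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

#' Read a database protein FASTA written by [write_db_fasta()]
#'
#' @param path FASTA file.
#' @return Database data.frame (`internal_id`, `source_accession`,
#'   `source`, `sequence`, `length`).
#' @export
read_db_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  parts <- strsplit(names(x), " ", fixed = TRUE)
  data.frame(
    internal_id = as.integer(sub("^lcl\\|", "", vapply(parts, `[`, "", 1L))),
    source_accession = vapply(parts, `[`, "", 2L),
    source = vapply(parts, `[`, "", 3L),
    sequence = as.character(x),
    length = Biostrings::width(x),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

.read_tsv <- function(path, colClasses = NA) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = colClasses, na.strings = "")
}

#' Write / read the accession conversion table
#'
#' TSV columns: `accession`, `internal_id` (empty when removed),
#' `removal_reason`, `representative`.
#'
#' @param conversion Conversion data.frame.
#' @param path TSV file.
#' @return `path` / the conversion data.frame.
#' @export
write_conversion_table <- function(conversion, path) .write_tsv(conversion, path)

#' @rdname write_conversion_table
#' @export
read_conversion_table <- function(path) {
  x <- .read_tsv(path, colClasses = c(accession = "character",
                                      internal_id = "integer",
                                      removal_reason = "character",
                                      representative = "character"))
  x
}

#' Write / read the annotation table
#'
#' @param annotations Annotation data.frame from [attach_annotations()].
#' @param path TSV file.
#' @return `path` / the annotation data.frame.
#' @export
write_annotation_table <- function(annotations, path) .write_tsv(annotations, path)

#' @rdname write_annotation_table
#' @export
read_annotation_table <- function(path) .read_tsv(path)

#' Read tabular BLAST-style hits
#'
#' Accepts the 12-column BLAST tabular dialect (query, subject, pident,
#' length, mismatch, gapopen, qstart, qend, sstart, send, evalue,
#' bitscore), optionally followed by `description` and `go_terms`
#' columns, with or without a header line.
#'
#' @param path TSV file.
#' @return data.frame `query`, `hit_accession`, `e_value`,
#'   `description`, `go_terms` suitable for [attach_annotations()].
#' @export
read_blast_hits <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("query", first, ignore.case = TRUE)
  x <- utils::read.delim(path, header = has_header,
                         stringsAsFactors = FALSE, na.strings = "")
  if (!has_header) {
    base <- c("query", "subject", "pident", "length", "mismatch", "gapopen",
              "qstart", "qend", "sstart", "send", "evalue", "bitscore")
    extra <- c("description", "go_terms")
    names(x) <- c(base, extra)[seq_len(ncol(x))]
  }
  names(x) <- tolower(names(x))
  out <- data.frame(query = as.character(x$query),
                    hit_accession = as.character(x$subject),
                    e_value = as.numeric(x$evalue),
                    stringsAsFactors = FALSE)
  out$description <- if ("description" %in% names(x))
    as.character(x$description) else NA_character_
  out$go_terms <- if ("go_terms" %in% names(x))
    as.character(x$go_terms) else NA_character_
  out
}

#' Write / read a PSM table
#'
#' TSV columns: `spectrum_id`, `run_id`, `condition`, `peptide`,
#' `charge`, `xcorr`, `peptide_probability`, `protein_refs`
#' (semicolon-joined), `is_decoy`.
#'
#' @param psms PSM data.frame.
#' @param path TSV file.
#' @return `path` / the PSM data.frame.
#' @export
write_psm_table <- function(psms, path) .write_tsv(psms, path)

#' @rdname write_psm_table
#' @export
read_psm_table <- function(path) {
  x <- .read_tsv(path)
  x$charge <- as.integer(x$charge)
  x$is_decoy <- as.logical(x$is_decoy)
  x$protein_refs <- as.character(x$protein_refs)
  x
}

#' Write / read an LC-MS feature observation table
#'
#' TSV columns: `run_id`, `condition`, `mz`, `rt`, `intensity`.
#'
#' @param features Feature data.frame.
#' @param path TSV file.
#' @return `path` / the feature data.frame.
#' @export
write_feature_table <- function(features, path) .write_tsv(features, path)

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) .read_tsv(path)

#' Write / read a protein-by-run spectral count matrix
#'
#' The TSV has proteins as rows (first column `internal_id`) and one
#' column per run, headers `run:condition`.
#'
#' @param cm Count matrix object from [count_spectra()].
#' @param path TSV file.
#' @return `path` / the count matrix object.
#' @export
write_count_matrix <- function(cm, path) {
  df <- data.frame(internal_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[-1] <- paste(cm$runs, cm$conditions, sep = ":")
  .write_tsv(df, path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- as.character(df[[1]])
  rc <- strsplit(colnames(counts), ":", fixed = TRUE)
  runs <- vapply(rc, `[`, "", 1L)
  conditions <- vapply(rc, `[`, "", 2L)
  colnames(counts) <- runs
  storage.mode(counts) <- "integer"
  list(counts = counts, runs = runs, conditions = conditions,
       run_totals = colSums(counts))
}
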