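test_that("six-frame translation matches the codon-table oracle on random sequences", {
  set.seed(11)
  for (i in 1:60) {
    s <- random_nt(sample(0:120, 1), ambig_prob = if (i %% 3 == 0) 0.05 else 0)
    expect_identical(six_frame_translate(s), oracle_six_frames(s),
                     label = sprintf("sequence %d: %s", i, s))
  }
})

test_that("translation handles the documented edge cases", {
  expect_identical(unname(six_frame_translate("ATGAAATAA")[["+1"]]), "MK*")
  expect_identical(unname(six_frame_translate("")),
                   rep("", 6))
  # strand symmetry: forward frames of S are reverse frames of revcomp(S)
  set.seed(12)
  s <- random_nt(90)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  a <- six_frame_translate(s)
  b <- six_frame_translate(rc)
  expect_identical(unname(a[c("+1", "+2", "+3")]),
                   unname(b[c("-1", "-2", "-3")]))
  # U is read as T; ambiguous codons translate to X unless resolvable
  expect_identical(unname(six_frame_translate("AUG")[["+1"]]), "M")
  expect_identical(unname(six_frame_translate("GCN")[["+1"]]), "A")  # GCx = Ala
  expect_identical(unname(six_frame_translate("ANT")[["+1"]]), "X")
  expect_error(six_frame_translate("ACGJ"), "position 4")
})

test_that("stop-codon splitting drops empty segments and reconstructs the input", {
  expect_identical(split_at_stop_codons("MK*AAL*"), c("MK", "AAL"))
  expect_identical(split_at_stop_codons("***"), character(0))
  expect_identical(split_at_stop_codons("MKWVA"), "MKWVA")
  set.seed(13)
  for (i in 1:20) {
    aa <- paste(sample(c(strsplit("ACDEFG", "")[[1]], "*"), 40,
                       replace = TRUE), collapse = "")
    segs <- split_at_stop_codons(aa)
    expect_identical(gsub("\\*+", "", aa), paste(segs, collapse = ""))
    expect_false(any(grepl("*", segs, fixed = TRUE)))
  }
})

test_that("length filter removes candidates shorter than the threshold, boundary inclusive", {
  cand <- data.frame(sequence = c(random_aa(49), random_aa(50), random_aa(51)))
  kept <- length_filter(cand, 50)
  expect_identical(nchar(kept$sequence), c(50L, 51L))
  expect_identical(nrow(length_filter(cand[0, , drop = FALSE], 50)), 0L)
})

test_that("redundancy removal equals the all-pairs substring oracle on planted sets", {
  for (seed in 1:8) {
    set.seed(seed * 100)
    n_base <- 25
    base <- data.frame(
      accession = sprintf("B%03d", 1:n_base),
      source = sample(c("assembly", "unigene", "protein-set"), n_base,
                      replace = TRUE),
      sequence = vapply(1:n_base, function(i) random_aa(sample(30:80, 1)),
                        character(1)),
      stringsAsFactors = FALSE)
    # plant substrings and exact duplicates
    extra <- do.call(rbind, lapply(1:10, function(k) {
      p <- sample(n_base, 1)
      full <- base$sequence[p]
      if (k <= 7) {
        len <- sample(5:(nchar(full) - 1), 1)
        st <- sample(nchar(full) - len + 1, 1)
        seqk <- substr(full, st, st + len - 1)
      } else seqk <- full
      data.frame(accession = sprintf("P%03d", k),
                 source = sample(c("assembly", "unigene", "protein-set"), 1),
                 sequence = seqk, stringsAsFactors = FALSE)
    }))
    entries <- rbind(base, extra)
    res <- remove_redundant(entries)
    removed <- sort(res$conversion$accession[
      res$conversion$removal_reason == "redundant"])
    expect_identical(removed, oracle_redundant_removed(entries))
    # substring-freeness of the retained set, checked exhaustively
    rs <- res$retained$sequence
    for (i in seq_along(rs)) {
      others <- rs[-i]
      expect_false(any(nchar(others) > nchar(rs[i]) &
                         grepl(rs[i], others, fixed = TRUE)))
    }
    # every removal names a retained representative containing it
    conv <- res$conversion
    red <- conv[conv$removal_reason == "redundant", ]
    for (j in seq_len(nrow(red))) {
      rep_seq <- res$retained$sequence[res$retained$accession ==
                                         red$representative[j]]
      own_seq <- entries$sequence[entries$accession == red$accession[j]]
      expect_true(grepl(own_seq, rep_seq, fixed = TRUE))
    }
  }
})

test_that("redundancy removal is idempotent and order-invariant", {
  set.seed(21)
  entries <- data.frame(
    accession = sprintf("E%02d", 1:30),
    source = sample(c("assembly", "unigene"), 30, replace = TRUE),
    sequence = c(vapply(1:20, function(i) random_aa(sample(20:60, 1)),
                        character(1)), character(10)),
    stringsAsFactors = FALSE)
  for (k in 21:30) {
    full <- entries$sequence[k - 20]
    entries$sequence[k] <- substr(full, 2, nchar(full) - 1)
  }
  res1 <- remove_redundant(entries)
  res2 <- remove_redundant(res1$retained)
  expect_identical(res1$retained, res2$retained)
  perm <- entries[sample(nrow(entries)), ]
  res3 <- remove_redundant(perm)
  expect_setequal(res1$retained$accession, res3$retained$accession)
  expect_identical(res1$conversion, res3$conversion)
})

test_that("tie-break for exact duplicates follows source rank then accession", {
  entries <- data.frame(accession = c("Z9", "A1", "M5"),
                        source = c("unigene", "protein-set", "unigene"),
                        sequence = rep("MKWVAMKWVA", 3),
                        stringsAsFactors = FALSE)
  res <- remove_redundant(entries)
  expect_identical(res$retained$accession, "M5")  # unigene beats protein-set
  expect_identical(
    res$conversion$representative[res$conversion$accession == "Z9"], "M5")
})

test_that("internal ids are dense and provenance counts conserve", {
  retained <- data.frame(
    accession = c("U2", "A1", "P9"),
    source = c("unigene", "assembly", "protein-set"),
    sequence = c("MKWVA", "AALKQ", "PQRST"), stringsAsFactors = FALSE)
  db <- assign_internal_ids(retained)
  expect_identical(db$internal_id, 1:3)
  expect_identical(db$source_accession, c("A1", "U2", "P9"))
  prov <- attr(db, "provenance")
  expect_identical(unname(prov$per_source), c(1L, 1L, 1L))
  expect_identical(prov$total, 3L)
  # the headline source mix of a real merged citrus EST/protein database
  prov_full <- provenance_summary(c(assembly = 41018, unigene = 20949,
                                    `protein-set` = 448))
  expect_identical(prov_full$total, 62415L)
})

test_that("full database build conserves every candidate in the conversion table", {
  cfg <- sim_config(seed = 5, n_proteins = 15, n_est = 40,
                    redundancy_rate = 0.2, short_rate = 0.1)
  sim <- simulate_est_collection(cfg)
  res <- build_protein_db(sim$records)
  conv <- res$conversion
  expect_false(anyDuplicated(conv$accession) > 0)
  expect_identical(sum(conv$removal_reason == "none"), nrow(res$database))
  # generator bookkeeping is the oracle for planted candidates
  tr <- sim$truth
  red <- tr[tr$kind == "redundant", ]
  got <- conv[match(red$candidate, conv$accession), ]
  expect_true(all(got$removal_reason == "redundant"))
  expect_identical(sub("\\|.*$", "", got$representative), red$parent)
  parents <- conv[match(tr$candidate[tr$kind == "parent"], conv$accession), ]
  expect_true(all(parents$removal_reason == "none"))
  shorts <- conv[match(tr$candidate[tr$kind == "short"], conv$accession), ]
  expect_true(all(shorts$removal_reason == "too-short"))
  expect_identical(res$provenance$total, nrow(res$database))
})

test_that("annotation attachment filters at the e-value cutoff and ranks hits", {
  db <- data.frame(internal_id = 1:3, source_accession = c("a", "b", "c"),
                   source = "assembly", sequence = c("MK", "AA", "WW"),
                   length = 2L, stringsAsFactors = FALSE)
  hits <- data.frame(query = c("1", "1", "2", "b", "zzz"),
                     hit_accession = c("AT1", "AT2", "AT3", "AT4", "AT5"),
                     e_value = c(1e-6, 1e-10, 1e-3, 0, 1e-9),
                     stringsAsFactors = FALSE)
  expect_warning(ann <- attach_annotations(db, hits), "unknown")
  expect_identical(nrow(ann[ann$internal_id == 2 & ann$e_value > 1e-4, ]), 0L)
  r1 <- ann[ann$internal_id == 1, ]
  expect_identical(r1$hit_accession[order(r1$rank)], c("AT2", "AT1"))
  expect_identical(ann$rank[ann$hit_accession == "AT4"], 1)
  expect_identical(nrow(ann[ann$internal_id == 3, ]), 0L)
})

test_that("decoy database reverses every sequence and keeps ids disjoint", {
  db <- data.frame(internal_id = 1:3, source_accession = c("a", "b", "c"),
                   source = "assembly",
                   sequence = c("MKWVA", "MAAM", "Q"),
                   length = c(5L, 4L, 1L), stringsAsFactors = FALSE)
  dec <- make_decoy_db(db)
  expect_identical(dec$sequence, c("AVWKM", "MAAM", "Q"))
  expect_identical(nrow(dec), nrow(db))
  expect_true(all(dec$is_decoy))
  expect_length(intersect(dec$decoy_id, as.character(db$internal_id)), 0)
})

test_that("database, conversion and annotation files round-trip", {
  cfg <- sim_config(seed = 9, n_proteins = 8, n_est = 20)
  sim <- simulate_est_collection(cfg)
  res <- build_protein_db(sim$records)
  tmp <- withr::local_tempdir()
  fa <- file.path(tmp, "db.fasta")
  write_db_fasta(res$database, fa)
  back <- read_db_fasta(fa)
  expect_identical(back, res$database[, names(back)],
                   ignore_attr = TRUE)
  tsv <- file.path(tmp, "conv.tsv")
  write_conversion_table(res$conversion, tsv)
  expect_identical(read_conversion_table(tsv), res$conversion,
                   ignore_attr = TRUE)
  # nucleotide fasta round-trip through Biostrings
  ntfa <- file.path(tmp, "est.fasta")
  x <- Biostrings::DNAStringSet(sim$records$sequence)
  names(x) <- sim$records$accession
  Biostrings::writeXStringSet(x, ntfa)
  rec <- read_nt_fasta(ntfa, "assembly")
  expect_identical(rec$sequence, sim$records$sequence)
  expect_identical(rec$accession, sim$records$accession)
})
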