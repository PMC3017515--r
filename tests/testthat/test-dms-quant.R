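make_features <- function(run_id, condition, mz, rt, intensity) {
  data.frame(run_id = run_id, condition = condition, mz = mz, rt = rt,
             intensity = intensity, stringsAsFactors = FALSE)
}

test_that("a run aligned to itself gets the identity warp", {
  set.seed(101)
  f <- make_features("R1", "A", runif(50, 300, 1400), runif(50, 10, 100),
                     runif(50, 1e5, 1e6))
  maps <- align_retention_times(rbind(f, transform(f, run_id = "R2")),
                                reference = "R1")
  aligned <- apply_alignment(f, maps["R1"])
  expect_equal(aligned$rt, f$rt)
  # a shift-free copy also maps onto itself
  aligned2 <- apply_alignment(transform(f, run_id = "R2"), maps)
  expect_equal(aligned2$rt, f$rt, tolerance = 1e-8)
})

test_that("a planted constant shift is recovered within one bin width", {
  for (shift in c(1.5, -1.5, 0.7)) {
    set.seed(103)
    base <- make_features("R1", "A", runif(400, 300, 1400),
                          runif(400, 10, 100), exp(rnorm(400, 13, 1)))
    shifted <- transform(base, run_id = "R2", rt = rt + shift)
    maps <- align_retention_times(rbind(base, shifted), reference = "R1",
                                  bin_width = 1)
    recovered <- mean(maps[["R2"]]$offsets$offset)
    expect_lt(abs(recovered - shift), 1)
    aligned <- apply_alignment(shifted, maps)
    expect_lt(median(abs(aligned$rt - base$rt)), 1)
  }
})

test_that("warps are monotone and preserve feature order within a run", {
  set.seed(104)
  f1 <- make_features("R1", "A", runif(200, 300, 1400), runif(200, 10, 100),
                      exp(rnorm(200, 13, 1)))
  f2 <- transform(f1, run_id = "R2", rt = rt + 0.8 + 0.3 * sin(rt / 10))
  maps <- align_retention_times(rbind(f1, f2), reference = "R1",
                                tile_size = 20)
  for (m in maps) {
    expect_true(all(diff(m$knots$ref_rt) >= 0))
  }
  aligned <- apply_alignment(f2, maps)
  expect_identical(order(aligned$rt), order(f2$rt))
})

test_that("a run with no features gets the identity warp with a warning", {
  f <- make_features("R1", "A", c(500, 600), c(20, 30), c(1e5, 1e5))
  expect_warning(maps <- align_retention_times(f, runs = c("R1", "R2")),
                 "no features")
  expect_identical(maps[["R2"]]$knots$obs_rt, maps[["R2"]]$knots$ref_rt)
})

test_that("frame detection honours the intensity threshold and working ranges", {
  f <- make_features(
    run_id = c("R1", "R1", "R1", "R2"),
    condition = c("A", "A", "A", "B"),
    mz = c(500.000, 250, 500.005, 500.002),
    rt = c(20, 20, 90, 20.5),
    intensity = c(49999, 1e6, 1e6, 1e6))
  det <- detect_frames(f)
  # the sub-threshold feature cannot seed, the m/z 250 feature is out of
  # range, so only the two in-range high-intensity features seed/join
  expect_identical(nrow(det$frames), 2L)
  twofold <- det$assignments[det$assignments$frame_id ==
    det$frames$frame_id[det$frames$rt_center == 20.5], ]
  expect_setequal(twofold$run_id, c("R1", "R2"))
  # sub-threshold features may join but never seed
  expect_true(all(det$frames$seed_intensity >= 50000))
  # each feature belongs to at most one frame
  expect_lte(max(table(paste(det$assignments$mz, det$assignments$rt))), 1)
})

test_that("area integration sums member intensities per run and is linear", {
  f <- make_features(c("R1", "R1", "R2"), c("A", "A", "B"),
                     c(500.001, 500.004, 500.002), c(20, 21, 20),
                     c(6e5, 4e5, 1e6))
  det <- detect_frames(f)
  areas <- integrate_areas(det, runs = c("R1", "R2", "R3"))
  expect_equal(unname(areas[1, ]), c(1e6, 1e6, 0))
  # splitting a feature into two half-intensity features keeps the area
  g <- make_features(c("R1", "R1"), "A", c(500.001, 500.002), c(20, 20),
                     c(5e5, 5e5))
  expect_equal(unname(integrate_areas(detect_frames(g), "R1")[1, 1]), 1e6)
})

test_that("frame tests return ratio 1 and p 1 for identical conditions", {
  areas <- matrix(rep(c(1e5, 2e5, 3e5, 1e5, 2e5, 3e5), 2), nrow = 2,
                  byrow = TRUE, dimnames = list(c("1", "2"), NULL))
  res <- test_frames(areas, rep(c("A", "B"), each = 3))
  expect_equal(res$ratio, c(1, 1))
  expect_equal(res$p_value, c(1, 1))
})

test_that("all-zero frames are dropped with a notice", {
  areas <- matrix(c(rep(0, 6), rep(1e5, 6)), nrow = 2, byrow = TRUE,
                  dimnames = list(c("z", "ok"), NULL))
  expect_message(res <- test_frames(areas, rep(c("A", "B"), each = 3)),
                 "all-zero")
  expect_identical(res$frame_id, "ok")
})

test_that("condition swap inverts ratios exactly and preserves p-values", {
  set.seed(107)
  areas <- matrix(exp(rnorm(200, 12, 1)), nrow = 20,
                  dimnames = list(as.character(1:20), NULL))
  areas[sample(length(areas), 15)] <- 0
  cond <- rep(c("A", "B"), each = 5)
  swap <- rep(c("B", "A"), each = 5)
  suppressMessages({
    r1 <- test_frames(areas, cond)
    r2 <- test_frames(areas, swap)
  })
  expect_equal(r1$ratio * r2$ratio, rep(1, nrow(r1)))
  expect_equal(r1$p_value, r2$p_value)
})

test_that("null frames reject at close to the nominal 5% level", {
  set.seed(109)
  n_frames <- 1500
  areas <- matrix(exp(rnorm(n_frames * 10, 12, 0.3)), nrow = n_frames)
  rownames(areas) <- as.character(seq_len(n_frames))
  res <- test_frames(areas, rep(c("A", "B"), each = 5))
  frac <- mean(res$p_value < 0.05)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
})

test_that("planted four-fold frames are estimated near four", {
  set.seed(110)
  n <- 300
  a <- matrix(exp(rnorm(n * 5, log(4e5 * 4), 0.3)), nrow = n)
  b <- matrix(exp(rnorm(n * 5, log(4e5), 0.3)), nrow = n)
  areas <- cbind(a, b)
  rownames(areas) <- as.character(seq_len(n))
  res <- test_frames(areas, rep(c("A", "B"), each = 5))
  expect_lt(abs(median(res$ratio) - 4) / 4, 0.2)
})

test_that("protein rollup weights ratios, combines p-values and calls directions", {
  fr <- data.frame(frame_id = c("f1", "f2", "f3"),
                   mean_a = c(2e5, 4e5, 1.8e5), mean_b = c(1e5, 1e5, 1e5),
                   ratio = c(2, 4, 1.8), p_value = c(0.001, 0.001, 0.001),
                   stringsAsFactors = FALSE)
  ids <- data.frame(frame_id = c("f1", "f2", "f3"),
                    peptide = c("p1", "p2", "p3"),
                    protein_refs = c("10", "10", "11"),
                    stringsAsFactors = FALSE)
  eq_w <- stats::setNames(c(1, 1, 1), c("f1", "f2", "f3"))
  roll <- protein_rollup(fr, ids, weights = eq_w, min_peptides = 1)
  p10 <- roll$proteins[roll$proteins$internal_id == "10", ]
  expect_equal(p10$ratio, 3.0)   # equal-weight mean of {2, 4}
  expect_identical(p10$direction, 1L)
  # a 1.8-fold change is significant but below the two-fold threshold
  p11 <- roll$proteins[roll$proteins$internal_id == "11", ]
  expect_identical(p11$direction, 0L)
  # weighted mean is bounded by the member ratios
  expect_gte(p10$ratio, 2); expect_lte(p10$ratio, 4)
  # an extreme but significant ratio is called up, as for the strongest
  # aconitase entry (ratio 24.9, p 9.9e-20)
  fr2 <- data.frame(frame_id = c("g1", "g2"), mean_a = c(2.49e6, 2.49e6),
                    mean_b = c(1e5, 1e5), ratio = c(24.9, 24.9),
                    p_value = c(9.9e-20, 9.9e-20), stringsAsFactors = FALSE)
  ids2 <- data.frame(frame_id = c("g1", "g2"), peptide = c("q1", "q2"),
                     protein_refs = "39802", stringsAsFactors = FALSE)
  roll2 <- protein_rollup(fr2, ids2)
  expect_identical(roll2$proteins$direction, 1L)
  expect_equal(roll2$proteins$ratio, 24.9)
})

test_that("proteins with fewer than two peptides are excluded and recorded", {
  fr <- data.frame(frame_id = "f1", mean_a = 2e5, mean_b = 1e5,
                   ratio = 2, p_value = 0.001, stringsAsFactors = FALSE)
  ids <- data.frame(frame_id = "f1", peptide = "p1", protein_refs = "7",
                    stringsAsFactors = FALSE)
  roll <- protein_rollup(fr, ids)
  expect_identical(nrow(roll$proteins), 0L)
  expect_identical(roll$excluded, "7")
})

test_that("the dMS workflow is deterministic and recovers planted extreme folds", {
  cfg <- sim_config(seed = 113, n_proteins = 40)
  sim <- simulate_features(cfg)
  wf1 <- dms_workflow(sim$features, sim$ids)
  wf2 <- dms_workflow(sim$features, sim$ids)
  expect_identical(wf1$proteins, wf2$proteins)
  m <- merge(wf1$proteins, sim$truth, by.x = "internal_id", by.y = "protein")
  extreme <- m[m$fold_change %in% c(0.25, 4), ]
  expect_gte(mean(extreme$direction.x == extreme$direction.y), 0.9)
  null_prot <- m[m$fold_change == 1, ]
  expect_gte(mean(null_prot$direction.x == 0), 0.9)
  # ratio point estimates track the planted folds
  agg <- stats::aggregate(list(r = m$ratio), list(fold = m$fold_change),
                          stats::median)
  expect_equal(agg$r, agg$fold, tolerance = 0.25)
})

test_that("noiseless planted folds are recovered exactly", {
  cfg <- sim_config(seed = 115, n_proteins = 10, noise_sigma = 0,
                    rt_jitter = 0, rt_shifts = 0, n_noise_features = 0)
  sim <- simulate_features(cfg)
  wf <- dms_workflow(sim$features, sim$ids, align = FALSE)
  m <- merge(wf$proteins, sim$truth, by.x = "internal_id", by.y = "protein")
  expect_equal(m$ratio, m$fold_change, tolerance = 1e-9)
})

test_that("feature tables round-trip through TSV", {
  cfg <- sim_config(seed = 117, n_proteins = 5, n_noise_features = 10)
  sim <- simulate_features(cfg)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(sim$features, tmp)
  back <- read_feature_table(tmp)
  expect_equal(back, sim$features, tolerance = 1e-12, ignore_attr = TRUE)
})
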