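# Peak-integration label-free quantification (dMS): retention-time
# alignment by tile-wise binned-intensity cross-correlation, seeded
# m/z x RT frame detection, per-run area integration, per-frame
# two-sample t-tests and intensity-weighted protein roll-up.

#' Align runs in retention time to a reference run
#'
#' Total ion intensity is binned along retention time (bins of
#' `bin_width` minutes). The RT axis is cut into tiles of `tile_size`
#' bins; within each tile the integer-bin offset maximizing the Pearson
#' correlation between the run's and the reference's binned profiles is
#' chosen and refined to sub-bin resolution by parabolic interpolation
#' around the correlation peak. Offsets exceeding
#' `time_threshold * tile span` (or with undefined correlation) are
#' rejected and interpolated from neighbouring tiles. The per-run warp
#' maps observed RT to reference RT by piecewise-linear interpolation
#' between tile centres and is forced monotone non-decreasing. A run
#' aligned to itself gets the identity warp; a run with no features
#' gets the identity warp with a warning.
#'
#' @param features Feature data.frame (`run_id`, `condition`, `mz`,
#'   `rt`, `intensity`).
#' @param reference Reference run id; default the first run in sorted
#'   order.
#' @param bin_width Correlation bin width in minutes (default 1).
#' @param tile_size Tile size in bins (default 300).
#' @param time_threshold Maximum accepted offset as a fraction of the
#'   tile span (default 0.6).
#' @param runs Optional character vector of run ids to map; defaults to
#'   the runs present in `features`. A listed run with no features gets
#'   the identity warp with a warning.
#' @return Named list of per-run alignment maps, each a list with
#'   `run_id`, `knots` (data.frame `obs_rt`, `ref_rt`) and `offsets`.
#' @export
align_retention_times <- function(features, reference = NULL, bin_width = 1,
                                  tile_size = 300, time_threshold = 0.6,
                                  runs = NULL) {
  runs <- sort(unique(c(features$run_id, runs)))
  stopifnot(length(runs) >= 1)
  if (is.null(reference)) reference <- runs[1]
  stopifnot(reference %in% runs)
  rt_lo <- floor(min(features$rt) / bin_width) * bin_width
  rt_hi <- ceiling(max(features$rt) / bin_width) * bin_width
  breaks <- seq(rt_lo, rt_hi + bin_width, by = bin_width)
  n_bins <- length(breaks) - 1L
  profile <- function(run) {
    f <- features[features$run_id == run, ]
    idx <- pmin(pmax(findInterval(f$rt, breaks), 1L), n_bins)
    p <- numeric(n_bins)
    agg <- tapply(f$intensity, idx, sum)
    p[as.integer(names(agg))] <- agg
    p
  }
  ref_prof <- profile(reference)
  tiles <- split(seq_len(n_bins), ceiling(seq_len(n_bins) / tile_size))
  maps <- lapply(runs, function(run) {
    f_run <- features[features$run_id == run, ]
    if (nrow(f_run) == 0L) {
      warning(sprintf("run '%s' has no features; identity warp", run))
      return(list(run_id = run,
                  knots = data.frame(obs_rt = c(rt_lo, rt_hi),
                                     ref_rt = c(rt_lo, rt_hi)),
                  offsets = NULL))
    }
    if (identical(run, reference)) {
      return(list(run_id = run,
                  knots = data.frame(obs_rt = c(rt_lo, rt_hi),
                                     ref_rt = c(rt_lo, rt_hi)),
                  offsets = data.frame(tile_center = (rt_lo + rt_hi) / 2,
                                       offset = 0)))
    }
    prof <- profile(run)
    centers <- vapply(tiles, function(b) rt_lo + bin_width * mean(b - 0.5),
                      numeric(1))
    offsets <- vapply(seq_along(tiles), function(k) {
      bins <- tiles[[k]]
      span_bins <- length(bins)
      max_lag <- max(1L, floor(time_threshold * span_bins))
      lags <- -max_lag:max_lag
      cors <- vapply(lags, function(l) {
        # a run shifted late by l bins matches the reference l bins back
        src <- bins + l
        ok <- src >= 1L & src <= n_bins
        if (sum(ok) < 3L) return(NA_real_)
        x <- prof[src[ok]]
        y <- ref_prof[bins[ok]]
        if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
        stats::cor(x, y)
      }, numeric(1))
      if (all(is.na(cors))) return(NA_real_)
      best <- which.max(cors)
      lag <- lags[best]
      # parabolic sub-bin refinement on the correlation peak
      if (best > 1L && best < length(lags) &&
          !is.na(cors[best - 1L]) && !is.na(cors[best + 1L])) {
        denom <- cors[best - 1L] - 2 * cors[best] + cors[best + 1L]
        if (denom < 0)
          lag <- lag + 0.5 * (cors[best - 1L] - cors[best + 1L]) / denom
      }
      off <- lag * bin_width
      if (abs(off) > time_threshold * span_bins * bin_width) NA_real_ else off
    }, numeric(1))
    if (all(is.na(offsets))) offsets[] <- 0
    if (anyNA(offsets)) {  # fill rejected tiles from neighbours
      ok <- which(!is.na(offsets))
      offsets <- stats::approx(centers[ok], offsets[ok], xout = centers,
                               rule = 2)$y
    }
    # observed RT - offset = reference RT; knots at tile centres plus
    # flat extension at the range ends
    knot_obs <- c(rt_lo - 1, centers, rt_hi + 1)
    knot_ref <- c(rt_lo - 1 - offsets[1], centers - offsets,
                  rt_hi + 1 - offsets[length(offsets)])
    knot_ref <- cummax(knot_ref)  # enforce monotone non-decreasing warp
    list(run_id = run,
         knots = data.frame(obs_rt = knot_obs, ref_rt = knot_ref),
         offsets = data.frame(tile_center = centers, offset = offsets))
  })
  stats::setNames(maps, runs)
}

#' Apply alignment maps to feature retention times
#'
#' Replaces each feature's RT by its warped (reference-scale) RT using
#' linear interpolation of the run's warp knots. Feature order within a
#' run is preserved because warps are monotone.
#'
#' @param features Feature data.frame.
#' @param maps Alignment maps from [align_retention_times()].
#' @return `features` with `rt` warped (original kept as `rt_observed`).
#' @export
apply_alignment <- function(features, maps) {
  features$rt_observed <- features$rt
  for (m in maps) {
    sel <- features$run_id == m$run_id
    if (!any(sel)) next
    features$rt[sel] <- stats::approx(m$knots$obs_rt, m$knots$ref_rt,
                                      xout = features$rt_observed[sel],
                                      rule = 2)$y
  }
  features
}

#' Detect m/z x RT frames by intensity-ordered seeding
#'
#' Features inside the m/z and RT working ranges are visited in
#' decreasing intensity order; each yet-unassigned feature whose
#' intensity reaches `intensity_min` seeds a frame, and all unassigned
#' features within `mz_width / 2` in m/z and `rt_width / 2` in RT of
#' the seed (across all runs) join it. Every feature belongs to at most
#' one frame; features outside the working ranges never seed nor join.
#'
#' @param features Aligned feature data.frame.
#' @param mz_width Full frame width in m/z (default 0.02 Da).
#' @param rt_width Full frame width in RT (default 5.0 min).
#' @param intensity_min Minimum seed intensity (default 50000).
#' @param mz_range,rt_range Working ranges (defaults `c(300, 1400)` Da
#'   and `c(5, 110)` min).
#' @return list with `frames` (data.frame `frame_id`, `mz_center`,
#'   `rt_center`, `rt_lo`, `rt_hi`, `seed_intensity`, `n_features`)
#'   and `assignments` (data.frame `frame_id`, `run_id`, `condition`,
#'   `mz`, `rt`, `intensity` for every member feature).
#' @export
detect_frames <- function(features, mz_width = 0.02, rt_width = 5.0,
                          intensity_min = 50000, mz_range = c(300, 1400),
                          rt_range = c(5, 110)) {
  f <- features[features$mz >= mz_range[1] & features$mz <= mz_range[2] &
                  features$rt >= rt_range[1] & features$rt <= rt_range[2], ,
                drop = FALSE]
  f <- f[order(-f$intensity), , drop = FALSE]
  n <- nrow(f)
  frame_of <- rep(NA_integer_, n)
  frames <- list()
  fid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(frame_of[i])) next
    if (f$intensity[i] < intensity_min) break  # sorted: no seed follows
    fid <- fid + 1L
    members <- which(is.na(frame_of) &
                       abs(f$mz - f$mz[i]) <= mz_width / 2 &
                       abs(f$rt - f$rt[i]) <= rt_width / 2)
    frame_of[members] <- fid
    frames[[fid]] <- data.frame(
      frame_id = fid, mz_center = f$mz[i], rt_center = f$rt[i],
      rt_lo = f$rt[i] - rt_width / 2, rt_hi = f$rt[i] + rt_width / 2,
      seed_intensity = f$intensity[i], n_features = length(members))
  }
  assignments <- f[!is.na(frame_of), , drop = FALSE]
  assignments$frame_id <- frame_of[!is.na(frame_of)]
  rownames(assignments) <- NULL
  frames <- if (fid > 0) do.call(rbind, frames) else
    data.frame(frame_id = integer(), mz_center = numeric(),
               rt_center = numeric(), rt_lo = numeric(), rt_hi = numeric(),
               seed_intensity = numeric(), n_features = integer())
  list(frames = frames, assignments = assignments)
}

#' Integrate per-run areas for detected frames
#'
#' The area of a frame in a run is the sum of that run's member-feature
#' intensities (discrete observations), 0 when the run contributed no
#' feature.
#'
#' @param detected Result of [detect_frames()].
#' @param runs Character vector of all run ids (columns of the result);
#'   default the runs present in the assignments.
#' @return Numeric matrix frames x runs of integrated areas, with the
#'   frame ids as row names.
#' @export
integrate_areas <- function(detected, runs = NULL) {
  a <- detected$assignments
  if (is.null(runs)) runs <- sort(unique(a$run_id))
  fids <- detected$frames$frame_id
  mat <- matrix(0, nrow = length(fids), ncol = length(runs),
                dimnames = list(fids, runs))
  if (nrow(a) > 0) {
    agg <- stats::aggregate(intensity ~ frame_id + run_id, data = a, FUN = sum)
    mat[cbind(match(agg$frame_id, fids), match(agg$run_id, runs))] <-
      agg$intensity
  }
  mat
}

# two-sided two-sample t-test p-value, tolerant of zero variance:
# equal means -> p = 1, unequal means with zero pooled variance -> p = 0
.t_test_p <- function(x, y, var_equal = TRUE) {
  nx <- length(x); ny <- length(y)
  mx <- mean(x); my <- mean(y)
  vx <- stats::var(x); vy <- stats::var(y)
  if (var_equal) {
    df <- nx + ny - 2
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / df
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- if (se > 0)
      (vx / nx + vy / ny)^2 /
        ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1)) else 1
  }
  if (!is.finite(se) || se == 0) return(if (mx == my) 1 else 0)
  2 * stats::pt(-abs((mx - my) / se), df)
}

#' Test per-frame area differences between two conditions
#'
#' A two-sided two-sample t-test (equal-variance by default, Welch
#' optional) on the per-run integrated areas of each frame, and the
#' ratio of condition mean areas. A condition mean of exactly zero is
#' replaced by a small positive floor (the global 1st percentile of
#' nonzero areas) before forming the ratio, so ratios are finite,
#' exactly reciprocal under condition swap, and untouched whenever both
#' means are nonzero. Frames with all areas zero in both conditions are
#' dropped with a message.
#'
#' @param areas Frames x runs area matrix from [integrate_areas()].
#' @param conditions Condition label per run (two levels; the first
#'   level in sort order is the ratio numerator).
#' @param var_equal Equal-variance t-test (default TRUE).
#' @param ratio_floor Positive floor for condition means; default the
#'   1st percentile of the nonzero entries of `areas`.
#' @return data.frame `frame_id`, `mean_a`, `mean_b`, `ratio`,
#'   `p_value`.
#' @export
test_frames <- function(areas, conditions, var_equal = TRUE,
                        ratio_floor = NULL) {
  conditions <- as.character(conditions)
  lev <- sort(unique(conditions))
  stopifnot(length(lev) == 2L, ncol(areas) == length(conditions))
  a_cols <- conditions == lev[1]
  nonzero <- areas[areas > 0]
  if (is.null(ratio_floor))
    ratio_floor <- if (length(nonzero) > 0)
      as.numeric(stats::quantile(nonzero, 0.01)) else 1
  all_zero <- rowSums(areas) == 0
  if (any(all_zero))
    message(sprintf("dropping %d frame(s) with all-zero areas",
                    sum(all_zero)))
  keep <- which(!all_zero)
  res <- lapply(keep, function(i) {
    x <- areas[i, a_cols]; y <- areas[i, !a_cols]
    data.frame(frame_id = rownames(areas)[i],
               mean_a = mean(x), mean_b = mean(y),
               ratio = (if (mean(x) > 0) mean(x) else ratio_floor) /
                 (if (mean(y) > 0) mean(y) else ratio_floor),
               p_value = .t_test_p(x, y, var_equal),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(res, list(NULL)))
  if (is.null(out))
    out <- data.frame(frame_id = character(), mean_a = numeric(),
                      mean_b = numeric(), ratio = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Fisher's combination of p-values, floored to avoid log(0)
.combine_p <- function(p, method = c("fisher", "min-bonferroni")) {
  method <- match.arg(method)
  p <- pmax(p, .Machine$double.xmin)
  if (method == "fisher") {
    stats::pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
  } else {
    min(1, min(p) * length(p))
  }
}

#' Roll frame results up to protein-level dMS calls
#'
#' Protein ratio is the intensity-weighted arithmetic mean of its
#' member frames' ratios, the weight of a frame being its total
#' integrated intensity across runs; the protein p-value combines the
#' member frames' p-values (Fisher's method by default). A protein
#' needs at least `min_peptides` distinct identified peptides among its
#' frames; otherwise it is excluded and listed separately. Direction is
#' `+1` if ratio >= `fold_threshold` and p < `p_max`, `-1` if ratio <=
#' `1 / fold_threshold` and p < `p_max`, else `0`.
#'
#' @param frame_results data.frame from [test_frames()].
#' @param frame_ids data.frame mapping `frame_id` to `peptide` and
#'   `protein_refs` (semicolon-joined internal ids).
#' @param weights Named numeric vector of frame weights (total frame
#'   intensity); default the sum of `mean_a + mean_b` scaled by run
#'   counts is approximated by `mean_a + mean_b`.
#' @param min_peptides Minimum distinct peptides per protein (default 2).
#' @param p_max Significance threshold (default 0.05).
#' @param fold_threshold Fold-change threshold (default 2).
#' @param p_combine `"fisher"` (default) or `"min-bonferroni"`.
#' @return list with `proteins` (data.frame `internal_id`, `ratio`,
#'   `p_value`, `n_peptides`, `direction`) and `excluded` (protein ids
#'   with fewer than `min_peptides` peptides).
#' @export
protein_rollup <- function(frame_results, frame_ids, weights = NULL,
                           min_peptides = 2, p_max = 0.05,
                           fold_threshold = 2,
                           p_combine = c("fisher", "min-bonferroni")) {
  p_combine <- match.arg(p_combine)
  fr <- merge(frame_results, frame_ids, by = "frame_id")
  if (is.null(weights)) {
    fr$weight <- fr$mean_a + fr$mean_b
  } else {
    fr$weight <- unname(weights[as.character(fr$frame_id)])
  }
  refs <- .split_refs(fr$protein_refs)
  long <- fr[rep(seq_len(nrow(fr)), lengths(refs)), , drop = FALSE]
  long$internal_id <- unlist(refs)
  split_rows <- split(long, long$internal_id)
  res <- lapply(split_rows, function(b) {
    data.frame(internal_id = b$internal_id[1],
               ratio = sum(b$weight * b$ratio) / sum(b$weight),
               p_value = .combine_p(b$p_value, p_combine),
               n_peptides = length(unique(b$peptide)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  excluded <- out$internal_id[out$n_peptides < min_peptides]
  out <- out[out$n_peptides >= min_peptides, , drop = FALSE]
  out$direction <- rep(0L, nrow(out))
  out$direction[out$ratio >= fold_threshold & out$p_value < p_max] <- 1L
  out$direction[out$ratio <= 1 / fold_threshold & out$p_value < p_max] <- -1L
  out <- out[order(out$internal_id), , drop = FALSE]
  rownames(out) <- NULL
  list(proteins = out, excluded = excluded)
}

#' Run the full dMS workflow on a feature table
#'
#' Aligns runs, detects frames, integrates areas, assigns peptide
#' identifications to frames by nearest m/z (within half the frame m/z
#' width), tests every frame and rolls results up to proteins.
#'
#' @param features Feature data.frame (`run_id`, `condition`, `mz`,
#'   `rt`, `intensity`).
#' @param ids data.frame mapping `mz` to `peptide` and `protein_refs`
#'   (one row per identified peptide ion).
#' @param align Align retention times first (default TRUE).
#' @param ... Passed on to [detect_frames()].
#' @inheritParams protein_rollup
#' @return list with `maps`, `frames`, `areas`, `frame_results`,
#'   `proteins`, `excluded`.
#' @export
dms_workflow <- function(features, ids, align = TRUE, min_peptides = 2,
                         p_max = 0.05, fold_threshold = 2, ...) {
  maps <- NULL
  if (align && length(unique(features$run_id)) >= 2) {
    maps <- align_retention_times(features)
    features <- apply_alignment(features, maps)
  }
  detected <- detect_frames(features, ...)
  runs <- sort(unique(features$run_id))
  areas <- integrate_areas(detected, runs)
  conditions <- features$condition[match(runs, features$run_id)]
  frame_results <- test_frames(areas, conditions)
  mzw <- list(...)$mz_width
  if (is.null(mzw)) mzw <- 0.02
  near <- vapply(detected$frames$mz_center, function(m) {
    d <- abs(ids$mz - m)
    j <- which.min(d)
    if (length(j) == 1L && d[j] <= mzw / 2) j else NA_integer_
  }, integer(1))
  frame_ids <- data.frame(frame_id = detected$frames$frame_id,
                          peptide = ids$peptide[near],
                          protein_refs = ids$protein_refs[near],
                          stringsAsFactors = FALSE)
  frame_ids <- frame_ids[!is.na(frame_ids$peptide), , drop = FALSE]
  rolled <- protein_rollup(frame_results, frame_ids,
                           min_peptides = min_peptides, p_max = p_max,
                           fold_threshold = fold_threshold)
  list(maps = maps, frames = detected$frames, areas = areas,
       frame_results = frame_results, proteins = rolled$proteins,
       excluded = rolled$excluded)
}
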