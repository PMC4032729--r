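## Cohort statistics and the selection of the optimal tolerance ST(x):
## leaves are grouped by observed length over a uniform partition; per-group
## mean errors, cohort means and pooled standard deviations define bands of
## acceptable deviation; the proportions of leaves in consistent groups give
## the selection index IS_x = beta_a / lambda_a, minimized over the sweep.

#' Build a uniform partition of the leaf-length range
#'
#' Splits \code{[0, lmax]} into \code{n} half-open intervals
#' \code{I_k = [q(k-1), qk)} of width \code{q = lmax/n}; the final interval
#' is closed at \code{lmax}.
#'
#' @param lmax maximum leaf length (mm), > 0.
#' @param n number of intervals, >= 1.
#' @return a \linkS4class{LengthPartition}.
#' @examples
#' buildPartition(460, 46)  # q = 10 mm, the grouping used for field cohorts
#' @export
buildPartition <- function(lmax, n) {
  if (length(lmax) != 1L || is.na(lmax) || lmax <= 0) stop("lmax must be > 0")
  if (length(n) != 1L || is.na(n) || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  new("LengthPartition", lmax = as.numeric(lmax), n = n, q = lmax / n)
}

#' @describeIn buildPartition the intervals as a data.frame (k, lower, upper)
#' @param partition a \linkS4class{LengthPartition}
#' @export
partitionIntervals <- function(partition) {
  k <- seq_len(partition@n)
  data.frame(k = k, lower = partition@q * (k - 1), upper = partition@q * k)
}

#' @describeIn buildPartition group index for a vector of lengths (NA outside
#'   the partition range)
#' @param l numeric vector of lengths (mm)
#' @export
partitionIndex <- function(partition, l) {
  k <- floor(l / partition@q) + 1L
  k[l == partition@lmax] <- partition@n   # closed top edge
  k[l < 0 | l > partition@lmax] <- NA_integer_
  as.integer(k)
}

#' Assign leaves to length groups
#'
#' Each leaf joins the group \code{G_k} whose interval contains its observed
#' length \code{l_o}.  Groups holding fewer than two leaves provide no
#' information for the deviation statistics and are flagged excluded; the
#' statistics run over the collection \code{C_G} of included groups only.
#' Leaves outside \code{[0, lmax]} are reported as an error, never silently
#' dropped.
#'
#' @param leaves data.frame with at least \code{leaf_id} and \code{l_o} (mm).
#' @param partition a \linkS4class{LengthPartition}.
#' @return a \linkS4class{LeafGrouping}.
#' @export
assignGroups <- function(leaves, partition) {
  stopifnot(is.data.frame(leaves), is(partition, "LengthPartition"))
  if (!all(c("leaf_id", "l_o") %in% names(leaves)))
    stop("leaves must have columns leaf_id and l_o")
  k <- partitionIndex(partition, leaves$l_o)
  if (anyNA(k))
    stop("leaves outside [0, lmax]: ",
         paste(leaves$leaf_id[is.na(k)], collapse = ", "))
  leaves$k <- k
  n_k <- tabulate(k, nbins = partition@n)
  groups <- data.frame(k = seq_len(partition@n), n_k = n_k,
                       included = n_k >= 2L)
  new("LeafGrouping", leaves = leaves, groups = groups, partition = partition)
}

#' @describeIn assignGroups the per-group table (k, n_k, included)
#' @param grouping a \linkS4class{LeafGrouping}
#' @export
groupTable <- function(grouping) grouping@groups

#' @describeIn assignGroups the annotated leaf table
#' @export
groupedLeaves <- function(grouping) grouping@leaves

#' Per-leaf approximation errors
#'
#' Observed minus image-derived values: \code{e_l = l_o - l_d},
#' \code{e_h = h_o - h_d}, \code{e_a = a_o - a_d}, \code{e_mc = a_o - a_mc},
#' with \code{a_o = l_o * h_o}.  Positive errors mean the image
#' underestimates.
#'
#' @param df data.frame with columns \code{l_o, h_o, l_d, h_d, a_d, a_mc}.
#' @return \code{df} with added columns \code{a_o, e_l, e_h, e_a, e_mc}.
#' @export
leafErrors <- function(df) {
  need <- c("l_o", "h_o", "l_d", "h_d", "a_d", "a_mc")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing measurement columns: ", paste(miss, collapse = ", "))
  df$a_o <- df$l_o * df$h_o
  df$e_l <- df$l_o - df$l_d
  df$e_h <- df$h_o - df$h_d
  df$e_a <- df$a_o - df$a_d
  df$e_mc <- df$a_o - df$a_mc
  df
}

#' Per-group mean deviations
#'
#' Arithmetic means of the per-leaf errors within each group:
#' \code{delta_l^k, delta_h^k, delta_a^k}.  Defined only for included groups
#' (two or more leaves).
#'
#' @param df data.frame of leaves from included groups, with columns
#'   \code{k, e_l, e_h, e_a}.
#' @return data.frame with one row per group: \code{k, n_k, delta_l,
#'   delta_h, delta_a}.
#' @export
groupDeviations <- function(df) {
  stopifnot(all(c("k", "e_l", "e_h", "e_a") %in% names(df)))
  n_k <- tapply(df$e_l, df$k, length)
  if (any(n_k < 2L))
    stop("group(s) with fewer than 2 leaves are excluded from the statistics: k = ",
         paste(names(n_k)[n_k < 2L], collapse = ", "))
  out <- data.frame(
    k = as.integer(names(n_k)),
    n_k = as.integer(n_k),
    delta_l = as.numeric(tapply(df$e_l, df$k, mean)),
    delta_h = as.numeric(tapply(df$e_h, df$k, mean)),
    delta_a = as.numeric(tapply(df$e_a, df$k, mean)))
  rownames(out) <- NULL
  out
}

#' Cohort-level deviations
#'
#' The cohort means \code{delta_l_bar, delta_h_bar} are the unweighted means
#' over the included groups of the per-group deviations.  The spreads
#' \code{sigma_dl, sigma_dh} are pooled within-group standard deviations of
#' the per-leaf errors about their group mean, with denominator
#' \code{sum(n_k - 1)}; pooling uses every leaf and reduces to the per-group
#' formula when a single group is included.
#'
#' @inheritParams groupDeviations
#' @return list with \code{delta_l_bar, delta_h_bar, sigma_dl, sigma_dh}.
#' @export
cohortDeviations <- function(df) {
  gd <- groupDeviations(df)
  mrg <- merge(df, gd[, c("k", "delta_l", "delta_h")], by = "k",
               suffixes = c("", ".grp"))
  denom <- sum(gd$n_k - 1L)
  if (denom <= 0) stop("no degrees of freedom for pooled deviations")
  list(delta_l_bar = mean(gd$delta_l),
       delta_h_bar = mean(gd$delta_h),
       sigma_dl = sqrt(sum((mrg$e_l - mrg$delta_l)^2) / denom),
       sigma_dh = sqrt(sum((mrg$e_h - mrg$delta_h)^2) / denom))
}

#' Cohort proportions entering the selection index
#'
#' A group passes the length band when its mean deviation lies within one
#' pooled standard deviation of the cohort mean,
#' \code{delta_l_bar - sigma_dl <= delta_l^k <= delta_l_bar + sigma_dl};
#' analogously for width.  Proportions are leaf-weighted: \code{lambda_l} is
#' the fraction of leaves (of the \code{N} in included groups) whose group
#' passes the length band, \code{theta_l = 1 - lambda_l}; \code{lambda_a} is
#' the fraction whose group passes both bands and whose own area error
#' \code{e_a >= 0} (no overestimation), \code{beta_a = 1 - lambda_a}; the
#' Monte Carlo pair uses \code{e_mc} in place of \code{e_a}.
#'
#' @param df data.frame of leaves from included groups with columns
#'   \code{k, e_l, e_h, e_a, e_mc}.
#' @return list of \code{lambda_l, theta_l, lambda_h, theta_h, lambda_a,
#'   beta_a, lambda_amc, beta_amc}.
#' @export
cohortProportions <- function(df) {
  gd <- groupDeviations(df)
  cd <- cohortDeviations(df)
  passL <- gd$delta_l >= cd$delta_l_bar - cd$sigma_dl &
           gd$delta_l <= cd$delta_l_bar + cd$sigma_dl
  passH <- gd$delta_h >= cd$delta_h_bar - cd$sigma_dh &
           gd$delta_h <= cd$delta_h_bar + cd$sigma_dh
  N <- sum(gd$n_k)
  lambda_l <- sum(gd$n_k[passL]) / N
  lambda_h <- sum(gd$n_k[passH]) / N
  passBoth <- gd$k[passL & passH]
  inBoth <- df$k %in% passBoth
  lambda_a <- sum(inBoth & df$e_a >= 0) / N
  lambda_amc <- sum(inBoth & df$e_mc >= 0) / N
  list(lambda_l = lambda_l, theta_l = 1 - lambda_l,
       lambda_h = lambda_h, theta_h = 1 - lambda_h,
       lambda_a = lambda_a, beta_a = 1 - lambda_a,
       lambda_amc = lambda_amc, beta_amc = 1 - lambda_amc)
}

#' Selection index IS_x
#'
#' \code{IS_x = beta_a / lambda_a}: the odds of area overestimation against
#' consistent estimation at a tolerance ST(x).  Smaller is better; the
#' tolerance minimizing IS_x is selected.  Undefined when \code{lambda_a}
#' is zero (no leaf consistently estimated): such tolerances are
#' inadmissible.
#'
#' @param lambda_a,beta_a proportions in \code{[0, 1]}.
#' @return nonnegative numeric.
#' @examples
#' truncate4(selectionIndex(0.7005, 0.2995))  # 0.4275
#' @export
selectionIndex <- function(lambda_a, beta_a) {
  if (any(lambda_a < 0) || any(beta_a < 0) || any(lambda_a > 1) || any(beta_a > 1))
    stop("proportions must lie in [0, 1]")
  if (any(lambda_a == 0))
    stop("lambda_a is zero: selection index undefined, tolerance inadmissible")
  beta_a / lambda_a
}

#' @rdname selectionIndex
#' @param lambda_amc,beta_amc Monte Carlo area proportions.
#' @export
selectionIndexMC <- function(lambda_amc, beta_amc)
  selectionIndex(lambda_amc, beta_amc)

#' Truncate to four decimal places
#'
#' Truncation (not rounding) toward zero, the convention used when quoting
#' selection-index values.
#'
#' @param v numeric vector.
#' @return numeric vector truncated to 4 decimals.
#' @export
truncate4 <- function(v) trunc(v * 1e4) / 1e4

#' Root-mean-square deviation
#'
#' \code{sqrt(mean((obs - est)^2))} between paired observed and estimated
#' values.
#'
#' @param observed,estimated equal-length nonempty numeric vectors.
#' @return nonnegative numeric.
#' @export
rmsd <- function(observed, estimated) {
  if (length(observed) == 0L || length(observed) != length(estimated))
    stop("observed and estimated must be nonempty and of equal length")
  sqrt(mean((observed - estimated)^2))
}

## One cohort-statistics row for a single tolerance.  `df` holds the leaves
## of the included groups with their errors at this tolerance.
.cohortRow <- function(df, x, n_flooded) {
  cd <- cohortDeviations(df)
  pp <- cohortProportions(df)
  IS <- if (pp$lambda_a > 0) pp$beta_a / pp$lambda_a else NA_real_
  IS_mc <- if (pp$lambda_amc > 0) pp$beta_amc / pp$lambda_amc else NA_real_
  data.frame(x = x,
             delta_h = cd$delta_h_bar, sigma_dh = cd$sigma_dh,
             delta_l = cd$delta_l_bar, sigma_dl = cd$sigma_dl,
             theta_l = pp$theta_l, theta_h = pp$theta_h,
             lambda_l = pp$lambda_l, lambda_h = pp$lambda_h,
             lambda_a = pp$lambda_a, beta_a = pp$beta_a, IS = IS,
             lambda_amc = pp$lambda_amc, beta_amc = pp$beta_amc,
             IS_mc = IS_mc,
             n_leaves = nrow(df), n_flooded = n_flooded,
             admissible = pp$lambda_a > 0)
}

#' Sweep tolerances over a leaf cohort
#'
#' Runs the two-stage procedure: for every tolerance \code{x} each leaf
#' image is segmented from its seed, measured (\code{l_d, h_d, a_d, a_mc}),
#' and the cohort statistics and selection indices are computed over the
#' length groups.  Regions that flood to the full image frame are recorded
#' per leaf, not fatal.
#'
#' @param manifest data.frame with columns \code{leaf_id, image_path,
#'   seed_x, seed_y, l_o, h_o, unp} (\code{image_path} may be omitted when
#'   \code{images} is supplied).
#' @param xValues integer vector of tolerances to sweep.
#' @param q partition interval width in mm (default 10, the grouping used in
#'   field practice); ignored when \code{partition} is given.
#' @param partition optional \linkS4class{LengthPartition}; by default one is
#'   built with width \code{q} covering \code{max(l_o)}.
#' @param UPN Monte Carlo points per mm; defaults to each image's scale.
#' @param sampler,mcSeed passed to \code{\link{monteCarloArea}}.
#' @param mode width mode passed to \code{\link{pixelExtents}}.
#' @param images optional named list of \linkS4class{LeafImage} keyed by
#'   \code{leaf_id}, bypassing file I/O.
#' @param verbose print per-leaf progress.
#' @return a \linkS4class{ToleranceSweep}.
#' @export
sweepCohort <- function(manifest, xValues, q = 10, partition = NULL,
                        UPN = NULL, sampler = "grid", mcSeed = NULL,
                        mode = "midpoint", images = NULL, verbose = FALSE) {
  stopifnot(is.data.frame(manifest), nrow(manifest) >= 1L)
  need <- c("leaf_id", "seed_x", "seed_y", "l_o", "h_o")
  miss <- setdiff(need, names(manifest))
  if (length(miss)) stop("manifest missing columns: ", paste(miss, collapse = ", "))
  if (is.null(partition)) {
    lmax <- q * ceiling(max(manifest$l_o) / q)
    partition <- buildPartition(lmax, as.integer(round(lmax / q)))
  }
  grouping <- assignGroups(manifest, partition)

  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    rec <- manifest[i, ]
    img <- if (!is.null(images)) images[[as.character(rec$leaf_id)]]
           else loadLeafImage(rec$image_path, unp = rec$unp)
    if (is.null(img)) stop("no image for leaf ", rec$leaf_id)
    upn_i <- if (is.null(UPN)) imageScale(img) else UPN
    per_x <- lapply(xValues, function(x)
      measureLeaf(img, x = x, seed = c(rec$seed_x, rec$seed_y), UPN = upn_i,
                  sampler = sampler, mcSeed = mcSeed, mode = mode))
    m <- do.call(rbind, per_x)
    m$leaf_id <- rec$leaf_id
    m$l_o <- rec$l_o
    m$h_o <- rec$h_o
    rows[[i]] <- m
    if (verbose)
      message(sprintf("leaf %s: %d tolerances, %d flooded",
                      rec$leaf_id, length(xValues), sum(m$flooded)))
  }
  meas <- leafErrors(do.call(rbind, rows))
  meas <- merge(meas, grouping@leaves[, c("leaf_id", "k")], by = "leaf_id")
  included_k <- grouping@groups$k[grouping@groups$included]
  if (length(included_k) == 0L)
    stop("every length group holds fewer than 2 leaves; no statistics possible")
  stats <- do.call(rbind, lapply(xValues, function(x) {
    dfx <- meas[meas$x == x & meas$k %in% included_k, ]
    .cohortRow(dfx, x, n_flooded = sum(dfx$flooded))
  }))
  rownames(stats) <- NULL
  new("ToleranceSweep", measurements = meas, stats = stats,
      partition = partition)
}

#' @describeIn sweepCohort per-x cohort statistics table
#' @param sweep a \linkS4class{ToleranceSweep}
#' @export
sweepStats <- function(sweep) sweep@stats

#' @describeIn sweepCohort per-leaf, per-x measurements with errors
#' @export
sweepMeasurements <- function(sweep) sweep@measurements

#' Choose the optimal tolerance ST(x)
#'
#' Returns the admissible tolerance minimizing the selection index IS_x;
#' ties are broken toward the smallest \code{x}, since a smaller tolerance
#' admits less noise.
#'
#' @param sweep a \linkS4class{ToleranceSweep} or its stats data.frame.
#' @return list with \code{x_star}, \code{IS}, \code{IS_mc}.
#' @export
selectOptimalST <- function(sweep) {
  stats <- if (is(sweep, "ToleranceSweep")) sweep@stats else sweep
  ok <- stats[stats$admissible & is.finite(stats$IS), , drop = FALSE]
  if (nrow(ok) == 0L) stop("no admissible tolerance: lambda_a = 0 everywhere")
  best <- ok[order(ok$IS, ok$x), , drop = FALSE][1L, ]
  list(x_star = best$x, IS = best$IS, IS_mc = best$IS_mc)
}

#' RMSD validation table
#'
#' Root-mean-square deviations of observed versus image-derived width,
#' length, rectangle-proxy area and Monte Carlo area, per tolerance, over
#' the leaves of the included groups.
#'
#' @param sweep a \linkS4class{ToleranceSweep}.
#' @param xValues tolerances to tabulate (default: all in the sweep).
#' @return data.frame with columns \code{x, rmsd_h, rmsd_l, rmsd_a, rmsd_amc}.
#' @export
rmsdTable <- function(sweep, xValues = NULL) {
  meas <- sweep@measurements
  if (is.null(xValues)) xValues <- sort(unique(meas$x))
  occupancy <- table(meas$k[!duplicated(meas$leaf_id)])
  included_k <- as.integer(names(occupancy)[occupancy >= 2L])
  out <- do.call(rbind, lapply(xValues, function(x) {
    d <- meas[meas$x == x & meas$k %in% included_k, ]
    data.frame(x = x,
               rmsd_h = rmsd(d$h_o, d$h_d),
               rmsd_l = rmsd(d$l_o, d$l_d),
               rmsd_a = rmsd(d$a_o, d$a_d),
               rmsd_amc = rmsd(d$a_o, d$a_mc))
  }))
  rownames(out) <- NULL
  out
}
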