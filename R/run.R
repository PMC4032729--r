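## High-level entry points tying the modules into the two-stage procedure:
## per-leaf measurement, and the cohort sweep + tolerance selection with its
## CSV/JSON outputs.  The script in inst/scripts/leafmetric.R exposes these
## from the shell.

#' Measure one leaf image file at a tolerance ST(x)
#'
#' @param imagePath path to a PNG/TIFF leaf image.
#' @param x tolerance upper bound.
#' @param unp image scale, pixels per mm.
#' @param seedX,seedY seed pixel (1-based; defaults to the image center).
#' @param UPN Monte Carlo points per mm (defaults to \code{unp}).
#' @param sampler,mcSeed passed to \code{\link{monteCarloArea}}.
#' @param cmax color levels per channel.
#' @return one-row data.frame as from \code{\link{measureLeaf}}.
#' @export
runMeasure <- function(imagePath, x, unp, seedX = NULL, seedY = NULL,
                       UPN = unp, sampler = "grid", mcSeed = NULL,
                       cmax = 256L) {
  img <- loadLeafImage(imagePath, unp = unp, cmax = cmax)
  seed <- if (is.null(seedX) || is.null(seedY)) NULL else c(seedX, seedY)
  measureLeaf(img, x = x, seed = seed, UPN = UPN, sampler = sampler,
              mcSeed = mcSeed)
}

#' Run the tolerance sweep and selection over a manifest
#'
#' Reads a leaf manifest CSV (\code{leaf_id, image_path, seed_x, seed_y,
#' l_o, h_o, unp}), sweeps the requested tolerances, and writes the per-x
#' cohort statistics CSV, the RMSD validation CSV, and a JSON selection
#' report naming the optimal tolerance and both selection indices.
#' Floating-point columns are written at full precision; a 4-decimal
#' truncated view of the indices is included in the report.
#'
#' @param manifest a data.frame or path to a manifest CSV.
#' @param outDir output directory (created if needed); NULL to skip writing.
#' @param xValues tolerances to sweep.
#' @param ... passed to \code{\link{sweepCohort}} (q, UPN, sampler, mcSeed,
#'   mode, images, ...).
#' @return invisible list: \code{sweep} (\linkS4class{ToleranceSweep}),
#'   \code{selection}, \code{rmsd}.
#' @export
runSweepSelect <- function(manifest, outDir = NULL,
                           xValues = seq(16L, 160L, by = 16L), ...) {
  if (is.character(manifest)) manifest <- read.csv(manifest)
  if (nrow(manifest) == 0L) stop("empty manifest")
  sweep <- sweepCohort(manifest, xValues = xValues, ...)
  sel <- selectOptimalST(sweep)
  rms <- rmsdTable(sweep)
  report <- list(
    x_star = sel$x_star,
    IS = sel$IS, IS_mc = sel$IS_mc,
    IS_trunc4 = truncate4(sel$IS), IS_mc_trunc4 = truncate4(sel$IS_mc),
    n_leaves = nrow(manifest),
    sigma_method = "pooled within-group SD, denominator sum(n_k - 1)",
    inadmissible_x = sweep@stats$x[!sweep@stats$admissible],
    flooded_by_x = stats::setNames(as.list(sweep@stats$n_flooded),
                                   sweep@stats$x))
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    write.csv(sweepStats(sweep), file.path(outDir, "cohort_stats.csv"),
              row.names = FALSE)
    write.csv(rms, file.path(outDir, "rmsd.csv"), row.names = FALSE)
    jsonlite::write_json(report, file.path(outDir, "selection_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(sweep = sweep, selection = sel, rmsd = rms,
                 report = report))
}
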