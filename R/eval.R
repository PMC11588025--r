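# Evaluation statistics against DMS assays: per-assay Spearman rank
# correlations, grouped aggregates with 95% confidence intervals
# (mean +/- 1.96 standard errors), phenotype-balanced averaging,
# one-tailed paired t-tests between predictors, and mutation-depth
# stratification.

#' AssayResult: evaluation of one landscape against one assay
#'
#' @slot assayId assay identifier
#' @slot proteinId protein identifier
#' @slot phenotype,taxon metadata carried over from the assay
#' @slot nVariants number of scoreable entries used
#' @slot nDropped entries dropped because their variant hit an
#'   undefined landscape cell
#' @slot rho Spearman correlation between predicted and measured scores
#' @slot depthBreakdown data.frame (depth, n, rho); rho is NA for
#'   strata with fewer than 2 entries or constant vectors
#' @aliases AssayResult-class
#' @export
setClass("AssayResult",
  representation(assayId = "character", proteinId = "character",
                 phenotype = "character", taxon = "character",
                 nVariants = "integer", nDropped = "integer",
                 rho = "numeric", depthBreakdown = "data.frame"))

setMethod("show", "AssayResult", function(object) {
  cat(sprintf("AssayResult %s [%s]: rho = %.4f over %d variants (%d dropped)\n",
              object@assayId, object@phenotype, object@rho,
              object@nVariants, object@nDropped))
})

#' Spearman rank correlation
#'
#' Pearson correlation of fractional (tie-averaged) ranks. Errors on
#' length mismatch, fewer than two observations, or a constant vector
#' (whose rank correlation is undefined).
#'
#' @param x,y numeric vectors of equal length >= 2
#' @return Numeric scalar in [-1, 1].
#' @examples
#' spearmanRho(1:3, c(10, 20, 30))  # 1
#' spearmanRho(1:3, c(1, 3, 2))     # 0.5
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y))
    stopf("vectors differ in length (%d vs %d)", length(x), length(y))
  if (length(x) < 2L) stopf("need at least 2 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("Spearman correlation undefined for a constant vector")
  stats::cor(x, y, method = "spearman")
}

#' Evaluate a landscape against a DMS assay
#'
#' Scores every assay variant additively on the landscape via
#' [scoreMulti()]; entries whose variant touches an undefined cell are
#' dropped and counted, not imputed. Reports the pooled Spearman rho
#' plus a per-mutation-depth breakdown. Note the sign convention: raw
#' and teacher landscapes are more negative for more deleterious
#' variants, so an assay where fitness decreases with damage correlates
#' positively, and a normalized landscape (1 = high impact) flips the
#' sign.
#'
#' @param ls a [Landscape-class]
#' @param assay a [DMSAssay-class] on the same protein
#' @return An [AssayResult-class].
#' @export
evaluateAssay <- function(ls, assay) {
  stopifnot(is(ls, "Landscape"), is(assay, "DMSAssay"))
  pred <- vapply(assay@variants, function(v)
    tryCatch(scoreMulti(ls, v), error = function(e) NA_real_),
    numeric(1))
  ok <- !is.na(pred)
  if (sum(ok) < 2L)
    stopf("assay %s: fewer than 2 scoreable entries", assay@assayId)
  meas <- assay@measured[ok]
  predOk <- pred[ok]
  rho <- spearmanRho(predOk, meas)
  depths <- vapply(assay@variants, depth, 1L)[ok]
  bd <- do.call(rbind, lapply(sort(unique(depths)), function(dd) {
    sel <- depths == dd
    r <- if (sum(sel) >= 2L && stats::sd(predOk[sel]) > 0 &&
             stats::sd(meas[sel]) > 0)
      spearmanRho(predOk[sel], meas[sel]) else NA_real_
    data.frame(depth = dd, n = sum(sel), rho = r)
  }))
  new("AssayResult", assayId = assay@assayId, proteinId = assay@proteinId,
      phenotype = assay@phenotype, taxon = assay@taxon,
      nVariants = as.integer(sum(ok)), nDropped = as.integer(sum(!ok)),
      rho = rho, depthBreakdown = bd)
}

#' Collect assay results into a data.frame
#' @param results list of [AssayResult-class]
#' @return data.frame with one row per assay.
#' @export
resultsTable <- function(results) {
  do.call(rbind, lapply(results, function(r)
    data.frame(assay_id = r@assayId, protein_id = r@proteinId,
               phenotype = r@phenotype, taxon = r@taxon,
               n_variants = r@nVariants, n_dropped = r@nDropped,
               rho = r@rho)))
}

#' Aggregate per-assay correlations with 95% confidence intervals
#'
#' Unweighted mean of per-assay rho values per group, with a
#' `1.96 * SE` half-width where SE uses the sample (n-1) standard
#' deviation; groups of size 1 report the mean with an NA half-width.
#'
#' @param results list of [AssayResult-class]
#' @param groupBy "none" (overall), "phenotype" or "taxon"
#' @return data.frame with columns group, mean_rho, ci_halfwidth, n.
#' @examples
#' # two assays with rho 0.4 and 0.6 -> mean 0.5, half-width 0.196
#' @export
aggregateResults <- function(results,
                             groupBy = c("none", "phenotype", "taxon")) {
  groupBy <- match.arg(groupBy)
  if (!length(results)) stopf("no assay results to aggregate")
  rhos <- vapply(results, function(r) r@rho, 1)
  grp <- switch(groupBy,
    none = rep("overall", length(results)),
    phenotype = vapply(results, function(r) r@phenotype, ""),
    taxon = vapply(results, function(r) r@taxon, ""))
  out <- lapply(split(rhos, grp), function(v) {
    hw <- if (length(v) >= 2L) 1.96 * stats::sd(v) / sqrt(length(v))
          else NA_real_
    data.frame(mean_rho = mean(v), ci_halfwidth = hw, n = length(v))
  })
  df <- do.call(rbind, out)
  data.frame(group = names(out), df, row.names = NULL)
}

#' Phenotype-balanced mean correlation
#'
#' Mean of the per-phenotype mean rho values, so each phenotype class
#' counts once regardless of how many assays it contributes.
#'
#' @param results list of [AssayResult-class]; all must carry a
#'   phenotype label
#' @return Numeric scalar.
#' @export
balancedPhenotypeMean <- function(results) {
  if (!length(results)) stopf("no assay results")
  ph <- vapply(results, function(r) r@phenotype, "")
  if (any(!nzchar(ph) | is.na(ph))) stopf("missing phenotype labels")
  rhos <- vapply(results, function(r) r@rho, 1)
  mean(vapply(split(rhos, ph), mean, 1))
}

#' One-tailed paired t-test between two predictors
#'
#' Tests whether predictor `a` outperforms predictor `b` on the same
#' assays: a paired t statistic on the per-assay rho differences with
#' the p-value from the upper tail of t(n-1). When the two predictors
#' agree exactly on every assay the statistic is 0 and p = 0.5;
#' constant non-zero differences leave the statistic undefined and are
#' an error.
#'
#' @param a,b numeric vectors of per-assay rho values, aligned by
#'   assay; names (if set) must match
#' @return List with `deltaMean`, `t`, `df` and `p`.
#' @export
pairedOneTailedT <- function(a, b) {
  if (length(a) != length(b))
    stopf("predictor vectors differ in length")
  if (length(a) < 2L) stopf("need at least 2 paired assays")
  if (!is.null(names(a)) && !is.null(names(b)) &&
      !identical(names(a), names(b)))
    stopf("assay ids of the two predictors are not aligned")
  d <- a - b
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(list(deltaMean = 0, t = 0, df = length(d) - 1L, p = 0.5))
    stopf("degenerate test: differences are constant and non-zero")
  }
  tt <- stats::t.test(a, b, paired = TRUE, alternative = "greater")
  list(deltaMean = unname(tt$estimate), t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value)
}

#' Stratify a DMS assay by mutation depth
#'
#' Partitions the entries by number of simultaneous substitutions;
#' empty strata are omitted. The strata sizes always sum to the assay
#' size.
#'
#' @param assay a [DMSAssay-class]
#' @return Named list of [DMSAssay-class], names = depth.
#' @export
stratifyByDepth <- function(assay) {
  stopifnot(is(assay, "DMSAssay"))
  depths <- vapply(assay@variants, depth, 1L)
  out <- lapply(sort(unique(depths)), function(dd) {
    sel <- depths == dd
    DMSAssay(sprintf("%s_depth%d", assay@assayId, dd), assay@proteinId,
             assay@variants[sel], assay@measured[sel],
             phenotype = assay@phenotype, taxon = assay@taxon)
  })
  names(out) <- sort(unique(depths))
  out
}
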