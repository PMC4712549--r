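# CT -> log2 expression and between-sample normalization. Because one PCR
# cycle corresponds to one doubling, log2 expression is taken as
# max_cycle - CT (direction preserving: higher value = higher abundance).

.provAppend <- function(se, tag) {
  metadata(se)$provenance <- c(metadata(se)$provenance, tag)
  se
}

#' Convert threshold cycles to log2 expression
#'
#' log2 expression = `maxCycle - ct`. Undetermined cells stay masked (`NA`);
#' they are never imputed here -- the detection rules in
#' [detectionPartition()] and [onoffLowerLimit()] own that decision.
#'
#' @param x a [CtExperiment-class]
#' @param maxCycle maximum instrument cycle; defaults to the value recorded
#'   in `x`. Must be >= every numeric CT.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"log2expr"`, row/column metadata carried over, and a provenance tag in
#'   `metadata()$provenance`.
#' @examples
#' sim <- simulateLda(nFeatures = 12, nDuplicates = 0, seed = 1)
#' x <- ctToLog2(CtExperiment(sim$ct, sim$samples))
#' @export
ctToLog2 <- function(x, maxCycle = ctMaxCycle(x)) {
  stopifnot(is(x, "CtExperiment"))
  ct <- ctValues(x)
  if (any(ct > maxCycle, na.rm = TRUE))
    stop(sprintf("ct value exceeds maxCycle = %g", maxCycle), call. = FALSE)
  se <- SummarizedExperiment(assays = list(log2expr = maxCycle - ct),
                             rowData = rowData(x), colData = colData(x))
  metadata(se) <- metadata(x)
  .provAppend(se, sprintf("ct_to_log2(max_cycle=%g)", maxCycle))
}

.assayMatrix <- function(x) {
  if (is(x, "SummarizedExperiment")) assay(x, 1L) else as.matrix(x)
}

.withAssay <- function(x, m, tag) {
  if (is(x, "SummarizedExperiment")) {
    SummarizedExperiment::assay(x, 1L) <- m
    .provAppend(x, tag)
  } else m
}

# One cyclic-loess pass over all unordered sample pairs of one matrix.
# Corrections from all pairs are computed on the same input and applied
# together, which makes the pass equivariant under sample permutation and
# keeps the grand mean fixed on complete data. Returns the corrected matrix
# and the largest absolute fitted trend seen in the pass.
.cyclicLoessPass <- function(m, span, degree, minCommon, pairLabel) {
  ns <- ncol(m)
  corr <- matrix(0, nrow(m), ns)
  maxfit <- 0
  for (i in seq_len(ns - 1L)) for (j in seq.int(i + 1L, ns)) {
    xi <- m[, i]; xj <- m[, j]
    common <- which(is.finite(xi) & is.finite(xj))
    if (length(common) < minCommon)
      stop(sprintf(
        "cyclicLoess: only %d commonly detected features for pair (%s, %s); minimum is %d",
        length(common), pairLabel[i], pairLabel[j], minCommon), call. = FALSE)
    M <- xi[common] - xj[common]
    A <- (xi[common] + xj[common]) / 2
    if (diff(range(M)) < 1e-10) {
      # constant difference: the trend is the constant itself (a flat or
      # converged pair); robust fitting would divide by a zero residual scale
      fitted <- rep(mean(M), length(M))
    } else {
      # robust (symmetric) fitting keeps genuinely differential features
      # from dragging the trend estimate
      fit <- stats::loess(M ~ A, span = span, degree = degree,
                          family = "symmetric",
                          control = stats::loess.control(surface = "direct"))
      fitted <- stats::fitted(fit)
    }
    maxfit <- max(maxfit, max(abs(fitted)))
    # masked features still receive their sample's correction: evaluate the
    # trend at the feature's available abundance, clamped to the fitted range
    ord <- order(A)
    predAt <- function(a) stats::approx(A[ord], fitted[ord], xout = a,
                                        rule = 2, ties = mean)$y
    fi <- which(is.finite(xi))
    fj <- which(is.finite(xj))
    ai <- ifelse(is.finite(xj[fi]), (xi[fi] + xj[fi]) / 2, xi[fi])
    aj <- ifelse(is.finite(xi[fj]), (xi[fj] + xj[fj]) / 2, xj[fj])
    corr[fi, i] <- corr[fi, i] - predAt(ai) / 2
    corr[fj, j] <- corr[fj, j] + predAt(aj) / 2
  }
  list(m = m + corr, maxfit = maxfit)
}

#' Cyclic LOESS normalization, separately per plate
#'
#' Removes intensity-dependent (MA-type) trends between samples by the
#' pairwise cyclic scheme: within each plate and for every unordered sample
#' pair, the difference `M = x_i - x_j` is smoothed against the average
#' `A = (x_i + x_j)/2` over commonly detected features, and half the fitted
#' trend is subtracted from sample *i* and added to sample *j*. Passes repeat
#' until the largest absolute fitted trend across pairs drops below `tol` or
#' `maxIter` passes have run. Masked (undetermined) features are excluded
#' from fitting but still receive their sample's correction, so features
#' detected in only some samples stay normalizable.
#'
#' @param x a `SummarizedExperiment` with a log2 expression assay (as from
#'   [ctToLog2()]) or a plain numeric matrix
#' @param plateOf plate per feature; defaults to `rowData(x)$plate` when
#'   available, else all features are treated as one plate
#' @param span loess span (default 0.7; the small sample counts of array-card
#'   designs make aggressive smoothing unstable)
#' @param degree loess degree (default 1)
#' @param maxIter maximum number of passes (default 3)
#' @param tol convergence tolerance on the largest absolute fitted trend, in
#'   log2 units (default 1e-3)
#' @param minCommon minimum number of commonly detected features required to
#'   fit a pair (default 10)
#' @return object of the same kind as `x`, normalized; for
#'   `SummarizedExperiment` input a provenance tag is appended.
#' @export
cyclicLoess <- function(x, plateOf = NULL, span = 0.7, degree = 1,
                        maxIter = 3, tol = 1e-3, minCommon = 10) {
  stopifnot(span > 0, span <= 1, maxIter >= 1, tol > 0)
  m <- .assayMatrix(x)
  if (ncol(m) < 2L)
    stop("cyclicLoess requires at least 2 samples", call. = FALSE)
  if (is.null(plateOf)) {
    plateOf <- if (is(x, "SummarizedExperiment") &&
                   "plate" %in% colnames(rowData(x)))
      as.character(rowData(x)$plate) else rep("A", nrow(m))
  }
  stopifnot(length(plateOf) == nrow(m))
  lab <- colnames(m)
  if (is.null(lab)) lab <- as.character(seq_len(ncol(m)))
  for (pl in unique(plateOf)) {
    rows <- which(plateOf == pl)
    sub <- m[rows, , drop = FALSE]
    for (it in seq_len(maxIter)) {
      res <- .cyclicLoessPass(sub, span, degree, minCommon, lab)
      sub <- res$m
      if (res$maxfit < tol) break
    }
    m[rows, ] <- sub
  }
  .withAssay(x, m, sprintf(
    "cyclic_loess(span=%g, degree=%d, max_iter=%d, tol=%g, per_plate)",
    span, degree, maxIter, tol))
}

#' Quantile normalization between arrays
#'
#' Each sample's sorted values are replaced by the across-sample mean of
#' order statistics; ranks within each sample are preserved. Tied values
#' receive the mean of the order-statistic replacements they span, which
#' makes the operation deterministic and idempotent.
#'
#' @param x a complete (no masked cells) `SummarizedExperiment` or numeric
#'   matrix with at least 2 samples
#' @return object of the same kind as `x`, quantile-normalized
#' @export
quantileNormalize <- function(x) {
  m <- .assayMatrix(x)
  if (ncol(m) < 2L)
    stop("quantileNormalize requires at least 2 samples", call. = FALSE)
  if (anyNA(m))
    stop("quantileNormalize: masked cells present; filter undetected ",
         "features upstream", call. = FALSE)
  meanstat <- rowMeans(apply(m, 2L, sort))
  out <- m
  n <- nrow(m)
  for (j in seq_len(ncol(m))) {
    pos <- integer(n)
    pos[order(m[, j])] <- seq_len(n)
    repl <- meanstat[pos]
    out[, j] <- stats::ave(repl, factor(m[, j]), FUN = mean)
  }
  .withAssay(x, out, "quantile_normalize")
}
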