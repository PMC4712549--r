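# Single-assay RT-qPCR quantification (delta-delta-CT with one or more
# reference genes), reference-gene stability ranking, and cross-platform
# validation by Spearman rank correlation.

#' Relative quantification by the delta-delta-CT method
#'
#' Per sample, \eqn{\Delta CT = CT_{target} - \overline{CT}_{refs}}
#' (arithmetic mean over the reference genes, i.e. the geometric mean of
#' their linear quantities); \eqn{\Delta\Delta CT} subtracts the mean
#' \eqn{\Delta CT} of the calibrator group; the fold change is
#' \eqn{2^{-\Delta\Delta CT}} and `log2fc = -ddct`. Technical-replicate CTs
#' should be averaged before calling this function. Undetermined target CTs
#' yield a record flagged not-quantifiable; a missing/undetermined reference
#' CT is an error naming the sample.
#'
#' @param qpcr long data.frame with columns `sample_id`, `assay_id`, `ct`,
#'   `role` (`"target"` or `"reference"`); exactly one target assay
#' @param samples sample sheet (`sample_id`, `group`)
#' @param calibrator calibrator group (default `"control"`)
#' @return data.frame per sample: `sample_id`, `group`, `target_id`,
#'   `delta_ct`, `ddct`, `fold_change`, `log2fc`, `quantifiable`
#' @export
ddctQuantify <- function(qpcr, samples, calibrator = "control") {
  .requireCols(qpcr, c("sample_id", "assay_id", "ct", "role"), "qPCR table")
  samples <- .validateSampleSheet(samples)
  if (!calibrator %in% samples$group)
    stop("calibrator group is empty: ", calibrator, call. = FALSE)
  if (!is.numeric(qpcr$ct)) qpcr$ct <- .parseCt(qpcr$ct)
  tgt <- qpcr[qpcr$role == "target", , drop = FALSE]
  refs <- qpcr[qpcr$role == "reference", , drop = FALSE]
  if (!nrow(tgt)) stop("no target rows in qPCR table", call. = FALSE)
  if (length(unique(tgt$assay_id)) != 1L)
    stop("expected exactly one target assay, got: ",
         paste(unique(tgt$assay_id), collapse = ", "), call. = FALSE)
  if (!nrow(refs)) stop("no reference rows in qPCR table", call. = FALSE)
  dct <- vapply(samples$sample_id, function(s) {
    r <- refs$ct[refs$sample_id == s]
    if (!length(r) || anyNA(r))
      stop("missing or undetermined reference CT for sample: ", s,
           call. = FALSE)
    t <- tgt$ct[tgt$sample_id == s]
    if (!length(t))
      stop("missing target CT for sample: ", s, call. = FALSE)
    mean(t) - mean(r)
  }, numeric(1))
  calDct <- dct[samples$group == calibrator]
  if (all(is.na(calDct)))
    stop("no quantifiable calibrator sample", call. = FALSE)
  ddct <- dct - mean(calDct, na.rm = TRUE)
  data.frame(
    sample_id = samples$sample_id,
    group = samples$group,
    target_id = tgt$assay_id[1L],
    delta_ct = unname(dct),
    ddct = unname(ddct),
    fold_change = 2^(-unname(ddct)),
    log2fc = -unname(ddct),
    quantifiable = !is.na(unname(dct)),
    stringsAsFactors = FALSE)
}

#' Rank candidate reference genes by expression stability
#'
#' Candidates are ranked ascending by total CT variance, decomposed into a
#' within-group (intra-experimental, pooled within-group mean square) and a
#' between-group (inter-experimental, between-group mean square of group
#' means) component; both components are reported. Ties are broken by
#' lexicographic assay id. Candidates with fewer than 2 observations are
#' excluded with a warning.
#'
#' @param ct long data.frame restricted to candidate reference assays
#'   (columns `assay_id`, `sample_id`, `ct`) or a [CtExperiment-class]
#' @param samples sample sheet (`sample_id`, `group`); defaults to the
#'   colData of a `CtExperiment` input
#' @return data.frame ordered by rank: `assay_id`, `intra_var`, `inter_var`,
#'   `total_var`, `n`, `rank`
#' @export
referenceStability <- function(ct, samples = NULL) {
  if (is(ct, "CtExperiment")) {
    if (is.null(samples))
      samples <- data.frame(sample_id = colnames(ct),
                            group = as.character(colData(ct)$group),
                            stringsAsFactors = FALSE)
    ct <- .ctLongFromExperiment(ct)
  }
  .requireCols(ct, c("assay_id", "sample_id", "ct"), "reference CT table")
  samples <- .validateSampleSheet(samples)
  grp <- stats::setNames(samples$group, samples$sample_id)
  res <- lapply(sort(unique(ct$assay_id)), function(a) {
    rows <- ct[ct$assay_id == a & !is.na(ct$ct), , drop = FALSE]
    if (nrow(rows) < 2L) {
      warning("reference candidate '", a,
              "' has fewer than 2 observations; excluded")
      return(NULL)
    }
    g <- factor(grp[rows$sample_id])
    means <- tapply(rows$ct, g, mean)
    ngrp <- tapply(rows$ct, g, length)
    withinSS <- sum((rows$ct - means[g])^2)
    dfW <- nrow(rows) - nlevels(g)
    intra <- if (dfW > 0) withinSS / dfW else 0
    inter <- if (nlevels(g) > 1L)
      sum(ngrp * (means - mean(rows$ct))^2) / (nlevels(g) - 1L) else 0
    data.frame(assay_id = a, intra_var = intra, inter_var = inter,
               total_var = intra + inter, n = nrow(rows),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res) || !nrow(res))
    stop("no usable reference candidates", call. = FALSE)
  if (nrow(res) == 1L)
    warning("only one usable reference candidate; ranking of length 1")
  res <- res[order(res$total_var, res$assay_id), , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

.permutationsMatrix <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutationsMatrix(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(rep.int(i, nrow(sub)),
          matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Spearman rank correlation for cross-platform validation
#'
#' Computes rho on mid-ranks (ties averaged). The two-sided p-value is exact
#' for n <= 9 -- obtained by enumerating all n! permutations of one rank
#' vector and counting |rho| at least as large as observed -- and uses the
#' t approximation with n - 2 df otherwise. The switch point is documented
#' rather than inherited from any particular software default.
#'
#' @param x,y paired per-feature values (e.g. log2 fold changes from two
#'   platforms); at least 3 complete pairs
#' @return list with `rho`, `p`, `n`, `method`
#' @export
spearmanValidate <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L)
    stop("spearmanValidate requires at least 3 complete pairs", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 9L) {
    perms <- .permutationsMatrix(n)
    rhos <- as.vector(stats::cor(rx, t(matrix(ry[perms], nrow(perms), n))))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p = min(p, 1), n = n, method = method)
}
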