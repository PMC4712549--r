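# Differential-expression calling for the knockdown screen: detection
# partitioning with a CT cutoff, empirical-Bayes moderated t, BH adjustment,
# detection-limit ("on/off") fold-change bounds, duplicate-assay concordance
# and candidate assembly; plus the replicate-probe consensus rule used for
# one-color expression arrays.

.groupIdx <- function(groups) {
  groups <- as.character(groups)
  list(kd = which(groups == "knockdown"), ctrl = which(groups == "control"))
}

#' Partition assays by detection status
#'
#' An assay is *excluded* (low expression) when in **both** groups every
#' sample is above the CT cutoff or undetermined. It is an *on/off
#' candidate* when it is undetermined in all samples of one group and
#' detected (CT at or below the cutoff) in all samples of the other; the
#' direction is `on_in_knockdown` when the control group is the silent one.
#' Everything else is *detected* and enters the moderated-t stage.
#'
#' @param x a [CtExperiment-class]
#' @param ctCutoff detection cutoff in cycles (default 34.5)
#' @return list with character vectors `detected` and `excluded`, and a
#'   data.frame `onoff` with columns `feature_id`, `direction`
#' @export
detectionPartition <- function(x, ctCutoff = 34.5) {
  stopifnot(is(x, "CtExperiment"))
  stopifnot(ctCutoff > 0, ctCutoff < ctMaxCycle(x))
  ct <- ctValues(x)
  gi <- .groupIdx(sampleGroups(x))
  above <- is.na(ct) | ct > ctCutoff
  allAboveKd <- apply(above[, gi$kd, drop = FALSE], 1L, all)
  allAboveCt <- apply(above[, gi$ctrl, drop = FALSE], 1L, all)
  allNaKd <- apply(is.na(ct[, gi$kd, drop = FALSE]), 1L, all)
  allNaCt <- apply(is.na(ct[, gi$ctrl, drop = FALSE]), 1L, all)
  allDetKd <- apply(!above[, gi$kd, drop = FALSE], 1L, all)
  allDetCt <- apply(!above[, gi$ctrl, drop = FALSE], 1L, all)
  excluded <- allAboveKd & allAboveCt
  onKd <- !excluded & allNaCt & allDetKd   # silent in control
  offKd <- !excluded & allNaKd & allDetCt  # silent in knockdown
  ids <- rownames(ct)
  onoff <- data.frame(
    feature_id = c(ids[onKd], ids[offKd]),
    direction = c(rep("on_in_knockdown", sum(onKd)),
                  rep("off_in_knockdown", sum(offKd))),
    stringsAsFactors = FALSE)
  onoff <- onoff[order(match(onoff$feature_id, ids)), , drop = FALSE]
  rownames(onoff) <- NULL
  list(detected = ids[!excluded & !onKd & !offKd],
       excluded = ids[excluded],
       onoff = onoff)
}

# Solve trigamma(x) = y by Newton iteration on the inverse scale.
.trigammaInverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

#' Empirical-Bayes moderated two-sample t-test
#'
#' Per feature, the log2 fold change is `mean(knockdown) - mean(control)`
#' and the pooled residual variance \eqn{s_g^2} has \eqn{d_g = n_1+n_2-2}
#' degrees of freedom. Hyperparameters \eqn{(d_0, s_0^2)} of the scaled
#' inverse-chi-square prior are estimated by moment matching of
#' \eqn{\log s_g^2} against a scaled F distribution (digamma/trigamma
#' inversion). The posterior variance
#' \eqn{\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)} gives
#' \eqn{t_g = \mathrm{log2fc}_g / \sqrt{\tilde s_g^2 (1/n_1 + 1/n_2)}} with
#' two-sided p from a t distribution on \eqn{d_0 + d_g} df. Features with
#' zero residual variance are floored at 1e-8 before taking logs.
#'
#' @param x `SummarizedExperiment` (first assay) or numeric matrix of log2
#'   expression, complete (no `NA`) across samples
#' @param groups per-sample group labels (`"knockdown"`/`"control"`), or a
#'   sample-sheet data.frame; defaults to `colData(x)$group`
#' @param priorDf optional forced prior degrees of freedom: `0` reduces the
#'   statistic to the classical pooled two-sample t; `Inf` with `priorVar`
#'   gives a common-variance test. When the design has zero residual df
#'   (one sample per group) this common-variance mode is the only option and
#'   both `priorDf` and `priorVar` must be supplied.
#' @param priorVar optional forced prior variance \eqn{s_0^2}
#' @return [S4Vectors::DataFrame] with columns `feature_id`, `log2fc`, `t`,
#'   `p`, `p_adj` (BH) and `df_total`; hyperparameters in
#'   `metadata()`: `prior_df`, `prior_var`, `n_per_group`.
#' @seealso [bhAdjust()], [assembleCandidates()]
#' @export
fitModeratedT <- function(x, groups = NULL, priorDf = NULL, priorVar = NULL) {
  m <- .assayMatrix(x)
  if (is.null(groups) && is(x, "SummarizedExperiment"))
    groups <- as.character(colData(x)$group)
  if (is.data.frame(groups)) {
    groups <- groups$group[match(colnames(m), groups$sample_id)]
  }
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(m))
  if (anyNA(m))
    stop("fitModeratedT: matrix contains masked cells; restrict to features ",
         "complete across samples", call. = FALSE)
  gi <- .groupIdx(groups)
  n1 <- length(gi$kd); n2 <- length(gi$ctrl)
  if (n1 < 1L || n2 < 1L)
    stop("fitModeratedT: both groups need at least one sample", call. = FALSE)
  dg <- n1 + n2 - 2L
  mk <- rowMeans(m[, gi$kd, drop = FALSE])
  mc <- rowMeans(m[, gi$ctrl, drop = FALSE])
  lfc <- mk - mc
  rss <- rowSums((m[, gi$kd, drop = FALSE] - mk)^2) +
    rowSums((m[, gi$ctrl, drop = FALSE] - mc)^2)
  if (dg == 0L) {
    if (is.null(priorDf) || is.null(priorVar))
      stop("fitModeratedT: zero residual degrees of freedom (one sample per ",
           "group); supply priorDf and priorVar explicitly to use the ",
           "common-variance mode", call. = FALSE)
    s2 <- rep(NA_real_, nrow(m))
  } else {
    s2 <- pmax(rss / dg, 1e-8)
  }
  if (is.null(priorDf)) {
    z <- log(s2)
    e <- z - digamma(dg / 2) + log(dg / 2)
    emean <- mean(e)
    evar <- stats::var(e) - trigamma(dg / 2)
    if (is.finite(evar) && evar > 0) {
      d0 <- 2 * .trigammaInverse(evar)
      s0sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s0sq <- exp(emean)
    }
  } else {
    d0 <- priorDf
    s0sq <- if (!is.null(priorVar)) priorVar
    else if (d0 > 0 && is.finite(d0))
      exp(mean(log(s2)) - digamma(dg / 2) + log(dg / 2) +
            digamma(d0 / 2) - log(d0 / 2))
    else if (is.infinite(d0))
      stop("fitModeratedT: priorDf = Inf requires priorVar", call. = FALSE)
    else NA_real_  # d0 == 0: prior never enters
  }
  if (dg == 0L && d0 <= 0)
    stop("fitModeratedT: common-variance mode needs priorDf > 0",
         call. = FALSE)
  post <- if (is.infinite(d0) || dg == 0L) rep(s0sq, nrow(m))
  else if (d0 == 0) s2
  else (d0 * s0sq + dg * s2) / (d0 + dg)
  tstat <- lfc / sqrt(post * (1 / n1 + 1 / n2))
  dfTot <- d0 + dg
  p <- 2 * stats::pt(-abs(tstat), df = dfTot)
  ids <- rownames(m)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(m)))
  res <- DataFrame(feature_id = ids, log2fc = unname(lfc),
                   t = unname(tstat), p = unname(p),
                   p_adj = bhAdjust(unname(p)),
                   df_total = rep(dfTot, nrow(m)),
                   row.names = ids)
  metadata(res) <- list(prior_df = d0, prior_var = s0sq,
                        n_per_group = c(knockdown = n1, control = n2),
                        residual_df = dg)
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; input order is preserved.
#' Delegates to [stats::p.adjust()] after validating the input.
#'
#' @param p numeric vector of p-values, all finite in \[0, 1\]
#' @return adjusted p-values, elementwise >= `p` and <= 1
#' @export
bhAdjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(!is.finite(p)) ||
      any(p < 0 | p > 1))
    stop("bhAdjust: p-values must be finite and within [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Detection-limit ("lower limit") fold change for an on/off assay
#'
#' For an assay undetermined in all samples of one group and detected in all
#' samples of the other, no ratio (and no p-value) can be computed. The
#' undetermined values are substituted by the detection cutoff -- the most
#' conservative detectable cycle -- and the group-mean difference of
#' `maxCycle - CT` is reported as a lower bound of the log2 fold change
#' (knockdown - control).
#'
#' @param x a [CtExperiment-class]
#' @param feature assay identifier (row name of `x`)
#' @param ctCutoff detection cutoff in cycles (default 34.5)
#' @return one-row data.frame: `feature_id`, `direction`,
#'   `log2fc_lower_limit`, `p` (`NA`, not calculable)
#' @export
onoffLowerLimit <- function(x, feature, ctCutoff = 34.5) {
  stopifnot(is(x, "CtExperiment"))
  ct <- ctValues(x)
  if (!feature %in% rownames(ct))
    stop("unknown feature: ", feature, call. = FALSE)
  gi <- .groupIdx(sampleGroups(x))
  kd <- ct[feature, gi$kd]; ctrl <- ct[feature, gi$ctrl]
  silentCtrl <- all(is.na(ctrl)) && !any(is.na(kd)) && all(kd <= ctCutoff)
  silentKd <- all(is.na(kd)) && !any(is.na(ctrl)) && all(ctrl <= ctCutoff)
  if (!silentCtrl && !silentKd)
    stop(sprintf("feature '%s' is not an on/off candidate", feature),
         call. = FALSE)
  kd[is.na(kd)] <- ctCutoff
  ctrl[is.na(ctrl)] <- ctCutoff
  # log2 expression difference: (max - ctKd) - (max - ctCtrl) = ctCtrl - ctKd
  limit <- mean(ctrl) - mean(kd)
  data.frame(
    feature_id = feature,
    direction = if (silentCtrl) "on_in_knockdown" else "off_in_knockdown",
    log2fc_lower_limit = limit,
    p = NA_real_,
    stringsAsFactors = FALSE)
}

#' All on/off lower-limit records of an experiment
#'
#' Convenience wrapper applying [onoffLowerLimit()] to every on/off candidate
#' found by [detectionPartition()].
#'
#' @inheritParams onoffLowerLimit
#' @return data.frame, one row per on/off candidate (possibly empty)
#' @export
onoffTable <- function(x, ctCutoff = 34.5) {
  part <- detectionPartition(x, ctCutoff)
  if (!nrow(part$onoff))
    return(data.frame(feature_id = character(), direction = character(),
                      log2fc_lower_limit = numeric(), p = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(part$onoff$feature_id, onoffLowerLimit,
                        x = x, ctCutoff = ctCutoff))
}

.signsConcordant <- function(s) {
  s <- s[s != 0]
  length(unique(s)) <= 1L
}

#' Duplicate-assay concordance filter
#'
#' Array cards measure some miRNAs in duplicate. A miRNA is removed entirely
#' when its duplicate assays disagree in the sign of the (lower-limit) log2
#' fold change; concordant duplicates are collapsed to one record (log2 fold
#' changes averaged, the smaller p retained). Singleton assays pass through
#' unchanged. A zero fold change is treated as concordant with either sign.
#'
#' @param de moderated-t results ([fitModeratedT()] output or a data.frame
#'   with `feature_id`, `log2fc`, `p`, `p_adj`)
#' @param onoff on/off records ([onoffTable()] output), may be empty or NULL
#' @param duplicateGroup named character vector mapping feature (assay) ids
#'   to duplicate-group labels (`""` = singleton), e.g.
#'   `duplicateGroups(cte)`
#' @param mirnaName optional named character vector mapping feature ids to
#'   miRNA names used for collapsed records (default: the feature id)
#' @return candidate-precursor data.frame with columns `feature_id`, `mirna`,
#'   `status` (`"tested"`/`"on_off"`), `direction`, `log2fc`, `p`, `p_adj`,
#'   `concordance_flag` (`"singleton"`, `"collapsed"`) and `note`
#' @export
duplicateConcordanceFilter <- function(de, onoff = NULL, duplicateGroup,
                                       mirnaName = NULL) {
  de <- as.data.frame(de)
  comb <- data.frame(
    feature_id = as.character(de$feature_id),
    status = rep("tested", nrow(de)),
    direction = rep(NA_character_, nrow(de)),
    log2fc = de$log2fc,
    p = de$p,
    p_adj = if ("p_adj" %in% names(de)) de$p_adj else NA_real_,
    stringsAsFactors = FALSE)
  if (!is.null(onoff) && nrow(onoff))
    comb <- rbind(comb, data.frame(
      feature_id = as.character(onoff$feature_id),
      status = "on_off",
      direction = onoff$direction,
      log2fc = onoff$log2fc_lower_limit,
      p = NA_real_,
      p_adj = NA_real_,
      stringsAsFactors = FALSE))
  if (is.null(mirnaName))
    mirnaName <- stats::setNames(comb$feature_id, comb$feature_id)
  comb$mirna <- unname(mirnaName[comb$feature_id])
  comb$mirna[is.na(comb$mirna)] <- comb$feature_id[is.na(comb$mirna)]
  dg <- duplicateGroup[comb$feature_id]
  dg[is.na(dg)] <- ""
  comb$dupgroup <- unname(dg)
  out <- list()
  for (g in unique(comb$dupgroup)) {
    rows <- comb[comb$dupgroup == g, , drop = FALSE]
    if (!nzchar(g) || nrow(rows) == 1L) {
      rows$concordance_flag <- "singleton"
      rows$note <- ""
      out[[length(out) + 1L]] <- rows
      next
    }
    if (!.signsConcordant(sign(rows$log2fc))) next  # discordant: drop miRNA
    collapsed <- rows[1L, , drop = FALSE]
    collapsed$feature_id <- rows$mirna[1L]
    collapsed$log2fc <- mean(rows$log2fc)
    collapsed$p <- if (all(is.na(rows$p))) NA_real_ else min(rows$p,
                                                             na.rm = TRUE)
    collapsed$p_adj <- if (all(is.na(rows$p_adj))) NA_real_ else
      min(rows$p_adj, na.rm = TRUE)
    collapsed$status <- if (any(rows$status == "tested")) "tested" else
      "on_off"
    dirs <- unique(rows$direction[!is.na(rows$direction)])
    collapsed$direction <- if (length(dirs) == 1L) dirs else NA_character_
    collapsed$concordance_flag <- "collapsed"
    collapsed$note <- paste0("duplicates: ",
                             paste(rows$feature_id, collapse = ","))
    out[[length(out) + 1L]] <- collapsed
  }
  cols <- c("feature_id", "mirna", "status", "direction", "log2fc", "p",
            "p_adj", "concordance_flag", "note")
  if (!length(out)) {
    res <- data.frame(feature_id = character(), mirna = character(),
                      status = character(), direction = character(),
                      log2fc = numeric(), p = numeric(), p_adj = numeric(),
                      concordance_flag = character(), note = character(),
                      stringsAsFactors = FALSE)
    return(res)
  }
  res <- do.call(rbind, out)
  res$dupgroup <- NULL
  rownames(res) <- NULL
  res[, cols]
}

#' Assemble the candidate table
#'
#' Candidates are the tested features with raw moderated-t p below `alpha`
#' (the screen's stated rule; the BH-adjusted p is reported alongside) plus
#' all on/off records, after duplicate-concordance filtering. The table is
#' sorted by log2 fold change, descending.
#'
#' @param precursor output of [duplicateConcordanceFilter()] (or a combined
#'   table in the same layout)
#' @param alpha raw-p significance threshold in (0, 1), default 0.05
#' @return data.frame with columns `mirna`, `feature_id`, `log2fc`, `p`,
#'   `p_adj`, `status` (`"significant"`/`"on_off"`), `direction`, `note`
#' @export
assembleCandidates <- function(precursor, alpha = 0.05) {
  stopifnot(alpha >= 0, alpha < 1)
  keep <- precursor$status == "on_off" |
    (precursor$status == "tested" & !is.na(precursor$p) &
       precursor$p < alpha)
  cand <- precursor[keep, , drop = FALSE]
  cand$status[cand$status == "tested"] <- "significant"
  cand <- cand[order(-cand$log2fc), , drop = FALSE]
  rownames(cand) <- NULL
  cand[, c("mirna", "feature_id", "log2fc", "p", "p_adj", "status",
           "direction", "note")]
}

#' Replicate-probe consensus for gene-level calls on expression arrays
#'
#' A gene is called differentially expressed only if **every** one of its
#' replicate probes is individually significant at `alpha` with a consistent
#' fold-change sign; the gene log2 fold change is the mean over probes.
#' Probes without a gene mapping are dropped with a warning.
#'
#' @param probeDe probe-level results ([fitModeratedT()] output or data.frame
#'   with `feature_id`, `log2fc`, `p`)
#' @param probeToGene named character vector probe id -> gene id
#' @param alpha per-probe significance threshold (default 0.05)
#' @return data.frame with `gene_id`, `log2fc`, `n_probes`, `max_p`, `called`
#' @export
replicateProbeConsensus <- function(probeDe, probeToGene, alpha = 0.05) {
  de <- as.data.frame(probeDe)
  gene <- unname(probeToGene[as.character(de$feature_id)])
  unmapped <- is.na(gene)
  if (any(unmapped)) {
    warning(sum(unmapped), " probe(s) without gene mapping dropped")
    de <- de[!unmapped, , drop = FALSE]
    gene <- gene[!unmapped]
  }
  sp <- split(seq_len(nrow(de)), gene)
  res <- lapply(names(sp), function(g) {
    rows <- de[sp[[g]], , drop = FALSE]
    data.frame(
      gene_id = g,
      log2fc = mean(rows$log2fc),
      n_probes = nrow(rows),
      max_p = max(rows$p),
      called = all(rows$p < alpha) && .signsConcordant(sign(rows$log2fc)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
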