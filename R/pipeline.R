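# The two end-to-end workflows: the miRNA knockdown screen (CT table ->
# candidate list) and the downstream target/ontology analysis. Both are
# composable library functions; when an output directory is given they also
# write TSVs plus a reproducibility manifest with the resolved parameters
# and package version.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

.writeManifest <- function(outDir, config) {
  config <- c(list(package = "mirkd",
                   version = as.character(utils::packageVersion("mirkd"))),
              config)
  lines <- vapply(names(config), function(k)
    paste0(k, "\t", paste(format(config[[k]]), collapse = ",")),
    character(1))
  writeLines(lines, file.path(outDir, "manifest.tsv"))
}

.writeTsv <- function(df, path, pFormat = NULL) {
  out <- df
  if (!is.null(pFormat))
    for (col in pFormat)
      if (col %in% names(out))
        out[[col]] <- ifelse(is.na(out[[col]]), "n.c.",
                             formatC(out[[col]], format = "g", digits = 6))
  for (col in names(out))
    if (is.numeric(out[[col]]))
      out[[col]] <- formatC(out[[col]], format = "g", digits = 6)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the miRNA knockdown screen end to end
#'
#' Executes ingest, CT-to-log2 conversion, per-plate cyclic LOESS
#' normalization, detection partitioning, the moderated t-test with BH
#' adjustment, on/off lower-limit records, the duplicate-concordance filter
#' and candidate assembly. Detected features with undetermined values in
#' some samples cannot be tested and are reported separately.
#'
#' @param ct CT input: file path (long dialect), long data.frame or
#'   [CtExperiment-class]
#' @param samples sample sheet: file path or data.frame (ignored when `ct`
#'   is a `CtExperiment`)
#' @param alpha raw-p candidate threshold (default 0.05)
#' @param ctCutoff detection cutoff in cycles (default 34.5)
#' @param maxCycle maximum instrument cycle (default 40)
#' @param span,maxIter,tol cyclic LOESS controls (see [cyclicLoess()])
#' @param outDir optional output directory; created if needed. Writes
#'   `candidates.tsv` (columns `mirna log2fc p p_adj status note`, on/off
#'   rows carry `p = n.c.`), `de.tsv`, `onoff.tsv`, `manifest.tsv`.
#' @return list with `candidates`, `precursor`, `de`, `onoff`, `partition`,
#'   `untestable` (detected but incomplete features), `normalized`
#'   (SummarizedExperiment) and `config`
#' @examples
#' sim <- simulateLda(nFeatures = 60, nDuplicates = 6, fracDe = 0.1,
#'                    fracOnoff = 0.03, seed = 7)
#' res <- runMirnaScreen(sim$ct, sim$samples)
#' head(res$candidates)
#' @export
runMirnaScreen <- function(ct, samples = NULL, alpha = 0.05, ctCutoff = 34.5,
                           maxCycle = 40, span = 0.7, maxIter = 3,
                           tol = 1e-3, outDir = NULL) {
  cte <- .stage("ingest", {
    if (is(ct, "CtExperiment")) ct
    else {
      if (is.character(ct)) ct <- readCtTable(ct, maxCycle = maxCycle)
      if (is.character(samples)) samples <- readSampleSheet(samples)
      if (!nrow(ct)) stop("empty CT table")
      CtExperiment(ct, samples, maxCycle = maxCycle)
    }
  })
  part <- .stage("detection_partition", detectionPartition(cte, ctCutoff))
  norm <- .stage("normalize", {
    x <- ctToLog2(cte, maxCycle)
    cyclicLoess(x, span = span, maxIter = maxIter, tol = tol)
  })
  m <- .assayMatrix(norm)[part$detected, , drop = FALSE]
  complete <- rowSums(is.na(m)) == 0L
  untestable <- rownames(m)[!complete]
  de <- .stage("fit_moderated_t", {
    if (!any(complete)) stop("no complete detected features to test")
    fitModeratedT(m[complete, , drop = FALSE], sampleGroups(cte))
  })
  onoff <- .stage("onoff_lower_limit", onoffTable(cte, ctCutoff))
  prec <- .stage("duplicate_filter",
                 duplicateConcordanceFilter(de, onoff,
                                            duplicateGroups(cte),
                                            mirnaNames(cte)))
  cand <- .stage("assemble_candidates", assembleCandidates(prec, alpha))
  config <- list(alpha = alpha, ct_cutoff = ctCutoff, max_cycle = maxCycle,
                 loess_span = span, loess_max_iter = maxIter,
                 loess_tol = tol, n_assays = nrow(cte),
                 n_samples = ncol(cte))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    .writeTsv(cand[, c("mirna", "log2fc", "p", "p_adj", "status", "note")],
              file.path(outDir, "candidates.tsv"), pFormat = c("p", "p_adj"))
    .writeTsv(as.data.frame(de), file.path(outDir, "de.tsv"))
    .writeTsv(onoff, file.path(outDir, "onoff.tsv"), pFormat = "p")
    .writeManifest(outDir, config)
  }
  list(candidates = cand, precursor = prec, de = de, onoff = onoff,
       partition = part, untestable = untestable, normalized = norm,
       config = config)
}

#' Regulation directions from a candidate table
#'
#' Up in knockdown = positive (lower-limit) log2 fold change.
#'
#' @param candidates output of [assembleCandidates()] / [runMirnaScreen()]
#' @return named character vector miRNA ->
#'   `"up_in_knockdown"`/`"down_in_knockdown"`
#' @export
candidateDirections <- function(candidates) {
  stats::setNames(ifelse(candidates$log2fc >= 0, "up_in_knockdown",
                         "down_in_knockdown"),
                  candidates$mirna)
}

#' Run the target-scoring and ontology-enrichment workflow
#'
#' Executes the MTI evidence/expression filter, signed gene-level context+
#' score sums with the cutoff, term-level signed sums, enrichment of the
#' passing genes against the expressed-gene background, the significance
#' filter, and (when extra term collections are supplied) the cross-dataset
#' presence table.
#'
#' @param directions named direction vector (see [candidateDirections()]) or
#'   a candidate table
#' @param mti MTI table (data.frame or file path, see [readMtiTable()])
#' @param expressedGenes expressed-gene background (character vector)
#' @param geneSets gene -> term map (data.frame or file path)
#' @param scoreCutoff gene-level |signed sum| cutoff (default 0.4)
#' @param evidenceMin curated-evidence minimum (default `"strong"`)
#' @param method enrichment statistic (default `"ease"`)
#' @param feMin,pMax significance rule (defaults 1.5 and 0.1)
#' @param extraCollections optional named list of term-label collections to
#'   compare against the enriched terms (e.g. an expression-profile result)
#' @param synonymMap optional term synonym map for the presence table
#' @param outDir optional output directory (TSVs + manifest)
#' @return list with `mtiFiltered`, `geneScores`, `termScores`, `enrichment`,
#'   `enriched` (filtered), `presence` (or NULL) and `config`
#' @export
runTargetAnalysis <- function(directions, mti, expressedGenes, geneSets,
                              scoreCutoff = 0.4, evidenceMin = "strong",
                              method = "ease", feMin = 1.5, pMax = 0.1,
                              extraCollections = NULL, synonymMap = NULL,
                              outDir = NULL) {
  if (is.data.frame(directions)) directions <- candidateDirections(directions)
  if (is.character(mti) && length(mti) == 1L) mti <- readMtiTable(mti)
  if (is.character(geneSets) && length(geneSets) == 1L)
    geneSets <- readGeneSets(geneSets)
  filt <- .stage("filter_mti",
                 filterMti(mti, evidenceMin, expressedGenes))
  gs <- .stage("signed_gene_score",
               signedGeneScore(filt, directions, scoreCutoff))
  passing <- gs$gene_id[gs$passes_cutoff]
  if (!length(passing)) {
    message("no gene reaches |signed sum| >= ", scoreCutoff,
            "; enrichment skipped")
    ts <- NULL; enr <- NULL; kept <- NULL; pres <- NULL
  } else {
    ts <- .stage("term_signed_score", termSignedScore(gs, geneSets))
    enr <- .stage("enrichment_test",
                  enrichmentTest(passing, expressedGenes, geneSets,
                                 method = method, termScores = ts))
    kept <- .stage("filter_enriched", filterEnriched(enr, feMin, pMax))
    pres <- if (!is.null(extraCollections))
      .stage("ontology_presence", ontologyPresenceTable(
        c(list(predicted_targets = kept$term_name), extraCollections),
        synonymMap = synonymMap))
    else NULL
  }
  config <- list(score_cutoff = scoreCutoff, evidence_min = evidenceMin,
                 method = method, fe_min = feMin, p_max = pMax,
                 n_expressed = length(expressedGenes))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    .writeTsv(gs, file.path(outDir, "gene_scores.tsv"))
    if (!is.null(ts)) .writeTsv(ts, file.path(outDir, "term_scores.tsv"))
    if (!is.null(enr)) .writeTsv(enr, file.path(outDir, "enrichment.tsv"))
    if (!is.null(kept)) .writeTsv(kept, file.path(outDir, "enriched.tsv"))
    if (!is.null(pres)) .writeTsv(pres, file.path(outDir, "presence.tsv"))
    .writeManifest(outDir, config)
  }
  list(mtiFiltered = filt, geneScores = gs, termScores = ts,
       enrichment = enr, enriched = kept, presence = pres, config = config)
}
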