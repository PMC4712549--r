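# Seedable generators emulating every input the pipeline consumes, with
# ground-truth manifests for recovery testing. All generators are pure
# functions of their arguments including the seed: the global RNG state is
# saved and restored around each call.

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(),
                       inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulate a TaqMan-style LDA CT experiment with ground truth
#'
#' Emulates the screening design: two array plates (A/B) covering
#' `nFeatures` distinct miRNAs of which `nDuplicates` are measured twice,
#' `nPerGroup` knockdown vs `nPerGroup` control samples, Gaussian CT noise,
#' planted log2 effects, and detection dropout. Baseline CTs are drawn
#' uniformly from `baselineCtRange`; any noisy latent CT beyond `maxCycle`
#' is emitted as undetermined (`NA`), so the upper part of the baseline
#' range yields the realistic ~50% above-background detection rate of these
#' cards. Differentially expressed features draw baselines from the
#' detectable subrange (up to `ctCutoff - 3.5` cycles) so planted effects
#' remain measurable, and receive effects of random sign with magnitude
#' uniform in `effectRange` (cycles = log2 units) applied to the knockdown
#' group. On/off features place the silent group's latent CT above
#' `maxCycle` so every sample of that group is emitted as undetermined.
#' Duplicated assays share the truth of their miRNA and receive independent
#' noise.
#'
#' @param nFeatures distinct miRNAs (default 664)
#' @param nDuplicates miRNAs measured in duplicate (default 72)
#' @param nPerGroup samples per group (default 2)
#' @param fracDe fraction of miRNAs with a true effect, on/off included
#'   (default 21/664)
#' @param fracOnoff fraction of miRNAs that are on/off (default 6/664; must
#'   not exceed `fracDe`)
#' @param effectRange magnitude range of planted log2 effects
#'   (default c(1.5, 4))
#' @param noiseSd Gaussian CT noise, cycles (default 0.25)
#' @param baselineCtRange baseline CT range (default c(27, 41))
#' @param ctCutoff detection cutoff (default 34.5)
#' @param maxCycle maximum instrument cycle (default 40)
#' @param seed integer seed; same seed, same output
#' @return list with `ct` (long CT data.frame), `samples` (sample sheet) and
#'   `truth` (per-miRNA: `feature_id`, `true_log2fc`, `is_de`, `is_onoff`,
#'   `onoff_direction`, `duplicate_group`, `noise_sd`, `seed`)
#' @export
simulateLda <- function(nFeatures = 664, nDuplicates = 72, nPerGroup = 2,
                        fracDe = 21 / 664, fracOnoff = 6 / 664,
                        effectRange = c(1.5, 4), noiseSd = 0.25,
                        baselineCtRange = c(27, 41), ctCutoff = 34.5,
                        maxCycle = 40, seed = 1) .withSeed(seed, {
  stopifnot(nFeatures >= 1, nDuplicates >= 0, nDuplicates <= nFeatures,
            nPerGroup >= 1, fracDe >= 0, fracDe <= 1, fracOnoff >= 0,
            fracOnoff <= 1, length(effectRange) == 2,
            all(effectRange > 0), noiseSd >= 0,
            baselineCtRange[1] < baselineCtRange[2],
            ctCutoff > 0, ctCutoff < maxCycle)
  if (fracOnoff > fracDe)
    stop("fracOnoff must not exceed fracDe (on/off features are a subset ",
         "of the differentially expressed ones)", call. = FALSE)
  nDe <- round(fracDe * nFeatures)
  nOn <- round(fracOnoff * nFeatures)
  mirnas <- sprintf("hsa-miR-sim-%04d", seq_len(nFeatures))
  deIdx <- sample.int(nFeatures, nDe)
  onIdx <- if (nOn > 0) sample(deIdx, nOn) else integer()
  sigIdx <- setdiff(deIdx, onIdx)

  baseline <- stats::runif(nFeatures, baselineCtRange[1], baselineCtRange[2])
  detectHi <- min(ctCutoff - 3.5, baselineCtRange[2])
  baseline[deIdx] <- stats::runif(nDe, baselineCtRange[1], detectHi)

  trueLfc <- numeric(nFeatures)  # log2 expression scale, knockdown - control
  sgn <- sample(c(-1, 1), nDe, replace = TRUE)
  names(sgn) <- as.character(deIdx)
  mag <- stats::runif(nDe, effectRange[1], effectRange[2])
  names(mag) <- as.character(deIdx)
  trueLfc[sigIdx] <- sgn[as.character(sigIdx)] * mag[as.character(sigIdx)]
  onDir <- ifelse(sgn[as.character(onIdx)] > 0, "on_in_knockdown",
                  "off_in_knockdown")
  trueLfc[onIdx] <- sgn[as.character(onIdx)] * (ctCutoff - baseline[onIdx])

  dupIdx <- if (nDuplicates > 0) sort(sample.int(nFeatures, nDuplicates))
  else integer()
  dupGroup <- character(nFeatures)
  dupGroup[dupIdx] <- mirnas[dupIdx]

  samples <- data.frame(
    sample_id = c(sprintf("KD%d", seq_len(nPerGroup)),
                  sprintf("CTRL%d", seq_len(nPerGroup))),
    group = rep(c("knockdown", "control"), each = nPerGroup),
    label = c(sprintf("siFUS-%d", seq_len(nPerGroup)),
              sprintf("siNEG-%d", seq_len(nPerGroup))),
    stringsAsFactors = FALSE)

  plate <- ifelse(seq_len(nFeatures) <= ceiling(nFeatures / 2), "A", "B")
  onoffDirFull <- rep(NA_character_, nFeatures)
  onoffDirFull[onIdx] <- onDir

  # latent group-level CT per miRNA
  latentKd <- baseline - trueLfc * (!(seq_len(nFeatures) %in% onIdx))
  latentCtrl <- baseline
  if (length(onIdx)) {
    on <- onIdx[onDir == "on_in_knockdown"]
    off <- onIdx[onDir == "off_in_knockdown"]
    latentKd[on] <- baseline[on];      latentCtrl[on] <- maxCycle + 2
    latentKd[off] <- maxCycle + 2;     latentCtrl[off] <- baseline[off]
  }

  emitAssay <- function(idx, suffix, assayPlate) {
    latent <- cbind(matrix(rep(latentKd[idx], nPerGroup), ncol = nPerGroup),
                    matrix(rep(latentCtrl[idx], nPerGroup), ncol = nPerGroup))
    noisy <- latent + matrix(stats::rnorm(length(latent), 0, noiseSd),
                             nrow(latent))
    noisy[noisy > maxCycle] <- NA  # detection dropout -> "Undetermined"
    noisy[noisy < 0] <- 0
    data.frame(
      assay_id = rep(paste0(mirnas[idx], suffix), ncol(latent)),
      mirna_name = rep(mirnas[idx], ncol(latent)),
      plate = rep(assayPlate, ncol(latent)),
      sample_id = rep(samples$sample_id, each = length(idx)),
      ct = as.vector(noisy),
      duplicate_group = rep(dupGroup[idx], ncol(latent)),
      stringsAsFactors = FALSE)
  }
  ct <- emitAssay(seq_len(nFeatures), "", plate)
  if (length(dupIdx)) {
    # the replicate assay sits on the other plate
    other <- ifelse(plate[dupIdx] == "A", "B", "A")
    ct <- rbind(ct, emitAssay(dupIdx, "-2", other))
  }
  truth <- data.frame(
    feature_id = mirnas,
    true_log2fc = trueLfc,
    is_de = seq_len(nFeatures) %in% deIdx,
    is_onoff = seq_len(nFeatures) %in% onIdx,
    onoff_direction = onoffDirFull,
    duplicate_group = dupGroup,
    noise_sd = noiseSd,
    seed = seed,
    stringsAsFactors = FALSE)
  list(ct = ct, samples = samples, truth = truth)
})

#' Simulate an MTI table, gene-set map and miRNA direction map
#'
#' Builds a random bipartite miRNA-target table: every gene receives at
#' least one predicted interaction, extra interactions are added at random,
#' context+ scores are drawn uniformly from `scoreRange`, and a fraction of
#' interactions is duplicated as curated rows with random evidence classes.
#' Genes are assigned 1-2 ontology terms; each miRNA gets a random
#' regulation direction.
#'
#' @param nMirnas number of miRNAs (default 21)
#' @param nGenes number of genes (default 200)
#' @param nTerms number of ontology terms (default 10)
#' @param scoreRange negative context+ score interval (default
#'   c(-0.6, -0.05))
#' @param extraPerMirna mean number of extra interactions per miRNA beyond
#'   the gene-coverage ones (default 10)
#' @param fracCurated fraction of interactions also emitted as curated rows
#'   (default 0.15)
#' @param seed integer seed
#' @return list with `mti`, `geneSets`, `directions` (named character
#'   vector)
#' @export
simulateMti <- function(nMirnas = 21, nGenes = 200, nTerms = 10,
                        scoreRange = c(-0.6, -0.05), extraPerMirna = 10,
                        fracCurated = 0.15, seed = 1) .withSeed(seed, {
  stopifnot(nMirnas >= 1, nGenes >= 1, nTerms >= 1,
            scoreRange[1] < scoreRange[2], scoreRange[2] <= 0,
            scoreRange[1] > -1)
  mirnas <- sprintf("hsa-miR-sim-%04d", seq_len(nMirnas))
  genes <- sprintf("GENE%04d", seq_len(nGenes))
  pairs <- data.frame(
    mirna_id = mirnas[sample.int(nMirnas, nGenes, replace = TRUE)],
    gene_id = genes, stringsAsFactors = FALSE)
  nExtra <- nMirnas * extraPerMirna
  extra <- data.frame(
    mirna_id = mirnas[sample.int(nMirnas, nExtra, replace = TRUE)],
    gene_id = genes[sample.int(nGenes, nExtra, replace = TRUE)],
    stringsAsFactors = FALSE)
  pairs <- rbind(pairs, extra)
  pairs <- pairs[!duplicated(paste(pairs$mirna_id, pairs$gene_id)), ,
                 drop = FALSE]
  # guarantee every miRNA appears
  absent <- setdiff(mirnas, pairs$mirna_id)
  if (length(absent))
    pairs <- rbind(pairs, data.frame(
      mirna_id = absent,
      gene_id = genes[sample.int(nGenes, length(absent), replace = TRUE)],
      stringsAsFactors = FALSE))
  pairs <- pairs[!duplicated(paste(pairs$mirna_id, pairs$gene_id)), ,
                 drop = FALSE]
  mti <- data.frame(pairs,
                    source = "predicted",
                    evidence = NA_character_,
                    context_score = stats::runif(nrow(pairs), scoreRange[1],
                                                 scoreRange[2]),
                    stringsAsFactors = FALSE)
  nCur <- round(fracCurated * nrow(mti))
  if (nCur > 0) {
    ci <- sample.int(nrow(mti), nCur)
    cur <- mti[ci, , drop = FALSE]
    cur$source <- "curated"
    cur$evidence <- sample(c("strong", "weak"), nCur, replace = TRUE)
    cur$context_score <- NA_real_
    mti <- rbind(mti, cur)
  }
  rownames(mti) <- NULL
  nt <- sample(1:2, nGenes, replace = TRUE)
  geneSets <- data.frame(
    gene_id = rep(genes, nt),
    term_id = sprintf("TERM%03d", unlist(lapply(nt, function(k)
      sample.int(nTerms, k)))),
    stringsAsFactors = FALSE)
  geneSets$term_name <- sub("TERM", "simulated process ", geneSets$term_id)
  directions <- stats::setNames(
    sample(c("up_in_knockdown", "down_in_knockdown"), nMirnas,
           replace = TRUE), mirnas)
  list(mti = mti, geneSets = geneSets, directions = directions)
})

#' Simulate a one-color expression array with replicate probes
#'
#' Genes receive 1-3 replicate probes (at least one each; `nProbes` total).
#' Differentially expressed genes receive a common effect across their
#' probes, applied to the knockdown group; Gaussian noise is added on the
#' log2-intensity scale.
#'
#' @param nProbes total probes (default 300; must be >= `nGenes`)
#' @param nGenes genes (default 150)
#' @param nPerGroup samples per group (default 2)
#' @param fracDe fraction of DE genes (default 0.1)
#' @param effectRange magnitude range of log2 effects (default c(1, 3))
#' @param noiseSd log2-intensity noise (default 0.25)
#' @param seed integer seed
#' @return list with `expr` (probe x sample log2 matrix), `groups`
#'   (per-sample labels), `probeToGene` (named character vector) and `truth`
#'   (`gene_id`, `true_log2fc`, `is_de`, `n_probes`)
#' @export
simulateExpressionArray <- function(nProbes = 300, nGenes = 150,
                                    nPerGroup = 2, fracDe = 0.1,
                                    effectRange = c(1, 3), noiseSd = 0.25,
                                    seed = 1) .withSeed(seed, {
  stopifnot(nProbes >= nGenes, nGenes >= 1, nPerGroup >= 1,
            fracDe >= 0, fracDe <= 1)
  genes <- sprintf("GENE%04d", seq_len(nGenes))
  counts <- rep(1L, nGenes)
  extra <- nProbes - nGenes
  while (extra > 0) {
    i <- sample.int(nGenes, 1L)
    if (counts[i] < 3L) { counts[i] <- counts[i] + 1L; extra <- extra - 1L }
  }
  probeGene <- rep(genes, counts)
  probes <- sprintf("P%05d", seq_len(nProbes))
  nDe <- round(fracDe * nGenes)
  deIdx <- sample.int(nGenes, nDe)
  effect <- numeric(nGenes)
  effect[deIdx] <- sample(c(-1, 1), nDe, replace = TRUE) *
    stats::runif(nDe, effectRange[1], effectRange[2])
  baseline <- stats::runif(nProbes, 6, 14)
  probeEffect <- effect[match(probeGene, genes)]
  groups <- rep(c("knockdown", "control"), each = nPerGroup)
  latent <- outer(baseline, rep(0, 2 * nPerGroup), `+`) +
    outer(probeEffect, as.numeric(groups == "knockdown"))
  m <- latent + matrix(stats::rnorm(length(latent), 0, noiseSd),
                       nrow(latent))
  dimnames(m) <- list(probes, c(sprintf("KD%d", seq_len(nPerGroup)),
                                sprintf("CTRL%d", seq_len(nPerGroup))))
  list(expr = m,
       groups = groups,
       probeToGene = stats::setNames(probeGene, probes),
       truth = data.frame(gene_id = genes, true_log2fc = effect,
                          is_de = seq_len(nGenes) %in% deIdx,
                          n_probes = counts, stringsAsFactors = FALSE))
})
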