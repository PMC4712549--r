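# miRNA-target interaction (MTI) handling: curated (evidence-classed) and
# predicted (context+ scored) interactions live in one table with a source
# tag so they share the filtering path. Signed score aggregation is
# direction-aware: interactions of miRNAs down-regulated upon knockdown keep
# their (negative) context+ score, those of up-regulated miRNAs are
# sign-flipped to positive, so genes targeted similarly from both directions
# cancel out.

.EVIDENCE_LEVELS <- c(none = 0L, weak = 1L, strong = 2L)

.validateMti <- function(t) {
  .requireCols(t, c("mirna_id", "gene_id", "source"), "MTI table")
  t$mirna_id <- as.character(t$mirna_id)
  t$gene_id <- as.character(t$gene_id)
  t$source <- as.character(t$source)
  if (!all(t$source %in% c("curated", "predicted")))
    stop("MTI source must be 'curated' or 'predicted'", call. = FALSE)
  if (!"evidence" %in% names(t)) t$evidence <- NA_character_
  if (!"context_score" %in% names(t)) t$context_score <- NA_real_
  t$evidence <- as.character(t$evidence)
  t$context_score <- suppressWarnings(as.numeric(t$context_score))
  cur <- t$source == "curated"
  if (any(cur & (is.na(t$evidence) | !t$evidence %in%
                 names(.EVIDENCE_LEVELS))))
    stop("curated MTI rows need an evidence class (strong/weak/none)",
         call. = FALSE)
  pred <- t$source == "predicted"
  if (any(pred & is.na(t$context_score)))
    stop("predicted MTI rows need a context_score", call. = FALSE)
  if (any(pred & t$context_score > 0))
    stop("context scores must be <= 0", call. = FALSE)
  key <- paste(t$mirna_id, t$gene_id, t$source, sep = "\r")
  dupPred <- duplicated(key) & pred
  if (any(duplicated(key[cur])))
    stop("duplicated curated (mirna_id, gene_id) row", call. = FALSE)
  if (any(dupPred)) {
    # site-level exports: per-gene context scores are sums over sites
    warning("duplicate predicted (mirna, gene) rows summed on load")
    agg <- stats::aggregate(context_score ~ mirna_id + gene_id, sum,
                            data = t[pred, , drop = FALSE])
    agg$source <- "predicted"
    agg$evidence <- NA_character_
    t <- rbind(t[cur, , drop = FALSE],
               agg[, c("mirna_id", "gene_id", "source", "evidence",
                       "context_score")])
  }
  rownames(t) <- NULL
  t[, c("mirna_id", "gene_id", "source", "evidence", "context_score")]
}

#' Read an MTI table
#'
#' Tab-delimited table with columns `mirna_id`, `gene_id`, `source`
#' (`"curated"`/`"predicted"`), `evidence` (`strong`/`weak`/`none`, curated
#' rows) and `context_score` (<= 0, predicted rows). Duplicate predicted
#' (miRNA, gene) rows -- site-level exports -- are summed on load with a
#' warning; duplicate curated rows are an error.
#'
#' @param path file path
#' @return validated MTI data.frame
#' @export
readMtiTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  .validateMti(utils::read.delim(path, sep = "\t", header = TRUE,
                                 colClasses = "character", quote = "",
                                 comment.char = ""))
}

#' Read a gene -> ontology-term map
#'
#' Tab-delimited, columns `gene_id`, `term_id` and optionally `term_name`.
#' @param path file path
#' @return data.frame `gene_id`, `term_id`, `term_name`
#' @export
readGeneSets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          comment.char = "")
  .requireCols(df, c("gene_id", "term_id"), "gene-set map")
  if (!"term_name" %in% names(df)) df$term_name <- df$term_id
  df[, c("gene_id", "term_id", "term_name")]
}

#' Filter MTIs by evidence class and expressed-gene background
#'
#' Curated rows with evidence below `evidenceMin` are removed; then all rows
#' whose gene is not in `expressedGenes` (the cellular-context expression
#' background) are removed. Predicted rows are untouched by the evidence
#' filter. Removal counts are attached as `attr(, "removed")` and reconcile
#' with the input row count.
#'
#' @param t MTI data.frame (see [readMtiTable()])
#' @param evidenceMin minimum evidence class for curated rows
#'   (`"strong"`, `"weak"` or `"none"`; default `"strong"`)
#' @param expressedGenes non-empty character vector of expressed gene ids
#' @return filtered MTI data.frame with attribute `removed`
#'   (`list(evidence=, expression=)`)
#' @export
filterMti <- function(t, evidenceMin = c("strong", "weak", "none"),
                      expressedGenes) {
  evidenceMin <- match.arg(evidenceMin)
  stopifnot(length(expressedGenes) > 0)
  t <- .validateMti(t)
  n0 <- nrow(t)
  minLevel <- .EVIDENCE_LEVELS[[evidenceMin]]
  keepEv <- t$source == "predicted" |
    .EVIDENCE_LEVELS[t$evidence] >= minLevel
  nEv <- sum(!keepEv)
  t <- t[keepEv, , drop = FALSE]
  keepEx <- t$gene_id %in% expressedGenes
  nEx <- sum(!keepEx)
  t <- t[keepEx, , drop = FALSE]
  rownames(t) <- NULL
  attr(t, "removed") <- list(evidence = nEv, expression = nEx)
  stopifnot(n0 == nrow(t) + nEv + nEx)
  t
}

.signedMtiScores <- function(t, directions) {
  pred <- t[t$source == "predicted", , drop = FALSE]
  missing <- setdiff(unique(pred$mirna_id), names(directions))
  if (length(missing))
    stop("no direction for miRNA(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  dir <- directions[pred$mirna_id]
  if (!all(dir %in% c("up_in_knockdown", "down_in_knockdown")))
    stop("directions must be 'up_in_knockdown' or 'down_in_knockdown'",
         call. = FALSE)
  pred$signed_score <- ifelse(dir == "down_in_knockdown",
                              pred$context_score, -pred$context_score)
  pred
}

#' Direction-aware signed context+ score sums per gene
#'
#' Per interaction, the signed score is the (negative) context+ score when
#' the miRNA is down-regulated in the knockdown and its negation (positive)
#' when up-regulated. Per gene these are summed over all of its predicted
#' interactions; the gene passes when `|signed_sum| >= cutoff`. Genes
#' targeted comparably by up- and down-regulated miRNAs cancel towards zero
#' and drop out.
#'
#' @param t MTI data.frame; only `source == "predicted"` rows are scored
#' @param directions named character vector miRNA id ->
#'   `"up_in_knockdown"`/`"down_in_knockdown"`; every scored miRNA needs one
#' @param cutoff positive cutoff on `|signed_sum|` (default 0.4)
#' @return data.frame `gene_id`, `signed_sum`, `n_mti`, `passes_cutoff`,
#'   with the per-MTI signed scores in `attr(, "mti")`
#' @export
signedGeneScore <- function(t, directions, cutoff = 0.4) {
  stopifnot(cutoff > 0)
  t <- .validateMti(t)
  pred <- .signedMtiScores(t, directions)
  if (!nrow(pred))
    return(structure(data.frame(gene_id = character(),
                                signed_sum = numeric(), n_mti = integer(),
                                passes_cutoff = logical()), mti = pred))
  sums <- tapply(pred$signed_score, pred$gene_id, sum)
  ns <- tapply(pred$signed_score, pred$gene_id, length)
  out <- data.frame(gene_id = names(sums),
                    signed_sum = unname(as.vector(sums)),
                    n_mti = as.integer(unname(as.vector(ns))),
                    passes_cutoff = abs(unname(as.vector(sums))) >= cutoff,
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "mti") <- pred
  out
}

#' Signed context+ score sums per ontology term
#'
#' Per term, sums the signed interaction scores over all predicted MTIs of
#' member genes that passed the gene-level cutoff (set `includeAll = TRUE`
#' to drop the gene filter). Negative sums indicate predominant targeting by
#' down-regulated miRNAs, positive sums by up-regulated miRNAs. Terms with
#' no scored member gene are omitted with a warning.
#'
#' @param geneScores output of [signedGeneScore()]
#' @param geneSets data.frame `gene_id`, `term_id`, `term_name`
#' @param includeAll include genes below the cutoff (default FALSE)
#' @return data.frame `term_id`, `term_name`, `signed_term_score`,
#'   `n_genes`, `n_mti`
#' @export
termSignedScore <- function(geneScores, geneSets, includeAll = FALSE) {
  mti <- attr(geneScores, "mti")
  if (is.null(mti))
    stop("geneScores must come from signedGeneScore()", call. = FALSE)
  .requireCols(geneSets, c("gene_id", "term_id"), "gene-set map")
  if (!"term_name" %in% names(geneSets)) geneSets$term_name <- geneSets$term_id
  use <- if (includeAll) geneScores$gene_id else
    geneScores$gene_id[geneScores$passes_cutoff]
  terms <- unique(geneSets[, c("term_id", "term_name")])
  out <- lapply(seq_len(nrow(terms)), function(i) {
    members <- geneSets$gene_id[geneSets$term_id == terms$term_id[i]]
    members <- intersect(members, use)
    rows <- mti[mti$gene_id %in% members, , drop = FALSE]
    if (!nrow(rows)) return(NULL)
    data.frame(term_id = terms$term_id[i], term_name = terms$term_name[i],
               signed_term_score = sum(rows$signed_score),
               n_genes = length(members), n_mti = nrow(rows),
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(out, is.null, logical(1)))
  if (dropped)
    warning(dropped, " term(s) without scored member genes omitted")
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(term_id = character(), term_name = character(),
                      signed_term_score = numeric(), n_genes = integer(),
                      n_mti = integer(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

.canonicalTerm <- function(x, synonymMap = NULL) {
  x <- .squishLower(x)
  if (!is.null(synonymMap) && length(synonymMap)) {
    names(synonymMap) <- .squishLower(names(synonymMap))
    synonymMap <- .squishLower(synonymMap)
    hit <- x %in% names(synonymMap)
    x[hit] <- unname(synonymMap[x[hit]])
  }
  x
}

.squishLower <- function(x) tolower(gsub("[[:space:]]+", " ", trimws(x)))

#' Cross-dataset ontology-term presence table
#'
#' Compares named collections of enriched term labels (e.g. from a gene
#' expression profile and from known and predicted miRNA target genes).
#' Labels are normalized case-insensitively with whitespace collapsing, then
#' mapped through an optional synonym map. Rows are the canonical terms
#' present in at least two collections; cells are presence flags. When
#' `flagCollection` names one collection (typically the expression data
#' set), rows absent from it but present elsewhere are flagged -- these are
#' the processes preferentially represented in the target-gene collections.
#'
#' @param collections named list (>= 2) of character vectors of term labels
#' @param synonymMap optional named character vector label -> canonical label
#' @param flagCollection optional name of the collection whose absences are
#'   flagged
#' @return data.frame `term` plus one logical column per collection and, if
#'   requested, a logical `flagged` column
#' @export
ontologyPresenceTable <- function(collections, synonymMap = NULL,
                                  flagCollection = NULL) {
  stopifnot(is.list(collections), length(collections) >= 2,
            !is.null(names(collections)), all(nzchar(names(collections))))
  canon <- lapply(collections, .canonicalTerm, synonymMap = synonymMap)
  terms <- sort(unique(unlist(canon)))
  pres <- vapply(canon, function(v) terms %in% v,
                 logical(length(terms)))
  pres <- matrix(pres, nrow = length(terms),
                 dimnames = list(NULL, names(collections)))
  keep <- rowSums(pres) >= 2L
  out <- data.frame(term = terms[keep], pres[keep, , drop = FALSE],
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(flagCollection)) {
    if (!flagCollection %in% names(collections))
      stop("unknown collection: ", flagCollection, call. = FALSE)
    out$flagged <- !out[[flagCollection]]
  }
  rownames(out) <- NULL
  out
}
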