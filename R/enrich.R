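# Stand-alone gene-ontology enrichment over user-supplied annotations,
# replacing a web service with a reproducible local computation. The default
# statistic is the conservative EASE variant (one list gene removed from the
# term overlap before the hypergeometric tail).

#' Term enrichment of a gene list against a background
#'
#' For each term with background count K out of N background genes and list
#' overlap k out of n list genes, the one-sided p-value is the
#' hypergeometric upper tail \eqn{P(X \ge k)}. Method `"ease"` replaces k by
#' `max(k - 1, 0)` before the tail computation (so a single-gene overlap is
#' never significant); fold enrichment `(k/n)/(K/N)` always uses the true k.
#' BH-adjusted p-values are reported as an auxiliary column; the screen's
#' significance rule ([filterEnriched()]) uses the raw p.
#'
#' The background should be the expressed-gene set of the cellular context
#' under study, not the whole annotation universe.
#'
#' @param geneList character vector, a subset of `background`
#' @param background character vector of background gene ids
#' @param geneSets data.frame `gene_id`, `term_id`, optionally `term_name`
#' @param method `"ease"` (default) or `"fisher"`
#' @param termScores optional data.frame `term_id`, `signed_term_score` to
#'   join (see [termSignedScore()])
#' @return data.frame per term: `term_id`, `term_name`, `k`, `n`, `K`, `N`,
#'   `fold_enrichment`, `p`, `p_adj` (and `signed_term_score` if supplied),
#'   ordered by increasing p
#' @export
enrichmentTest <- function(geneList, background, geneSets,
                           method = c("ease", "fisher"),
                           termScores = NULL) {
  method <- match.arg(method)
  geneList <- unique(as.character(geneList))
  background <- unique(as.character(background))
  outside <- setdiff(geneList, background)
  if (length(outside))
    stop("gene list not contained in background: ",
         paste(utils::head(outside, 5), collapse = ", "),
         if (length(outside) > 5) ", ..." else "", call. = FALSE)
  .requireCols(geneSets, c("gene_id", "term_id"), "gene-set map")
  if (!"term_name" %in% names(geneSets)) geneSets$term_name <- geneSets$term_id
  geneSets <- geneSets[geneSets$gene_id %in% background, , drop = FALSE]
  N <- length(background)
  n <- length(geneList)
  terms <- unique(geneSets[, c("term_id", "term_name")])
  rows <- lapply(seq_len(nrow(terms)), function(i) {
    members <- unique(geneSets$gene_id[geneSets$term_id == terms$term_id[i]])
    K <- length(members)
    k <- length(intersect(members, geneList))
    kTest <- if (method == "ease") max(k - 1L, 0L) else k
    p <- stats::phyper(kTest - 1L, K, N - K, n, lower.tail = FALSE)
    fe <- if (n > 0 && K > 0) (k / n) / (K / N) else 0
    data.frame(term_id = terms$term_id[i], term_name = terms$term_name[i],
               k = k, n = n, K = K, N = N, fold_enrichment = fe,
               p = min(p, 1), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res) || !nrow(res))
    return(data.frame(term_id = character(), term_name = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), fold_enrichment = numeric(),
                      p = numeric(), p_adj = numeric(),
                      stringsAsFactors = FALSE))
  res$p_adj <- bhAdjust(res$p)
  if (!is.null(termScores))
    res$signed_term_score <-
      termScores$signed_term_score[match(res$term_id, termScores$term_id)]
  res <- res[order(res$p, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Filter enrichment results by the screen's significance rule
#'
#' Keeps terms with fold enrichment at least `feMin` **and** raw p strictly
#' below `pMax` (defaults 1.5 and 0.1). Boundary behaviour: a term at
#' exactly `feMin` is kept; a term at exactly `pMax` is dropped.
#'
#' @param r output of [enrichmentTest()]
#' @param feMin minimum fold enrichment (>= 0), default 1.5
#' @param pMax raw-p upper bound in (0, 1], default 0.1
#' @return filtered data.frame
#' @export
filterEnriched <- function(r, feMin = 1.5, pMax = 0.1) {
  stopifnot(feMin >= 0, pMax > 0, pMax <= 1)
  out <- r[r$fold_enrichment >= feMin & r$p < pMax, , drop = FALSE]
  rownames(out) <- NULL
  out
}
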