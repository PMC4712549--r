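mtiFixture <- function() {
  data.frame(
    mirna_id = c("m1", "m1", "m2", "m2", "m3"),
    gene_id = c("CCND1", "G2", "G2", "G3", "G3"),
    source = "predicted",
    evidence = NA_character_,
    context_score = c(-0.43, -0.3, -0.3, -0.25, -0.25),
    stringsAsFactors = FALSE)
}

test_that("evidence and expression filters reproduce the curated-count
           arithmetic", {
  # 328 curated interactions of which 265 carry only weak evidence
  cur <- data.frame(
    mirna_id = sprintf("m%02d", rep(1:14, length.out = 328)),
    gene_id = sprintf("G%03d", 1:328),
    source = "curated",
    evidence = c(rep("weak", 265), rep("strong", 63)),
    context_score = NA_real_,
    stringsAsFactors = FALSE)
  out <- filterMti(cur, evidenceMin = "strong",
                   expressedGenes = cur$gene_id)
  expect_equal(nrow(out), 63)
  expect_equal(attr(out, "removed")$evidence, 265)
  # removal counts reconcile: input = output + removed
  expect_equal(nrow(cur),
               nrow(out) + attr(out, "removed")$evidence +
                 attr(out, "removed")$expression)
  # expression background restriction applies after the evidence filter
  out2 <- filterMti(cur, "strong", expressedGenes = cur$gene_id[300:328])
  expect_equal(nrow(out2), 29)
  expect_equal(attr(out2, "removed")$expression, 63 - 29)
  # disjoint background: empty table, counts still reconcile
  out3 <- filterMti(cur, "strong", expressedGenes = "NOT_A_GENE")
  expect_equal(nrow(out3), 0)
  expect_equal(attr(out3, "removed")$expression, 63)
})

test_that("predicted rows pass the evidence filter untouched", {
  t <- rbind(mtiFixture(),
             data.frame(mirna_id = "m9", gene_id = "G9", source = "curated",
                        evidence = "weak", context_score = NA_real_))
  out <- filterMti(t, "strong",
                   expressedGenes = unique(t$gene_id))
  expect_equal(out[out$source == "predicted", c("mirna_id", "gene_id")],
               mtiFixture()[, c("mirna_id", "gene_id")])
  expect_false("m9" %in% out$mirna_id)
})

test_that("signed gene scores are direction-aware and additive", {
  dirs <- c(m1 = "up_in_knockdown", m2 = "down_in_knockdown",
            m3 = "down_in_knockdown")
  gs <- signedGeneScore(mtiFixture(), dirs, cutoff = 0.4)
  # single interaction of an up-regulated miRNA: sign flips to positive
  expect_equal(gs$signed_sum[gs$gene_id == "CCND1"], 0.43)
  expect_true(gs$passes_cutoff[gs$gene_id == "CCND1"])
  # -0.3 (up, flipped) and -0.3 (down, kept) cancel
  expect_equal(gs$signed_sum[gs$gene_id == "G2"], 0)
  expect_false(gs$passes_cutoff[gs$gene_id == "G2"])
  # two down-regulated interactions of -0.25 add to -0.5
  expect_equal(gs$signed_sum[gs$gene_id == "G3"], -0.5)
  expect_true(gs$passes_cutoff[gs$gene_id == "G3"])
  # a scored miRNA without a direction is an error naming it
  expect_error(signedGeneScore(mtiFixture(), dirs[-3]), "m3")
})

test_that("restricted to one miRNA the signed scores are the raw context+
           scores up to sign", {
  t <- mtiFixture()[1:2, ]
  up <- signedGeneScore(t, c(m1 = "up_in_knockdown"), cutoff = 0.1)
  down <- signedGeneScore(t, c(m1 = "down_in_knockdown"), cutoff = 0.1)
  expect_equal(sort(up$signed_sum), sort(-t$context_score))
  expect_equal(sort(down$signed_sum), sort(t$context_score))
})

test_that("direction flip negates every gene and term sum (antisymmetry)", {
  sim <- simulateMti(nMirnas = 8, nGenes = 60, nTerms = 5, seed = 5)
  flip <- ifelse(sim$directions == "up_in_knockdown",
                 "down_in_knockdown", "up_in_knockdown")
  names(flip) <- names(sim$directions)
  g1 <- signedGeneScore(sim$mti, sim$directions, cutoff = 0.4)
  g2 <- signedGeneScore(sim$mti, flip, cutoff = 0.4)
  expect_equal(g1$gene_id, g2$gene_id)
  expect_equal(g1$signed_sum, -g2$signed_sum, tolerance = 1e-12)
  expect_equal(g1$passes_cutoff, g2$passes_cutoff)
  t1 <- suppressWarnings(termSignedScore(g1, sim$geneSets))
  t2 <- suppressWarnings(termSignedScore(g2, sim$geneSets))
  expect_equal(t1$signed_term_score, -t2$signed_term_score,
               tolerance = 1e-12)
})

test_that("term sums cover passing genes and conserve the total over a
           partition", {
  dirs <- c(m1 = "up_in_knockdown", m2 = "down_in_knockdown",
            m3 = "down_in_knockdown")
  t <- mtiFixture()
  gs <- signedGeneScore(t, dirs, cutoff = 0.4)
  sets <- data.frame(gene_id = c("CCND1", "G2", "G3"),
                     term_id = c("T1", "T1", "T2"),
                     term_name = c("term one", "term one", "term two"))
  ts <- termSignedScore(gs, sets)
  # G2 cancels below the cutoff, so T1 holds only CCND1's interaction
  expect_equal(ts$signed_term_score[ts$term_id == "T1"], 0.43)
  expect_equal(ts$signed_term_score[ts$term_id == "T2"], -0.5)
  # disjoint terms partitioning the passing genes conserve the total
  passTotal <- sum(vapply(gs$gene_id[gs$passes_cutoff], function(g)
    sum(attr(gs, "mti")$signed_score[attr(gs, "mti")$gene_id == g]),
    numeric(1)))
  expect_equal(sum(ts$signed_term_score), passTotal, tolerance = 1e-12)
  # includeAll restores genes below the cutoff (G2's scores cancel to 0,
  # but its interaction count now enters)
  tsAll <- termSignedScore(gs, sets, includeAll = TRUE)
  expect_equal(tsAll$signed_term_score[tsAll$term_id == "T1"], 0.43,
               tolerance = 1e-12)
  expect_equal(tsAll$n_mti[tsAll$term_id == "T1"], 3)
  # terms whose genes all failed are omitted with a warning
  sets2 <- data.frame(gene_id = "G2", term_id = "T9", term_name = "t9")
  expect_warning(ts2 <- termSignedScore(gs, sets2), "omitted")
  expect_equal(nrow(ts2), 0)
})

test_that("duplicate predicted rows are summed on load with a warning", {
  t <- rbind(mtiFixture(), mtiFixture()[1, ])
  expect_warning(out <- filterMti(t, "strong",
                                  expressedGenes = unique(t$gene_id)),
                 "summed")
  expect_equal(out$context_score[out$mirna_id == "m1" &
                                   out$gene_id == "CCND1"], -0.86)
})

test_that("MTI tables round-trip through the reader", {
  sim <- simulateMti(nMirnas = 5, nGenes = 30, seed = 9)
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(sim$mti, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- readMtiTable(f)
  expect_equal(nrow(back), nrow(sim$mti))
  expect_equal(sort(unique(back$mirna_id)), sort(unique(sim$mti$mirna_id)))
  pred <- back$source == "predicted"
  expect_true(all(back$context_score[pred] <= 0))
})

test_that("the presence table keeps terms shared by two collections and
           flags absences from the reference set", {
  cols <- list(
    expression = c("Transcription factor", "apoptosis", "DNA replication"),
    known = c("transcription  factor", "cell cycle", "apoptosis"),
    predicted = c("transcription factor", "cell cycle",
                  "stem cell maintenance"))
  out <- ontologyPresenceTable(cols, flagCollection = "expression")
  expect_true("transcription factor" %in% out$term)   # in all three
  row <- out[out$term == "transcription factor", ]
  expect_true(all(unlist(row[, c("expression", "known", "predicted")])))
  expect_false(row$flagged)
  # present in only one collection: excluded
  expect_false("dna replication" %in% out$term)
  expect_false("stem cell maintenance" %in% out$term)
  # absent from the expression set but shared by targets: flagged
  cc <- out[out$term == "cell cycle", ]
  expect_true(cc$flagged)
  # synonym mapping merges labels
  out2 <- ontologyPresenceTable(
    list(a = "stem cell maintenance", b = "stem cell development"),
    synonymMap = c("stem cell development" = "stem cell maintenance"))
  expect_equal(out2$term, "stem cell maintenance")
})
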