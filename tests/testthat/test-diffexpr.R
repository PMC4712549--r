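test_that("detection partition applies the CT-cutoff and on/off rules", {
  cte <- makeCte(list(
    lowexpr = c(35, 36, 35, 37),        # above cutoff everywhere -> excluded
    onKd = c(30, 31, NA, NA),           # silent in control -> on
    offKd = c(NA, NA, 28, 29),          # silent in knockdown -> off
    detected = c(34.4, 30, 33, 31),
    partial = c(30, NA, 31, 31),        # partly undetermined -> detected
    allna = c(NA, NA, NA, NA)))         # excluded
  part <- detectionPartition(cte, ctCutoff = 34.5)
  expect_setequal(part$excluded, c("lowexpr", "allna"))
  expect_setequal(part$detected, c("detected", "partial"))
  expect_equal(part$onoff$feature_id, c("onKd", "offKd"))
  expect_equal(part$onoff$direction,
               c("on_in_knockdown", "off_in_knockdown"))
})

test_that("moderated t reduces to classical pooled t when the prior df is
           forced to zero", {
  set.seed(10)
  m <- matrix(rnorm(1000 * 6, mean = 8), 1000,
              dimnames = list(sprintf("f%04d", 1:1000), NULL))
  groups <- rep(c("knockdown", "control"), each = 3)
  fit <- fitModeratedT(m, groups, priorDf = 0)
  tRef <- apply(m, 1, function(r) classicalT(r[1:3], r[4:6]))
  expect_lt(max(abs(fit$t - tRef) / pmax(abs(tRef), 1e-12)), 1e-10)
  pRef <- 2 * pt(-abs(tRef), df = 4)
  expect_equal(fit$p, unname(pRef), tolerance = 1e-12)
})

test_that("a feature with identical group values gives log2fc 0, t 0, p 1", {
  m <- rbind(flat = c(5, 5, 5, 5), eff = c(9, 9, 5, 5),
             noise = c(5.3, 4.9, 5.2, 4.8))
  fit <- fitModeratedT(m, rep(c("knockdown", "control"), each = 2))
  expect_equal(fit["flat", "log2fc"], 0)
  expect_equal(fit["flat", "t"], 0)
  expect_equal(fit["flat", "p"], 1)
  expect_gt(fit["eff", "log2fc"], 3.9)
})

test_that("null p-values are uniform (seeded Kolmogorov-Smirnov check)", {
  set.seed(2024)
  m <- matrix(rnorm(1000 * 6), 1000)
  fit <- fitModeratedT(m, rep(c("knockdown", "control"), each = 3))
  ks <- suppressWarnings(ks.test(fit$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("moderated t agrees with the limma reference implementation", {
  skip_if_not_installed("limma")
  set.seed(99)
  m <- matrix(rnorm(500 * 4, sd = rep(runif(500, 0.2, 2), 4)), 500) +
    c(rep(0, 450), runif(50, -2, 2))
  colnames(m) <- c("KD1", "KD2", "C1", "C2")
  rownames(m) <- sprintf("f%03d", 1:500)
  groups <- c("knockdown", "knockdown", "control", "control")
  fit <- fitModeratedT(m, groups)
  design <- cbind(1, as.numeric(groups == "knockdown"))
  lfit <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(S4Vectors::metadata(fit)$prior_df, lfit$df.prior,
               tolerance = 1e-6)
  expect_equal(S4Vectors::metadata(fit)$prior_var, lfit$s2.prior,
               tolerance = 1e-6)
  expect_equal(fit$t, unname(lfit$t[, 2]), tolerance = 1e-8)
  expect_equal(fit$p, unname(lfit$p.value[, 2]), tolerance = 1e-8)
})

test_that("swapping group labels negates log2fc and keeps p", {
  set.seed(4)
  m <- matrix(rnorm(200 * 4, 8), 200)
  g1 <- rep(c("knockdown", "control"), each = 2)
  g2 <- rep(c("control", "knockdown"), each = 2)
  f1 <- fitModeratedT(m, g1)
  f2 <- fitModeratedT(m, g2)
  expect_equal(f1$log2fc, -f2$log2fc)
  expect_equal(f1$p, f2$p)
})

test_that("degenerate designs demand the explicit common-variance mode", {
  m <- matrix(rnorm(20), 10, 2)
  g <- c("knockdown", "control")
  expect_error(fitModeratedT(m, g), "priorDf and priorVar")
  fit <- fitModeratedT(m, g, priorDf = 10, priorVar = 1)
  expect_equal(unique(fit$df_total), 10)
  m[1, 1] <- NA
  expect_error(fitModeratedT(m, g, priorDf = 10, priorVar = 1), "masked")
})

test_that("BH adjustment matches the defining step-up minimum", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(bhAdjust(0.03), 0.03)
  set.seed(12)
  for (i in 1:25) {
    p <- runif(sample(1:30, 1))
    adj <- bhAdjust(p)
    expect_equal(adj, bruteBH(p), tolerance = 1e-12)
    expect_true(all(adj >= p) && all(adj <= 1))
  }
  # permutation invariance (up to reordering)
  p <- runif(15)
  o <- sample(15)
  expect_equal(bhAdjust(p)[o], bhAdjust(p[o]))
  expect_error(bhAdjust(c(0.2, 1.3)), "within")
  expect_error(bhAdjust(c(0.2, NA)), "finite")
})

test_that("on/off lower limits use the detection-cutoff substitution", {
  cte <- makeCte(list(
    on = c(30, 30, NA, NA),
    off = c(NA, NA, 28, 28),
    boundary = c(34.5, 34.5, NA, NA),
    plain = c(30, 30, 30, 30)))
  on <- onoffLowerLimit(cte, "on", ctCutoff = 34.5)
  expect_equal(on$log2fc_lower_limit, 4.5)
  expect_equal(on$direction, "on_in_knockdown")
  expect_true(is.na(on$p))
  off <- onoffLowerLimit(cte, "off", ctCutoff = 34.5)
  expect_equal(off$log2fc_lower_limit, -6.5)
  expect_equal(off$direction, "off_in_knockdown")
  expect_equal(onoffLowerLimit(cte, "boundary", 34.5)$log2fc_lower_limit, 0)
  expect_error(onoffLowerLimit(cte, "plain", 34.5), "not an on/off")
})

test_that("duplicate concordance removes discordant miRNAs and collapses
           concordant ones", {
  de <- data.frame(
    feature_id = c("a", "a-2", "b", "b-2", "c"),
    log2fc = c(0.5, 0.2, 0.5, -0.3, 1.2),
    p = c(0.01, 0.04, 0.001, 0.2, 0.03),
    p_adj = c(0.05, 0.1, 0.01, 0.4, 0.09))
  dg <- c(a = "a", `a-2` = "a", b = "b", `b-2` = "b", c = "")
  nm <- c(a = "a", `a-2` = "a", b = "b", `b-2` = "b", c = "c")
  out <- duplicateConcordanceFilter(de, NULL, dg, nm)
  expect_setequal(out$mirna, c("a", "c"))       # b removed, discordant
  arow <- out[out$mirna == "a", ]
  expect_equal(arow$log2fc, 0.35)               # averaged
  expect_equal(arow$p, 0.01)                    # smaller p retained
  expect_equal(arow$concordance_flag, "collapsed")
  expect_equal(out$concordance_flag[out$mirna == "c"], "singleton")
})

test_that("concordance treats on/off records and mixed pairs by sign", {
  onoff <- data.frame(feature_id = c("x", "x-2"),
                      direction = "on_in_knockdown",
                      log2fc_lower_limit = c(4, 5), p = NA_real_)
  dg <- c(x = "x", `x-2` = "x")
  out <- duplicateConcordanceFilter(
    data.frame(feature_id = character(), log2fc = numeric(),
               p = numeric(), p_adj = numeric()),
    onoff, dg)
  expect_equal(nrow(out), 1)
  expect_equal(out$log2fc, 4.5)
  expect_equal(out$status, "on_off")
  # a tested + on/off pair with opposite signs is discordant
  de <- data.frame(feature_id = "y", log2fc = -0.4, p = 0.01, p_adj = 0.02)
  onoff2 <- data.frame(feature_id = "y-2", direction = "on_in_knockdown",
                       log2fc_lower_limit = 3, p = NA_real_)
  out2 <- duplicateConcordanceFilter(de, onoff2,
                                     c(y = "y", `y-2` = "y"))
  expect_equal(nrow(out2), 0)
})

test_that("candidate assembly unions raw-p significant and on/off rows", {
  prec <- data.frame(
    feature_id = c("s1", "s2", "ns", "oo"),
    mirna = c("s1", "s2", "ns", "oo"),
    status = c("tested", "tested", "tested", "on_off"),
    direction = c(NA, NA, NA, "off_in_knockdown"),
    log2fc = c(2, -1, 0.3, -4),
    p = c(0.01, 0.04, 0.5, NA),
    p_adj = c(0.1, 0.2, 0.9, NA),
    concordance_flag = "singleton", note = "")
  cand <- assembleCandidates(prec, alpha = 0.05)
  expect_equal(cand$mirna, c("s1", "s2", "oo"))  # sorted by log2fc desc
  expect_equal(cand$status, c("significant", "significant", "on_off"))
  # degenerate threshold keeps only on/off rows
  expect_equal(assembleCandidates(prec, alpha = 0)$mirna, "oo")
  # nothing significant and no on/off -> empty
  expect_equal(nrow(assembleCandidates(prec[3, ], alpha = 0.05)), 0)
})

test_that("replicate-probe consensus requires every probe significant with
           one sign", {
  de <- data.frame(
    feature_id = c("p1", "p2", "p3", "p4", "p5", "p6"),
    log2fc = c(1.0, 1.2, 0.8, -0.9, 2.0, 0.5),
    p = c(0.01, 0.04, 0.01, 0.20, 0.03, 0.01))
  map <- c(p1 = "gA", p2 = "gA", p3 = "gB", p4 = "gB", p5 = "gC",
           p6 = "gD", p7 = "gE")
  out <- replicateProbeConsensus(de, map, alpha = 0.05)
  expect_true(out$called[out$gene_id == "gA"])   # {0.01, 0.04} same sign
  expect_false(out$called[out$gene_id == "gB"])  # one probe at p = 0.20
  expect_true(out$called[out$gene_id == "gC"])   # single probe
  expect_equal(out$log2fc[out$gene_id == "gA"], 1.1)
  # discordant signs fail even when significant
  de2 <- data.frame(feature_id = c("p1", "p2"), log2fc = c(1, -1),
                    p = c(0.01, 0.01))
  expect_false(replicateProbeConsensus(de2, c(p1 = "g", p2 = "g"))$called)
  # unmapped probes are dropped with a warning
  expect_warning(replicateProbeConsensus(de, map[-1]), "without gene")
})
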