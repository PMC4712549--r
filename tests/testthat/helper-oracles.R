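# Independent brute-force oracles used to check the package implementations.
# These deliberately avoid the code paths they verify.

# BH step-up by direct enumeration of the defining minimum
bruteBH <- function(p) {
  n <- length(p)
  r <- rank(p, ties.method = "first")
  sapply(seq_len(n), function(i) {
    js <- which(r >= r[i])
    min(1, min(sort(p)[r[js]] * n / r[js]))
  })
}

# quantile normalization by explicit order-statistic averaging
bruteQuantile <- function(m) {
  meanstat <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    o <- order(m[, j])
    pos <- integer(nrow(m)); pos[o] <- seq_len(nrow(m))
    vals <- meanstat[pos]
    for (v in unique(m[, j])) {
      idx <- which(m[, j] == v)
      out[idx, j] <- mean(vals[idx])
    }
  }
  out
}

# classical pooled-variance two-sample t, coded independently
classicalT <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  sp2 <- (sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)) / (n1 + n2 - 2)
  (mean(x1) - mean(x2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# hypergeometric upper tail P(X >= k) by explicit summation of the pmf
bruteHyperTail <- function(k, K, N, n) {
  if (k <= 0) return(1)
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# exact two-sided Spearman p by exhaustive permutation, using cor() directly
bruteSpearmanP <- function(x, y) {
  n <- length(x)
  perms <- asplit(permuteAll(n), 1)
  rx <- rank(x); ry <- rank(y)
  obs <- abs(cor(rx, ry))
  hits <- vapply(perms, function(pm) abs(cor(rx, ry[pm])) >= obs - 1e-12,
                 logical(1))
  mean(hits)
}

permuteAll <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permuteAll(n - 1)
  out <- NULL
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# small hand-sized CT fixture: 4 assays x 4 samples, one duplicate pair
toyCtLong <- function() {
  samples <- c("KD1", "KD2", "CTRL1", "CTRL2")
  rows <- expand.grid(assay_id = c("mirA", "mirB", "mirB-2", "mirC"),
                      sample_id = samples, stringsAsFactors = FALSE)
  rows$mirna_name <- ifelse(rows$assay_id %in% c("mirB", "mirB-2"),
                            "mirB", rows$assay_id)
  rows$plate <- ifelse(rows$assay_id %in% c("mirA", "mirB"), "A", "B")
  rows$duplicate_group <- ifelse(rows$mirna_name == "mirB", "mirB", "")
  ct <- c(mirA = 25, mirB = 28, `mirB-2` = 28.2, mirC = 31)
  rows$ct <- ct[rows$assay_id] + (match(rows$sample_id, samples) - 1) * 0.1
  rows[, c("assay_id", "mirna_name", "plate", "sample_id", "ct",
           "duplicate_group")]
}

toySampleSheet <- function() {
  data.frame(sample_id = c("KD1", "KD2", "CTRL1", "CTRL2"),
             group = c("knockdown", "knockdown", "control", "control"),
             label = c("siFUS-1", "siFUS-2", "siNEG-1", "siNEG-2"),
             stringsAsFactors = FALSE)
}

# CtExperiment with fully controlled CT values: `ctRows` is a named list of
# length-4 numeric vectors (KD1, KD2, CTRL1, CTRL2); NA = undetermined
makeCte <- function(ctRows, plate = NULL, dupGroup = NULL) {
  ids <- names(ctRows)
  if (is.null(plate)) plate <- rep("A", length(ids))
  if (is.null(dupGroup)) dupGroup <- rep("", length(ids))
  long <- do.call(rbind, lapply(seq_along(ids), function(i)
    data.frame(assay_id = ids[i], mirna_name = sub("-2$", "", ids[i]),
               plate = plate[i],
               sample_id = c("KD1", "KD2", "CTRL1", "CTRL2"),
               ct = ctRows[[i]], duplicate_group = dupGroup[i],
               stringsAsFactors = FALSE)))
  CtExperiment(long, toySampleSheet())
}
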