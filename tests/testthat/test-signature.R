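test_that("composite score is the mean of per-gene z-scores", {
  mat <- toy_matrix(matrix(c(1, 2, 3, 4, 4, 4), 2, byrow = TRUE),
                    genes = c("G1", "G2"))
  sc <- composite_score(mat, gene_set("sig", c("G1", "G2")))
  expect_equal(sc$score, c(-0.5, 0, 0.5))
  one <- composite_score(mat, gene_set("sig", "G1"))
  expect_equal(one$score, c(-1, 0, 1))
})

test_that("composite score is invariant to per-gene positive affine maps", {
  set.seed(17)
  m <- matrix(rnorm(40, 10, 2), 4, dimnames = list(paste0("G", 1:4), NULL))
  mat <- toy_matrix(m, genes = rownames(m))
  sig <- gene_set("s", rownames(m))
  base <- composite_score(mat, sig)$score
  m2 <- m * runif(4, 0.5, 3) + rnorm(4)
  mat2 <- toy_matrix(m2, genes = rownames(m))
  expect_equal(composite_score(mat2, sig)$score, base, tolerance = 1e-12)
})

test_that("missing signature genes are skipped; none present is an error", {
  mat <- toy_matrix(matrix(1:6, 2), genes = c("A", "B"))
  expect_message(sc <- composite_score(mat, gene_set("s", c("A", "ZZ"))),
                 "absent")
  expect_equal(nrow(sc), 3L)
  expect_error(composite_score(mat, gene_set("s", "ZZ")), "no signature gene")
})

test_that("duplicated sample profiles co-cluster at distance zero", {
  m <- cbind(a = c(1, 5, 2, 7), b = c(1, 5, 2, 7), c = c(7, 1, 6, 0))
  rownames(m) <- paste0("G", 1:4)
  mat <- toy_matrix(m, genes = rownames(m), samples = colnames(m))
  hc <- hierarchical_cluster(mat, gene_set("s", rownames(m)))
  expect_equal(hc$clusters[["a"]], hc$clusters[["b"]])
  expect_false(hc$clusters[["a"]] == hc$clusters[["c"]])
  merge_h <- hc$hclust$height
  expect_equal(min(merge_h), 0, tolerance = 1e-12)
  expect_true(grepl("^\\(", hc$newick))
})

test_that("sample order does not change cluster membership", {
  set.seed(4)
  m <- matrix(rnorm(50, 5), 5, 10,
              dimnames = list(paste0("G", 1:5), paste0("s", 1:10)))
  m[, 6:10] <- m[, 6:10] + 4
  mat <- toy_matrix(m, genes = rownames(m), samples = colnames(m))
  sig <- gene_set("s", rownames(m))
  c1 <- hierarchical_cluster(mat, sig)$clusters
  perm <- sample(colnames(m))
  mat2 <- toy_matrix(m[, perm], genes = rownames(m), samples = perm)
  c2 <- hierarchical_cluster(mat2, sig)$clusters
  # same partition up to label swap
  agree <- mean(outer(c1[perm], c1[perm], "==") == outer(c2, c2, "=="))
  expect_equal(agree, 1)
})

test_that("contact samples cluster with the donor on simulated data", {
  hits <- 0L
  for (s in 1:10) {
    truth <- simulation_truth(seed = 300L + s)
    expr <- simulate_coculture(truth)
    lg <- normalize_log2cpm(expr)
    sig <- gene_set("transfer", truth$transfer_genes)
    cl <- hierarchical_cluster(lg, sig)$clusters
    cond <- lg$annotations$condition
    names(cond) <- colnames(lg$values)
    grp_of <- function(cnd) unique(cl[names(cond)[cond == cnd]])
    ok <- length(grp_of("donor_mono")) == 1 &&
      length(grp_of("recipient_cc")) == 1 &&
      grp_of("donor_mono") == grp_of("recipient_cc") &&
      all(!grp_of("recipient_mono") %in% grp_of("donor_mono")) &&
      all(!grp_of("recipient_cm") %in% grp_of("donor_mono"))
    hits <- hits + ok
  }
  expect_gte(hits, 9L)
})

test_that("ANOVA with Tukey matches direct sums-of-squares arithmetic", {
  set.seed(8)
  y <- rnorm(15, rep(c(0, 1, 3), each = 5))
  g <- rep(c("a", "b", "c"), each = 5)
  res <- anova_tukey(data.frame(score = y, group = g))
  grand <- mean(y)
  ssb <- sum(tapply(y, g, function(v) 5 * (mean(v) - grand)^2))
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  f_hand <- (ssb / 2) / (ssw / 12)
  expect_equal(res$F, f_hand, tolerance = 1e-8)
  expect_equal(res$p, pf(f_hand, 2, 12, lower.tail = FALSE), tolerance = 1e-8)
  # Tukey by hand: studentized range on one pair
  mse <- ssw / 12
  dab <- abs(mean(y[g == "b"]) - mean(y[g == "a"]))
  p_ab <- ptukey(dab / sqrt(mse / 5), nmeans = 3, df = 12, lower.tail = FALSE)
  row_ab <- res$pairwise[res$pairwise$comparison == "b-a", ]
  expect_equal(row_ab$adj_p, p_ab, tolerance = 1e-8)
})

test_that("ANOVA degenerate contracts: flat data and zero residual variance", {
  flat <- data.frame(score = rep(c(1, 2, 3), 3),
                     group = rep(c("a", "b", "c"), each = 3))
  res <- anova_tukey(flat)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
  expect_true(all(res$pairwise$adj_p == 1))
  sep <- data.frame(score = rep(c(0, 10, 0), each = 3),
                    group = rep(c("a", "b", "c"), each = 3))
  res2 <- anova_tukey(sep)
  expect_equal(res2$F, Inf)
  expect_equal(res2$p, .Machine$double.xmin)
  pw <- res2$pairwise
  expect_equal(pw$adj_p[pw$comparison == "b-a"], .Machine$double.xmin)
  expect_equal(pw$adj_p[pw$comparison == "c-a"], 1)
  expect_error(anova_tukey(data.frame(score = 1:3, group = c("a", "a", "b"))),
               ">= 2 samples")
})

test_that("roc_auc equals exhaustive pair counting with half-credit ties", {
  expect_equal(roc_auc(c(3, 5), c(1, 4)), 0.75)
  expect_equal(roc_auc(c(10, 11), c(1, 2)), 1)
  expect_equal(roc_auc(c(1, 2, 3), c(1, 2, 3)), 0.5)
  set.seed(12)
  for (i in 1:1000) {
    pos <- sample(0:5, sample(1:6, 1), replace = TRUE)
    neg <- sample(0:5, sample(1:6, 1), replace = TRUE)
    pairs <- outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n))
    expect_equal(roc_auc(pos, neg), mean(pairs), tolerance = 1e-12)
    expect_equal(roc_auc(pos, neg) + roc_auc(neg, pos), 1, tolerance = 1e-12)
  }
  expect_error(roc_auc(numeric(), 1), "non-empty")
})

test_that("refine_by_auc keeps genes above threshold in every dataset", {
  # two tiny datasets engineered to known AUCs via direct separation
  mk <- function(vals) {
    m <- rbind(G1 = vals$g1, G2 = vals$g2, G3 = vals$g3)
    toy_matrix(m, genes = rownames(m))
  }
  d1 <- mk(list(g1 = c(1, 1, 9, 9), g2 = c(1, 9, 1, 9), g3 = c(1, 1, 9, 9)))
  d2 <- mk(list(g1 = c(0, 0, 5, 5), g2 = c(0, 0, 5, 5), g3 = c(5, 5, 0, 0)))
  ds <- list(list(mat = d1, pos = c("s3", "s4"), neg = c("s1", "s2")),
             list(mat = d2, pos = c("s3", "s4"), neg = c("s1", "s2")))
  kept <- refine_by_auc(gene_set("c", c("G1", "G2", "G3")), ds, 0.85)
  expect_equal(kept$genes, "G1")
  # monotone: raising the threshold never adds genes
  kept_lo <- refine_by_auc(gene_set("c", c("G1", "G2", "G3")), ds, 0.51)
  expect_true(all(kept$genes %in% kept_lo$genes))
  # absent candidates are excluded with a warning
  expect_warning(
    out <- refine_by_auc(gene_set("c", c("G1", "MISSING")), ds, 0.85),
    "absent")
  expect_equal(out$genes, "G1")
})

test_that("refinement recovers planted candidates across two datasets", {
  truth <- simulation_truth()
  mk <- function(seed) {
    t2 <- truth
    t2$seed <- seed
    e <- simulate_coculture(t2)
    list(mat = normalize_log2cpm(e),
         pos = em_samples(e, "recipient_cc"),
         neg = em_samples(e, "recipient_mono"))
  }
  ds <- list(mk(101L), mk(102L))
  planted <- c(truth$transfer_genes, truth$intrinsic_genes, truth$cm_genes)
  null50 <- setdiff(truth$gene_ids, planted)[1:50]
  cand <- gene_set("cand", c(truth$transfer_genes, null50))
  kept <- refine_by_auc(cand, ds, 0.85)
  expect_gte(mean(truth$transfer_genes %in% kept$genes), 0.9)
  expect_lte(mean(null50 %in% kept$genes), 0.1)
})

test_that("recapitulation fractions count perfectly separating genes", {
  m <- rbind(G1 = c(1, 1, 9, 9), G2 = c(5, 9, 1, 9), G3 = c(2, 2, 8, 8))
  mat <- toy_matrix(m, genes = rownames(m))
  part <- classify_induced(c("G1", "G2"), character(), c("G1", "G2"))
  rec <- recapitulation_fraction(mat, c("s1", "s2"), c("s3", "s4"), part)
  expect_equal(rec$recap_borrowed$genes, "G1")
  expect_equal(unname(rec$fractions["borrowed"]), 0.5)
  expect_true(is.na(rec$fractions["intrinsic"]))
})

test_that("a planted 20% perturbation is recovered to within 5 points", {
  fracs <- vapply(1:10, function(s) {
    set.seed(600 + s)
    genes <- sprintf("G%03d", 1:100)
    hit <- sample(genes, 20)
    m <- matrix(rnorm(100 * 8, 5, 1), 100, dimnames = list(genes, NULL))
    m[hit, 5:8] <- m[hit, 5:8] + 6
    mat <- toy_matrix(m, genes = genes)
    part <- classify_induced(genes, character(), genes)
    rec <- recapitulation_fraction(mat, paste0("s", 1:4), paste0("s", 5:8),
                                   part)
    unname(rec$fractions["borrowed"])
  }, numeric(1))
  expect_lte(abs(mean(fracs) - 0.2), 0.05)
})

test_that("ORA p-values share the hypergeometric core and BH across sets", {
  uni <- sprintf("U%02d", 1:10)
  q <- gene_set("q", uni[1:5])
  hit <- gene_set("hit", uni[1:5])
  miss <- gene_set("miss", c("Z1", "Z2"))
  tab <- ora_enrichment(q, list(hit, miss), uni)
  expect_equal(tab$p[1], 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(tab$overlap_k[2], 0L)
  expect_equal(tab$p[2], 1)
  expect_equal(tab$adj_p, bh_adjust(tab$p))
  expect_equal(tab$p[1], hypergeom_upper(5, 5, 5, 10), tolerance = 1e-15)
  # duplicated collections give identical rows
  tab2 <- ora_enrichment(q, list(hit, hit), uni)
  expect_equal(tab2$p[1], tab2$p[2])
  expect_warning(ora_enrichment(gene_set("q", c(uni[1], "OUT")), list(hit), uni),
                 "outside")
  expect_error(ora_enrichment(q, list(hit), character()), "empty")
})
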