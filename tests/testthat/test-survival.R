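test_that("step fit solves zero-error and hand-checked splits", {
  f <- fit_step_threshold(c(1, 1, 1, 9, 9))
  expect_equal(f$split_index, 3L)
  expect_equal(f$threshold, 5)
  expect_equal(f$sse, 0, tolerance = 1e-12)
  g <- fit_step_threshold(c(9, 1, 8, 2))  # order-free
  expect_equal(g$split_index, 2L)
  expect_equal(c(g$low_mean, g$high_mean), c(1.5, 8.5))
  expect_equal(g$threshold, 5)
  expect_equal(g$sse, 1, tolerance = 1e-12)
})

test_that("constant input is flagged degenerate", {
  f <- fit_step_threshold(rep(2.5, 4))
  expect_true(f$degenerate)
  expect_equal(f$threshold, 2.5)
  expect_error(fit_step_threshold(numeric()), "empty")
})

test_that("step fit equals brute-force split search on random vectors", {
  brute <- function(v) {
    v <- sort(v)
    n <- length(v)
    best <- NULL
    for (i in 1:(n - 1)) {
      sse <- sum((v[1:i] - mean(v[1:i]))^2) +
        sum((v[(i + 1):n] - mean(v[(i + 1):n]))^2)
      if (is.null(best) || sse < best$sse - 1e-12) best <- list(i = i, sse = sse)
    }
    best
  }
  set.seed(77)
  for (r in 1:1000) {
    v <- rnorm(sample(3:200, 1), sd = sample(c(0.5, 2), 1))
    f <- fit_step_threshold(v)
    b <- brute(v)
    expect_equal(f$sse, b$sse, tolerance = 1e-8)
    expect_equal(f$split_index, b$i)
  }
})

test_that("KM product-limit matches hand arithmetic", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0), tolerance = 1e-12)
  km2 <- km_estimate(c(1, 1, 2), c(1, 1, 1))
  expect_equal(km2$surv[km2$time == 1], 1 / 3, tolerance = 1e-12)
  cens <- km_estimate(c(5, 6, 7), c(0, 0, 0))
  expect_true(all(cens$surv == 1))
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(14)
  for (r in 1:20) {
    t_ <- sample(1:30, sample(3:25, 1), replace = TRUE)
    km <- km_estimate(t_, rep(1, length(t_)))
    emp <- vapply(km$time, function(u) mean(t_ > u), numeric(1))
    expect_equal(km$surv, emp, tolerance = 1e-12)
  }
})

test_that("log-rank matches a direct observed-minus-expected accumulation", {
  ta <- c(2, 4, 5, 7, 9, 12); ea <- c(1, 1, 0, 1, 0, 1)
  tb <- c(1, 3, 6, 8, 10, 11); eb <- c(1, 0, 1, 1, 1, 0)
  res <- logrank_test(ta, ea, tb, eb)
  # independent accumulation over distinct event times
  time <- c(ta, tb); event <- c(ea, eb)
  grp <- rep(c(0, 1), each = 6)
  o_minus_e <- 0; v <- 0
  for (u in sort(unique(time[event == 1]))) {
    at_risk <- time >= u
    n <- sum(at_risk); n1 <- sum(at_risk & grp == 1)
    d <- sum(time == u & event == 1)
    d1 <- sum(time == u & event == 1 & grp == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  expect_equal(res$chi2, o_minus_e^2 / v, tolerance = 1e-10)
})

test_that("log-rank symmetry, null identity and time-shift invariance", {
  t_ <- c(3, 5, 8, 11); e_ <- c(1, 0, 1, 1)
  same <- logrank_test(t_, e_, t_, e_)
  expect_equal(same$chi2, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)
  t2 <- c(1, 2, 3, 9); e2 <- c(1, 1, 0, 1)
  ab <- logrank_test(t_, e_, t2, e2)
  ba <- logrank_test(t2, e2, t_, e_)
  expect_equal(ab$chi2, ba$chi2, tolerance = 1e-12)
  shifted <- logrank_test(t_ + 100, e_, t2 + 100, e2)
  expect_equal(ab$chi2, shifted$chi2, tolerance = 1e-12)
})

test_that("stratified survival separates a bimodal cohort exactly", {
  set.seed(31)
  n <- 40
  state <- rep(c(0, 1), each = n / 2)
  genes <- paste0("G", 1:5)
  expr <- matrix(rnorm(5 * n, 5, 0.2), 5,
                 dimnames = list(genes, sprintf("p%02d", 1:n)))
  expr[, state == 1] <- expr[, state == 1] + 10
  ct <- cohort_table(
    data.frame(patient_id = colnames(expr), time = rexp(n, 0.02),
               event = rbinom(n, 1, 0.7)), expr)
  sv <- stratified_survival(ct, gene_set("s", genes), method = "step")
  expect_equal(unname(sv$groups == "high"), state == 1)
  expect_equal(sv$n_high, n / 2)
})

test_that("median stratification puts the median patient in the low group", {
  n <- 5
  expr <- matrix(c(1, 2, 3, 4, 5), 1,
                 dimnames = list("G1", paste0("p", 1:n)))
  ct <- cohort_table(
    data.frame(patient_id = paste0("p", 1:n), time = 1:5,
               event = rep(1, n)), expr)
  sv <- stratified_survival(ct, gene_set("s", "G1"), method = "median")
  expect_equal(sv$n_low, 3L)
  expect_equal(sv$n_high, 2L)
  expect_equal(unname(sv$groups[3]), factor("low", levels = c("low", "high")))
})

test_that("a hazard-ratio-2 cohort is detected by the full stratification", {
  hits <- 0L
  for (s in 1:10) {
    truth <- simulation_truth(seed = 7000L + s)
    sig <- gene_set("sig", truth$transfer_genes[1:20])
    ct <- simulate_cohort(truth, sig)
    sv <- stratified_survival(ct, sig, method = "step")
    hits <- hits + (sv$logrank$p < 0.05)
  }
  expect_gte(hits, 9L)
})
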