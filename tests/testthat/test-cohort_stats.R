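test_that("Kaplan-Meier matches the hand product-limit on toy data", {
  km <- km_estimate(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(km$curve$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(unname(km$median), 2)
  # no events: S identically 1, median undefined
  km0 <- km_estimate(c(5, 7, 9), c(FALSE, FALSE, FALSE))
  expect_true(all(km0$curve$surv == 1) || nrow(km0$curve) == 0)
  expect_true(is.na(km0$median))
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(4)
  t <- sort(stats::rexp(40, 0.2))
  km <- km_estimate(t, rep(TRUE, 40))
  emp <- vapply(km$curve$time, function(tt) mean(t > tt), numeric(1))
  expect_equal(km$curve$surv, emp)
})

test_that("KM median approaches the closed form on exponential data", {
  set.seed(8)
  t <- stats::rexp(500, rate = 0.1)
  km <- km_estimate(t, rep(TRUE, 500))
  expect_lt(abs(unname(km$median) - log(2) / 0.1) / (log(2) / 0.1), 0.10)
})

test_that("log-rank equals the hand-computed hypergeometric sum", {
  # toy data: group A events at 2,4,6; group B events at 8,10,12
  time <- c(2, 4, 6, 8, 10, 12)
  event <- rep(TRUE, 6)
  group <- rep(c("A", "B"), each = 3)
  # independent hand computation of sum(O-E) and its variance
  o_minus_e <- 0; v <- 0
  for (tt in sort(unique(time))) {
    at_risk <- time >= tt
    n <- sum(at_risk); n_a <- sum(at_risk & group == "A")
    d <- sum(time == tt & event)
    d_a <- sum(time == tt & event & group == "A")
    o_minus_e <- o_minus_e + d_a - d * n_a / n
    if (n > 1) v <- v + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
  }
  expected_chisq <- o_minus_e^2 / v
  lr <- logrank_test(time, event, group)
  expect_equal(lr$statistic, expected_chisq, tolerance = 1e-10)
  # label swap leaves statistic and p unchanged
  lr2 <- logrank_test(time, event, rev(group))
  expect_equal(lr2$statistic, lr$statistic)
  expect_equal(lr2$p.value, lr$p.value)
})

test_that("log-rank on identical groups is null", {
  time <- rep(c(3, 6, 9), 2)
  event <- rep(TRUE, 6)
  group <- rep(c("A", "B"), 3) # same event times in both groups
  lr <- logrank_test(time, event, group)
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p.value, 1, tolerance = 1e-12)
  expect_error(logrank_test(c(1, 2), c(TRUE, TRUE), c("A", "A")),
               "two")
  expect_error(logrank_test(c(1, 2), c(FALSE, FALSE), c("A", "B")),
               "event")
})

test_that("correlations: identity, constants and rank equivalence", {
  x <- c(1, 3, 5, 7, 9)
  expect_equal(correlate(x, x)$estimate, 1)
  expect_error(correlate(rep(2, 5), x), "constant")
  expect_error(correlate(1:2, 2:3), "3 complete pairs")
  # Spearman equals Pearson on (tie-corrected) ranks
  set.seed(10)
  for (i in 1:5) {
    a <- stats::rnorm(30); b <- a + stats::rnorm(30)
    sp <- correlate(a, b, method = "spearman")$estimate
    pr <- stats::cor(rank(a), rank(b))
    expect_equal(sp, pr, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney exact p equals full-permutation enumeration", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(mw$U), 0)
  expect_true(mw$exact)
  # full enumeration over all assignments of ranks to group 1
  enum_p <- function(x, y) {
    m <- length(x); pooled <- c(x, y)
    u_obs <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    combs <- utils::combn(length(pooled), m)
    us <- apply(combs, 2, function(idx) {
      xx <- pooled[idx]; yy <- pooled[-idx]
      sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
    })
    mean_u <- m * (length(pooled) - m) / 2
    mean(abs(us - mean_u) >= abs(u_obs - mean_u) - 1e-9)
  }
  expect_equal(mw$p.value, enum_p(c(1, 2, 3), c(4, 5, 6)))
  set.seed(3)
  for (i in 1:5) {
    x <- sample(100, 4); y <- sample(200, 4) + 0.5
    expect_equal(mann_whitney(x, y)$p.value, enum_p(x, y),
                 tolerance = 1e-9)
  }
})

test_that("2x2 association picks Fisher or chi-square by expected counts", {
  # mutation detection by liver metastasis: 68/71 vs 16/22
  tab <- matrix(c(68, 3, 16, 6), nrow = 2, byrow = TRUE)
  res <- assoc_2x2(tab, both = TRUE)
  expect_true(min(res$expected) < 5)
  expect_equal(res$test_used, "fisher")
  expect_lt(res$p.value, 0.05)
  expect_lt(res$p_chisq, 0.05)
  # large balanced table: chi-square
  big <- matrix(c(50, 50, 30, 70), nrow = 2, byrow = TRUE)
  expect_equal(assoc_2x2(big)$test_used, "chisq")
  expect_error(assoc_2x2(matrix(1:6, 2)), "2x2")
})

test_that("frequency tables count mutations and patients per gene", {
  calls <- tibble::tibble(
    patient_id = c("P1", "P1", "P2", "P3", "P3"),
    gene = c("APC", "APC", "APC", "TP53", "MAP2K1"))
  patients <- tibble::tibble(patient_id = c("P1", "P2", "P3", "P4"),
                             panel_version = c("v3", "v3", "v3", "v2"))
  fr <- summarize_frequencies(calls, patients)
  apc <- fr$table[fr$table$gene == "APC", ]
  expect_equal(apc$n_mutations, 3)
  expect_equal(apc$n_patients, 2)
  expect_equal(apc$pct_patients, 50) # 2 of 4 patients
  # v3-only gene percentages use the v3 denominator
  m2k <- fr$table[fr$table$gene == "MAP2K1", ]
  expect_true(m2k$panel_restricted)
  expect_equal(m2k$pct_patients, 33.3) # 1 of 3 v3 patients
  expect_equal(fr$total_mutations, 5)
  expect_equal(fr$n_positive, 3)
  expect_equal(fr$mean_mutations_per_positive, 5 / 3)
})

test_that("exact binomial power matches direct binom.test enumeration", {
  # independent oracle: call binom.test for every outcome
  oracle_power <- function(p0, p1, n, alpha) {
    rej <- vapply(0:n, function(x)
      stats::binom.test(x, n, p0)$p.value <= alpha, logical(1))
    sum(stats::dbinom((0:n)[rej], n, p1))
  }
  for (n in c(10, 35, 78))
    expect_equal(binomial_power(0.7, 0.9, n, 0.05),
                 oracle_power(0.7, 0.9, n, 0.05), tolerance = 1e-12)
  # n = 1: enumerate by hand; a single trial cannot reject at 5%
  expect_equal(binomial_power(0.5, 0.9, 1, 0.05),
               oracle_power(0.5, 0.9, 1, 0.05))
  # under the null the rejection rate is bounded by alpha
  expect_lte(binomial_power(0.7, 0.7 + 1e-12, 50, 0.05), 0.05)
  # power rises with n up to the exact test's discreteness sawtooth:
  # between jumps of the critical value the power declines slightly, so
  # strict monotonicity cannot hold; the dips are bounded and the
  # envelope climbs from ~0.35 to ~1 over the grid
  pw <- vapply(10:100, function(n) binomial_power(0.7, 0.9, n, 0.05),
               numeric(1))
  expect_true(all(diff(pw) > -0.05))
  expect_true(all(diff(cummax(pw)) >= 0))
  expect_lt(pw[1], 0.5)
  expect_gt(pw[length(pw)], 0.99)
  expect_error(binomial_power(0, 0.9, 10), "strictly")
  # design-stage helper: prevalence-scaled evaluable n
  expect_equal(n_evaluable(93, 0.4), 37)
})
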