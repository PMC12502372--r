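test_that("Mann-Whitney exact p matches enumeration on the canonical example", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 2 / 6)
  expect_equal(r$method, "exact")

  # symmetry: swapping samples and shifting both leaves the exact p unchanged
  expect_equal(mann_whitney_u(c(3, 4), c(1, 2))$p, 2 / 6)
  expect_equal(mann_whitney_u(c(11, 12), c(13, 14))$p, 2 / 6)
})

test_that("identical samples give p = 1 and ties route to the corrected normal branch", {
  r <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$p, 1)
  expect_equal(r$method, "normal")
  expect_error(mann_whitney_u(numeric(0), 1), "empty")
  expect_error(mann_whitney_u(c(1, 1), c(1, 1)), "variance")
})

test_that("exact and approximate Mann-Whitney agree with oracles on random tie-free samples", {
  set.seed(201)
  for (i in 1:40) {
    n1 <- sample(2:5, 1L); n2 <- sample(2:5, 1L)
    vals <- sample(1:100, n1 + n2)
    x <- vals[seq_len(n1)]; y <- vals[-seq_len(n1)]
    got <- mann_whitney_u(x, y)
    expect_equal(got$method, "exact")
    expect_equal(got$p, oracle_mwu_exact(x, y))
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(got$p, ref$p.value)
    expect_equal(got$statistic, unname(ref$statistic))
  }
})

test_that("normal approximation tracks the exact p for n = m = 6", {
  # every rank configuration at n = m = 6; full enumeration puts the true
  # maximum |p_normal - p_exact| at 0.0155 (attained at U = 12/24), so the
  # continuity-corrected approximation stays within 0.016 of exact
  subsets <- utils::combn(12L, 6L)
  worst <- 0
  for (j in seq_len(ncol(subsets))) {
    x <- subsets[, j]; y <- setdiff(1:12, x)
    pe <- mann_whitney_u(x, y, method = "exact")$p
    pn <- mann_whitney_u(x, y, method = "normal")$p
    worst <- max(worst, abs(pe - pn))
  }
  expect_lt(worst, 0.016)
})

test_that("BH adjustment reproduces the step-up closed form", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4L))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(202)
  for (i in 1:100) {
    p <- stats::runif(sample(1:40, 1L))
    q <- bh_adjust(p)
    expect_equal(q, stats::p.adjust(p, method = "BH"))
    expect_true(all(q <= 1) && all(q >= p))
  }
  expect_error(bh_adjust(c(0.5, 0)), "p-values")
})

test_that("effect sizes follow their definitions with log2FC-to-d fallback", {
  expect_equal(log2fc_of_means(c(2, 2), c(1, 1)), 1)
  expect_equal(log2fc_of_means(1:3, 1:3), 0)
  expect_equal(log2fc_of_means(c(1, 1), c(4, 4)), -2)

  expect_equal(cohens_d(c(1, 2, 3), c(2, 3, 4)), -1)
  expect_equal(cohens_d(c(2, 3, 4), c(1, 2, 3)), 1)
  expect_equal(cohens_d(1:4, 1:4), 0)
  expect_error(cohens_d(c(1, 1), c(1, 1)), "zero")

  # fallback engages exactly when a mean is non-positive
  es <- effect_size(c(-1, 0, 1), c(1, 2, 3))
  expect_equal(es$effect_kind, "cohens_d")
  expect_equal(es$effect, cohens_d(c(-1, 0, 1), c(1, 2, 3)))
  es2 <- effect_size(c(2, 4), c(1, 1))
  expect_equal(es2$effect_kind, "log2fc")

  set.seed(203)
  x <- rnorm(20); y <- rnorm(20)
  d <- cohens_d(x, y)
  num <- mean(x) - mean(y)
  sp <- sqrt((19 * var(x) + 19 * var(y)) / 38)
  expect_equal(d, num / sp, tolerance = 1e-12)
  expect_equal(cohens_d(y, x), -d)
})

test_that("significance labels use strict cuts in both schemes", {
  expect_equal(significance_label(0.2), "ns")
  expect_equal(significance_label(0.0005), "***")
  expect_equal(significance_label(0.05), "ns")      # at the cut: less significant
  expect_equal(significance_label(0.049999), "*")
  expect_equal(significance_label(0.2, "printed"), "*")
  expect_equal(significance_label(0.0005, "printed"), "****")
  expect_equal(significance_label(c(1, 1e-9)), c("ns", "****"))
})

test_that("Pearson matrix matches the textbook formula and flags constant columns", {
  set.seed(204)
  m <- matrix(rpois(50 * 20, 3), nrow = 50,
              dimnames = list(NULL, rgcontext::AA20))
  r <- pearson_matrix(m)
  expect_equal(r, t(r), ignore_attr = TRUE)
  expect_equal(unname(diag(r)), rep(1, 20))
  for (pair in list(c("A", "C"), c("R", "G"), c("F", "Y"))) {
    expect_equal(r[pair[1L], pair[2L]],
                 oracle_pearson(m[, pair[1L]], m[, pair[2L]]),
                 tolerance = 1e-12)
  }

  m2 <- cbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1),
              k = c(5, 5, 5, 5))
  r2 <- pearson_matrix(m2)
  expect_equal(r2["a", "b"], 1)
  expect_equal(r2["a", "c"], -1)
  expect_true(is.na(r2["a", "k"]))
  expect_equal(attr(r2, "constant_columns"), "k")
  expect_error(pearson_matrix(m2[1:2, ]), "at least 3")
})
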