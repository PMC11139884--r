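test_that("exact Mann-Whitney p matches full enumeration and wilcox.test", {
  r <- mann_whitney_assoc(c(1, 2, 3, 4), c("a", "a", "b", "b"), B = 50)
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)

  # property: for all small two-group inputs the exact p equals the
  # enumeration oracle (wilcox.test exact, no ties)
  set.seed(7)
  for (i in 1:25) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- sample(100, n1); y <- sample(100, n2) + 0.5  # tie-free
    r <- mann_whitney_assoc(c(x, y), rep(c("g1", "g2"), c(n1, n2)), B = 10)
    w <- wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(r$p_value, w, tolerance = 1e-10,
                 info = paste("n1", n1, "n2", n2))
  }
})

test_that("normal approximation agrees with wilcox.test under ties", {
  set.seed(11)
  x <- round(rnorm(30), 1); y <- round(rnorm(40, 0.4), 1)
  r <- mann_whitney_assoc(c(x, y), rep(c("g1", "g2"), c(30, 40)), B = 10)
  w <- wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  expect_equal(r$p_value, w, tolerance = 1e-10)
})

test_that("effect size follows the group1 - group2 pooled-sd convention", {
  expect_equal(cohens_d(c(5, 5, 5), c(5, 5, 5)), 0)
  set.seed(3)
  x <- rnorm(2000, 0, 1); y <- rnorm(2000, 1, 1)
  expect_equal(cohens_d(x, y), -1, tolerance = 0.1)
  # d = 0 iff equal sample means
  a <- c(1, 2, 3); bb <- c(0, 2, 4)
  expect_equal(cohens_d(a, bb), 0)
})

test_that("null p-values are uniform (KS check)", {
  set.seed(5)
  ps <- replicate(400, {
    v <- rnorm(40)
    g <- rep(c("a", "b"), 20)
    ptsdlang:::u_normal_p(v[g == "a"], v[g == "b"])
  })
  # U is integer-valued, so replicate p-values repeat; the KS distance is
  # still the right uniformity summary
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("Monte-Carlo power is monotone in |d| and n", {
  pw <- function(d, n) ptsdlang:::mc_power_u(d, n, n, B = 400, seed = 9)
  grid_d <- vapply(c(0.2, 0.5, 1.0, 1.5), pw, 0, n = 30)
  expect_true(all(diff(grid_d) >= -0.02))
  grid_n <- vapply(c(10, 30, 80), function(n) pw(0.5, n), 0)
  expect_true(all(diff(grid_n) >= -0.02))
  expect_true(all(c(grid_d, grid_n) >= 0 & c(grid_d, grid_n) <= 1))
})

test_that("ANOVA screen: identical groups give F = 0, separation is detected", {
  r <- anova_assoc(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3), B = 20)
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1, tolerance = 1e-12)

  set.seed(13)
  v2 <- c(rnorm(30), rnorm(30), rnorm(30, 3))
  g2 <- rep(c("a", "b", "c"), each = 30)
  r2 <- anova_assoc(v2, g2, B = 20)
  expect_lt(r2$p_value, 1e-6)
  expect_true(r2$effect_size > 0 && r2$effect_size < 1)

  expect_error(anova_assoc(rnorm(10), rep(c("a", "b"), 5)), "3 groups")
  # zero variance everywhere, unequal means: degenerate flag
  r3 <- anova_assoc(rep(c(0, 0, 1), each = 3), rep(c("a", "b", "c"), each = 3),
                    B = 10)
  expect_true(isTRUE(r3$degenerate))
  expect_equal(r3$p_value, 0)
})

test_that("chi-squared screen handles 2x2 correction and validates input", {
  r <- chi2_assoc(matrix(10, 2, 2), B = 20)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # cohort sex-by-exposure table reconstructed from printed percentages
  tab <- matrix(c(61, 49, 26, 12), 2,
                dimnames = list(c("F", "M"), c("A1", "A2")))
  r2 <- chi2_assoc(tab, B = 50)
  expect_equal(r2$p_value, 0.22, tolerance = 0.05)
  expect_error(chi2_assoc(matrix(c(1, 2), 1)), "2x2")
  expect_error(chi2_assoc(matrix(c(0, 0, 1, 2), 2)), "marginal")
})

test_that("association screen flags planted features and calibrates nulls", {
  b <- syn_planted_bundle()
  lab <- diagnosis_label(b$metadata)
  at <- association_table(b$features, lab, B = 30)
  expect_equal(nrow(at), 81)
  planted <- c("model_death", "model_body", "model_physical_sensations")
  expect_true(all(at$p_value[at$feature %in% planted] < 0.01))
  expect_true(all(at$significant[at$feature %in% planted]))
  # elevated in the symptomatic group (group 2): negative d
  expect_true(all(at$effect_size[at$feature %in% planted] < 0))

  # shuffled labels: close to nominal type-I rate
  set.seed(77)
  sh <- lab; names(sh) <- sample(names(sh))
  at2 <- association_table(b$features, sh, B = 5)
  expect_lt(mean(at2$significant), 0.15)

  empty <- association_table(b$features[, "doc_id", drop = FALSE], lab, B = 5)
  expect_equal(nrow(empty), 0)

  expect_error(association_table(b$features, lab[1:10]), "missing")
})
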