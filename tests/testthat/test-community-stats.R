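test_that("alpha diversity matches closed forms", {
  expect_equal(alpha_diversity(rep(5, 8), "shannon"), log(8))
  expect_equal(alpha_diversity(c(0, 10, 0), "shannon"), 0)
  expect_equal(alpha_diversity(c(0, 10, 0), "invsimpson"), 1)
  expect_equal(alpha_diversity(rep(3, 5), "invsimpson"), 5)
  expect_equal(alpha_diversity(rep(2, 6), "pielou"), 1)
  expect_equal(alpha_diversity(c(1, 2, 3, 0), "richness"), 3)
  expect_error(alpha_diversity(c(0, 0), "shannon"), "zero total")
})

test_that("the correlation-method heuristic reports failing criteria", {
  pick <- choose_correlation_method(20, 0.3, TRUE)
  expect_equal(pick$method, "LSA")
  expect_length(pick$failed_criteria, 0)
  expect_match(choose_correlation_method(5, 0.3, TRUE)$failed_criteria,
               "neff", all = FALSE)
  expect_match(choose_correlation_method(20, 0.8, TRUE)$failed_criteria,
               "sparsity", all = FALSE)
  expect_match(choose_correlation_method(20, 0.3, FALSE)$failed_criteria,
               "time series", all = FALSE)
  expect_equal(effective_species(rep(4, 20)), 20)
})

test_that("Bray-Curtis follows its formula and bounds", {
  tab <- make_table(cbind(a = c(6, 2), b = c(2, 2), c = c(6, 2),
                          d = c(0, 4)), asv = c("x", "y"))
  d <- as.matrix(bray_curtis(tab))
  expect_equal(d["a", "b"], 4 / 12)
  expect_equal(d["a", "c"], 0)
  expect_equal(d["b", "d"], (2 + 2) / (2 + 6))
  disjoint <- make_table(cbind(s1 = c(5, 0), s2 = c(0, 7)))
  expect_equal(as.matrix(bray_curtis(disjoint))[1, 2], 1)
  expect_error(bray_curtis(make_table(cbind(s1 = c(1, 1), s2 = c(0, 0)))),
               "zero total")
})

test_that("UPGMA reproduces hand agglomeration and ultrametric input", {
  d <- as.dist(matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
                      dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
  tr <- upgma_tree(d)
  co <- cophenetic_distances(tr)
  expect_equal(co["A", "B"], 2)
  expect_equal(co["A", "C"], 6)
  expect_equal(co["B", "C"], 6)
  # ultrametric input is reproduced exactly
  expect_equal(co[c("A", "B", "C"), c("A", "B", "C")],
               as.matrix(d)[c("A", "B", "C"), c("A", "B", "C")])
  two <- as.dist(matrix(c(0, 3, 3, 0), 2, dimnames = list(c("x", "y"),
                                                          c("x", "y"))))
  co2 <- cophenetic_distances(upgma_tree(two))
  expect_equal(co2["x", "y"], 3)
  expect_error(upgma_tree(dist(1)), "two samples")
})

test_that("ANOSIM attains R = 1 for perfectly separated groups", {
  m <- matrix(1, 6, 6) - diag(6)
  m[1:3, 1:3] <- 0
  m[4:6, 4:6] <- 0
  groups <- rep(c("g1", "g2"), each = 3)
  r <- anosim_test(as.dist(m), groups, n_perm = 199, seed = 5)
  expect_equal(r$observed, 1)
  expect_gte(r$p_value, 1 / 200)
  r2 <- anosim_test(as.dist(m), groups, n_perm = 199, seed = 5)
  expect_identical(r$p_value, r2$p_value)
  expect_error(anosim_test(as.dist(m), rep("g1", 6)), "two groups")
})

test_that("PERMANOVA separates tight clusters at the permutation floor", {
  set.seed(8)
  x <- cbind(matrix(rnorm(10 * 3, 1, 0.01), ncol = 10),
             matrix(rnorm(10 * 3, 5, 0.01), ncol = 10))
  tab <- make_table(round(abs(x) * 100))
  d <- bray_curtis(tab)
  groups <- rep(c("a", "b"), each = 10)
  r <- permanova_test(d, groups, n_perm = 999, seed = 2)
  expect_equal(r$p_value, 1 / 1000)
  expect_gt(r$r_squared, 0.9)
  expect_lte(r$r_squared, 1)
})

test_that("MRPP yields delta 0 and A 1 for zero within-group distances", {
  m <- matrix(1, 6, 6) - diag(6)
  m[1:3, 1:3] <- 0
  m[4:6, 4:6] <- 0
  r <- mrpp_test(as.dist(m), rep(c("g1", "g2"), each = 3), n_perm = 99,
                 seed = 3)
  expect_equal(r$delta, 0)
  expect_equal(r$A, 1)
})

test_that("Mantel recovers identical and monotone-related matrices", {
  set.seed(13)
  d1 <- dist(matrix(rnorm(30), 10))
  expect_equal(mantel_test(d1, d1, n_perm = 99, seed = 1)$observed, 1)
  expect_equal(mantel_test(d1, d1^2, method = "spearman", n_perm = 99,
                           seed = 1)$observed, 1)
  expect_error(mantel_test(d1, dist(matrix(rnorm(12), 4))), "different")
})

test_that("VIF screening drops collinear and keeps independent variables", {
  set.seed(31)
  n <- 100
  x1 <- as.numeric(scale(rnorm(n)))
  e <- as.numeric(scale(residuals(lm(rnorm(n) ~ x1))))
  env <- data.frame(v1 = x1, v2 = 0.9 * x1 + sqrt(1 - 0.81) * e)
  out <- vif_screen(env, threshold = 20)
  expect_setequal(out$retained, c("v1", "v2"))
  expect_equal(unname(out$vif["v1"]), 1 / (1 - 0.81), tolerance = 1e-6)

  dup <- data.frame(a = x1, b = x1, c = rnorm(n))
  out2 <- vif_screen(dup, threshold = 20)
  expect_length(out2$dropped, 1)
  expect_true(out2$dropped %in% c("a", "b"))

  ortho <- data.frame(p = x1, q = e)
  out3 <- vif_screen(ortho, threshold = 20)
  expect_equal(unname(out3$vif), c(1, 1), tolerance = 1e-9)
})
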