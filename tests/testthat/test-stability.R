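# Unit tests for the five stability estimators on hand-computable cases.

test_that("bestkeeper reproduces hand-computed SD and CV", {
  mat <- rbind(flat = rep(20, 6), vari = 15:20)
  res <- bestkeeper(matrix_ct_table(mat))
  expect_equal(unname(res$scores["flat"]), 0)
  expect_equal(unname(res$meta$cv_pct["flat"]), 0)
  expect_true(res$meta$accepted["flat"])
  expect_equal(unname(res$scores["vari"]), 1.8708, tolerance = 1e-4)
  expect_equal(unname(res$meta$cv_pct["vari"]), 10.69, tolerance = 1e-3)
  expect_false(res$meta$accepted["vari"])   # SD > 1 cycle
  expect_equal(res$ranking, c("flat", "vari"))
})

test_that("bestkeeper offers the geometric-mean MAD variant", {
  mat <- rbind(a = c(18, 20, 22), b = c(20, 20, 20))
  res <- bestkeeper(matrix_ct_table(mat), dispersion = "mad_geomean")
  gm <- exp(mean(log(c(18, 20, 22))))
  expect_equal(unname(res$scores["a"]), mean(abs(c(18, 20, 22) - gm)))
  expect_equal(unname(res$scores["b"]), 0)
})

test_that("cv method matches the hand computation on (20,21,22)", {
  mat <- rbind(g = c(20, 21, 22), h = c(25, 25, 25), i = c(30, 31, 30))
  res <- cv_method(matrix_ct_table(mat))
  # Q = (1, 0.5, 0.25): SD 0.38188, mean 0.58333
  expect_equal(unname(res$scores["g"]), 65.465, tolerance = 1e-3)
  expect_equal(unname(res$scores["h"]), 0)
})

test_that("delta-Ct scores match the brute-force three-gene example", {
  mat <- rbind(A = c(20, 21, 22), B = c(25, 26, 27), C = c(30, 30, 31))
  res <- delta_ct_method(matrix_ct_table(mat))
  expect_equal(unname(res$scores["A"]), 0.28868, tolerance = 1e-4)
  expect_equal(unname(res$scores["B"]), 0.28868, tolerance = 1e-4)
  expect_equal(unname(res$scores["C"]), 0.57735, tolerance = 1e-4)
  expect_equal(res$ranking[3], "C")
})

test_that("perfectly co-varying genes score zero in co-variation methods", {
  base <- c(20, 21.5, 19, 22, 20.5, 21)
  mat <- rbind(a = base, b = base + 3, c = base - 2, d = base + 0.5)
  tab <- matrix_ct_table(mat)
  expect_true(all(delta_ct_method(tab)$scores == 0))
  g <- genorm(tab)
  expect_true(all(g$scores < 1e-12))
  pv <- genorm_pairwise_variation(tab, ranking = g$ranking)
  expect_true(all(pv$v < 1e-12))
  expect_equal(pv$recommended, 2)
})

test_that("genorm eliminates stepwise, records rounds and flags high M", {
  set.seed(31)
  base <- rnorm(8, 20, 2)
  mat <- rbind(a = base + rnorm(8, 0, 0.05), b = base + rnorm(8, 0, 0.05),
               c = base + rnorm(8, 0, 0.3), d = base + rnorm(8, 0, 1.5))
  res <- genorm(matrix_ct_table(mat))
  expect_equal(res$meta$elimination_order, c("d", "c"))
  expect_equal(res$meta$final_pair, c("a", "b"))
  expect_equal(length(res$meta$m_by_round), 3)
  expect_equal(res$ranking, c("a", "b", "c", "d"))
  # pair M is the mutual V of the two survivors
  v_ab <- sd((mat["a", ] - min(mat["a", ])) - (mat["b", ] - min(mat["b", ])))
  expect_equal(unname(res$meta$pair_m), v_ab, tolerance = 1e-12)
  expect_true("d" %in% res$meta$unsuitable)
  expect_false("a" %in% res$meta$unsuitable)
})

test_that("genorm breaks ties at the maximal M deterministically", {
  base <- c(20, 21, 22, 23)
  # two genes with identical, symmetric deviation patterns tie on M
  mat <- rbind(a = base, b = base, x = base + c(0.5, -0.5, 0.5, -0.5),
               y = base + c(-0.5, 0.5, -0.5, 0.5))
  res <- genorm(matrix_ct_table(mat))
  expect_equal(res$meta$elimination_order[1], "y")  # later id removed first
})

test_that("two co-varying survivors give V = 0 and pair M = 0", {
  base <- c(20, 22, 21, 23)
  mat <- rbind(a = base, b = base + 4, noisy = base + c(2, -2, 1, -1))
  res <- genorm(matrix_ct_table(mat))
  expect_equal(res$meta$final_pair, c("a", "b"))
  expect_equal(unname(res$meta$pair_m), 0)
})

test_that("pairwise variation follows the ranking and the 0.15 rule", {
  set.seed(5)
  base <- rnorm(10, 22, 1.5)
  mat <- rbind(a = base + rnorm(10, 0, 0.02), b = base + rnorm(10, 0, 0.02),
               c = base + rnorm(10, 0, 0.03), d = base + rnorm(10, 0, 0.05),
               e = base + rnorm(10, 0, 1.2))
  tab <- matrix_ct_table(mat)
  g <- genorm(tab)
  pv <- genorm_pairwise_variation(tab, ranking = g$ranking)
  expect_length(pv$v, 3)                # V2/3, V3/4, V4/5
  expect_equal(pv$recommended, 2)       # low-noise top genes suffice
  oracle <- naive_pairwise_variation(mat, g$ranking)
  expect_equal(unname(pv$v), unname(oracle), tolerance = 1e-9)
  # k < 3 is degenerate
  expect_error(genorm_pairwise_variation(matrix_ct_table(mat[1:2, ])),
               "at least 3 genes")
})

test_that("normfinder decomposes variance and finds a best pair", {
  mat <- random_ct_matrix(5, 8, seed = 99)
  groups <- rep(c("egg", "cortex"), each = 4)
  colnames(mat) <- paste0("s", 1:8)
  tab <- matrix_ct_table(mat, groups = groups)
  res <- normfinder(tab)
  expect_true(all(res$scores >= 0))
  expect_length(res$meta$best_pair, 2)
  # intergroup differences sum to zero over genes within each group
  expect_equal(colSums(res$meta$d), c(cortex = 0, egg = 0), tolerance = 1e-12)
  # and over groups within each gene
  expect_equal(unname(rowSums(res$meta$d)), rep(0, 5), tolerance = 1e-12)
})

test_that("constant expression gives minimal, equal normfinder scores", {
  mat <- matrix(rep(c(18, 22, 26), 6), 3, 6,
                dimnames = list(c("a", "b", "c"), paste0("s", 1:6)))
  tab <- matrix_ct_table(mat, groups = rep(c("egg", "cortex"), each = 3))
  res <- normfinder(tab)
  expect_equal(unname(res$scores), rep(0, 3))
  expect_equal(res$meta$gamma2, 0)
  expect_true(all(res$meta$sigma2 == 0))
})

test_that("a designed intergroup shift is detected as the largest |d|", {
  hits <- vapply(1:200, function(s) {
    set.seed(s)
    k <- 5; n <- 8
    mu <- runif(k, 18, 26)
    mat <- matrix(rnorm(k * n, rep(mu, n), 0.2), k, n,
                  dimnames = list(paste0("g", 1:k), paste0("s", 1:n)))
    mat[1, 5:8] <- mat[1, 5:8] + 1     # 1-cycle shift in group B for g1
    tab <- matrix_ct_table(mat, groups = rep(c("egg", "cortex"), each = 4))
    res <- normfinder(tab)
    d_abs <- rowMeans(abs(res$meta$d))
    shifted_biggest <- names(which.max(d_abs)) == "g1"
    worst_rho <- res$ranking[5] == "g1"
    # d recovered: |d| for g1 should be near 0.5 (half the shift, by the
    # sum-to-zero-over-groups constraint)
    d_ok <- abs(d_abs["g1"] - 0.5) < 0.35
    shifted_biggest && worst_rho && d_ok
  }, logical(1))
  expect_gt(mean(hits), 0.95)
})

test_that("group structure is validated", {
  mat <- random_ct_matrix(4, 6, seed = 3)
  one_group <- matrix_ct_table(mat, groups = rep("egg", 6))
  expect_error(normfinder(one_group), "exactly 2 groups")
  three <- matrix_ct_table(mat, groups = rep(c("a", "b", "c"), 2))
  expect_error(normfinder(three), "exactly 2 groups")
  tiny <- matrix_ct_table(mat[, 1:3], groups = c("egg", "egg", "cortex"))
  expect_error(normfinder(tiny), "at least 2 samples")
  expect_error(delta_ct_method(matrix_ct_table(mat[1:2, ])),
               "at least 3 genes")
  expect_error(bestkeeper(matrix_ct_table(mat[, 1, drop = FALSE])),
               "at least 2 samples")
})

test_that("per-gene efficiencies change the quantity base coherently", {
  mat <- rbind(a = c(20, 21, 22), b = c(25, 25.5, 26), c = c(30, 31, 32))
  tab <- matrix_ct_table(mat)
  eff <- c(a = 100, b = 100, c = 100)
  same <- cv_method(tab, efficiencies = eff)
  expect_equal(same$scores, cv_method(tab)$scores, tolerance = 1e-12)
  eff2 <- c(a = 90, b = 100, c = 110)
  diff <- cv_method(tab, efficiencies = eff2)
  expect_false(isTRUE(all.equal(diff$scores, same$scores)))
  expect_error(cv_method(tab, efficiencies = c(a = 100)), "no efficiency")
})
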