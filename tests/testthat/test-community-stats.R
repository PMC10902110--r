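toy_counts <- function() {
  m <- matrix(c(2, 0, 7,
                0, 0, 0,
                1, 2, 3), 3, 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"), c("d1", "d2", "z1")))
  sub <- setNames(c("Anisoptera", "Anisoptera", "Zygoptera"), colnames(m))
  list(m = m, sub = sub)
}

test_that("abundance, richness and Shannon aggregate per suborder", {
  tc <- toy_counts()
  expect_equal(unname(site_abundance(tc$m, "Anisoptera", tc$sub)), c(2, 0, 3))
  expect_equal(unname(site_richness(tc$m, "Anisoptera", tc$sub)), c(1, 0, 2))
  expect_equal(unname(site_shannon(tc$m, "Zygoptera", tc$sub)), c(0, 0, 0))
  expect_error(site_abundance(tc$m, "Plecoptera", tc$sub), "Plecoptera")

  # equal proportions: H = ln 3; single species: 0; (1,2,3): direct formula
  sub3 <- setNames(rep("Anisoptera", 3), c("a", "b", "c"))
  m1 <- matrix(c(10, 10, 10), 1, 3, dimnames = list("s", names(sub3)))
  expect_equal(unname(site_shannon(m1, "Anisoptera", sub3)), log(3))
  m2 <- matrix(c(5, 0, 0), 1, 3, dimnames = list("s", names(sub3)))
  expect_equal(unname(site_shannon(m2, "Anisoptera", sub3)), 0)
  m3 <- matrix(c(1, 2, 3), 1, 3, dimnames = list("s", names(sub3)))
  p <- c(1, 2, 3) / 6
  expect_equal(unname(site_shannon(m3, "Anisoptera", sub3)), -sum(p * log(p)))
  expect_equal(unname(site_shannon(m3, "Anisoptera", sub3)), 1.0114, tolerance = 1e-4)
})

test_that("summaries agree with brute-force and vegan oracles on random matrices", {
  skip_if_not_installed("vegan")
  set.seed(6)
  for (rep in 1:5) {
    m <- matrix(rpois(30, 3), 5, 6,
                dimnames = list(paste0("s", 1:5), paste0("sp", 1:6)))
    sub <- setNames(rep(c("Anisoptera", "Zygoptera"), 3), colnames(m))
    for (so in c("Anisoptera", "Zygoptera")) {
      cols <- which(sub == so)
      brute_ab <- apply(m, 1, function(r) sum(r[cols]))
      brute_ri <- apply(m, 1, function(r) sum(r[cols] > 0))
      expect_equal(unname(site_abundance(m, so, sub)), unname(brute_ab))
      expect_equal(unname(site_richness(m, so, sub)), unname(brute_ri))
      expect_equal(unname(site_shannon(m, so, sub)),
                   unname(vegan::diversity(m[, cols, drop = FALSE])),
                   tolerance = 1e-12)
    }
    # Shannon <= ln(richness), equality iff equal counts
    H <- site_shannon(m, "Anisoptera", sub)
    S <- site_richness(m, "Anisoptera", sub)
    expect_true(all(H[S > 0] <= log(S[S > 0]) + 1e-12))
  }
})

test_that("the Gaussian GLM matches closed-form normal equations", {
  # exact line
  x <- 1:10
  f <- suppressWarnings(fit_gaussian_glm(2 * x, x)) # exact fit: sigma ~ 0
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)

  # worked dataset vs the normal-equations oracle
  xd <- c(1, 2, 3, 4); yd <- c(1, 3, 2, 5)
  b1 <- sum((xd - mean(xd)) * (yd - mean(yd))) / sum((xd - mean(xd))^2)
  b0 <- mean(yd) - b1 * mean(xd)
  r2 <- 1 - sum((yd - b0 - b1 * xd)^2) / sum((yd - mean(yd))^2)
  f2 <- fit_gaussian_glm(yd, xd)
  expect_equal(f2$slope, b1, tolerance = 1e-10)
  expect_equal(f2$intercept, b0, tolerance = 1e-10)
  expect_equal(f2$r_squared, r2, tolerance = 1e-10)
  expect_equal(f2$n, 4)

  expect_error(fit_gaussian_glm(yd, rep(1, 4)), "zero variance")
  expect_error(fit_gaussian_glm(c(1, NA, 3, 4), xd), "finite")

  # null slope CI coverage ~95% over replicates
  cover <- vapply(1:100, function(s) {
    set.seed(s)
    y <- rnorm(200); x <- rnorm(200)
    ci <- stats::confint(attr(fit_gaussian_glm(y, x), "fit"))[2, ]
    ci[1] <= 0 && 0 <= ci[2]
  }, logical(1))
  expect_gt(mean(cover), 0.88)
  expect_lt(mean(cover), 1)
})

test_that("uninformative-parameter screening drops null covariates, keeps real ones", {
  # identical model vs itself: delta = 0 => drop
  y <- rnorm(50); x <- rnorm(50)
  f <- stats::lm(y ~ x)
  sc <- screen_uninformative(f, f)
  expect_equal(sc$delta, 0)
  expect_equal(sc$decision, "drop")

  dropped <- 0; kept <- 0
  for (s in 1:100) {
    set.seed(s + 900)
    x1 <- rnorm(200); x2 <- rnorm(200)
    y <- 1 + 0.8 * x1 + rnorm(200)
    full_null <- stats::lm(y ~ x1 + x2)       # x2 truly uninformative
    reduced <- stats::lm(y ~ x1)
    base <- stats::lm(y ~ x2)                 # missing the true covariate
    full_true <- stats::lm(y ~ x2 + x1)
    if (screen_uninformative(full_null, reduced)$decision == "drop") dropped <- dropped + 1
    if (screen_uninformative(full_true, base)$decision == "keep") kept <- kept + 1
  }
  expect_gte(dropped, 90)
  expect_gte(kept, 99)
})

test_that("the Hellinger transform normalizes rows of square-rooted proportions", {
  m <- matrix(c(1, 0, 3), 1, 3)
  expect_equal(as.vector(hellinger(m)), c(0.5, 0, sqrt(3) / 2))
  expect_equal(as.vector(hellinger(matrix(7, 1, 1))), 1)
  set.seed(2)
  M <- matrix(rpois(60, 2), 6, 10)
  M[1, ] <- M[1, ] + 1 # ensure no zero rows here
  H <- hellinger(M[rowSums(M) > 0, , drop = FALSE])
  expect_equal(rowSums(H^2), rep(1, nrow(H)), tolerance = 1e-12)
  expect_warning(hellinger(matrix(0, 2, 2)), "all-zero")
  skip_if_not_installed("vegan")
  expect_equal(H, vegan::decostand(M[rowSums(M) > 0, , drop = FALSE],
                                   "hellinger"),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("tb-RDA recovers perfect constraints, the Ezekiel formula and vegan's answer", {
  # Ezekiel closed form at R2 = 0.5, n = 11, m = 1
  set.seed(8)
  n <- 11
  expect_equal(1 - (1 - 0.5) * (n - 1) / (n - 1 - 1), 4 / 9, tolerance = 1e-12)

  # perfectly constrained (pre-transformed) community: R2 = 1, minimal p
  x <- rnorm(20)
  Y <- cbind(2 * x, -x, 0.5 * x) + 5
  r <- tb_rda(Y, x, permutations = 999, seed = 1, transform = FALSE)
  expect_equal(r$r_squared, 1, tolerance = 1e-10)
  expect_equal(r$p_value, 0.001)
  expect_equal(r$adj_r_squared, 1, tolerance = 1e-10)

  # adjusted R2 <= R2 always; affine predictor rescaling leaves R2 unchanged
  set.seed(9)
  M <- matrix(rpois(20 * 6, 4), 20, 6)
  x2 <- rnorm(20)
  ra <- tb_rda(M, x2, seed = 2)
  rb <- tb_rda(M, 3 * x2 - 7, seed = 2)
  expect_lte(ra$adj_r_squared, ra$r_squared)
  expect_equal(ra$r_squared, rb$r_squared, tolerance = 1e-12)
  expect_equal(ra$p_value, rb$p_value)

  expect_error(tb_rda(M, rep(1, 20)), "constant")

  skip_if_not_installed("vegan")
  H <- vegan::decostand(M, "hellinger")
  vr <- vegan::rda(H ~ x2)
  expect_equal(ra$r_squared, vegan::RsquareAdj(vr)$r.squared, tolerance = 1e-10)
  expect_equal(ra$adj_r_squared, vegan::RsquareAdj(vr)$adj.r.squared,
               tolerance = 1e-10)
  av <- vegan::anova.cca(vr, permutations = 499)
  expect_equal(ra$pseudo_f, av$F[1], tolerance = 1e-8)
})

test_that("permutation p-values are uniform under a null predictor", {
  # predictor orthogonalized against the community: R2 ~ 0; over replicates
  # the permutation p is uniform (KS test, alpha = 0.01)
  pvals <- vapply(1:200, function(s) {
    set.seed(s + 300)
    M <- matrix(rpois(30 * 8, 3), 30, 8)
    x <- rnorm(30)
    tb_rda(M, x, permutations = 199, seed = s)$p_value
  }, numeric(1))
  # p-values are discrete (multiples of 1/200), so KS tie warnings are expected
  ks <- suppressWarnings(
    stats::ks.test(pvals, function(q) pmin(pmax((q * 200 - 1) / 199, 0), 1)))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(pvals >= 1 / 200 & pvals <= 1))
})

test_that("Wilcoxon comparisons follow the exact/approximate contract", {
  w <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(w$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(w$method, "exact")

  w2 <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w2$p_value, 1)
  expect_equal(w2$method, "normal approximation") # midranks for ties

  # exact and approximate paths agree within 0.05 for n >= 10 without ties
  set.seed(12)
  for (k in 1:5) {
    a <- sample(seq(1, 400, by = 7), 5)
    b <- sample(seq(3, 401, by = 7), 5)
    pe <- stats::wilcox.test(a, b, exact = TRUE)$p.value
    pa <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
    expect_lt(abs(pe - pa), 0.05)
  }

  # type-I calibration at alpha = 0.05 under equal distributions
  rej <- vapply(1:400, function(s) {
    set.seed(s + 5000)
    wilcoxon_rank_sum(rnorm(30), rnorm(30))$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.08)
})

test_that("predictor correlations match the covariance formula", {
  expect_equal(predictor_correlation(1:5, 1:5), 1)
  expect_equal(predictor_correlation(1:5, -(1:5)), -1)
  a <- c(1, 2, 3); b <- c(1, 2, 4)
  oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(predictor_correlation(a, b), oracle, tolerance = 1e-12)
  expect_equal(oracle, 0.982, tolerance = 1e-3)
})

test_that("the model battery emits 12 GLMs and 4 RDAs with diagnostics", {
  set.seed(14)
  n <- 49
  met <- rbind(toy_metrics(n, rnorm(n), scale_m = 900),
               toy_metrics(n, rnorm(n), scale_m = 300))
  com <- generate_community(met, community_config(seed = 5))
  b <- run_model_battery(met, com, permutations = 99, seed = 3)
  expect_equal(nrow(b$glm_table), 12)
  expect_length(b$rda_results, 4)
  expect_setequal(unique(b$glm_table$predictor),
                  c("mean_current", "n_neighbours"))
  expect_true(all(b$glm_table$r_squared >= 0 & b$glm_table$r_squared <= 1))
  expect_true(all(c("resid_skewness", "var_trend_p", "sd_current_decision")
                  %in% names(b$glm_table)))
  expect_true(all(b$rda_table$adj_r_squared <= b$rda_table$r_squared))
  expect_true(all(b$rda_table$p_value >= 1 / 100))

  # a suborder with no species is a named error
  drag_only <- com$counts[, com$suborder == "Anisoptera"]
  expect_error(run_model_battery(met, drag_only,
                                 suborder_vec = com$suborder[com$suborder == "Anisoptera"]),
               "Zygoptera")
})
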