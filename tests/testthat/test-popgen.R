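test_that("frequencies are copy number over ploidy for the counted allele", {
  gm <- make_gm(list(tet = c("l1:1" = "A:3,T:1", "l2:1" = "A:2,C:1,T:1"),
                     dip = c("l1:1" = "A:1,T:1")),
                ploidy = c(tet = 4L, dip = 2L))
  fm <- freq_matrix(gm)
  expect_equal(colnames(fm), "l1:1")  # tri-allelic l2 excluded
  expect_equal(attr(fm, "n_dropped_nonbiallelic"), 1L)
  expect_equal(fm["tet", "l1:1"], 0.25)
  expect_equal(fm["dip", "l1:1"], 0.5)
  expect_equal(attr(fm, "counted_allele")[["l1:1"]], "T")
  # values are exact rationals of the ploidy
  cfg <- sim_config(n_samples = 8L, ploidies = c(2L, 4L), n_loci = 50L,
                    error_rate = 0, seed = 14L)
  sim <- simulate_cohort(cfg)
  gm2 <- genotype_matrix(sim$truth$genotype, sim$truth$ploidy)
  fm2 <- freq_matrix(gm2)
  k <- attr(fm2, "ploidy")
  back <- sweep(fm2, 1L, k, `*`)
  expect_true(all(abs(back - round(back)) < 1e-12, na.rm = TRUE))
})

test_that("imputation fills missing cells sensibly", {
  m <- matrix(c(0.5, 0.5, NA, 0.5, 0, 1), nrow = 3L,
              dimnames = list(c("a", "b", "c"), c("l1", "l2")))
  out <- impute_missing(m, "mean")
  expect_equal(out["c", "l1"], 0.5)
  # complete matrix unchanged
  full <- matrix(runif(12), 3L)
  expect_identical(impute_missing(full, "mean"), full)
  # all-missing column rejected
  m2 <- m; m2[, 2] <- NA
  expect_error(impute_missing(m2), "all-missing locus")
})

test_that("low-rank imputation beats random filling on structured data", {
  set.seed(42)
  # two clusters of samples with distinct frequency profiles
  base <- rbind(matrix(rep(runif(80, 0, 0.2), each = 20), nrow = 20),
                matrix(rep(runif(80, 0.8, 1), each = 20), nrow = 20))
  noise <- matrix(rnorm(length(base), 0, 0.05), nrow = nrow(base))
  truth <- pmin(pmax(base + noise, 0), 1)
  dimnames(truth) <- list(sprintf("s%02d", 1:40), sprintf("l%02d", 1:80))
  masked <- truth
  idx <- sample(length(truth), round(0.05 * length(truth)))
  masked[idx] <- NA
  imp <- impute_missing(masked, "iterative-lowrank", ncp = 2L)
  rmse <- sqrt(mean((imp[idx] - truth[idx])^2))
  set.seed(43)
  rmse_rand <- sqrt(mean((runif(length(idx)) - truth[idx])^2))
  expect_lt(rmse, rmse_rand)
  expect_false(anyNA(imp))
})

test_that("F_ST hits its analytic extremes", {
  # fixed differences at every locus -> 1
  f <- rbind(matrix(0, 5, 20), matrix(1, 5, 20))
  rownames(f) <- sprintf("s%02d", 1:10)
  colnames(f) <- sprintf("l%02d", 1:20)
  grp <- rep(c("g1", "g2"), each = 5L)
  expect_equal(fst(f, grp), 1)
  expect_equal(fst(f, grp, method = "hudson"), 1)
  # identical frequency profiles -> 0
  f2 <- rbind(matrix(0.5, 5, 20), matrix(0.5, 5, 20))
  dimnames(f2) <- dimnames(f)
  expect_equal(fst(f2, grp), 0)
  # per-locus mode: NaN where no variation at all
  f3 <- f2; f3[, 1] <- 0
  per <- fst(f3, grp, mode = "per_locus")
  expect_true(is.nan(per[1]))
  expect_equal(unname(per[2]), 0)
  expect_error(fst(f, rep("g1", 10)), "two groups")
})

test_that("pairwise mode fills a symmetric matrix", {
  set.seed(8)
  f <- matrix(runif(30 * 40), 30, 40,
              dimnames = list(sprintf("s%02d", 1:30), sprintf("l%02d", 1:40)))
  grp <- rep(c("a", "b", "c"), each = 10L)
  pw <- fst(f, grp, mode = "pairwise")
  expect_equal(dim(pw), c(3L, 3L))
  expect_equal(pw, t(pw))
  expect_equal(diag(pw), c(a = 0, b = 0, c = 0))
})

test_that("Balding-Nichols divergence is recovered by the corrected estimator", {
  cfg <- sim_config(n_samples = 50L, ploidies = 2L, n_loci = 1500L,
                    group_divergence = 0.1, error_rate = 0, seed = 6L)
  sim <- simulate_cohort(cfg)
  gm <- genotype_matrix(sim$truth$genotype, sim$truth$ploidy)
  fm <- freq_matrix(gm)
  grp <- setNames(sim$meta$population_id, sim$meta$sample_id)
  est <- fst(fm, grp, method = "hudson")
  expect_lt(abs(est - 0.1), 0.02)
  # the uncorrected Nei ratio with two demes sits near (F/2)/(1 - F/2)
  est_nei <- fst(fm, grp, method = "nei")
  expect_lt(est_nei, est)
})

test_that("PCA separates planted clusters and respects conventions", {
  set.seed(77)
  c1 <- matrix(rbinom(20 * 100, 2, 0.15) / 2, nrow = 20)
  c2 <- matrix(rbinom(20 * 100, 2, 0.85) / 2, nrow = 20)
  f <- rbind(c1, c2)
  dimnames(f) <- list(sprintf("s%02d", 1:40), sprintf("l%03d", 1:100))
  p <- pca_scores(f, 3L)
  g1 <- p$scores[1:20, 1]; g2 <- p$scores[21:40, 1]
  sep <- abs(mean(g1) - mean(g2))
  expect_gt(sep, 5 * max(sd(g1), sd(g2)))
  # explained fractions sum to <= 1 and are non-increasing
  expect_lte(sum(p$explained), 1 + 1e-12)
  expect_true(all(diff(p$explained) <= 1e-12))
  # identical rows -> all scores zero
  same <- matrix(0.5, 10, 8)
  expect_true(all(abs(pca_scores(same, 2L)$scores) < 1e-12))
  # invariance to locus permutation (scores identical up to tolerance)
  perm <- sample(ncol(f))
  p2 <- pca_scores(f[, perm], 3L)
  expect_equal(abs(p$scores[, 1]), abs(p2$scores[, 1]), tolerance = 1e-8)
  expect_error(pca_scores(f, 200L), "exceeds")
  expect_error(pca_scores(cbind(f[, 1:3], NA), 1L), "complete")
})

test_that("cline regression recovers a simulated latitudinal slope", {
  sim <- simulate_admixture_cline(n_pops = 20L, per_pop = 6L,
                                  beta0 = 0.8, beta1 = -0.01,
                                  sigma_pop = 0.05, sigma_resid = 0.05,
                                  seed = 123L)
  fit <- cline_fit(sim$records)
  expect_lt(abs(fit$slope - (-0.01)), 2 * fit$slope_se)
  expect_gte(fit$sigma2_pop, 0)
  expect_gte(fit$sigma2_resid, 0)
  expect_equal(length(fit$population_effects), 20L)
  expect_equal(length(fit$population_means), 20L)
})

test_that("noise-free linear data gives the exact slope and zero variances", {
  lat <- rep(seq(50, 60, length.out = 5L), each = 3L)
  y <- 1.5 - 0.02 * lat  # stays inside (0, pi/2) so the transform is exact
  recs <- data.frame(sample_id = sprintf("i%02d", seq_along(lat)),
                     Q = sin(y)^2,
                     population_id = rep(sprintf("p%d", 1:5), each = 3L),
                     latitude = lat)
  fit <- cline_fit(recs)
  expect_equal(fit$slope, -0.02, tolerance = 1e-6)
  expect_lt(fit$sigma2_pop + fit$sigma2_resid, 1e-8)
  # degenerate designs are rejected
  expect_error(cline_fit(transform(recs, latitude = 55)), "degenerate")
  expect_error(cline_fit(recs[1:3, ]), "3 populations")
  # arcsine transform is monotone in Q
  q <- sort(runif(20))
  expect_true(all(diff(asin(sqrt(q))) > 0))
})
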