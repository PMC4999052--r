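test_that("heterozygous-site ratio collection applies coverage and censoring", {
  recs <- rbind(
    one_rec(c("A", "T"), c(15, 14), locus = "c1:1"),   # 29x -> excluded
    one_rec(c("A", "T"), c(27, 3), locus = "c2:1"),    # ratio 0.10 -> kept
    one_rec(c("A", "T"), c(28, 2), locus = "c3:1"),    # ratio < 0.1 -> out
    one_rec(c("A", "T"), c(30, 30), locus = "c4:1"),   # kept
    one_rec(c("A", "T", "G"), c(20, 15, 10), locus = "c5:1"),  # multiallelic
    one_rec(c("A", "T"), c(40, 0), locus = "c6:1"))    # homozygous
  r <- heterozygous_ratios(recs)
  expect_setequal(r$locus_id, c("c2:1", "c4:1"))
  expect_equal(r$x[r$locus_id == "c2:1"], 3)   # focal = second-listed allele
  expect_equal(r$ratio[r$locus_id == "c2:1"], 0.1)
  expect_equal(attr(r, "status"), "ok")
  r0 <- heterozygous_ratios(recs[recs$locus_id == "c1:1", ])
  expect_equal(nrow(r0), 0L)
  expect_equal(attr(r0, "status"), "insufficient heterozygous sites")
})

test_that("censored beta-binomial density is symmetric at p = 0.5", {
  for (x in 4:20) {
    expect_equal(censored_betabinom_logpmf(x, 40, 0.5, 0.05),
                 censored_betabinom_logpmf(40 - x, 40, 0.5, 0.05),
                 tolerance = 1e-12)
  }
})

test_that("beta-binomial degenerates to the binomial as rho -> 0", {
  supp <- 3:27
  cb <- dbinom(supp, 30, 0.5)
  cb <- log(cb / sum(cb))
  expect_equal(censored_betabinom_logpmf(15, 30, 0.5, 1e-8),
               cb[supp == 15], tolerance = 1e-6)
})

test_that("censored density matches a numeric-integration oracle", {
  expect_equal(censored_betabinom_logpmf(10, 30, 1 / 3, 0.02),
               oracle_censored_bb_logpmf(10, 30, 1 / 3, 0.02),
               tolerance = 1e-10)
  expect_equal(censored_betabinom_logpmf(40, 60, 0.75, 0.1),
               oracle_censored_bb_logpmf(40, 60, 0.75, 0.1),
               tolerance = 1e-9)
})

test_that("censored density normalizes to 1 over its support", {
  for (n in c(30L, 47L, 100L)) for (p in c(0.25, 0.5, 2 / 3))
    for (rho in c(0.005, 0.02, 0.2)) {
      supp <- seq.int(ceiling(0.1 * n - 1e-9), floor(0.9 * n + 1e-9))
      tot <- sum(exp(censored_betabinom_logpmf(supp, n, p, rho)))
      expect_equal(tot, 1, tolerance = 1e-10)
    }
})

test_that("density evaluation outside the window is a domain error", {
  expect_error(censored_betabinom_logpmf(1, 30, 0.5, 0.02), "window")
})

test_that("mixture likelihood reduces, adds and nests correctly", {
  obs1 <- data.frame(x = 15L, n = 30L)
  s2 <- ploidy_model_spec(2)
  expect_equal(mixture_loglik(obs1, s2, 1, 0.03),
               censored_betabinom_logpmf(15, 30, 0.5, 0.03),
               tolerance = 1e-12)
  obs2 <- rbind(obs1, obs1)
  expect_equal(mixture_loglik(obs2, s2, 1, 0.03),
               2 * mixture_loglik(obs1, s2, 1, 0.03), tolerance = 1e-12)
  # k=4 with all weight on p=1/2 equals k=2 on the same data
  set.seed(1)
  obs <- data.frame(x = rbinom(50, 60, 0.5), n = 60L)
  obs <- obs[obs$x / obs$n >= 0.1 & obs$x / obs$n <= 0.9, ]
  s4 <- ploidy_model_spec(4)
  expect_equal(mixture_loglik(obs, s4, c(0, 1, 0), 0.02),
               mixture_loglik(obs, s2, 1, 0.02), tolerance = 1e-10)
  expect_error(mixture_loglik(obs, s4, c(0.5, 0.6, 0.1), 0.02), "sum to 1")
})

test_that("the ploidy grid holds the canonical heterozygote expectations", {
  expect_equal(ploidy_model_spec(2)$p_grid, 0.5)
  expect_equal(ploidy_model_spec(3)$p_grid, c(1, 2) / 3)
  expect_equal(ploidy_model_spec(4)$p_grid, c(0.25, 0.5, 0.75))
  expect_error(ploidy_model_spec(1), ">= 2")
})

test_that("tetraploid mixture parameters are recovered from simulation", {
  set.seed(202)
  n_loci <- 5000L
  m_true <- c(0.25, 0.5, 0.25)
  rho_true <- 0.02
  comp <- sample.int(3L, n_loci, replace = TRUE, prob = m_true)
  p0 <- c(0.25, 0.5, 0.75)[comp]
  n <- rep(60L, n_loci)
  a <- p0 * (1 - rho_true) / rho_true
  b <- (1 - p0) * (1 - rho_true) / rho_true
  x <- rbinom(n_loci, n, rbeta(n_loci, a, b))
  keep <- x / n >= 0.1 & x / n <= 0.9
  obs <- data.frame(x = x[keep], n = n[keep])
  fit <- fit_ploidy_model(obs, ploidy_model_spec(4))
  expect_true(all(abs(fit$m - m_true) < 0.03))
  expect_true(abs(fit$rho - rho_true) < 0.01)
  expect_equal(fit$aic, 2 * fit$n_free_params - 2 * fit$loglik)
  expect_equal(fit$n_free_params, 3L)
  # rho CI bracket from the observed information covers the truth
  expect_true(fit$rho_ci[1] < rho_true && rho_true < fit$rho_ci[2])
})

test_that("the fitted maximum dominates any manual rho on a grid", {
  set.seed(31)
  x <- rbinom(400, 60, rbeta(400, 0.5 * 49, 0.5 * 49))
  keep <- x / 60 >= 0.1 & x / 60 <= 0.9
  obs <- data.frame(x = x[keep], n = 60L)
  s2 <- ploidy_model_spec(2)
  fit <- fit_ploidy_model(obs, s2)
  for (rho in seq(0.002, 0.3, length.out = 20))
    expect_gte(fit$loglik + 1e-6, mixture_loglik(obs, s2, 1, rho))
  expect_error(fit_ploidy_model(obs[0, ], s2), "at least")
})

test_that("AIC classification recovers simulated ploidies and nests models", {
  mk_obs <- function(k, n_loci, rho, seed) {
    set.seed(seed)
    p0 <- sample(seq_len(k - 1L) / k, n_loci, replace = TRUE)
    n <- sample(40:80, n_loci, replace = TRUE)
    x <- rbinom(n_loci, n, rbeta(n_loci, p0 * (1 - rho) / rho,
                                 (1 - p0) * (1 - rho) / rho))
    keep <- x / n >= 0.1 & x / n <= 0.9
    data.frame(x = x[keep], n = n[keep])
  }
  obs2 <- mk_obs(2L, 2000L, 0.02, 11)
  cl2 <- classify_ploidy(obs2)
  expect_equal(cl2$best_k, 2L)
  obs3 <- mk_obs(3L, 2000L, 0.02, 12)
  expect_equal(classify_ploidy(obs3)$best_k, 3L)
  # nesting: the tetraploid mixture can match the diploid likelihood, so its
  # maximized loglik is >= the diploid one, but AIC pays the 2 extra params
  expect_gte(cl2$table$loglik[cl2$table$k == 4] + 1e-4,
             cl2$table$loglik[cl2$table$k == 2])
  expect_lt(cl2$table$aic[cl2$table$k == 2],
            cl2$table$aic[cl2$table$k == 4])
  # too few observations -> undetermined, not an exception
  und <- classify_ploidy(obs2[1:10, ])
  expect_equal(und$status, "undetermined")
  expect_true(is.na(und$best_k))
})

test_that("simulated ratio dispersion grows with rho", {
  set.seed(99)
  vars <- vapply(c(0.005, 0.05, 0.2), function(rho) {
    cfg <- sim_config(ploidies = 2L, n_loci = 3000L, rho = rho,
                      error_rate = 0,
                      coverage_law = list(dist = "fixed", value = 60),
                      seed = 77L)
    sim <- simulate_individual(cfg, 2L, het_only = TRUE)
    r <- heterozygous_ratios(sim$counts, censor = c(0, 1))
    var(r$ratio)
  }, 0)
  expect_true(all(diff(vars) > 0))
})
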