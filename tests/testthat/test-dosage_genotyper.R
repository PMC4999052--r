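test_that("dosage model enumeration matches the canonical tables", {
  fmt <- function(n) vapply(enumerate_dosage_models(n), paste,
                            "", collapse = ":")
  expect_equal(fmt(2), c("2:0", "1:1"))
  expect_equal(fmt(3), c("3:0:0", "2:1:0", "1:1:1"))
  expect_equal(fmt(4), c("4:0:0:0", "3:1:0:0", "2:2:0:0", "2:1:1:0",
                         "1:1:1:1"))
  expect_error(enumerate_dosage_models(0), ">= 1")
  # every model sums to n, is descending, and has length n
  for (n in 2:6) {
    ms <- enumerate_dosage_models(n)
    expect_true(all(vapply(ms, sum, 0L) == n))
    expect_true(all(vapply(ms, function(m) all(diff(m) <= 0), TRUE)))
    expect_true(all(lengths(ms) == n))
  }
})

test_that("counts sort descending with phreds paired, truncated to ploidy", {
  p <- prepare_counts(one_rec(c("A", "T"), c(5, 10), c(28, 30)), 2L)
  expect_equal(p$x, c(10L, 5L))
  expect_equal(p$q, c(30, 28))
  expect_equal(p$alleles, c("T", "A"))
  # more alleles than ploidy: right truncation
  p2 <- prepare_counts(one_rec(c("A", "T", "G"), c(50, 30, 2)), 2L)
  expect_equal(p2$x, c(50L, 30L))
  expect_equal(p2$total, 82L)
  # count tie broken by allele label order
  p3 <- prepare_counts(one_rec(c("T", "A"), c(10, 10)), 2L)
  expect_equal(p3$alleles, c("A", "T"))
  expect_error(prepare_counts(one_rec("A", 0), 2L), "no observed reads")
})

test_that("model log-likelihood reproduces hand-computed values", {
  # perfect homozygote: multinomial coefficient 1, (2/2)^20, no error reads
  expect_equal(model_loglik(20L, 30, c(2L, 0L)), 0)
  # balanced het: log(choose(20,10)) - 20 log 2
  expect_equal(model_loglik(c(10L, 10L), c(30, 30), c(1L, 1L)),
               log(184756) - 20 * log(2), tolerance = 1e-12)
  # 2 unexpected reads at phred 20: L2 = (0.01)^2
  expect_equal(model_loglik(c(18L, 2L), c(30, 20), c(2L, 0L)),
               2 * log(0.01), tolerance = 1e-12)
  # exp(logL) is a probability
  set.seed(4)
  for (i in 1:20) {
    rec <- random_record()
    prep <- prepare_counts(record_df(rec), rec$ploidy)
    for (m in enumerate_dosage_models(rec$ploidy))
      expect_lte(model_loglik(prep$x, prep$q, m), 1e-12)
  }
})

test_that("genotype calls respect the per-ploidy coverage window", {
  # tetraploid at 19 reads: below 5 * 4
  low <- call_genotype(one_rec(c("A", "T"), c(10, 9)), 4L)
  expect_equal(low$status, "missing_low_cov")
  ok <- call_genotype(one_rec(c("A", "T"), c(10, 10)), 4L)
  expect_equal(ok$status, "called")
  # diploid window: 10 is in, 9 is out; 200 in, 201 out
  expect_equal(call_genotype(one_rec("A", 9), 2L)$status, "missing_low_cov")
  expect_equal(call_genotype(one_rec("A", 10), 2L)$status, "called")
  expect_equal(call_genotype(one_rec("A", 200), 2L)$status, "called")
  expect_equal(call_genotype(one_rec("A", 201), 2L)$status,
               "missing_high_cov")
})

test_that("BIC selection matches brute-force scoring on key records", {
  # tetraploid 15:5 at high quality: 3:1:0:0 beats 2:2:0:0
  cl <- call_genotype(one_rec(c("A", "T"), c(15, 5), c(38, 38)), 4L)
  expect_equal(paste(cl$model, collapse = ":"), "3:1:0:0")
  expect_equal(cl$genotype, "A:3,T:1")
  l31 <- model_loglik(c(15L, 5L), c(38, 38), c(3L, 1L, 0L, 0L))
  l22 <- model_loglik(c(15L, 5L), c(38, 38), c(2L, 2L, 0L, 0L))
  expect_equal(l31, log(choose(20, 5)) + 15 * log(3 / 4) + 5 * log(1 / 4),
               tolerance = 1e-12)
  expect_gt(l31, l22)
  # single-allele record: perfect fit with minimal complexity
  expect_equal(call_genotype(one_rec("A", 30), 4L)$genotype, "A:4")
  expect_error(call_genotype(one_rec("A", 30), NA), "ploidy")
})

test_that("selected models equal the exact brute-force oracle", {
  set.seed(1234)
  n_rec <- 800L
  mismatch <- 0L
  for (i in seq_len(n_rec)) {
    rec <- random_record()
    ours <- call_genotype(record_df(rec), rec$ploidy)
    orac <- oracle_call(rec$counts, rec$phreds, rec$alleles, rec$ploidy)
    if (!identical(ours$status, orac$status)) mismatch <- mismatch + 1L
    else if (ours$status == "called" &&
             !identical(paste(ours$model, collapse = ":"), orac$pattern))
      mismatch <- mismatch + 1L
  }
  expect_equal(mismatch, 0L)
})

test_that("per-sample genotyping is deterministic and accurate on truth", {
  cfg <- sim_config(ploidies = 2L, n_loci = 120L, error_rate = 0.001,
                    coverage_law = list(dist = "fixed", value = 60),
                    seed = 9L)
  sim <- simulate_individual(cfg, 2L, sample_id = "D1")
  gt <- genotype_sample(sim$counts, 2L)
  gt2 <- genotype_sample(sim$counts, 2L)
  expect_identical(gt, gt2)
  called <- gt$status == "called"
  truth <- sim$truth$genotype[match(gt$locus_id, sim$truth$locus_id)]
  expect_gte(mean(gt$genotype[called] == truth[called]), 0.99)
  expect_equal(attr(gt, "n_called") + attr(gt, "n_missing"), nrow(gt))
  empty <- genotype_sample(sim$counts[0, ], 2L)
  expect_equal(nrow(empty), 0L)
})

test_that("more coverage never hurts recovery of the true dosage model", {
  # empirical monotonicity on a 3:1 tetraploid genotype, error-free ratios
  set.seed(55)
  probs <- vapply(c(20L, 40L, 80L, 160L), function(cov) {
    hits <- 0L
    for (r in 1:200) {
      x <- rbinom(1L, cov, 0.75)
      cl <- call_genotype(one_rec(c("A", "T"), c(x, cov - x), c(33, 33)), 4L,
                          cov_max = 1000L)
      if (identical(paste(cl$model, collapse = ":"), "3:1:0:0"))
        hits <- hits + 1L
    }
    hits / 200
  }, 0)
  expect_true(all(diff(probs) >= -0.03))  # monotone up to MC noise
  expect_gt(probs[4], probs[1])
})

test_that("call assembly produces a consistent genotype matrix", {
  cfg <- sim_config(n_samples = 2L, ploidies = c(2L, 4L), n_loci = 40L,
                    seed = 21L)
  sim <- simulate_cohort(cfg)
  calls <- lapply(split(sim$counts, sim$counts$sample_id), function(cs)
    genotype_sample(cs, sim$truth$ploidy[cs$sample_id[1L]]))
  gm <- build_genotype_matrix(calls, sim$truth$ploidy)
  expect_equal(dim(gm), c(4L, 40L))
  expect_true(all(rownames(gm$calls) == names(sim$truth$ploidy)))
})
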