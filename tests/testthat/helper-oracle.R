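# Independent oracles used across tests. These deliberately avoid the
# package's algorithms: dosage models are enumerated by exhaustive grid
# filtering (not recursive partitioning) and likelihoods use direct
# factorial()/log arithmetic (not lgamma); the beta-binomial point oracle
# integrates the binomial kernel against the beta density numerically.

# all dosage vectors of length n: exhaustive grid, filtered
oracle_models <- function(n) {
  grid <- do.call(expand.grid, rep(list(0:n), n))
  keep <- rowSums(grid) == n &
    apply(grid, 1L, function(v) all(diff(v) <= 0))
  m <- unique(as.matrix(grid[keep, , drop = FALSE]))
  lapply(seq_len(nrow(m)), function(i) as.integer(m[i, ]))
}

# direct-arithmetic log-likelihood of one dosage model (coverage <= ~150
# so factorial() stays finite in double precision)
oracle_model_loglik <- function(x, q, model) {
  n <- sum(model)
  x <- c(x, integer(n - length(x)))[seq_len(n)]
  q <- c(q, numeric(n - length(q)))[seq_len(n)]
  s <- which(model > 0)
  sb <- setdiff(seq_len(n), s)
  l1 <- log(factorial(sum(x[s]))) - sum(log(factorial(x[s]))) +
    sum(x[s] * log(model[s] / n))
  perr <- 10^(-q[sb] / 10)
  l1 + sum(ifelse(x[sb] > 0, x[sb] * log(perr), 0))  # x=0 terms contribute 0
}

# full brute-force genotype call: sort/truncate, score all models with
# direct arithmetic, select min BIC with the documented tie-break
oracle_call <- function(counts, phreds, alleles, ploidy,
                        cov_min = 5 * ploidy, cov_max = 200) {
  total <- sum(counts)
  if (total < cov_min) return(list(status = "missing_low_cov"))
  if (total > cov_max) return(list(status = "missing_high_cov"))
  ord <- order(-counts, alleles)
  keep <- ord[seq_len(min(length(ord), ploidy))]
  x <- counts[keep]; q <- phreds[keep]
  models <- oracle_models(ploidy)
  ll <- vapply(models, function(m) {
    n <- sum(m)
    xx <- c(x, integer(n))[seq_len(n)]
    qq <- c(q, numeric(n))[seq_len(n)]
    s <- which(m > 0); sb <- setdiff(seq_len(n), s)
    log(factorial(sum(xx[s]))) - sum(log(factorial(xx[s]))) +
      sum(xx[s] * log(m[s] / n)) +
      sum(ifelse(xx[sb] > 0, xx[sb] * log(10^(-qq[sb] / 10)), 0))
  }, 0)
  kmod <- vapply(models, function(m) sum(m > 0), 0)
  bic <- kmod * log(total) - 2 * ll
  tol <- 1e-9 * max(1, abs(min(bic)))
  cand <- which(bic <= min(bic) + tol)
  if (length(cand) > 1L) {
    cand <- cand[kmod[cand] == min(kmod[cand])]
    cand <- cand[which.max(vapply(models[cand], `[`, 0L, 1L))]
  }
  list(status = "called", model = models[[cand[1L]]],
       pattern = paste(models[[cand[1L]]], collapse = ":"))
}

# high-precision censored beta-binomial log density by numeric integration
oracle_censored_bb_logpmf <- function(x, n, p, rho, censor = c(0.1, 0.9)) {
  a <- p * (1 - rho) / rho
  b <- (1 - p) * (1 - rho) / rho
  pmf1 <- function(y) {
    integrate(function(t) dbinom(y, n, t) * dbeta(t, a, b),
              lower = 0, upper = 1, rel.tol = 1e-13,
              subdivisions = 2000L)$value
  }
  eps <- 1e-9
  supp <- seq.int(ceiling(censor[1] * n - eps), floor(censor[2] * n + eps))
  dens <- vapply(supp, pmf1, 0)
  log(pmf1(x)) - log(sum(dens))
}

# random genotyping records for the oracle-equivalence suite
random_record <- function() {
  ploidy <- sample(2:4, 1L)
  n_alleles <- sample(1:4, 1L, prob = c(0.3, 0.4, 0.2, 0.1))
  alleles <- sample(c("A", "C", "G", "T"), n_alleles)
  total <- sample(10:60, 1L)
  counts <- as.integer(rmultinom(1L, total,
                                 prob = runif(n_alleles, 0.05, 1)))
  # guarantee an observed record
  if (all(counts == 0L)) counts[1L] <- total
  phreds <- round(runif(n_alleles, 20, 40), 1)
  list(ploidy = ploidy, alleles = alleles, counts = counts, phreds = phreds)
}

record_df <- function(rec, sample_id = "S1", locus_id = "ctg1:101") {
  data.frame(sample_id = sample_id, locus_id = locus_id,
             allele = rec$alleles, count = rec$counts,
             mean_phred = rec$phreds, stringsAsFactors = FALSE)
}
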