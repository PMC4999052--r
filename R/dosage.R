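#' Enumerate allele-dosage models for a ploidy
#'
#' All integer partitions of the ploidy `n` into at most `n` positive
#' parts, each sorted descending and zero-padded to length `n`, in
#' lexicographically decreasing order. For a diploid these are `2:0` and
#' `1:1`; for a tetraploid `4:0:0:0`, `3:1:0:0`, `2:2:0:0`, `2:1:1:0` and
#' `1:1:1:1`.
#'
#' @param n ploidy (integer >= 1).
#' @return list of integer vectors of length `n`.
#' @export
enumerate_dosage_models <- function(n) {
  n <- as.integer(n)
  if (n < 1L) stop("ploidy must be >= 1")
  parts <- function(total, maxpart) {
    if (total == 0L) return(list(integer()))
    out <- list()
    for (first in seq.int(min(maxpart, total), 1L)) {
      for (rest in parts(total - first, first))
        out[[length(out) + 1L]] <- c(first, rest)
    }
    out
  }
  lapply(parts(n, n), function(p) c(p, integer(n - length(p))))
}

#' Sort, truncate and pair counts with their qualities
#'
#' Prepares one locus record for dosage scoring: read counts are sorted in
#' descending order with their mean phred qualities permuted identically;
#' ties in counts are broken by allele label sort order. If more than `n`
#' alleles were observed, only the `n` most frequent are kept (right
#' truncation).
#'
#' @param rec `allele_counts` rows of one (sample, locus) record.
#' @param n ploidy.
#' @return list with `x` (sorted counts), `q` (matched phreds), `alleles`
#'   (matched labels), `total` (total reads before truncation).
#' @export
prepare_counts <- function(rec, n) {
  if (nrow(rec) == 0L || all(rec$count == 0L))
    stop("record has no observed reads")
  ord <- order(-rec$count, rec$allele)
  keep <- ord[seq_len(min(length(ord), n))]
  list(x = rec$count[keep], q = rec$mean_phred[keep],
       alleles = rec$allele[keep], total = sum(rec$count))
}

#' Dosage-model log-likelihood (multinomial x phred error)
#'
#' Log of the two-part likelihood `L = L1 * L2` for a dosage model `m`
#' with ploidy `n = sum(m)`. `L1` is the multinomial probability of the
#' counts at positions where the model expects alleles (`m_i > 0`), with
#' category probabilities `m_i / n`. `L2` is the error probability of reads
#' observed at positions where the model expects none: each such read
#' contributes its allele's per-base error probability
#' `p = 10^(-q/10)` recovered from the mean phred score. Computed in
#' natural-log space via `lgamma`, so no factorial overflow.
#'
#' @param x counts prepared by [prepare_counts()] (descending; shorter
#'   vectors are zero-padded to the model length).
#' @param q mean phred qualities matched to `x`.
#' @param model integer dosage vector (see [enumerate_dosage_models()]).
#' @return the log-likelihood (scalar, `<= 0`).
#' @export
model_loglik <- function(x, q, model) {
  n <- sum(model)
  if (length(x) > length(model)) stop("x longer than model; truncate first")
  x <- c(x, integer(length(model) - length(x)))
  q <- c(q, numeric(length(model) - length(q)))
  s <- model > 0L
  xs <- x[s]
  l1 <- lgamma(sum(xs) + 1) - sum(lgamma(xs + 1)) +
    sum(xs * log(model[s] / n))
  xe <- x[!s]
  l2 <- -sum(xe * q[!s] / 10) * log(10)
  l1 + l2
}

#' Call the allele-dosage genotype at one locus
#'
#' Applies the coverage window (at least `5 * ploidy` reads, at most
#' `cov_max`; bounds inclusive), scores every dosage model of the ploidy
#' with [model_loglik()], and selects the model minimizing
#' `BIC = k_model * ln(N) - 2 * logL`, where `N` is the total read count at
#' the locus and `k_model` the number of non-zero dosage entries. BIC ties
#' are broken toward fewer distinct alleles, then toward the larger leading
#' dosage (conservative against overcalling heterozygosity).
#'
#' @param rec `allele_counts` rows of one (sample, locus) record.
#' @param n ploidy of the sample.
#' @param cov_min minimum coverage (default `5 * n`).
#' @param cov_max maximum coverage (default 200).
#' @return a `genotype_call` list: `locus_id`, `status` (`called`,
#'   `missing_low_cov`, `missing_high_cov` or `ambiguous`), `genotype`
#'   (canonical string or `NA`), `dosages` (named integer vector), `model`,
#'   `loglik`, `bic`, `delta_bic_runnerup`.
#' @export
call_genotype <- function(rec, n, cov_min = 5L * n, cov_max = 200L) {
  if (is.null(n) || is.na(n)) stop("ploidy must be known to call genotypes")
  locus <- rec$locus_id[1L]
  total <- sum(rec$count)
  empty <- function(status)
    structure(list(locus_id = locus, status = status, genotype = NA_character_,
                   dosages = NULL, model = NULL, loglik = NA_real_,
                   bic = NA_real_, delta_bic_runnerup = NA_real_),
              class = "genotype_call")
  if (total < cov_min) return(empty("missing_low_cov"))
  if (total > cov_max) return(empty("missing_high_cov"))
  prep <- prepare_counts(rec, n)
  models <- enumerate_dosage_models(n)
  ll <- vapply(models, function(m) model_loglik(prep$x, prep$q, m), 0)
  kmod <- vapply(models, function(m) sum(m > 0L), 0L)
  bic <- kmod * log(total) - 2 * ll
  tol <- 1e-9 * max(1, abs(min(bic)))
  cand <- which(bic <= min(bic) + tol)
  if (length(cand) > 1L) {
    cand <- cand[kmod[cand] == min(kmod[cand])]
    lead <- vapply(models[cand], `[`, 0L, 1L)
    cand <- cand[which.max(lead)]
  }
  best <- cand[1L]
  m <- models[[best]]
  n_distinct <- sum(m > 0L)
  status <- "called"
  if (n_distinct > length(prep$alleles)) {
    # best model expects more distinct alleles than were observed at all;
    # copy numbers cannot be attached to labels
    status <- "ambiguous"
    dos <- NULL
    geno <- NA_character_
  } else {
    dos <- setNames(m[seq_len(n_distinct)], prep$alleles[seq_len(n_distinct)])
    geno <- format_genotype(dos)
  }
  runner <- if (length(bic) > 1L) sort(bic)[2L] - min(bic) else Inf
  structure(list(locus_id = locus, status = status, genotype = geno,
                 dosages = dos, model = m, loglik = ll[best],
                 bic = bic[best], delta_bic_runnerup = max(runner, 0)),
            class = "genotype_call")
}

#' Genotype every locus of one sample
#'
#' @param recs `allele_counts` records of a single sample.
#' @param n ploidy of the sample.
#' @param cov_min,cov_max coverage window (see [call_genotype()]).
#' @return data frame with one row per locus: `locus_id`, `status`,
#'   `genotype`, `loglik`, `bic`, `delta_bic_runnerup`. Input locus order
#'   is preserved. Attribute `n_called` / `n_missing` summarize the column.
#' @export
genotype_sample <- function(recs, n, cov_min = 5L * n, cov_max = 200L) {
  if (nrow(recs) == 0L) {
    out <- data.frame(locus_id = character(), status = character(),
                      genotype = character(), loglik = numeric(),
                      bic = numeric(), delta_bic_runnerup = numeric(),
                      stringsAsFactors = FALSE)
    attr(out, "n_called") <- 0L; attr(out, "n_missing") <- 0L
    return(out)
  }
  if (length(unique(recs$sample_id)) > 1L)
    stop("genotype_sample expects records from a single sample")
  loci <- unique(recs$locus_id)
  spl <- split(seq_len(nrow(recs)), factor(recs$locus_id, levels = loci))
  calls <- lapply(spl, function(idx)
    call_genotype(recs[idx, , drop = FALSE], n, cov_min, cov_max))
  out <- data.frame(
    locus_id = loci,
    status = vapply(calls, `[[`, "", "status"),
    genotype = vapply(calls, `[[`, "", "genotype"),
    loglik = vapply(calls, `[[`, 0, "loglik"),
    bic = vapply(calls, `[[`, 0, "bic"),
    delta_bic_runnerup = vapply(calls, `[[`, 0, "delta_bic_runnerup"),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_called") <- sum(out$status == "called")
  attr(out, "n_missing") <- sum(out$status != "called")
  out
}

#' Assemble per-sample genotype calls into a genotype matrix
#'
#' @param call_list named list (by sample id) of [genotype_sample()]
#'   outputs.
#' @param ploidy named integer vector of per-sample ploidies.
#' @return a [genotype_matrix()]; loci are the union of loci seen, calls
#'   with non-`called` status are missing.
#' @export
build_genotype_matrix <- function(call_list, ploidy) {
  samples <- names(call_list)
  loci <- unique(unlist(lapply(call_list, `[[`, "locus_id"), use.names = FALSE))
  calls <- matrix(NA_character_, nrow = length(samples), ncol = length(loci),
                  dimnames = list(samples, loci))
  for (s in samples) {
    df <- call_list[[s]]
    ok <- df$status == "called"
    calls[s, df$locus_id[ok]] <- df$genotype[ok]
  }
  genotype_matrix(calls, ploidy[samples])
}
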