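#' Simulation configuration
#'
#' Defines the statistical conditions of a synthetic RAD read-count data
#' set: per-locus coverage follows a (>= 1 truncated) negative binomial;
#' allele counts at heterozygous sites are beta-binomially overdispersed
#' around the dosage expectation with correlation `rho`; each read is
#' miscalled with probability `error_rate` to a uniformly random base not
#' in the true genotype; per-allele mean phred qualities are the constant
#' `-10 log10(error_rate)` (or `phred_default` when the error rate is 0).
#' Defaults mirror a typical RAD experiment: mean coverage 60 with
#' dispersion 5, `rho = 0.02`, `error_rate = 0.005`, population allele
#' frequencies uniform on (0.05, 0.95), Hardy-Weinberg-like binomial
#' dosage sampling.
#'
#' @param n_samples samples simulated per ploidy class.
#' @param ploidies integer subset of 2:4.
#' @param n_loci loci per data set.
#' @param coverage_law list: `dist = "nbinom"` with `mean`, `size`, or
#'   `dist = "fixed"` with `value`.
#' @param rho beta-binomial intraclass correlation in [0, 1); 0 gives
#'   binomial counts.
#' @param error_rate per-read miscall probability.
#' @param phred_default phred attached when `error_rate = 0`.
#' @param allele_freq_law list: `dist = "uniform"` with `min`, `max`.
#' @param group_divergence optional Balding-Nichols F for a two-deme
#'   scenario (deme frequencies drawn from
#'   `Beta(q(1-F)/F, (1-q)(1-F)/F)` around the ancestral frequency `q`).
#' @param triallelic_prop,tetraallelic_prop fraction of loci planted with
#'   a third (fourth) segregating allele.
#' @param seed mandatory integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_samples = 30L, ploidies = c(2L, 3L, 4L),
                       n_loci = 2000L,
                       coverage_law = list(dist = "nbinom", mean = 60, size = 5),
                       rho = 0.02, error_rate = 0.005, phred_default = 40,
                       allele_freq_law = list(dist = "uniform",
                                              min = 0.05, max = 0.95),
                       group_divergence = NULL,
                       triallelic_prop = 0, tetraallelic_prop = 0,
                       seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  stopifnot(n_samples >= 1L, n_loci >= 1L,
            all(ploidies %in% 2:4),
            rho >= 0, rho < 1, error_rate >= 0, error_rate < 1,
            triallelic_prop >= 0, tetraallelic_prop >= 0,
            triallelic_prop + tetraallelic_prop <= 1)
  if (!coverage_law$dist %in% c("nbinom", "fixed"))
    stop("unsupported coverage law: ", coverage_law$dist)
  if (!allele_freq_law$dist %in% "uniform")
    stop("unsupported allele frequency law: ", allele_freq_law$dist)
  structure(list(n_samples = as.integer(n_samples),
                 ploidies = as.integer(ploidies), n_loci = as.integer(n_loci),
                 coverage_law = coverage_law, rho = rho,
                 error_rate = error_rate, phred_default = phred_default,
                 allele_freq_law = allele_freq_law,
                 group_divergence = group_divergence,
                 triallelic_prop = triallelic_prop,
                 tetraallelic_prop = tetraallelic_prop,
                 seed = as.integer(seed)),
            class = "sim_config")
}

draw_coverage <- function(law, n) {
  if (law$dist == "fixed") return(rep(as.integer(law$value), n))
  cov <- rnbinom(n, mu = law$mean, size = law$size)
  while (any(cov < 1L))                      # truncate to >= 1 by redraw
    cov[cov < 1L] <- rnbinom(sum(cov < 1L), mu = law$mean, size = law$size)
  cov
}

sim_phred <- function(cfg) {
  if (cfg$error_rate > 0) -10 * log10(cfg$error_rate) else cfg$phred_default
}

# draw a table of loci: ids, ref/alt bases, allele frequencies (and extra
# alleles for planted multi-allelic loci)
draw_loci <- function(cfg) {
  L <- cfg$n_loci
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, L, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  freq <- runif(L, cfg$allele_freq_law$min, cfg$allele_freq_law$max)
  n_tri <- round(cfg$triallelic_prop * L)
  n_tet <- round(cfg$tetraallelic_prop * L)
  extra <- integer(L)
  if (n_tri + n_tet > 0L) {
    pick <- sample.int(L, n_tri + n_tet)
    extra[pick] <- rep(c(1L, 2L), c(n_tri, n_tet))
  }
  data.frame(locus_id = sprintf("ctg%05d:%d", seq_len(L), 101L),
             ref = ref, alt = alt, freq = freq, n_extra = extra,
             stringsAsFactors = FALSE)
}

# per-locus allele label sets (ref, alt, planted extras)
locus_alleles <- function(loci) {
  bases <- c("A", "C", "G", "T")
  lapply(seq_len(nrow(loci)), function(j) {
    al <- c(loci$ref[j], loci$alt[j])
    if (loci$n_extra[j] > 0L)
      al <- c(al, sample(setdiff(bases, al), loci$n_extra[j]))
    al
  })
}

sim_one_sample <- function(cfg, ploidy, sample_id, loci, allele_sets,
                           freqs = NULL, het_only = FALSE) {
  L <- nrow(loci)
  k <- ploidy
  f <- if (is.null(freqs)) loci$freq else freqs
  multi <- loci$n_extra > 0L
  # genotype dosage of the alt allele (biallelic loci)
  if (het_only) {
    pr <- vapply(f, function(p) {
      d <- dbinom(1:(k - 1L), k, p); d / sum(d)
    }, numeric(k - 1L))
    if (k == 2L) dos <- rep(1L, L)
    else dos <- apply(matrix(pr, nrow = k - 1L), 2L,
                      function(p) sample.int(k - 1L, 1L, prob = p))
  } else {
    dos <- rbinom(L, k, f)
  }
  n <- draw_coverage(cfg$coverage_law, L)
  p0 <- dos / k
  y <- integer(L)
  mid <- p0 > 0 & p0 < 1
  if (cfg$rho > 0 && any(mid)) {
    a <- p0[mid] * (1 - cfg$rho) / cfg$rho
    b <- (1 - p0[mid]) * (1 - cfg$rho) / cfg$rho
    pl <- rbeta(sum(mid), a, b)
    y[mid] <- rbinom(sum(mid), n[mid], pl)
  } else if (any(mid)) {
    y[mid] <- rbinom(sum(mid), n[mid], p0[mid])
  }
  y[p0 == 1] <- n[p0 == 1]

  q <- sim_phred(cfg)
  e <- cfg$error_rate
  geno_str <- character(L)
  rows <- vector("list", L)
  bases_all <- c("A", "C", "G", "T")
  for (j in seq_len(L)) {
    al <- allele_sets[[j]]
    if (multi[j]) {
      # planted multi-allelic locus: multinomial genotype and reads
      fj <- c(1 - 0.15 * loci$n_extra[j] - f[j] * (1 - 0.15 * loci$n_extra[j]),
              f[j] * (1 - 0.15 * loci$n_extra[j]),
              rep(0.15, loci$n_extra[j]))
      g <- as.integer(rmultinom(1L, k, fj))
      reads <- as.integer(rmultinom(1L, n[j], g / k))
    } else {
      g <- c(k - dos[j], dos[j])
      reads <- c(n[j] - y[j], y[j])
    }
    names(g) <- names(reads) <- al
    # per-read miscalls onto bases outside the true genotype
    if (e > 0) {
      kept <- setNames(rbinom(length(reads), reads, 1 - e), names(reads))
      n_err <- sum(reads - kept)
      reads <- kept
      if (n_err > 0L) {
        tgt <- setdiff(bases_all, al[g > 0L])
        if (length(tgt) > 0L) {
          err_counts <- as.integer(rmultinom(1L, n_err,
                                             rep(1 / length(tgt), length(tgt))))
          names(err_counts) <- tgt
          hit <- tgt %in% names(reads)
          reads[tgt[hit]] <- reads[tgt[hit]] + err_counts[hit]
          if (any(!hit)) reads <- c(reads, err_counts[!hit])
        }
      }
    }
    reads <- reads[reads > 0L | names(reads) %in% al]
    rows[[j]] <- data.frame(locus_id = loci$locus_id[j],
                            allele = names(reads),
                            count = as.integer(reads),
                            stringsAsFactors = FALSE)
    geno_str[j] <- format_genotype(g)
  }
  counts <- do.call(rbind, rows)
  counts <- data.frame(sample_id = sample_id, counts,
                       mean_phred = q, stringsAsFactors = FALSE)
  truth <- data.frame(locus_id = loci$locus_id, ploidy = k,
                      dosage_alt = ifelse(multi, NA_integer_, dos),
                      genotype = geno_str, coverage = n,
                      stringsAsFactors = FALSE)
  list(counts = as_allele_counts(counts), truth = truth)
}

#' Simulate read counts for one individual
#'
#' Per locus: a population allele frequency is drawn from the configured
#' law, a genotype dosage from `Binomial(ploidy, freq)` (or conditioned on
#' heterozygosity with `het_only = TRUE`), a coverage from the coverage
#' law, the focal-allele read count from a beta-binomial with correlation
#' `rho`, and sequencing errors are sprinkled onto non-genotype bases at
#' `error_rate`, with phreds consistent with the error rate.
#'
#' @param cfg a [sim_config()].
#' @param ploidy ploidy of the individual.
#' @param sample_id sample identifier.
#' @param het_only condition every locus on being heterozygous (useful to
#'   generate a fixed number of ratio observations).
#' @param seed optional seed overriding `cfg$seed`.
#' @return list with `counts` (an `allele_counts` data frame) and `truth`
#'   (per-locus dosage, genotype string, coverage).
#' @export
simulate_individual <- function(cfg, ploidy, sample_id = "S001",
                                het_only = FALSE, seed = cfg$seed) {
  set.seed(seed)
  loci <- draw_loci(cfg)
  allele_sets <- locus_alleles(loci)
  sim_one_sample(cfg, ploidy, sample_id, loci, allele_sets,
                 het_only = het_only)
}

#' Simulate a multi-sample cohort with ground truth
#'
#' Simulates `n_samples` individuals per configured ploidy over a shared
#' locus set. With `group_divergence = F`, samples are split into two
#' demes whose per-locus frequencies diverge from the shared ancestral
#' frequency under the Balding-Nichols model. Metadata (species label by
#' ploidy, population, latitude, raw read count) is generated alongside.
#' Optionally writes the data set to disk as a VCF with AD fields or a
#' tabular variant file readable by [read_vcf_allele_depths()] /
#' [read_variant_table()].
#'
#' @param cfg a [sim_config()].
#' @param dir optional output directory.
#' @param format `"none"`, `"vcf"` or `"table"`.
#' @return list with `counts` (all samples, long format), `meta` (sample
#'   metadata), `truth` (list: `ploidy`, `genotype` samples x loci string
#'   matrix, `allelicity` realized distinct-allele count per locus,
#'   `freq`, `deme_freq`, `loci`) and `paths` (written files, if any).
#' @export
simulate_cohort <- function(cfg, dir = NULL,
                            format = c("none", "vcf", "table")) {
  format <- match.arg(format)
  set.seed(cfg$seed)
  loci <- draw_loci(cfg)
  allele_sets <- locus_alleles(loci)
  ploidy_vec <- rep(cfg$ploidies, each = cfg$n_samples)
  ids <- sprintf("S%03d_k%d", seq_along(ploidy_vec), ploidy_vec)
  two_demes <- !is.null(cfg$group_divergence)
  if (two_demes) {
    FF <- cfg$group_divergence
    q <- loci$freq
    deme_freq <- cbind(rbeta(nrow(loci), q * (1 - FF) / FF,
                             (1 - q) * (1 - FF) / FF),
                       rbeta(nrow(loci), q * (1 - FF) / FF,
                             (1 - q) * (1 - FF) / FF))
    deme <- rep_len(1:2, length(ids))
  } else {
    deme_freq <- NULL
    deme <- rep(1L, length(ids))
  }
  counts <- vector("list", length(ids))
  geno <- matrix(NA_character_, nrow = length(ids), ncol = nrow(loci),
                 dimnames = list(ids, loci$locus_id))
  for (i in seq_along(ids)) {
    fr <- if (two_demes) deme_freq[, deme[i]] else NULL
    sim <- sim_one_sample(cfg, ploidy_vec[i], ids[i], loci, allele_sets,
                          freqs = fr)
    counts[[i]] <- sim$counts
    geno[i, ] <- sim$truth$genotype
  }
  counts <- as_allele_counts(do.call(rbind, counts))
  allelicity <- apply(geno, 2L, function(col)
    length(unique(unlist(lapply(col, function(s) names(parse_genotype(s)))))))
  meta <- data.frame(
    sample_id = ids,
    species_label = c(`2` = "diploid_sp", `3` = "triploid",
                      `4` = "tetraploid_sp")[as.character(ploidy_vec)],
    population_id = if (two_demes) paste0("deme", deme) else "pop1",
    latitude = round(runif(length(ids), 50, 60), 3),
    raw_read_count = round(runif(length(ids), 2e6, 9e6)),
    stringsAsFactors = FALSE)
  truth <- list(ploidy = setNames(ploidy_vec, ids), genotype = geno,
                allelicity = allelicity, freq = loci$freq,
                deme_freq = deme_freq, loci = loci)
  paths <- NULL
  if (format != "none") {
    if (is.null(dir)) stop("dir required when writing output")
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    if (format == "vcf") {
      p <- file.path(dir, "cohort.vcf")
      write_counts_vcf(counts, p)
    } else {
      p <- file.path(dir, "cohort.tsv")
      write.table(counts, p, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    pm <- file.path(dir, "meta.tsv")
    write.table(meta, pm, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(data = p, meta = pm)
  }
  list(counts = counts, meta = meta, truth = truth, paths = paths)
}

#' Write allele-count records as a minimal VCF with AD fields
#'
#' Emits a VCF (v4.2) whose only FORMAT field is `AD`: per site, the REF
#' allele is the first allele listed at that locus and ALT collects every
#' other allele observed in any sample (the deletion symbol `"-"` is coded
#' as `*`). Intended for simulator output; re-read with
#' [read_vcf_allele_depths()].
#'
#' @param counts an `allele_counts` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts_vcf <- function(counts, path) {
  samples <- unique(counts$sample_id)
  loci <- unique(counts$locus_id)
  chrom <- sub(":[0-9]+$", "", loci)
  pos <- sub("^.*:", "", loci)
  by_locus <- split(counts, factor(counts$locus_id, levels = loci))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  lines <- character(length(loci))
  for (j in seq_along(loci)) {
    d <- by_locus[[j]]
    al <- unique(d$allele)
    ref <- al[1L]
    alt <- if (length(al) > 1L) al[-1L] else "."
    ad <- vapply(samples, function(s) {
      rows <- d[d$sample_id == s, ]
      if (nrow(rows) == 0L) return(".")
      cnt <- setNames(rep(0L, length(al)), al)
      cnt[rows$allele] <- rows$count
      paste(cnt, collapse = ",")
    }, "")
    enc <- function(a) ifelse(a == "-", "*", a)
    lines[j] <- paste(c(chrom[j], pos[j], ".", enc(ref),
                        paste(enc(alt), collapse = ","), ".", "PASS", ".",
                        "AD", ad), collapse = "\t")
  }
  writeLines(lines, con)
  invisible(path)
}

#' Simulate a latitudinal admixture gradient
#'
#' Generates per-individual admixture proportions whose arcsine-transformed
#' values follow `beta0 + beta1 * latitude + u_pop + eps`, with population
#' random intercepts `u_pop ~ N(0, sigma_pop^2)` and residual noise
#' `eps ~ N(0, sigma_resid^2)`; Q is recovered as `sin(y)^2` with `y`
#' clamped to `[0, pi/2]`.
#'
#' @param n_pops number of populations.
#' @param per_pop individuals per population.
#' @param beta0,beta1 intercept and slope on the arcsine scale.
#' @param sigma_pop,sigma_resid random-intercept and residual SDs.
#' @param lat_range latitude range populations are spread over.
#' @param seed integer seed.
#' @return list with `records` (AdmixtureRecord data frame: `sample_id`,
#'   `Q`, `population_id`, `latitude`) and `truth` (the parameters).
#' @export
simulate_admixture_cline <- function(n_pops = 20L, per_pop = 6L,
                                     beta0 = 0.8, beta1 = -0.01,
                                     sigma_pop = 0.05, sigma_resid = 0.05,
                                     lat_range = c(50, 60), seed) {
  if (missing(seed)) stop("a seed is mandatory")
  set.seed(seed)
  lat_pop <- seq(lat_range[1L], lat_range[2L], length.out = n_pops)
  u <- rnorm(n_pops, 0, sigma_pop)
  recs <- do.call(rbind, lapply(seq_len(n_pops), function(p) {
    y <- beta0 + beta1 * lat_pop[p] + u[p] + rnorm(per_pop, 0, sigma_resid)
    y <- pmin(pmax(y, 0), pi / 2)
    data.frame(sample_id = sprintf("P%02dI%02d", p, seq_len(per_pop)),
               Q = sin(y)^2,
               population_id = sprintf("pop%02d", p),
               latitude = lat_pop[p], stringsAsFactors = FALSE)
  }))
  list(records = recs,
       truth = list(beta0 = beta0, beta1 = beta1, sigma_pop = sigma_pop,
                    sigma_resid = sigma_resid, u = u))
}

#' Compare genotype calls with simulator ground truth
#'
#' @param calls a [genotype_matrix()] of calls.
#' @param truth the `truth` element of [simulate_cohort()] (needs
#'   `ploidy` and `genotype`).
#' @param ploidy_calls optional named integer vector of inferred ploidies
#'   to score against the true ones.
#' @return a `truth_comparison` list: `per_ploidy` (data frame with called
#'   / missing counts and accuracy; accuracy is `NA` when nothing was
#'   called), `confusion` (table of true vs called dosage patterns at
#'   shared loci), `ploidy_accuracy` (or `NA`).
#' @export
truth_compare <- function(calls, truth, ploidy_calls = NULL) {
  samples <- intersect(rownames(calls$calls), rownames(truth$genotype))
  loci <- intersect(colnames(calls$calls), colnames(truth$genotype))
  if (length(samples) == 0L || length(loci) == 0L)
    stop("calls and truth share no samples/loci")
  cm <- calls$calls[samples, loci, drop = FALSE]
  tm <- truth$genotype[samples, loci, drop = FALSE]
  kvec <- truth$ploidy[samples]
  pattern <- function(s) paste(sort(parse_genotype(s), decreasing = TRUE),
                               collapse = ":")
  per <- lapply(sort(unique(kvec)), function(k) {
    sel <- kvec == k
    called <- !is.na(cm[sel, , drop = FALSE])
    n_called <- sum(called)
    acc <- if (n_called > 0L)
      mean(cm[sel, , drop = FALSE][called] == tm[sel, , drop = FALSE][called])
    else NA_real_
    data.frame(ploidy = k, n_called = n_called,
               n_missing = sum(!called), accuracy = acc)
  })
  per <- do.call(rbind, per)
  called <- !is.na(cm)
  confusion <- if (any(called)) {
    tp <- vapply(tm[called], pattern, "")
    cp <- vapply(cm[called], pattern, "")
    table(truth = tp, called = cp)
  } else NULL
  pacc <- NA_real_
  if (!is.null(ploidy_calls)) {
    shared <- intersect(names(ploidy_calls), samples)
    pacc <- mean(ploidy_calls[shared] == truth$ploidy[shared])
  }
  structure(list(per_ploidy = per, confusion = confusion,
                 ploidy_accuracy = pacc),
            class = "truth_comparison")
}

#' @export
print.truth_comparison <- function(x, ...) {
  cat("truth comparison\n")
  print(x$per_ploidy, row.names = FALSE)
  if (!is.na(x$ploidy_accuracy))
    cat(sprintf("ploidy classification accuracy: %.3f\n", x$ploidy_accuracy))
  invisible(x)
}
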