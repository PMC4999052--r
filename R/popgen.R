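#' Ploidy-normalized allele-frequency matrix
#'
#' Converts a genotype matrix to within-individual allele frequencies: at
#' each biallelic locus, the counted allele is the second in allele sort
#' order and each sample's value is its copy number divided by the
#' sample's ploidy (a tetraploid `A:3,T:1` gives 0.25 for `T`; a diploid
#' `A:1,T:1` gives 0.5). Missing calls stay missing (`NA`).
#'
#' @param gm a [genotype_matrix()].
#' @param biallelic_only keep only loci with exactly two distinct alleles
#'   across all non-missing calls (default `TRUE`; dosage-to-frequency
#'   coding of a single counted allele is only meaningful there).
#' @return numeric samples x loci matrix with attributes
#'   `counted_allele` (named character), `ploidy` (named integer) and
#'   `n_dropped_nonbiallelic`.
#' @export
freq_matrix <- function(gm, biallelic_only = TRUE) {
  sets <- locus_allele_sets(gm)
  nal <- lengths(sets)
  keep <- if (biallelic_only) nal == 2L else nal >= 1L
  loci <- colnames(gm$calls)[keep]
  counted <- vapply(sets[keep], function(a) a[min(2L, length(a))], "")
  names(counted) <- loci
  out <- matrix(NA_real_, nrow = nrow(gm$calls), ncol = length(loci),
                dimnames = list(rownames(gm$calls), loci))
  # parse each distinct genotype string once
  u <- unique(gm$calls[!is.na(gm$calls)])
  parsed <- lapply(u, parse_genotype)
  names(parsed) <- u
  cols <- which(keep)
  for (jj in seq_along(cols)) {
    col <- gm$calls[, cols[jj]]
    nz <- !is.na(col)
    dos <- vapply(parsed[col[nz]], function(g) {
      v <- g[counted[jj]]
      if (is.na(v)) 0L else as.integer(v)
    }, 0L)
    out[nz, jj] <- dos / gm$ploidy[nz]
  }
  attr(out, "counted_allele") <- counted
  attr(out, "ploidy") <- gm$ploidy
  attr(out, "n_dropped_nonbiallelic") <- sum(!keep)
  out
}

#' Impute missing allele frequencies
#'
#' `"mean"` replaces each missing entry by its locus (column) mean.
#' `"iterative-lowrank"` starts from the mean imputation and alternates a
#' rank-`ncp` truncated-SVD reconstruction with re-imputation of the
#' missing cells until the largest change is below `tol` or `maxit`
#' iterations, clamping to the unit interval.
#'
#' @param freqs numeric matrix with `NA`s (e.g. from [freq_matrix()]).
#' @param method `"mean"` or `"iterative-lowrank"`.
#' @param ncp rank of the low-rank reconstruction (default 2).
#' @param tol,maxit convergence controls for the iterative method.
#' @return the completed matrix (attributes preserved).
#' @export
impute_missing <- function(freqs, method = c("mean", "iterative-lowrank"),
                           ncp = 2L, tol = 1e-6, maxit = 100L) {
  method <- match.arg(method)
  x <- freqs
  miss <- is.na(x)
  if (!any(miss)) return(freqs)
  if (any(colSums(!miss) == 0L))
    stop("all-missing locus: ",
         paste(colnames(x)[colSums(!miss) == 0L], collapse = ", "))
  if (any(rowSums(!miss) == 0L))
    stop("all-missing sample: ",
         paste(rownames(x)[rowSums(!miss) == 0L], collapse = ", "))
  mu <- colMeans(x, na.rm = TRUE)
  x[miss] <- mu[col(x)[miss]]
  if (method == "iterative-lowrank") {
    ncp <- min(ncp, dim(x) - 1L)
    for (it in seq_len(maxit)) {
      ctr <- colMeans(x)
      xc <- sweep(x, 2L, ctr)
      sv <- svd(xc, nu = ncp, nv = ncp)
      recon <- sv$u %*% (sv$d[seq_len(ncp)] * t(sv$v))
      recon <- sweep(recon, 2L, ctr, `+`)
      recon <- pmin(pmax(recon, 0), 1)
      delta <- max(abs(recon[miss] - x[miss]))
      x[miss] <- recon[miss]
      if (delta < tol) break
    }
  }
  for (a in setdiff(names(attributes(freqs)), c("dim", "dimnames")))
    attr(x, a) <- attr(freqs, a)
  x
}

fst_locus_components <- function(freqs, groups, ploidy) {
  gl <- split(seq_len(nrow(freqs)), groups)
  comp <- lapply(gl, function(idx) {
    sub <- freqs[idx, , drop = FALSE]
    w <- matrix(ploidy[idx], nrow = length(idx), ncol = ncol(sub))
    w[is.na(sub)] <- 0
    n <- colSums(w)                       # allele copies with data
    p <- colSums(sub * w, na.rm = TRUE) / ifelse(n > 0, n, NA)
    list(p = p, n = n)
  })
  comp
}

#' F_ST from ploidy-normalized allele frequencies
#'
#' Default estimator (`method = "nei"`) is the Nei-style ratio of averages
#' `1 - mean(H_S) / mean(H_T)`: per locus, `H_S` is the allele-copy-
#' weighted mean of the within-group expected heterozygosities
#' `2 p_g (1 - p_g)` and `H_T = 2 p. (1 - p.)` uses the pooled
#' (copy-weighted) mean frequency. `method = "hudson"` is the sample-size-
#' corrected two-group ratio-of-averages estimator
#' (`sum N_l / sum D_l` with
#' `N = (p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and
#' `D = p1(1-p2) + p2(1-p1)`), which is approximately unbiased for the
#' divergence parameter with few groups; use it when estimating a
#' Balding-Nichols-type F from two demes.
#'
#' @param freqs matrix from [freq_matrix()] (or any samples x loci
#'   frequency matrix).
#' @param groups factor/character of group membership per sample (named or
#'   in row order).
#' @param mode `"global"` (scalar), `"pairwise"` (group x group matrix of
#'   global estimates) or `"per_locus"` (vector; `NaN` where `H_T = 0`).
#' @param method `"nei"` or `"hudson"` (the latter requires exactly two
#'   groups except in pairwise mode).
#' @param ploidy per-sample allele-copy weights; defaults to the matrix's
#'   `ploidy` attribute, else 2.
#' @return raw (unclipped) estimate(s); small negatives are possible for
#'   the corrected estimator.
#' @export
fst <- function(freqs, groups, mode = c("global", "pairwise", "per_locus"),
                method = c("nei", "hudson"), ploidy = NULL) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  if (is.null(ploidy)) ploidy <- attr(freqs, "ploidy")
  if (is.null(ploidy)) ploidy <- rep(2L, nrow(freqs))
  if (!is.null(names(groups)) && !is.null(rownames(freqs)))
    groups <- groups[rownames(freqs)]
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (mode == "pairwise") {
    lv <- levels(groups)
    out <- matrix(NA_real_, nlevels(groups), nlevels(groups),
                  dimnames = list(lv, lv))
    for (i in seq_along(lv)[-length(lv)]) for (j in seq.int(i + 1L, length(lv))) {
      sel <- groups %in% lv[c(i, j)]
      out[i, j] <- out[j, i] <-
        fst(freqs[sel, , drop = FALSE], droplevels(groups[sel]), "global",
            method, ploidy[sel])
    }
    diag(out) <- 0
    return(out)
  }
  comp <- fst_locus_components(freqs, groups, ploidy)
  ng <- length(comp)
  pm <- do.call(rbind, lapply(comp, `[[`, "p"))   # groups x loci
  nm <- do.call(rbind, lapply(comp, `[[`, "n"))
  has_data <- colSums(!is.na(pm) & nm > 0) == ng
  if (any(vapply(comp, function(g) all(g$n == 0), TRUE)))
    stop("a group has no data at any locus")
  if (method == "nei") {
    hs <- colSums(nm * 2 * pm * (1 - pm), na.rm = TRUE) / colSums(nm)
    pbar <- colSums(nm * pm, na.rm = TRUE) / colSums(nm)
    ht <- 2 * pbar * (1 - pbar)
    if (mode == "per_locus") {
      v <- 1 - hs / ht                     # NaN where ht == 0
      v[!has_data] <- NA_real_
      return(v)
    }
    ok <- has_data
    if (sum(ht[ok]) == 0) return(NaN)
    return(1 - sum(hs[ok]) / sum(ht[ok]))
  }
  # hudson: exactly two groups
  if (ng != 2L) stop("method 'hudson' requires exactly two groups")
  p1 <- pm[1L, ]; p2 <- pm[2L, ]; n1 <- nm[1L, ]; n2 <- nm[2L, ]
  ok <- has_data & n1 > 1 & n2 > 1
  N <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  D <- p1 * (1 - p2) + p2 * (1 - p1)
  if (mode == "per_locus") {
    v <- ifelse(D == 0, NaN, N / D)
    v[!ok] <- NA_real_
    return(v)
  }
  if (sum(D[ok]) == 0) return(NaN)
  sum(N[ok]) / sum(D[ok])
}

#' PCA scores of a complete frequency matrix
#'
#' Column-centered SVD (no scaling). Scores are deterministic up to sign;
#' the sign convention makes the largest-magnitude loading of each
#' component positive.
#'
#' @param freqs complete numeric matrix (impute first).
#' @param n_components number of components to return.
#' @return list with `scores` (samples x components), `explained`
#'   (variance fractions, all components) and `loadings`.
#' @export
pca_scores <- function(freqs, n_components = 2L) {
  if (anyNA(freqs)) stop("matrix must be complete; impute missing values first")
  if (n_components > min(dim(freqs)))
    stop("n_components exceeds matrix dimensions")
  pr <- prcomp(freqs, center = TRUE, scale. = FALSE)
  nc <- min(n_components, ncol(pr$x))
  tot <- sum(pr$sdev^2)
  explained <- if (tot > 0) pr$sdev^2 / tot else rep(0, length(pr$sdev))
  scores <- pr$x[, seq_len(nc), drop = FALSE]
  load <- pr$rotation[, seq_len(nc), drop = FALSE]
  for (j in seq_len(nc)) {
    flip <- sign(load[which.max(abs(load[, j])), j])
    if (flip < 0) { scores[, j] <- -scores[, j]; load[, j] <- -load[, j] }
  }
  list(scores = scores, explained = explained, loadings = load)
}

#' Latitudinal cline regression on admixture proportions
#'
#' Fits the mixed-effects model
#' `asin(sqrt(Q)) ~ latitude + (1 | population)` by REML: the latitudinal
#' slope is a fixed effect and the population a random intercept, allowing
#' populations to drift away from the overall trend. The slope p-value is
#' a Wald test against the normal reference (documented as approximate).
#'
#' @param records data frame with columns `sample_id`, `Q` (admixture
#'   proportion in the unit interval), `population_id`, `latitude`.
#' @return a `cline_fit` list: `slope` (per degree latitude on the arcsine
#'   scale), `slope_se`, `p_value`, `intercept`, `sigma2_pop`,
#'   `sigma2_resid`, `population_effects` (random intercepts),
#'   `population_means` (fitted mean per population at its mean latitude),
#'   `model` (the lmer fit).
#' @export
cline_fit <- function(records) {
  if (any(records$Q < 0 | records$Q > 1)) stop("Q must lie in [0, 1]")
  if (length(unique(records$population_id)) < 3L)
    stop("need at least 3 populations")
  if (length(unique(records$latitude)) < 2L)
    stop("degenerate design: latitude does not vary")
  d <- data.frame(y = asin(sqrt(records$Q)),
                  latitude = records$latitude,
                  population = factor(records$population_id))
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(y ~ latitude + (1 | population), data = d, REML = TRUE)))
  co <- summary(fit)$coefficients
  slope <- co["latitude", "Estimate"]
  se <- co["latitude", "Std. Error"]
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2_pop <- vc$vcov[vc$grp == "population"][1L]
  s2_res <- vc$vcov[vc$grp == "Residual"][1L]
  re <- lme4::ranef(fit)$population
  u <- setNames(re[, 1L], rownames(re))
  lat_mean <- tapply(d$latitude, d$population, mean)
  fe <- lme4::fixef(fit)
  pop_means <- fe[1L] + fe[2L] * lat_mean[names(u)] + u
  structure(list(slope = slope, slope_se = se,
                 p_value = 2 * pnorm(-abs(slope / se)),
                 intercept = fe[[1L]],
                 sigma2_pop = s2_pop, sigma2_resid = s2_res,
                 population_effects = u,
                 population_means = setNames(as.numeric(pop_means), names(u)),
                 model = fit),
            class = "cline_fit")
}

#' @export
print.cline_fit <- function(x, ...) {
  cat(sprintf("cline_fit: slope %.5f (SE %.5f) per degree latitude, p = %.3g\n",
              x$slope, x$slope_se, x$p_value))
  cat(sprintf("variance components: population %.5g, residual %.5g\n",
              x$sigma2_pop, x$sigma2_resid))
  invisible(x)
}
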