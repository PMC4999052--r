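#' Candidate-ploidy model specification
#'
#' For a candidate ploidy `k`, the expected focal-allele read fraction at a
#' heterozygous site takes values on the grid `{1/k, ..., (k-1)/k}`: a
#' diploid has the single expectation 0.5, a triploid 1/3 and 2/3, a
#' tetraploid 1/4, 1/2 and 3/4. Observed ratios are censored to
#' `[censor_lo, censor_hi]` (inclusive) to exclude loci that are in fact
#' homozygous but appear heterozygous through mistyping.
#'
#' @param k candidate ploidy (integer >= 2).
#' @param censor length-2 numeric, the inclusive censoring window.
#' @return a `ploidy_model_spec` list with fields `k`, `p_grid`,
#'   `censor_lo`, `censor_hi`.
#' @export
ploidy_model_spec <- function(k, censor = c(0.1, 0.9)) {
  k <- as.integer(k)
  if (k < 2L) stop("candidate ploidy must be >= 2")
  if (length(censor) != 2L || censor[1L] >= censor[2L] ||
      censor[1L] < 0 || censor[2L] > 1)
    stop("censor must be an increasing pair within [0, 1]")
  structure(list(k = k, p_grid = seq_len(k - 1L) / k,
                 censor_lo = censor[1L], censor_hi = censor[2L]),
            class = "ploidy_model_spec")
}

#' Collect allele-ratio observations at heterozygous sites
#'
#' From one sample's allele-count records, extracts the focal-allele read
#' ratio at apparently heterozygous biallelic sites. A site enters if
#' exactly two alleles have at least one read each (sites with three or
#' more observed alleles are excluded from ploidy estimation); the focal
#' allele is the second-listed of the two observed alleles. Sites with
#' total coverage below `min_cov` or with ratio outside the inclusive
#' censoring window are excluded.
#'
#' @param counts `allele_counts` records belonging to a single sample.
#' @param min_cov minimum total coverage (default 30).
#' @param censor inclusive censoring window (default `c(0.1, 0.9)`).
#' @return data frame with columns `locus_id`, `x` (focal-allele reads),
#'   `n` (total reads) and `ratio`; attribute `status` is `"ok"` or
#'   `"insufficient heterozygous sites"` when empty.
#' @export
heterozygous_ratios <- function(counts, min_cov = 30L, censor = c(0.1, 0.9)) {
  if (length(unique(counts$sample_id)) > 1L)
    stop("heterozygous_ratios expects records from a single sample")
  obs <- counts[counts$count > 0L, , drop = FALSE]
  spl <- split(seq_len(nrow(obs)), obs$locus_id)
  keep <- vapply(spl, length, integer(1L)) == 2L
  spl <- spl[keep]
  eps <- 1e-9
  res <- lapply(spl, function(idx) {
    cnt <- obs$count[idx]           # record order preserved by split of rows
    n <- sum(cnt)
    x <- cnt[2L]                    # focal = second-listed observed allele
    c(x = x, n = n)
  })
  out <- data.frame(locus_id = names(spl),
                    x = vapply(res, `[[`, 0, "x"),
                    n = vapply(res, `[[`, 0, "n"),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$ratio <- out$x / out$n
  out <- out[out$n >= min_cov &
               out$ratio >= censor[1L] - eps &
               out$ratio <= censor[2L] + eps, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "status") <- if (nrow(out) == 0L)
    "insufficient heterozygous sites" else "ok"
  out
}

#' Censored beta-binomial log density
#'
#' Log density of the beta-binomial distribution with expectation `p` and
#' intraclass correlation `rho` (`alpha = p(1-rho)/rho`,
#' `beta = (1-p)(1-rho)/rho`), renormalized over the censored support
#' `{y : lo <= y/n <= hi}` (bounds inclusive). Vectorized over `x`.
#'
#' @param x focal-allele read count(s); `x/n` must lie inside the window.
#' @param n total read count (scalar).
#' @param p expectation in (0, 1).
#' @param rho correlation in (0, 1).
#' @param censor inclusive censoring window.
#' @return log density value(s), finite for all valid inputs.
#' @export
censored_betabinom_logpmf <- function(x, n, p, rho, censor = c(0.1, 0.9)) {
  stopifnot(length(n) == 1L, p > 0, p < 1, rho > 0, rho < 1)
  eps <- 1e-9
  if (any(x / n < censor[1L] - eps | x / n > censor[2L] + eps))
    stop("x/n outside the censoring window; censor observations first")
  a <- p * (1 - rho) / rho
  b <- (1 - p) * (1 - rho) / rho
  lpmf <- function(y) lchoose(n, y) + lbeta(y + a, n - y + b) - lbeta(a, b)
  supp <- seq.int(ceiling(censor[1L] * n - eps), floor(censor[2L] * n + eps))
  ls <- lpmf(supp)
  mx <- max(ls)
  logZ <- mx + log(sum(exp(ls - mx)))
  lpmf(x) - logZ
}

#' Mixture log-likelihood of allele-ratio observations
#'
#' Log-likelihood `sum_l log( sum_p m_p * bb_cens(x_l, n_l, p, rho) )` of
#' heterozygous-site ratio observations under a mixture of censored
#' beta-binomials on the candidate ploidy's expectation grid, with a single
#' correlation `rho` shared across components.
#'
#' @param obs data frame with columns `x` and `n` (see
#'   [heterozygous_ratios()]).
#' @param spec a [ploidy_model_spec()].
#' @param m mixture weights over `spec$p_grid` (non-negative, summing to 1
#'   within 1e-8).
#' @param rho shared beta-binomial correlation in (0, 1).
#' @return the log-likelihood (scalar).
#' @export
mixture_loglik <- function(obs, spec, m, rho) {
  if (length(m) != length(spec$p_grid))
    stop("weights m must match spec$p_grid in length")
  if (any(m < -1e-12) || abs(sum(m) - 1) > 1e-8)
    stop("weights m must be non-negative and sum to 1")
  if (nrow(obs) == 0L) return(0)
  bbmix_loglik_cpp(as.integer(obs$x), as.integer(obs$n),
                   spec$p_grid, pmax(m, 0), rho,
                   spec$censor_lo, spec$censor_hi)
}

softmax <- function(eta) {
  z <- c(0, eta)
  e <- exp(z - max(z))
  e / sum(e)
}

#' Fit the censored beta-binomial mixture for one candidate ploidy
#'
#' Maximizes [mixture_loglik()] over the mixture weights (softmax
#' parameterization on the simplex) and the shared correlation `rho`
#' (logit parameterization), with multi-start optimization over a ladder of
#' starting `rho` values and uniform starting weights. A confidence
#' interval for `rho` is obtained from the observed information at the
#' optimum (delta method through the logit transform).
#'
#' @param obs ratio observations (data frame with `x`, `n`).
#' @param spec a [ploidy_model_spec()].
#' @param min_obs minimum number of observations required (default 50).
#' @param rho_starts starting values of `rho` for the multi-start.
#' @param reltol convergence tolerance on the transformed parameters.
#' @return a `ploidy_fit` list: `k`, `p_grid`, `m`, `rho`, `rho_ci`
#'   (95%, observed-information), `loglik`, `n_free_params`, `aic`,
#'   `n_obs`, `converged`, `ci_method`.
#' @export
fit_ploidy_model <- function(obs, spec, min_obs = 50L,
                             rho_starts = c(0.005, 0.02, 0.05, 0.1, 0.2),
                             reltol = 1e-8) {
  if (nrow(obs) < min_obs)
    stop("need at least ", min_obs, " ratio observations (got ", nrow(obs), ")")
  J <- length(spec$p_grid)
  npar <- (J - 1L) + 1L
  x <- as.integer(obs$x); n <- as.integer(obs$n)
  negll <- function(theta) {
    m <- if (J > 1L) softmax(theta[seq_len(J - 1L)]) else 1
    rho <- plogis(theta[npar])
    rho <- min(max(rho, 1e-9), 1 - 1e-9)
    -bbmix_loglik_cpp(x, n, spec$p_grid, m, rho,
                      spec$censor_lo, spec$censor_hi)
  }
  best <- NULL
  any_conv <- FALSE
  for (r0 in rho_starts) {
    start <- c(rep(0, J - 1L), qlogis(r0))
    fit <- if (npar == 1L) {
      o <- optimize(function(t) negll(t), interval = c(-16, 5),
                    tol = 1e-10)
      list(par = o$minimum, value = o$objective, convergence = 0L)
    } else {
      optim(start, negll, method = "Nelder-Mead",
            control = list(reltol = reltol, maxit = 5000L))
    }
    any_conv <- any_conv || fit$convergence == 0L
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  theta <- best$par
  m_hat <- if (J > 1L) softmax(theta[seq_len(J - 1L)]) else 1
  rho_hat <- plogis(theta[npar])
  ll <- -best$value
  # observed-information CI for rho via the logit-scale Hessian
  rho_ci <- c(NA_real_, NA_real_)
  H <- try(optimHess(theta, negll), silent = TRUE)
  if (!inherits(H, "try-error")) {
    V <- try(solve(H), silent = TRUE)
    if (!inherits(V, "try-error") && all(is.finite(diag(V))) &&
        diag(V)[npar] > 0) {
      se_eta <- sqrt(diag(V)[npar])
      rho_ci <- plogis(theta[npar] + c(-1.96, 1.96) * se_eta)
    }
  }
  structure(list(k = spec$k, p_grid = spec$p_grid, m = m_hat, rho = rho_hat,
                 rho_ci = rho_ci, loglik = ll, n_free_params = npar,
                 aic = 2 * npar - 2 * ll, n_obs = nrow(obs),
                 converged = any_conv, ci_method = "observed_information"),
            class = "ploidy_fit")
}

#' @export
print.ploidy_fit <- function(x, ...) {
  cat(sprintf("ploidy_fit k=%d: loglik %.3f AIC %.3f rho %.4f [%.4f, %.4f]\n",
              x$k, x$loglik, x$aic, x$rho, x$rho_ci[1L], x$rho_ci[2L]))
  cat("weights:", paste(sprintf("%.3f@%.2f", x$m, x$p_grid), collapse = " "), "\n")
  invisible(x)
}

#' Classify a sample's ploidy by AIC over candidate ploidies
#'
#' Fits the censored beta-binomial mixture for each candidate ploidy and
#' selects the candidate with minimum AIC; ties (within 1e-9) are broken
#' toward the lower ploidy. Samples with fewer than `min_obs` usable ratio
#' observations are reported as `"undetermined"` rather than classified.
#'
#' @param obs ratio observations (see [heterozygous_ratios()]).
#' @param candidate_ks integer vector of candidate ploidies (default 2:4).
#' @param censor inclusive censoring window.
#' @param min_obs minimum usable observations (default 50).
#' @param ... passed to [fit_ploidy_model()].
#' @return a `ploidy_classification` list: `best_k`, `status`
#'   (`"ok"`/`"undetermined"`), `fits` (per-k `ploidy_fit`s) and `table`
#'   (data frame of k, loglik, n_free_params, aic, delta_aic).
#' @export
classify_ploidy <- function(obs, candidate_ks = c(2L, 3L, 4L),
                            censor = c(0.1, 0.9), min_obs = 50L, ...) {
  candidate_ks <- sort(as.integer(candidate_ks))
  if (nrow(obs) < min_obs) {
    return(structure(list(best_k = NA_integer_, status = "undetermined",
                          fits = list(), table = NULL, n_obs = nrow(obs)),
                     class = "ploidy_classification"))
  }
  fits <- lapply(candidate_ks, function(k)
    fit_ploidy_model(obs, ploidy_model_spec(k, censor), min_obs = min_obs, ...))
  names(fits) <- paste0("k", candidate_ks)
  aic <- vapply(fits, `[[`, 0, "aic")
  if (!any(vapply(fits, `[[`, TRUE, "converged")))
    return(structure(list(best_k = NA_integer_, status = "undetermined",
                          fits = fits, table = NULL, n_obs = nrow(obs)),
                     class = "ploidy_classification"))
  best_idx <- which(aic <= min(aic) + 1e-9)[1L]  # ks sorted: tie -> lower k
  tab <- data.frame(k = candidate_ks,
                    loglik = vapply(fits, `[[`, 0, "loglik"),
                    n_free_params = vapply(fits, `[[`, 0L, "n_free_params"),
                    aic = aic, delta_aic = aic - min(aic),
                    row.names = NULL)
  structure(list(best_k = candidate_ks[best_idx], status = "ok",
                 fits = fits, table = tab, n_obs = nrow(obs)),
            class = "ploidy_classification")
}

#' @export
print.ploidy_classification <- function(x, ...) {
  if (x$status != "ok") {
    cat("ploidy classification:", x$status, sprintf("(%d observations)\n", x$n_obs))
  } else {
    cat("ploidy classification: best k =", x$best_k, "\n")
    print(x$table, digits = 6)
  }
  invisible(x)
}
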