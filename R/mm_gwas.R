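# Kinship-corrected mixed-model association scan.
#
# The model is y = X alpha + u + e with u ~ N(0, sigma_g^2 K) carrying the
# population structure and e ~ N(0, sigma_e^2 I).  Variance components are
# estimated once on the null model by REML, profiling the criterion over the
# ratio delta = sigma_e^2 / sigma_g^2 after a single eigendecomposition of K
# (the EMMA device); per-marker effects are then tested by generalized least
# squares in the rotated coordinates with delta held fixed.

#' Analysis configuration
#'
#' @param alpha Family-wise significance level of the Bonferroni correction.
#' @param r_threshold Collinearity threshold on the Pearson correlation of
#'   marker genotype vectors (markers at `|r| >=` this are one QTL).
#' @param meff_window Window size of [effective_marker_number()].
#' @param qq_sample_size Markers sampled for the cumulative p-value
#'   diagnostic.
#' @param seed Seed for the diagnostic's marker sample.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(alpha = 0.05, r_threshold = 0.3,
                            meff_window = 200L, qq_sample_size = 3000L,
                            seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, r_threshold > 0, r_threshold < 1,
            meff_window >= 1, qq_sample_size >= 1)
  structure(list(alpha = alpha, r_threshold = r_threshold,
                 meff_window = as.integer(meff_window),
                 qq_sample_size = as.integer(qq_sample_size),
                 seed = as.integer(seed)),
            class = "analysis_config")
}

# REML log-likelihood of y = X b + u + e at ratio delta, given the rotated
# data yt = U'y, Xt = U'X and eigenvalues lambda of K.  Profiles sigma_g^2.
reml_loglik_rotated <- function(log10_delta, yt, Xt, lambda, xtx_logdet) {
  delta <- 10^log10_delta
  n <- length(yt); q <- ncol(Xt)
  w <- 1 / (lambda + delta)
  XtW <- Xt * w
  A <- crossprod(Xt, XtW)
  b <- solve(A, crossprod(XtW, yt))
  r <- yt - Xt %*% b
  rss <- sum(w * r^2)
  s2 <- rss / (n - q)
  -0.5 * ((n - q) * (log(2 * pi * s2) + 1) + sum(log(lambda + delta)) +
            determinant(A, logarithm = TRUE)$modulus[1] - xtx_logdet)
}

#' Fit the null mixed model by REML
#'
#' Estimates `(sigma_g^2, sigma_e^2)` for `y = mu + u + e`,
#' `u ~ N(0, sigma_g^2 K)`, by eigendecomposing `K` once and profiling the
#' REML criterion over `log10(delta)` on a grid from -5 to 5 (0.1 spacing)
#' followed by bounded one-dimensional refinement.
#'
#' @param y Named trait vector (names matching `rownames(K)`); accessions
#'   with missing values are dropped case-wise.
#' @param K Kinship matrix from [compute_kinship()].
#' @return A `mm_fit` list: `logLik`, `sigma_g2`, `sigma_e2`, `delta`, `h2`,
#'   `mu`, `n`, and the eigendecomposition reused by [association_scan()].
#' @export
fit_null_model <- function(y, K) {
  if (is.null(names(y))) stop("`y` must be named by accession")
  ids <- intersect(names(y)[!is.na(y)], rownames(K))
  y <- y[ids]
  n <- length(y)
  if (n < 10) stop("need at least 10 accessions with phenotype")
  if (var(y) == 0) stop("zero-variance phenotype")
  K <- K[ids, ids]
  eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (min(eg$values) < -1e-8)
    stop("kinship matrix is not positive semi-definite")
  lambda <- pmax(eg$values, 0)
  U <- eg$vectors
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, matrix(1, n, 1))
  xtx_logdet <- log(n)

  grid <- seq(-5, 5, by = 0.1)
  ll <- vapply(grid, reml_loglik_rotated, numeric(1),
               yt = yt, Xt = Xt, lambda = lambda, xtx_logdet = xtx_logdet)
  i <- which.max(ll)
  lo <- grid[max(i - 1L, 1L)]; hi <- grid[min(i + 1L, length(grid))]
  opt <- optimize(reml_loglik_rotated, c(lo, hi), maximum = TRUE,
                  tol = 1e-8, yt = yt, Xt = Xt, lambda = lambda,
                  xtx_logdet = xtx_logdet)
  if (opt$objective < ll[i]) {            # guard: grid end optimum
    opt <- list(maximum = grid[i], objective = ll[i])
  }
  delta <- 10^opt$maximum
  w <- 1 / (lambda + delta)
  A <- crossprod(Xt, Xt * w)
  mu <- drop(solve(A, crossprod(Xt * w, yt)))
  rss <- sum(w * (yt - Xt %*% mu)^2)
  sigma_g2 <- rss / (n - 1)
  structure(list(logLik = opt$objective, sigma_g2 = sigma_g2,
                 sigma_e2 = delta * sigma_g2, delta = delta,
                 h2 = 1 / (1 + delta), mu = mu, n = n, accessions = ids,
                 eigenvalues = lambda, rotation = U),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("REML fit (n = %d): sigma_g2 = %.4g, sigma_e2 = %.4g, delta = %.4g, h2 = %.3f, logLik = %.4f\n",
              x$n, x$sigma_g2, x$sigma_e2, x$delta, x$h2, x$logLik))
  invisible(x)
}

#' Mixed-model association scan
#'
#' Tests each marker as a fixed effect with the variance ratio `delta` held
#' at its null-model REML estimate (the usual population-parameters-
#' previously-determined shortcut): the phenotype and each marker column are
#' rotated by the kinship eigenvectors and a per-marker weighted least
#' squares yields the effect, its standard error, the Wald statistic
#' `(effect / se)^2` and a p-value from the chi-square(1 df) upper tail.
#' With `K = NULL` the scan is an uncorrected ordinary least-squares scan
#' (useful as the naive contrast in calibration diagnostics).  Markers that
#' are constant after rotation are reported with missing effects and excluded
#' from significance.
#'
#' @param y Named trait vector.
#' @param g A [genotype_matrix()].
#' @param K Kinship matrix, or `NULL` for the uncorrected scan.
#' @param config An [analysis_config()].
#' @param m_eff Effective marker number for the Bonferroni threshold;
#'   computed from `g` by [effective_marker_number()] when missing.
#' @param null_fit Optional pre-computed [fit_null_model()] result.
#' @param exact_per_marker If `TRUE`, re-estimate `delta` by REML for every
#'   marker model (slow; default reuses the null-model `delta`).
#' @param trait,location_id Optional labels copied into the records.
#' @return Data frame with one row per marker (`marker_id`, `scaffold`,
#'   `position`, `effect`, `se`, `wald`, `neg_log10_p`, `significant`) and
#'   attributes `threshold`, `m_eff`, `delta`, `null_fit`.
#' @export
association_scan <- function(y, g, K, config = analysis_config(),
                             m_eff = NULL, null_fit = NULL,
                             exact_per_marker = FALSE,
                             trait = NA_character_,
                             location_id = NA_character_) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(config, "analysis_config"))
  corrected <- !is.null(K)
  if (is.null(m_eff)) m_eff <- effective_marker_number(g, config$meff_window)
  threshold <- bonferroni_threshold(m_eff, config$alpha)

  if (corrected) {
    if (is.null(null_fit)) null_fit <- fit_null_model(y, K)
    ids <- null_fit$accessions
    lambda <- null_fit$eigenvalues
    U <- null_fit$rotation
    delta <- null_fit$delta
    yt <- drop(crossprod(U, y[ids]))
    Gt <- crossprod(U, g$values[ids, , drop = FALSE])
    Xt0 <- drop(crossprod(U, matrix(1, length(ids), 1)))
    w <- 1 / (lambda + delta)
  } else {
    ids <- intersect(names(y)[!is.na(y)], rownames(g$values))
    yt <- y[ids]
    Gt <- g$values[ids, , drop = FALSE]
    Xt0 <- rep(1, length(ids))
    w <- rep(1, length(ids))
    delta <- NA_real_
  }
  n <- length(yt)

  if (exact_per_marker && corrected) {
    res <- exact_scan(y[ids], g$values[ids, , drop = FALSE], U, lambda)
    alpha_hat <- res$effect; se <- res$se
  } else {
    # weighted simple regression of yt on each marker column, vectorized;
    # the intercept is handled by weighted centering (Xt0 is not constant
    # after rotation, so center on its weighted projection instead)
    sw0 <- sum(w * Xt0^2)
    yc <- yt - Xt0 * sum(w * Xt0 * yt) / sw0
    proj <- colSums(w * Xt0 * Gt) / sw0
    Gc <- Gt - outer(Xt0, proj)
    Sxx <- colSums(w * Gc^2)
    Sxy <- colSums(w * Gc * yc)
    Syy <- sum(w * yc^2)
    const <- Sxx < 1e-12
    Sxx[const] <- NA_real_
    alpha_hat <- Sxy / Sxx
    rss <- pmax(Syy - Sxy^2 / Sxx, 0)
    s2 <- rss / (n - 2)
    se <- sqrt(s2 / Sxx)
  }

  wald <- (alpha_hat / se)^2
  neg_log10_p <- -pchisq(wald, df = 1, lower.tail = FALSE, log.p = TRUE) / log(10)
  significant <- !is.na(neg_log10_p) & neg_log10_p >= threshold
  par <- g$markers[match(colnames(g$values), g$markers$marker_id),
                   c("marker_id", "scaffold", "position")]
  out <- data.frame(par, trait = trait, location_id = location_id,
                    effect = alpha_hat, se = se, wald = wald,
                    neg_log10_p = neg_log10_p, significant = significant,
                    row.names = NULL)
  attr(out, "threshold") <- threshold
  attr(out, "m_eff") <- m_eff
  attr(out, "delta") <- delta
  attr(out, "null_fit") <- if (corrected) null_fit else NULL
  class(out) <- c("assoc_scan", "data.frame")
  out
}

# Per-marker exact mode: re-estimate delta by REML for each marker model
# y = [1, x] b + u + e, then GLS at that delta.
exact_scan <- function(y, X, U, lambda) {
  n <- length(y)
  yt <- drop(crossprod(U, y))
  Xt0 <- drop(crossprod(U, matrix(1, n, 1)))
  m <- ncol(X)
  effect <- se <- rep(NA_real_, m)
  grid <- seq(-5, 5, by = 0.1)
  for (j in seq_len(m)) {
    xt <- drop(crossprod(U, X[, j]))
    Xt <- cbind(Xt0, xt)
    xtx_logdet <- determinant(crossprod(cbind(1, X[, j])), TRUE)$modulus[1]
    if (!is.finite(xtx_logdet)) next
    ll <- vapply(grid, reml_loglik_rotated, numeric(1), yt = yt, Xt = Xt,
                 lambda = lambda, xtx_logdet = xtx_logdet)
    i <- which.max(ll)
    opt <- optimize(reml_loglik_rotated, c(grid[max(i - 1, 1)], grid[min(i + 1, length(grid))]),
                    maximum = TRUE, tol = 1e-8, yt = yt, Xt = Xt,
                    lambda = lambda, xtx_logdet = xtx_logdet)
    wj <- 1 / (lambda + 10^opt$maximum)
    A <- crossprod(Xt, Xt * wj)
    b <- solve(A, crossprod(Xt * wj, yt))
    r <- yt - Xt %*% b
    s2 <- sum(wj * r^2) / (n - 2)
    cov_b <- solve(A) * s2
    effect[j] <- b[2]
    se[j] <- sqrt(cov_b[2, 2])
  }
  list(effect = effect, se = se)
}

#' Bonferroni threshold on the effective marker number
#'
#' @param m_eff Effective number of independent markers (>= 1).
#' @param alpha Family-wise significance level in `(0, 1)`.
#' @return The genome-wide `-log10(p)` cut-off `-log10(alpha / m_eff)`.
#' @export
bonferroni_threshold <- function(m_eff, alpha = 0.05) {
  if (m_eff < 1) stop("m_eff must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  -log10(alpha / m_eff)
}

#' Cumulative p-value diagnostic
#'
#' Draws a seeded sample of markers from a scan, pairs the sorted observed
#' `-log10(p)` with uniform order-statistic expectations, and summarizes
#' calibration by the genomic-inflation factor (median Wald statistic over
#' the chi-square(1) median) and a Kolmogorov-Smirnov statistic against the
#' uniform distribution.
#'
#' @param scan An [association_scan()] result.
#' @param config An [analysis_config()] (sample size and seed).
#' @return List with `table` (expected vs observed `-log10 p`), `lambda_gc`,
#'   `ks_stat` and `n`.
#' @export
qq_diagnostic <- function(scan, config = analysis_config()) {
  ok <- !is.na(scan$neg_log10_p)
  p <- 10^(-scan$neg_log10_p[ok])
  wald <- scan$wald[ok]
  if (length(p) > config$qq_sample_size) {
    set.seed(substream_seed(config$seed, 6L))
    keep <- sample(length(p), config$qq_sample_size)
    p <- p[keep]; wald <- wald[keep]
  } else {
    message("fewer than ", config$qq_sample_size,
            " markers available; using all ", length(p))
  }
  n <- length(p)
  obs <- sort(-log10(p), decreasing = TRUE)
  expd <- -log10((seq_len(n) - 0.5) / n)
  expd <- sort(expd, decreasing = TRUE)
  lambda_gc <- median(wald) / qchisq(0.5, df = 1)
  ks <- suppressWarnings(ks.test(p, "punif"))
  list(table = data.frame(expected = expd, observed = obs),
       lambda_gc = unname(lambda_gc),
       ks_stat = unname(ks$statistic), n = n)
}
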