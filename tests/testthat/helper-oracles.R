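# Independent oracles: every routine here deliberately avoids the package's
# computational paths (dense matrix algebra instead of eigen-rotations,
# explicit loops instead of vectorized screens) so tests compare two
# derivations of the same quantity.

# Dense REML log-likelihood profile for y = mu + u + e, maximized over
# log10(delta) by grid + refinement, with V = K + delta * I formed explicitly.
oracle_reml_loglik <- function(y, K) {
  n <- length(y)
  X <- matrix(1, n, 1)
  f <- function(l10d) {
    V <- K + diag(10^l10d, n)
    Vi <- solve(V)
    A <- crossprod(X, Vi %*% X)
    b <- solve(A, crossprod(X, Vi %*% y))
    r <- y - X %*% b
    rss <- drop(crossprod(r, Vi %*% r))
    s2 <- rss / (n - 1)
    -0.5 * ((n - 1) * (log(2 * pi * s2) + 1) +
              determinant(V, logarithm = TRUE)$modulus[1] +
              determinant(A, logarithm = TRUE)$modulus[1] - log(n))
  }
  grid <- seq(-5, 5, by = 0.1)
  ll <- vapply(grid, f, numeric(1))
  i <- which.max(ll)
  opt <- optimize(f, c(grid[max(i - 1, 1)], grid[min(i + 1, length(grid))]),
                  maximum = TRUE, tol = 1e-8)
  max(opt$objective, ll[i])
}

# Dense GLS Wald statistic of one marker at a fixed variance ratio.
oracle_gls_wald <- function(y, x, K, delta) {
  n <- length(y)
  Vi <- solve(K + diag(delta, n))
  X <- cbind(1, x)
  A <- crossprod(X, Vi %*% X)
  b <- solve(A, crossprod(X, Vi %*% y))
  r <- y - X %*% b
  s2 <- drop(crossprod(r, Vi %*% r)) / (n - 2)
  covb <- solve(A) * s2
  drop((b[2] / sqrt(covb[2, 2]))^2)
}

# Weir-Cockerham ANOVA FST estimator (ratio of averages) from per-subpop
# haplotype allele counts: `alt` and `total` are marker x subpop matrices of
# alternate-allele counts and haplotype numbers.
oracle_wc_fst <- function(alt, total) {
  num <- den <- 0
  r <- ncol(alt)
  for (j in seq_len(nrow(alt))) {
    nk <- total[j, ]
    pk <- alt[j, ] / nk
    N <- sum(nk)
    pbar <- sum(nk * pk) / N
    msb <- sum(nk * (pk - pbar)^2) / (r - 1)
    msw <- sum(nk * pk * (1 - pk)) / (N - r)
    nc <- (N - sum(nk^2) / N) / (r - 1)
    num <- num + (msb - msw)
    den <- den + (msb + (nc - 1) * msw)
  }
  num / den
}

# Li-Ji effective number of tests on the full correlation matrix.
oracle_li_ji <- function(values) {
  lam <- pmax(eigen(cor(values), symmetric = TRUE, only.values = TRUE)$values, 0)
  sum((lam >= 1) + (lam - floor(lam)))
}

# Marker-by-marker evaluation of the four SNP selection predicates.
oracle_filter_keep <- function(values, top2_sum, t) {
  vapply(seq_len(ncol(values)), function(j) {
    x <- values[, j]
    if (mean(!is.na(x)) < t$call_rate_min) return(FALSE)
    if (top2_sum[j] < t$biallelic_sum_min) return(FALSE)
    if (mean(x, na.rm = TRUE) > 1 - t$maf_min) return(FALSE)
    s <- sd(x, na.rm = TRUE)
    !is.na(s) && s >= t$major_freq_sd_min
  }, logical(1))
}

# Sliding-window Hamming scan of a motif over a character sequence.
oracle_hamming_hits <- function(seq_str, motif, max_mismatch, both = TRUE) {
  revcomp <- function(s) {
    map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
  }
  s <- strsplit(seq_str, "")[[1]]
  scan1 <- function(pat, strand) {
    p <- strsplit(pat, "")[[1]]
    L <- length(p)
    out <- NULL
    for (start in seq_len(length(s) - L + 1)) {
      win <- s[start:(start + L - 1)]
      mm <- sum(win != p | win == "N")
      if (mm <= max_mismatch)
        out <- rbind(out, data.frame(start = start, end = start + L - 1,
                                     strand = strand, mismatches = mm))
    }
    out
  }
  res <- scan1(motif, "+")
  if (both) res <- rbind(res, scan1(revcomp(motif), "-"))
  if (is.null(res)) return(data.frame(start = integer(), end = integer(),
                                      strand = character(),
                                      mismatches = integer()))
  res <- res[order(res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# A small structured panel used across tests: returns genotypes, truth,
# temperatures and the aggregated trait table.
small_panel <- function(seed = 11L, n_accessions = 60L, n_scaffolds = 40L,
                        planted = list(), h2 = c(FL_Begin = 0.9, FL_Full = 0.9,
                                                 Sex_det = 0.9),
                        read_depth = Inf, ...) {
  cfg <- sim_config(n_accessions = n_accessions, n_scaffolds = n_scaffolds,
                    markers_per_scaffold = c(3L, 6L), planted_qtls = planted,
                    heritability = h2, read_depth = read_depth, seed = seed,
                    ...)
  panel <- simulate_panel(cfg)
  locs <- paste0("LOC", seq_len(cfg$n_locations))
  temps <- lapply(seq_along(locs), function(l)
    simulate_temperature(locs[l], mean_temp = 14 + 2 * l,
                         seed = seed + 100L + l))
  names(temps) <- locs
  phe <- suppressMessages(simulate_phenotypes(panel$genotypes, panel$truth,
                                              cfg, temps))
  list(config = cfg, genotypes = panel$genotypes, truth = phe$truth,
       temps = temps, records = phe$records, traits = phe$traits)
}

# Random per-accession %ACGT allele-frequency table for score_major_allele.
random_allele_table <- function(n_acc, n_marker, seed) {
  set.seed(seed)
  rows <- expand.grid(accession_id = sprintf("A%03d", seq_len(n_acc)),
                      marker_id = sprintf("scaffold%d_%d", seq_len(n_marker),
                                          seq_len(n_marker) * 13),
                      stringsAsFactors = FALSE)
  # two main alleles per marker plus a small third-allele contamination
  out <- NULL
  for (mk in unique(rows$marker_id)) {
    alleles <- sample(c("A", "C", "G", "T"), 3)
    p <- runif(1, 0.4, 0.95)
    third <- runif(1, 0, 0.08)
    f1 <- pmin(pmax(rnorm(n_acc, p, 0.15), 0), 1 - third)
    m <- matrix(0, n_acc, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
    m[, alleles[1]] <- f1 * (1 - third)
    m[, alleles[2]] <- (1 - f1) * (1 - third)
    m[, alleles[3]] <- m[, alleles[3]] + third
    m <- m / rowSums(m)
    out <- rbind(out, data.frame(marker_id = mk,
                                 accession_id = sprintf("A%03d", seq_len(n_acc)),
                                 m, stringsAsFactors = FALSE))
  }
  out
}

# Constructed LD-block fixture: `blocks` latent variables, `per_block`
# correlated markers each, plus a trait driven by the designated causal
# blocks.  Returns the genotype matrix, trait vector and a scan-like table
# marking every marker significant.
block_fixture <- function(seed = 1L, n = 150L, blocks = 3L, per_block = 4L,
                          causal = c(1L, 2L), noise = 0.3) {
  set.seed(seed)
  latent <- matrix(rnorm(n * blocks), n, blocks)
  v <- matrix(0, n, blocks * per_block)
  for (b in seq_len(blocks)) for (k in seq_len(per_block))
    v[, (b - 1L) * per_block + k] <- latent[, b] + rnorm(n, 0, noise)
  v <- (v - min(v)) / diff(range(v))   # map into [0, 1]
  colnames(v) <- sprintf("s%d_%d", rep(seq_len(blocks), each = per_block),
                         rep(seq_len(per_block), blocks) * 100)
  rownames(v) <- sprintf("A%03d", seq_len(n))
  mk <- data.frame(marker_id = colnames(v),
                   scaffold = sub("_.*", "", colnames(v)),
                   position = rep(seq_len(per_block), blocks) * 100,
                   major = "A", minor = "C", top2_sum = 1)
  y <- drop(latent[, causal, drop = FALSE] %*% rep(1, length(causal))) +
    rnorm(n, 0, 0.8)
  names(y) <- rownames(v)
  scan <- data.frame(marker_id = colnames(v), trait = "FL_Begin",
                     location_id = "L1",
                     wald = vapply(seq_len(ncol(v)), function(j)
                       summary(lm(y ~ v[, j]))$coefficients[2, 3]^2, numeric(1)),
                     significant = rep(seq_len(blocks), each = per_block) %in%
                       causal)
  list(g = genotype_matrix(v, mk), y = y, scan = scan)
}
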