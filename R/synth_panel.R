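# Synthetic pooled-frequency panel generator with planted truth.
#
# The generator emulates the statistical structure of a pooled-DNA hemp
# accession panel: a structured population (Balding-Nichols subpopulation
# frequencies at a configured FST), pooled genotypes of a small number of
# plants per accession, binomial read-sampling noise around the pool
# frequency, many short scaffolds carrying local LD blocks, and
# multi-location phenology with high heritability and genotype-by-environment
# correlation.

#' Describe a planted QTL
#'
#' @param trait One of `"FL_Begin"`, `"FL_Full"`, `"Sex_det"`.  `VEG` is a
#'   derived trait (calendar days from emergence to beginning of flowering)
#'   and inherits the genetics of `FL_Begin`, so it cannot carry its own
#'   planted effects.
#' @param variance_fraction Fraction of the phenotypic variance explained by
#'   the QTL (on the accession-by-location mean scale).
#' @param shared_across_locations If `TRUE` the QTL effect is identical in
#'   every location; otherwise it acts in a single location.
#' @param marker_id Optional marker to carry the effect; by default the
#'   generator picks a high-variance marker in an unused, non-collinear LD
#'   block.
#' @return A `planted_qtl` list.
#' @export
planted_qtl <- function(trait, variance_fraction, shared_across_locations = TRUE,
                        marker_id = NA_character_) {
  stopifnot(trait %in% c("FL_Begin", "FL_Full", "Sex_det"),
            is.numeric(variance_fraction), variance_fraction > 0,
            variance_fraction < 1)
  structure(list(trait = trait, variance_fraction = variance_fraction,
                 shared_across_locations = isTRUE(shared_across_locations),
                 marker_id = marker_id),
            class = "planted_qtl")
}

#' Simulation configuration
#'
#' Defaults reproduce the study conditions the generator emulates: 123
#' accessions genotyped as equimolar pools of 8 plants each, three locations
#' with three plots per accession and location in each, a structured
#' population, and broad-sense heritabilities in the 0.93-0.95 range.
#'
#' @param n_accessions Number of accessions (pools).
#' @param n_subpops Number of ancestral subpopulations.
#' @param fst Wright's FST of the Balding-Nichols subpopulation model, in
#'   `[0, 1)`.
#' @param accession_fst Accession-level differentiation within a
#'   subpopulation, in `[0, 1)`: each accession (a distinct cultivar or
#'   landrace, not a random sample of its subpopulation) draws its own
#'   allele frequencies around the subpopulation frequency by a second
#'   Balding-Nichols layer.  This is what makes pooled accession frequencies
#'   heritable signals rather than pure pool-sampling noise.
#' @param n_scaffolds Number of genomic scaffolds carrying markers.
#' @param markers_per_scaffold Integer range `c(lo, hi)`; the marker count of
#'   each scaffold is drawn uniformly from it.
#' @param ld_block_length LD block length in bp; markers within the same
#'   block of a scaffold share a latent haplotype.
#' @param mutation_rate Per-marker, per-haplotype probability of breaking
#'   away from the block's latent haplotype (controls within-block r).
#' @param pool_size Diploid plants pooled per accession.
#' @param read_depth Mean sequencing depth per site (Poisson distributed);
#'   `Inf` disables read-sampling noise.
#' @param planted_qtls List of [planted_qtl()] objects.
#' @param heritability Named vector of per-trait heritabilities on the
#'   accession-by-location mean scale.
#' @param env_genetic_correlation Correlation of the polygenic values between
#'   locations, in `[0, 1]`.
#' @param n_locations Number of locations.
#' @param n_plots Plot replicates per accession and location.
#' @param trait_scales Means and SDs mapping standardized flowering values to
#'   degree-days (`FL_Begin`, `FL_Full`).
#' @param emergence_lag Days from sowing to emergence.
#' @param seed Integer seed; equal seeds give byte-identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_accessions = 123L,
                       n_subpops = 3L,
                       fst = 0.15,
                       accession_fst = 0.2,
                       n_scaffolds = 150L,
                       markers_per_scaffold = c(4L, 10L),
                       ld_block_length = 8000L,
                       mutation_rate = 0.05,
                       pool_size = 8L,
                       read_depth = 30,
                       planted_qtls = list(),
                       heritability = c(FL_Begin = 0.93, FL_Full = 0.94, Sex_det = 0.95),
                       env_genetic_correlation = 0.8,
                       n_locations = 3L,
                       n_plots = 3L,
                       trait_scales = list(FL_Begin = c(mean = 420, sd = 60),
                                           FL_Full = c(mean = 620, sd = 70)),
                       emergence_lag = 5L,
                       seed = 1L) {
  if (!is.numeric(fst) || fst < 0 || fst >= 1)
    stop("`fst` must lie in [0, 1)")
  if (!is.numeric(accession_fst) || accession_fst < 0 || accession_fst >= 1)
    stop("`accession_fst` must lie in [0, 1)")
  if (pool_size < 1) stop("`pool_size` must be >= 1")
  counts <- c(n_accessions = n_accessions, n_subpops = n_subpops,
              n_scaffolds = n_scaffolds, n_locations = n_locations,
              n_plots = n_plots)
  if (any(counts < 1)) stop("all counts must be >= 1")
  stopifnot(length(markers_per_scaffold) == 2,
            markers_per_scaffold[1] >= 1,
            markers_per_scaffold[2] >= markers_per_scaffold[1],
            ld_block_length >= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            env_genetic_correlation >= 0, env_genetic_correlation <= 1,
            all(heritability >= 0), all(heritability <= 1))
  if (length(planted_qtls) > 0 && inherits(planted_qtls, "planted_qtl"))
    planted_qtls <- list(planted_qtls)
  for (q in planted_qtls) stopifnot(inherits(q, "planted_qtl"))
  vf <- vapply(planted_qtls, function(q) q$variance_fraction, numeric(1))
  tr <- vapply(planted_qtls, function(q) q$trait, character(1))
  for (t in unique(tr)) {
    if (sum(vf[tr == t]) >= heritability[[t]])
      stop("planted variance fractions for ", t,
           " must sum to less than the trait heritability")
  }
  structure(list(n_accessions = as.integer(n_accessions),
                 n_subpops = as.integer(n_subpops), fst = fst,
                 accession_fst = accession_fst,
                 n_scaffolds = as.integer(n_scaffolds),
                 markers_per_scaffold = as.integer(markers_per_scaffold),
                 ld_block_length = as.integer(ld_block_length),
                 mutation_rate = mutation_rate,
                 pool_size = as.integer(pool_size), read_depth = read_depth,
                 planted_qtls = planted_qtls, heritability = heritability,
                 env_genetic_correlation = env_genetic_correlation,
                 n_locations = as.integer(n_locations),
                 n_plots = as.integer(n_plots), trait_scales = trait_scales,
                 emergence_lag = as.integer(emergence_lag),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config:", x$n_accessions, "accessions,", x$n_subpops,
      "subpopulations (FST", x$fst, "),", x$n_scaffolds, "scaffolds,",
      x$n_locations, "locations,", length(x$planted_qtls), "planted QTLs\n")
  invisible(x)
}

#' Simulate a pooled-frequency genotype panel
#'
#' Draws ancestral LD-block allele frequencies, disperses them into
#' subpopulation frequencies by the Balding-Nichols construction at the
#' configured FST, samples `2 * pool_size` haplotypes per accession (markers
#' of one LD block copy a shared latent haplotype, broken per marker with
#' probability `mutation_rate`), pools them into allele frequencies, and adds
#' binomial read-sampling noise at Poisson-distributed depth.  Genotype
#' values are the proportion of the panel-major allele per accession.
#'
#' @param config A [sim_config()].
#' @return A list with elements `genotypes` (a [genotype_matrix()]) and
#'   `truth` (a `truth_record` holding subpopulation labels, noise-free pool
#'   frequencies, haplotype allele counts, LD-block ids and resolved planted
#'   QTL markers).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))

  ## stream 1: marker map, allele labels, population frequencies
  set.seed(substream_seed(config$seed, 1L))
  n <- config$n_accessions
  S <- config$n_subpops
  mps <- config$markers_per_scaffold
  m_k <- if (mps[1] == mps[2]) rep(mps[1], config$n_scaffolds) else
    sample(seq(mps[1], mps[2]), config$n_scaffolds, replace = TRUE)
  maps <- lapply(seq_len(config$n_scaffolds), function(k) {
    pos <- cumsum(sample(200:3000, m_k[k], replace = TRUE))
    data.frame(scaffold = paste0("scaffold", k), position = pos,
               block = paste0("scaffold", k, "_b",
                              (pos - 1L) %/% config$ld_block_length + 1L),
               stringsAsFactors = FALSE)
  })
  markers <- do.call(rbind, maps)
  markers$marker_id <- paste0(markers$scaffold, "_", markers$position)
  m <- nrow(markers)
  nuc <- c("A", "C", "G", "T")
  allele_pair <- t(replicate(m, sample(nuc, 2L)))

  blocks <- unique(markers$block)
  nb <- length(blocks)
  block_of <- match(markers$block, blocks)
  p_anc <- runif(nb, 0.2, 0.8)
  if (config$fst == 0) {
    p_sub <- matrix(p_anc, nb, S)
  } else {
    a <- p_anc * (1 - config$fst) / config$fst
    b <- (1 - p_anc) * (1 - config$fst) / config$fst
    p_sub <- matrix(rbeta(nb * S, rep(a, S), rep(b, S)), nb, S)
    p_sub <- pmin(pmax(p_sub, 1e-4), 1 - 1e-4)
  }

  subpop <- rep_len(seq_len(S), n)
  acc_ids <- sprintf("Acc%03d", seq_len(n))
  names(subpop) <- acc_ids

  ## stream 2: haplotypes
  set.seed(substream_seed(config$seed, 2L))
  H <- 2L * config$pool_size
  counts <- matrix(0L, n, m, dimnames = list(acc_ids, markers$marker_id))
  f_acc <- config$accession_fst
  for (i in seq_len(n)) {
    pb <- p_sub[, subpop[i]]                  # per-block subpop frequency
    if (f_acc > 0) {                          # accession-level drift layer
      pb <- rbeta(nb, pb * (1 - f_acc) / f_acc,
                  (1 - pb) * (1 - f_acc) / f_acc)
      pb <- pmin(pmax(pb, 1e-4), 1 - 1e-4)
    }
    pm <- pb[block_of]                        # per-marker accession frequency
    pmat <- matrix(pm, H, m, byrow = TRUE)
    U <- matrix(runif(H * nb), H, nb)
    A <- U[, block_of, drop = FALSE] < pmat   # block-copy latent haplotypes
    if (config$mutation_rate > 0) {
      mut <- matrix(runif(H * m) < config$mutation_rate, H, m)
      if (any(mut)) A[mut] <- runif(sum(mut)) < pmat[mut]
    }
    counts[i, ] <- colSums(A)
  }
  f_true <- counts / H

  ## stream 3: read-depth noise
  set.seed(substream_seed(config$seed, 3L))
  if (is.finite(config$read_depth)) {
    depth <- matrix(rpois(n * m, config$read_depth), n, m)
    depth[depth < 1L] <- 1L
    obs <- matrix(rbinom(n * m, depth, f_true), n, m) / depth
    dimnames(obs) <- dimnames(f_true)
  } else {
    obs <- f_true
  }

  panel_mean <- colMeans(obs)
  flip <- panel_mean < 0.5
  values <- obs
  values[, flip] <- 1 - obs[, flip]
  major <- ifelse(flip, allele_pair[, 2L], allele_pair[, 1L])
  minor <- ifelse(flip, allele_pair[, 1L], allele_pair[, 2L])

  marker_info <- data.frame(marker_id = markers$marker_id,
                            scaffold = markers$scaffold,
                            position = markers$position,
                            major = major, minor = minor,
                            top2_sum = rep(1, m),
                            stringsAsFactors = FALSE)
  g <- genotype_matrix(values, marker_info)

  qtls <- resolve_planted_qtls(config, values, f_true, markers, subpop)

  truth <- structure(list(subpop = subpop,
                          freq_true = f_true,
                          allele1_counts = counts,
                          haplotypes_per_pool = H,
                          value_is_allele1 = !flip,
                          blocks = setNames(markers$block, markers$marker_id),
                          qtls = qtls,
                          config = config),
                     class = "truth_record")
  list(genotypes = g, truth = truth)
}

# Assign planted QTLs to concrete markers.  Blocks are ranked by the
# within-subpopulation variance of their best marker: a causal variant must
# segregate within subpopulations to be distinguishable from the population
# structure that the kinship term absorbs, so planting on markers whose
# variance is mostly between-subpopulation would make the truth unattainable
# by any structure-corrected scan.  Chosen representatives are additionally
# required to be pairwise near-orthogonal (|r| <= 0.15, well below the 0.3
# collinearity threshold of the QTL clustering) so the planted truth is
# identifiable and the planted variance fractions are realized cleanly
# instead of leaking into each other through marker cross-correlation.
resolve_planted_qtls <- function(config, values, f_true, markers, subpop) {
  qtls <- config$planted_qtls
  if (length(qtls) == 0)
    return(data.frame(marker_id = character(), trait = character(),
                      variance_fraction = numeric(), shared = logical(),
                      block = character(), scaffold = character(),
                      stringsAsFactors = FALSE))
  # within-subpopulation variance of each marker's true pool frequency
  centered <- f_true
  for (s in unique(subpop)) {
    rows <- subpop == s
    centered[rows, ] <- sweep(f_true[rows, , drop = FALSE], 2,
                              colMeans(f_true[rows, , drop = FALSE]))
  }
  v <- colSums(centered^2) / (nrow(f_true) - 1)
  chosen <- character(0)
  blocks_used <- character(0)
  out <- vector("list", length(qtls))
  block_best <- vapply(split(seq_len(nrow(markers)), markers$block),
                       function(ix) ix[which.max(v[ix])], integer(1))
  ord <- order(v[block_best], decreasing = TRUE)
  block_queue <- block_best[ord]
  for (k in seq_along(qtls)) {
    q <- qtls[[k]]
    id <- q$marker_id
    if (is.na(id)) {
      for (j in block_queue) {
        mid <- markers$marker_id[j]
        blk <- markers$block[j]
        if (blk %in% blocks_used) next
        if (length(chosen) > 0 &&
            any(abs(cor(values[, mid], values[, chosen, drop = FALSE])) > 0.15))
          next
        id <- mid
        break
      }
      if (is.na(id)) stop("could not place planted QTL ", k,
                          " in a non-collinear LD block")
    } else if (!id %in% markers$marker_id) {
      stop("planted QTL marker ", id, " does not exist in the generated panel")
    }
    j <- match(id, markers$marker_id)
    blocks_used <- c(blocks_used, markers$block[j])
    chosen <- c(chosen, id)
    out[[k]] <- data.frame(marker_id = id, trait = q$trait,
                           variance_fraction = q$variance_fraction,
                           shared = q$shared_across_locations,
                           block = markers$block[j],
                           scaffold = markers$scaffold[j],
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate a daily mean-temperature series
#'
#' A seasonal half-sine bump plus Gaussian noise over consecutive calendar
#' days, emulating a spring-to-autumn growing season.
#'
#' @param location_id Location identifier.
#' @param season_start First day (coerced with [as.Date()]).
#' @param n_days Season length in days (>= 1).
#' @param mean_temp Season mean temperature, degrees C.
#' @param amplitude Peak elevation of the seasonal bump above its own mean.
#' @param noise_sd SD of the day-to-day Gaussian noise.
#' @param seed Integer seed.
#' @return A [temperature_series()].
#' @export
simulate_temperature <- function(location_id, season_start = "2013-04-01",
                                 n_days = 183L, mean_temp = 16,
                                 amplitude = 5, noise_sd = 2, seed = 1L) {
  if (n_days < 1) stop("season length must be >= 1 day")
  set.seed(substream_seed(seed, 4L))
  t <- seq_len(n_days)
  bump <- sin(pi * (t - 0.5) / n_days)
  tmean <- mean_temp + amplitude * (bump - mean(bump)) + rnorm(n_days, 0, noise_sd)
  temperature_series(location_id,
                     dates = as.Date(season_start) + (t - 1L),
                     tmean = tmean)
}

#' Simulate multi-location phenology records
#'
#' Per trait, the accession genetic value is the sum of the planted QTL
#' effects (on the 2 x pool-frequency dosage of the noise-free pool
#' frequencies) and a polygenic term with covariance proportional to the
#' true-frequency genomic relationship matrix; polygenic values are
#' correlated across locations at `env_genetic_correlation`.  Plot values add
#' Gaussian noise sized so the accession-by-location plot mean attains the
#' target heritability.  Flowering values are expressed in degree-days and
#' inverted through each location's temperature accumulation into calendar
#' dates; sex determination is a latent liability cut at +/- 1 SD into plot
#' scores 1 (diecious), 2 (mixed), 3 (monecious).
#'
#' @param genotypes,truth Output of [simulate_panel()].
#' @param config The same [sim_config()].
#' @param temps Named list of [temperature_series()], one per location.
#' @return List with `records` (plot-level phenology data frame), `traits`
#'   (the aggregated [trait_table]) and `truth` (the input truth record
#'   augmented with per-location genetic values and realized variance
#'   components).
#' @export
simulate_phenotypes <- function(genotypes, truth, config, temps) {
  stopifnot(inherits(config, "sim_config"), is.list(temps),
            length(temps) == config$n_locations)
  if (is.null(names(temps)) || any(!nzchar(names(temps))))
    names(temps) <- vapply(temps, function(s) attr(s, "location_id"), character(1))
  locs <- names(temps)
  qtls <- truth$qtls
  if (nrow(qtls) > 0 && !all(qtls$marker_id %in% colnames(truth$freq_true)))
    stop("planted QTL markers missing from the panel")

  set.seed(substream_seed(config$seed, 5L))
  n <- config$n_accessions
  acc <- rownames(truth$freq_true)
  rho <- config$env_genetic_correlation

  # normalize the true-frequency kinship to unit mean diagonal so a draw
  # u ~ N(0, s2 * Kt) has expected empirical variance s2
  Kt <- compute_kinship(truth$freq_true)
  Kt <- Kt / mean(diag(Kt))
  L <- t(chol(Kt + diag(1e-6, n)))

  # assign private QTLs to locations round-robin
  if (nrow(qtls) > 0) {
    qtls$location <- NA_character_
    priv <- which(!qtls$shared)
    if (length(priv) > 0) qtls$location[priv] <- locs[(seq_along(priv) - 1L) %% length(locs) + 1L]
    qtls$effect <- NA_real_
  }

  traits <- c("FL_Begin", "FL_Full", "Sex_det")
  gvals <- list()
  varcomp <- list()
  plotval <- list()
  for (tr in traits) {
    h2 <- config$heritability[[tr]]
    qt <- if (nrow(qtls) > 0) which(qtls$trait == tr) else integer(0)
    qtl_part <- matrix(0, n, length(locs), dimnames = list(acc, locs))
    for (j in qt) {
      d <- 2 * truth$freq_true[, qtls$marker_id[j]]
      beta <- sample(c(-1, 1), 1L) * sqrt(qtls$variance_fraction[j] / var(d))
      qtls$effect[j] <- beta
      dc <- d - mean(d)
      if (qtls$shared[j]) {
        qtl_part <- qtl_part + beta * dc
      } else {
        qtl_part[, qtls$location[j]] <- qtl_part[, qtls$location[j]] + beta * dc
      }
    }
    # polygenic draws are orthogonalized against the planted-QTL dosages and
    # rescaled to their target variance, so the planted variance fractions
    # and the trait heritability are realized exactly in every panel rather
    # than only in expectation (the structured kinship has few effective
    # degrees of freedom, which would otherwise make both very noisy)
    D <- if (length(qt) > 0)
      cbind(1, 2 * truth$freq_true[, qtls$marker_id[qt], drop = FALSE])
    else matrix(1, n, 1)
    Dqr <- qr(D)
    z0 <- L %*% rnorm(n)
    g_loc <- matrix(0, n, length(locs), dimnames = list(acc, locs))
    s2p <- numeric(length(locs))
    for (l in seq_along(locs)) {
      vf_loc <- if (length(qt) > 0)
        sum(qtls$variance_fraction[qt][qtls$shared[qt] | qtls$location[qt] == locs[l]])
      else 0
      s2p[l] <- max(h2 - vf_loc, 0)
      zl <- L %*% rnorm(n)
      u <- qr.resid(Dqr, drop(sqrt(rho) * z0 + sqrt(1 - rho) * zl))
      vu <- var(u)
      u <- if (s2p[l] > 0 && vu > 0) u * sqrt(s2p[l] / vu) else u * 0
      g_loc[, l] <- qtl_part[, l] + u
    }
    gvals[[tr]] <- g_loc

    noise_sd <- sqrt(config$n_plots * (1 - h2))
    pv <- array(0, dim = c(n, length(locs), config$n_plots),
                dimnames = list(acc, locs, NULL))
    err_mean_var <- numeric(length(locs))
    for (l in seq_along(locs)) {
      e <- matrix(rnorm(n * config$n_plots, 0, noise_sd), n, config$n_plots)
      pv[, l, ] <- g_loc[, l] + e
      err_mean_var[l] <- var(rowMeans(e))
    }
    plotval[[tr]] <- pv
    varcomp[[tr]] <- data.frame(location_id = locs,
                                var_qtl = apply(qtl_part, 2, var),
                                var_polygenic = apply(g_loc - qtl_part, 2, var),
                                var_genetic = apply(g_loc, 2, var),
                                var_error_mean = err_mean_var,
                                target_h2 = h2,
                                row.names = NULL)
    varcomp[[tr]]$h2_realized <- varcomp[[tr]]$var_genetic /
      (varcomp[[tr]]$var_genetic + varcomp[[tr]]$var_error_mean)
  }

  ## express in observables
  sc_b <- config$trait_scales$FL_Begin
  sc_f <- config$trait_scales$FL_Full
  liab_sd <- sqrt(config$heritability[["Sex_det"]] +
                    config$n_plots * (1 - config$heritability[["Sex_det"]]))
  recs <- vector("list", length(locs))
  for (l in seq_along(locs)) {
    series <- temps[[l]]
    sowing <- series$date[1]
    emergence <- sowing + config$emergence_lag
    cum <- thermal_time_profile(series, emergence)
    total <- max(cum$cd)
    begin_cd <- sc_b[["mean"]] + sc_b[["sd"]] * plotval$FL_Begin[, l, , drop = FALSE]
    full_cd <- sc_f[["mean"]] + sc_f[["sd"]] * plotval$FL_Full[, l, , drop = FALSE]
    full_cd <- pmax(full_cd, begin_cd)
    if (any(begin_cd > total) || any(full_cd > total))
      stop("a flowering degree-day value (max ",
           round(max(c(begin_cd, full_cd)), 1), " Cd) exceeds the season's ",
           "accumulable thermal time (", round(total, 1), " Cd) at ", locs[l])
    begin_date <- cd_to_date(begin_cd, cum, emergence)
    full_date <- cd_to_date(full_cd, cum, emergence)
    liab <- plotval$Sex_det[, l, , drop = FALSE] / liab_sd
    score <- 1L + (liab >= -1) + (liab > 1)
    recs[[l]] <- data.frame(
      location_id = locs[l],
      accession_id = rep(acc, config$n_plots),
      plot_id = paste0("plot", rep(seq_len(config$n_plots), each = n)),
      sowing_date = sowing,
      emergence_date = emergence,
      begin_flowering_date = as.Date(as.vector(begin_date), origin = "1970-01-01"),
      full_flowering_date = as.Date(as.vector(full_date), origin = "1970-01-01"),
      sex_score = as.integer(score),
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL

  tt <- aggregate_plots(records, temps)
  truth$qtls <- qtls
  truth$genetic_values <- gvals
  truth$variance_components <- varcomp
  list(records = records, traits = tt, truth = truth)
}

# Cumulative thermal time from `emergence` (half-open day intervals):
# cd[t + 1] = thermal time accumulated over [emergence, emergence + t).
thermal_time_profile <- function(series, emergence, base_temp = 1) {
  i0 <- match(emergence, series$date)
  if (is.na(i0)) stop("emergence date ", emergence, " outside the series")
  inc <- pmax(series$tmean_c[i0:nrow(series)] - base_temp, 0)
  data.frame(offset = 0:length(inc), cd = c(0, cumsum(inc)))
}

# Invert degree-day targets to calendar dates: the first day on which the
# accumulated thermal time from emergence reaches the target.
cd_to_date <- function(target_cd, cum, emergence) {
  idx <- findInterval(target_cd, cum$cd, left.open = TRUE) + 1L
  # findInterval gives the last cd <= target; with left.open the first index
  # whose cumulative value is >= target is recovered below
  idx <- pmin(idx, nrow(cum))
  emergence + cum$offset[idx]
}
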