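test_that("forward selection finds the causal blocks and clusters their members", {
  fx <- block_fixture(seed = 2L)
  model <- forward_select(fx$scan, fx$g, fx$y, analysis_config())
  expect_s3_class(model, "multiqtl_model")
  expect_equal(nrow(model$qtls), 2)
  causal_scaffolds <- c("s1", "s2")
  reps <- model$qtls$representative
  expect_setequal(sub("_.*", "", reps), causal_scaffolds)
  # memberships equal the representative's block
  for (r in reps) {
    blk <- sub("_.*", "", r)
    expect_setequal(c(r, model$members[[r]]),
                    fx$scan$marker_id[startsWith(fx$scan$marker_id,
                                                 paste0(blk, "_"))])
  }
})

test_that("the first pick maximizes marginal explained variance", {
  fx <- block_fixture(seed = 9L)
  model <- forward_select(fx$scan, fx$g, fx$y, analysis_config())
  marg <- vapply(setNames(nm = fx$scan$marker_id[fx$scan$significant]),
                 function(mk) cor(fx$g$values[, mk], fx$y)^2, numeric(1))
  expect_equal(model$qtls$representative[1], names(which.max(marg)))
  expect_equal(model$qtls$incremental_r2[1], max(marg), tolerance = 1e-10)
})

test_that("representatives and members partition the significant set, representatives non-collinear", {
  for (seed in c(3L, 14L)) {
    fx <- block_fixture(seed = seed, blocks = 4L, causal = c(1L, 3L))
    model <- forward_select(fx$scan, fx$g, fx$y, analysis_config())
    assigned <- c(model$qtls$representative, unlist(model$members))
    expect_setequal(assigned, fx$scan$marker_id[fx$scan$significant])
    expect_equal(anyDuplicated(assigned), 0L)
    reps <- model$qtls$representative
    if (length(reps) > 1) {
      cm <- abs(cor(fx$g$values[, reps]))
      expect_true(all(cm[upper.tri(cm)] < 0.3))
    }
    for (r in reps) for (mmb in model$members[[r]])
      expect_gte(abs(cor(fx$g$values[, r], fx$g$values[, mmb])), 0.3)
  }
})

test_that("cumulative explained variance is non-decreasing in selection order", {
  fx <- block_fixture(seed = 5L, blocks = 5L, causal = c(1L, 2L, 4L))
  model <- forward_select(fx$scan, fx$g, fx$y, analysis_config())
  expect_true(all(model$qtls$incremental_r2 > -1e-10))
  cum <- vapply(seq_len(nrow(model$qtls)), function(k)
    explained_variance(model$qtls$representative[seq_len(k)], fx$g, fx$y),
    numeric(1))
  expect_true(all(diff(cum) >= -1e-10))
  expect_equal(cum[length(cum)], model$full_r2, tolerance = 1e-10)
  expect_equal(cum, cumsum(model$qtls$incremental_r2), tolerance = 1e-8)
})

test_that("degenerate forward-selection inputs behave as specified", {
  fx <- block_fixture(seed = 6L)
  one <- fx$scan[fx$scan$marker_id == "s1_100", ]
  m1 <- forward_select(one, fx$g, fx$y, analysis_config())
  expect_equal(nrow(m1$qtls), 1)
  expect_equal(m1$full_r2, cor(fx$g$values[, "s1_100"], fx$y)^2,
               tolerance = 1e-10)
  # two perfectly collinear markers collapse to one QTL with one member
  g2 <- fx$g
  g2$values[, "s2_100"] <- g2$values[, "s1_100"]
  two <- fx$scan[fx$scan$marker_id %in% c("s1_100", "s2_100"), ]
  m2 <- forward_select(two, g2, fx$y, analysis_config())
  expect_equal(nrow(m2$qtls), 1)
  expect_equal(unname(lengths(m2$members)), 1L)
  # empty significant set
  none <- fx$scan[0, ]
  expect_message(m0 <- forward_select(none, fx$g, fx$y, analysis_config()),
                 "empty")
  expect_equal(nrow(m0$qtls), 0)
  expect_true(is.na(m0$full_r2))
})

test_that("explained variance equals an independent multiple-regression oracle", {
  fx <- block_fixture(seed = 7L, blocks = 4L, causal = c(2L, 3L))
  reps <- c("s1_100", "s2_200", "s4_300")
  r2 <- explained_variance(reps, fx$g, fx$y)
  fit <- lm(fx$y ~ fx$g$values[, reps])
  expect_equal(r2, summary(fit)$r.squared, tolerance = 1e-10)
  # perfect fit and intercept-only limits
  yhat <- setNames(fx$g$values[, "s1_100"], names(fx$y))
  expect_equal(explained_variance("s1_100", fx$g, yhat), 1, tolerance = 1e-12)
  set.seed(1)
  ortho <- setNames(rnorm(length(fx$y)), names(fx$y))
  expect_lt(explained_variance("s1_100", fx$g,
                               setNames(resid(lm(ortho ~ fx$g$values[, "s1_100"])),
                                        names(fx$y))), 1e-12)
})

test_that("marker-profile PCA matches a covariance eigendecomposition and its invariances", {
  fx <- block_fixture(seed = 8L)
  scan <- fx$scan
  scan$significant <- TRUE            # all profiles enter the PCA
  scan$neg_log10_p <- seq_len(nrow(scan))
  pca <- pca_marker_profiles(fx$g, scan)
  X <- t(fx$g$values[, scan$marker_id])
  Xc <- scale(X, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(Xc) / 1, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(attr(pca, "var_explained")[1:2],
               (ev / sum(ev))[1:2], tolerance = 1e-10)
  # duplicated marker rows get identical scores
  g2 <- fx$g
  g2$values[, "s3_100"] <- g2$values[, "s1_100"]
  pca2 <- pca_marker_profiles(g2, scan)
  expect_equal(pca2$PC1[pca2$marker_id == "s3_100"],
               pca2$PC1[pca2$marker_id == "s1_100"], tolerance = 1e-10)
  # adding a constant to one accession's column leaves scores unchanged
  g3 <- fx$g
  g3$values <- g3$values * 0.5          # headroom to stay within [0, 1]
  pca3a <- pca_marker_profiles(g3, scan)
  g3$values[, ] <- g3$values            # same matrix, shift one accession
  g4 <- g3
  g4$values[3, ] <- g4$values[3, ] + 0.2
  pca3b <- pca_marker_profiles(g4, scan)
  expect_equal(pca3a$PC1, pca3b$PC1, tolerance = 1e-10)
  expect_equal(pca3a$PC2, pca3b$PC2, tolerance = 1e-10)
  expect_error(pca_marker_profiles(fx$g, scan[1:2, ]), "at least 3")
})

test_that("cross-location consolidation links representatives at |r| >= 0.3 spanning 2+ locations", {
  fx <- block_fixture(seed = 10L, blocks = 4L)
  mk_model <- function(loc, reps) {
    structure(list(trait = "FL_Begin", location_id = loc,
                   qtls = data.frame(order = seq_along(reps),
                                     representative = reps,
                                     n_members = 0L,
                                     incremental_r2 = 0.1),
                   members = setNames(rep(list(character(0)), length(reps)),
                                      reps),
                   full_r2 = 0.3), class = "multiqtl_model")
  }
  # the same marker in all three models: one QTL spanning three locations
  ms <- list(mk_model("CRA", "s1_100"), mk_model("FNPC", "s1_100"),
             mk_model("VDS", "s1_100"))
  cl <- consolidate_across_locations(ms, fx$g, analysis_config())
  expect_equal(length(cl), 1)
  expect_equal(cl[[1]]$n_locations, 3)
  expect_equal(cl[[1]]$name, "QTL_FL_Begin_1")
  # correlated same-block markers across two models, plus an uncorrelated one
  ms2 <- list(mk_model("CRA", c("s1_100", "s3_100")),
              mk_model("FNPC", "s1_200"))
  cl2 <- consolidate_across_locations(ms2, fx$g, analysis_config())
  expect_equal(length(cl2), 1)
  expect_setequal(names(cl2[[1]]$locations), c("CRA", "FNPC"))
  expect_equal(cl2[[1]]$locations$CRA, "s1_100")
  # all cross-model correlations below the threshold: empty output
  ms3 <- list(mk_model("CRA", "s1_100"), mk_model("FNPC", "s2_100"))
  cl3 <- consolidate_across_locations(ms3, fx$g, analysis_config())
  expect_equal(length(cl3), 0)
  # invariance to input model order
  cl_rev <- consolidate_across_locations(rev(ms), fx$g, analysis_config())
  expect_equal(cl, cl_rev)
  # mixed traits are rejected
  bad <- ms
  bad[[2]]$trait <- "VEG"
  expect_error(consolidate_across_locations(bad, fx$g, analysis_config()),
               "different traits")
})

test_that("a planted shared QTL consolidates across locations while location-private ones do not", {
  qtls <- list(planted_qtl("FL_Begin", 0.25, shared_across_locations = TRUE),
               planted_qtl("FL_Begin", 0.2, shared_across_locations = FALSE))
  sp <- small_panel(seed = 31L, n_accessions = 120L, n_scaffolds = 50L,
                    planted = qtls,
                    h2 = c(FL_Begin = 0.9, FL_Full = 0.9, Sex_det = 0.9))
  g <- filter_snps(sp$genotypes)$genotypes
  K <- compute_kinship(g)
  me <- effective_marker_number(g)
  cfg <- analysis_config()
  models <- lapply(names(sp$temps), function(l) {
    y <- trait_vector(sp$traits, "FL_Begin", l)
    sc <- association_scan(y, g, K, cfg, m_eff = me, trait = "FL_Begin",
                           location_id = l)
    suppressMessages(forward_select(sc, g, y, cfg))
  })
  cl <- consolidate_across_locations(models, g, cfg)
  blocks <- sp$truth$blocks
  qinfo <- sp$truth$qtls
  shared_block <- qinfo$block[qinfo$shared]
  rep_blocks <- unique(unlist(lapply(cl, function(q)
    blocks[unlist(q$locations)])))
  expect_true(shared_block %in% rep_blocks)
  private_block <- qinfo$block[!qinfo$shared]
  for (q in cl) {
    locs_with_private <- names(q$locations)[vapply(q$locations, function(ids)
      private_block %in% blocks[ids], logical(1))]
    expect_lte(length(locs_with_private), 1)
  }
})
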