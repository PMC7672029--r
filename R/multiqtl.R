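# MultiQTL modeling: forward selection of significant markers with
# collinearity clustering, explained variance, marker-profile PCA, and
# cross-location QTL consolidation.

#' Forward-selection MultiQTL model
#'
#' Iterates over the significant markers of a scan: the candidate maximizing
#' the incremental explained variance of the joint linear model (the marginal
#' r-squared at the first step) becomes the next representative QTL-marker;
#' every remaining candidate whose genotype vector is correlated with the
#' representative at `|r| >= r_threshold` is assigned to that QTL as a
#' collinear member and removed from candidacy; selection continues until no
#' candidates remain.  Ties on incremental variance are broken by the larger
#' Wald statistic, then by marker id.
#'
#' @param scan An [association_scan()] result (its `significant` column
#'   defines the candidates) or any data frame with `marker_id`, `wald` and
#'   `significant` columns.
#' @param g A [genotype_matrix()] containing the candidate markers.
#' @param y Named trait vector.
#' @param config An [analysis_config()] (collinearity threshold).
#' @return A `multiqtl_model`: trait/location labels, an ordered `qtls` data
#'   frame (`order`, `representative`, `n_members`, `incremental_r2`), a
#'   `members` list keyed by representative, and the full-model `r2`.
#' @export
forward_select <- function(scan, g, y, config = analysis_config()) {
  stopifnot(inherits(g, "genotype_matrix"))
  cand <- scan$marker_id[which(scan$significant)]
  trait <- if ("trait" %in% names(scan)) scan$trait[1] else NA_character_
  loc <- if ("location_id" %in% names(scan)) scan$location_id[1] else NA_character_
  if (length(cand) == 0) {
    message("no significant markers; returning an empty MultiQTL model")
    return(structure(list(trait = trait, location_id = loc,
                          qtls = data.frame(order = integer(),
                                            representative = character(),
                                            n_members = integer(),
                                            incremental_r2 = numeric()),
                          members = list(), full_r2 = NA_real_),
                     class = "multiqtl_model"))
  }
  miss <- setdiff(cand, colnames(g$values))
  if (length(miss) > 0)
    stop("significant markers absent from the genotype matrix: ",
         paste(miss, collapse = ", "))
  ids <- intersect(names(y)[!is.na(y)], rownames(g$values))
  yv <- y[ids]
  G <- g$values[ids, cand, drop = FALSE]
  wald <- setNames(scan$wald, scan$marker_id)[cand]
  cmat <- abs(cor(G))

  reps <- character(0)
  members <- list()
  inc_r2 <- numeric(0)
  remaining <- cand
  r2_prev <- 0
  while (length(remaining) > 0) {
    r2_new <- vapply(remaining, function(mk)
      model_r2(yv, G[, c(reps, mk), drop = FALSE]), numeric(1))
    inc <- r2_new - r2_prev
    ord <- order(-inc, -wald[remaining], remaining)
    pick <- remaining[ord[1]]
    reps <- c(reps, pick)
    inc_r2 <- c(inc_r2, unname(inc[ord[1]]))
    r2_prev <- unname(r2_new[ord[1]])
    remaining <- setdiff(remaining, pick)
    coll <- remaining[cmat[remaining, pick] >= config$r_threshold]
    members[[pick]] <- coll
    remaining <- setdiff(remaining, coll)
  }
  structure(list(trait = trait, location_id = loc,
                 qtls = data.frame(order = seq_along(reps),
                                   representative = reps,
                                   n_members = lengths(members[reps]),
                                   incremental_r2 = inc_r2,
                                   row.names = NULL),
                 members = members,
                 full_r2 = r2_prev),
            class = "multiqtl_model")
}

#' @export
print.multiqtl_model <- function(x, ...) {
  cat("MultiQTL model", if (!is.na(x$trait)) paste0("for ", x$trait),
      if (!is.na(x$location_id)) paste0("at ", x$location_id),
      ":", nrow(x$qtls), "QTLs, explained variance r2 =",
      round(100 * x$full_r2, 2), "%\n")
  invisible(x)
}

# Squared correlation between fitted and observed values; computed as
# 1 - RSS/TSS (identical for least squares with an intercept, but stable when
# the fitted values are numerically constant).
model_r2 <- function(y, X) {
  fit <- lm.fit(cbind(`(Intercept)` = 1, X), y)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(0)
  min(max(1 - sum(fit$residuals^2) / tss, 0), 1)
}

#' Explained variance of a MultiQTL model
#'
#' Regresses the trait on the representative markers jointly (with intercept)
#' and returns the squared Pearson correlation between fitted and observed
#' trait values.
#'
#' @param model A `multiqtl_model` from [forward_select()], or a character
#'   vector of representative marker ids.
#' @param g A [genotype_matrix()].
#' @param y Named trait vector.
#' @return The full-model r-squared in `[0, 1]`.
#' @export
explained_variance <- function(model, g, y) {
  reps <- if (inherits(model, "multiqtl_model")) model$qtls$representative
          else as.character(model)
  if (length(reps) == 0) stop("empty MultiQTL model")
  ids <- intersect(names(y)[!is.na(y)], rownames(g$values))
  X <- cbind(1, g$values[ids, reps, drop = FALSE])
  if (qr(X)$rank < ncol(X))
    stop("representative markers are collinear; explained variance undefined")
  model_r2(y[ids], g$values[ids, reps, drop = FALSE])
}

#' PCA of the allele-frequency profiles of significant markers
#'
#' Markers are the observations and accessions the variables: the marker x
#' accession matrix of genotype values is column-centered and decomposed by
#' SVD.  Each marker's scores on the first two components are joined with its
#' association significance, the coordinates of the usual three-dimensional
#' (PC1, PC2, -log10 P) QTL landscape.  Component signs are fixed so the
#' largest-magnitude accession loading of each component is positive.
#'
#' @param g A [genotype_matrix()].
#' @param records An [association_scan()] result; rows with
#'   `significant == TRUE` (at least 3) enter the PCA.
#' @return Data frame (`marker_id`, `PC1`, `PC2`, `neg_log10_p`) with a
#'   `var_explained` attribute giving every component's variance fraction.
#' @export
pca_marker_profiles <- function(g, records) {
  ids <- records$marker_id[which(records$significant)]
  if (length(ids) < 3) stop("marker-profile PCA needs at least 3 significant markers")
  X <- t(g$values[, ids, drop = FALSE])       # markers x accessions
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc)
  for (k in seq_along(sv$d)) {
    j <- which.max(abs(sv$v[, k]))
    if (sv$v[j, k] < 0) { sv$v[, k] <- -sv$v[, k]; sv$u[, k] <- -sv$u[, k] }
  }
  scores <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  nlp <- setNames(records$neg_log10_p, records$marker_id)[ids]
  out <- data.frame(marker_id = ids, PC1 = scores[, 1], PC2 = scores[, 2],
                    neg_log10_p = unname(nlp), row.names = NULL)
  attr(out, "var_explained") <- sv$d^2 / sum(sv$d^2)
  out
}

#' Consolidate QTLs across locations
#'
#' Computes the Pearson correlation between the genotype vectors of every
#' pair of representative QTL-markers from different-location models of one
#' trait, links pairs at `|r| >= r_threshold`, and reports each connected
#' component spanning at least two locations as one cross-location QTL
#' (components confined to a single location are dropped).  QTLs are named
#' `QTL_<trait>_<k>` in a deterministic discovery order that does not depend
#' on the input model order.
#'
#' @param models List of `multiqtl_model`s for the same trait from >= 2
#'   locations.
#' @param g A [genotype_matrix()].
#' @param config An [analysis_config()].
#' @return List of `cross_location_qtl`s: `name`, `trait`, `locations` (a
#'   named list mapping each location to its representative marker ids) and
#'   `n_locations`.
#' @export
consolidate_across_locations <- function(models, g, config = analysis_config()) {
  stopifnot(length(models) >= 2)
  traits <- vapply(models, function(m) m$trait, character(1))
  if (length(unique(traits)) != 1)
    stop("models for different traits cannot be consolidated")
  trait <- traits[1]
  nodes <- do.call(rbind, lapply(models, function(m) {
    if (nrow(m$qtls) == 0) return(NULL)
    data.frame(location_id = m$location_id,
               marker_id = m$qtls$representative, stringsAsFactors = FALSE)
  }))
  out <- list()
  if (is.null(nodes) || nrow(nodes) == 0) return(structure(out, class = "crossloc_set", trait = trait))
  if (anyNA(nodes$location_id))
    stop("models must carry location ids to be consolidated across locations")
  if (length(unique(nodes$location_id)) < 2)
    return(structure(out, class = "crossloc_set", trait = trait))
  nodes <- nodes[order(nodes$location_id, nodes$marker_id), , drop = FALSE]
  nn <- nrow(nodes)
  V <- g$values[, nodes$marker_id, drop = FALSE]
  cmat <- abs(cor(V))
  adj <- cmat >= config$r_threshold &
    outer(nodes$location_id, nodes$location_id, "!=")

  comp <- rep(NA_integer_, nn)
  cid <- 0L
  for (i in seq_len(nn)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    comp[i] <- cid
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  k <- 0L
  for (cc in seq_len(cid)) {
    sel <- comp == cc
    locs <- unique(nodes$location_id[sel])
    if (length(locs) < 2) next
    k <- k + 1L
    by_loc <- split(nodes$marker_id[sel], nodes$location_id[sel])
    out[[k]] <- structure(list(name = paste0("QTL_", trait, "_", k),
                               trait = trait,
                               locations = lapply(by_loc, sort),
                               n_locations = length(locs)),
                          class = "cross_location_qtl")
  }
  structure(out, class = "crossloc_set", trait = trait)
}

#' @export
print.cross_location_qtl <- function(x, ...) {
  cat(x$name, " (", x$trait, "): ", sep = "")
  cat(paste0(names(x$locations), " [",
             vapply(x$locations, paste, character(1), collapse = "; "), "]"),
      sep = " | ")
  cat("\n")
  invisible(x)
}

#' @export
print.crossloc_set <- function(x, ...) {
  cat(length(x), "cross-location QTLs for", attr(x, "trait"), "\n")
  for (q in x) print(q)
  invisible(x)
}
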