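# Marker scoring, SNP selection filters, VanRaden genomic relationship
# matrix, and the Li-Ji effective number of independent markers.

#' Construct a pooled-frequency genotype matrix
#'
#' @param values Numeric accession x marker matrix of panel-major-allele
#'   proportions in `[0, 1]` (`NA` allowed before filtering), with accession
#'   row names and marker column names.
#' @param markers Data frame with one row per marker: `marker_id`,
#'   `scaffold`, `position`, `major`, `minor` and optionally `top2_sum` (the
#'   panel-mean frequency sum of the two most frequent alleles, used by the
#'   biallelic filter; taken as 1 when absent).
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(values, markers) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values), !is.null(rownames(values)),
            !is.null(colnames(values)),
            identical(colnames(values), markers$marker_id))
  rng <- range(values, na.rm = TRUE)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stop("genotype values must be proportions in [0, 1]")
  if (!"top2_sum" %in% names(markers)) markers$top2_sum <- 1
  rownames(markers) <- NULL
  structure(list(values = values, markers = markers), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Pooled-frequency genotype matrix:", nrow(x$values), "accessions x",
      ncol(x$values), "markers on", length(unique(x$markers$scaffold)),
      "scaffolds\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

#' Score markers as panel-major-allele proportions
#'
#' From per-accession allele frequencies (%A/%C/%G/%T per marker), determines
#' the panel-major allele of each marker as the allele with the largest mean
#' frequency over accessions and extracts its per-accession frequency as the
#' genotype value.  Ties are broken by the fixed allele order A < C < G < T
#' and reported via a message.
#'
#' @param freqs Long data frame with columns `marker_id`, `accession_id`,
#'   `A`, `C`, `G`, `T`; the four frequencies of each row must sum to 1
#'   within `tol`.
#' @param tol Tolerance on the per-row frequency sum.
#' @return A [genotype_matrix()] whose `markers` table carries the major and
#'   minor allele and their panel-mean frequency sum (`top2_sum`).
#' @export
score_major_allele <- function(freqs, tol = 1e-6) {
  need <- c("marker_id", "accession_id", "A", "C", "G", "T")
  stopifnot(all(need %in% names(freqs)))
  fm <- as.matrix(freqs[, c("A", "C", "G", "T")])
  bad <- abs(rowSums(fm) - 1) > tol
  if (any(bad))
    stop("allele frequencies do not sum to 1 for markers: ",
         paste(unique(freqs$marker_id[bad]), collapse = ", "))
  mids <- unique(freqs$marker_id)
  accs <- unique(freqs$accession_id)
  values <- matrix(NA_real_, length(accs), length(mids),
                   dimnames = list(accs, mids))
  info <- data.frame(marker_id = mids, major = NA_character_,
                     minor = NA_character_, top2_sum = NA_real_,
                     stringsAsFactors = FALSE)
  ties <- character(0)
  for (k in seq_along(mids)) {
    rows <- freqs$marker_id == mids[k]
    mean_f <- colMeans(fm[rows, , drop = FALSE])
    ord <- order(-mean_f, c("A", "C", "G", "T"))   # ties: fixed allele order
    if (sum(mean_f == max(mean_f)) > 1) ties <- c(ties, mids[k])
    info$major[k] <- c("A", "C", "G", "T")[ord[1]]
    info$minor[k] <- c("A", "C", "G", "T")[ord[2]]
    info$top2_sum[k] <- sum(mean_f[ord[1:2]])
    values[match(freqs$accession_id[rows], accs), k] <- fm[rows, ord[1]]
  }
  if (length(ties) > 0)
    message("major-allele ties broken by allele order A<C<G<T for: ",
            paste(ties, collapse = ", "))
  par <- parse_marker_ids(mids, strict = FALSE)
  info <- cbind(info[, "marker_id", drop = FALSE], par[, c("scaffold", "position")],
                info[, c("major", "minor", "top2_sum")])
  genotype_matrix(values, info)
}

#' SNP selection thresholds
#'
#' Defaults mirror the selection applied to the pooled RAD-seq panel: 100%
#' call rate, minor allele frequency of at least 2%, frequency sum of the two
#' major alleles of at least 95% (biallelic), and a standard deviation of the
#' major-allele frequency of at least 0.1.
#'
#' @param call_rate_min Minimum fraction of non-missing accessions.
#' @param maf_min Minimum panel-mean minor-allele frequency.
#' @param biallelic_sum_min Minimum panel-mean frequency sum of the two most
#'   frequent alleles.
#' @param major_freq_sd_min Minimum SD of the major-allele frequency across
#'   accessions.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(call_rate_min = 1.0, maf_min = 0.02,
                          biallelic_sum_min = 0.95, major_freq_sd_min = 0.1) {
  vals <- c(call_rate_min, maf_min, biallelic_sum_min, major_freq_sd_min)
  if (any(vals < 0 | vals > 1)) stop("all thresholds must lie in [0, 1]")
  structure(list(call_rate_min = call_rate_min, maf_min = maf_min,
                 biallelic_sum_min = biallelic_sum_min,
                 major_freq_sd_min = major_freq_sd_min),
            class = "qc_thresholds")
}

#' Apply the SNP selection filters
#'
#' Filters are applied in the fixed order call rate, biallelic frequency sum,
#' minor allele frequency, major-frequency SD; the surviving set does not
#' depend on the order, only the per-rule removal counts do.
#'
#' @param g A [genotype_matrix()].
#' @param thresholds A [qc_thresholds()].
#' @return List with `genotypes` (the filtered matrix) and `report` (data
#'   frame of removal counts per rule, in application order).
#' @export
filter_snps <- function(g, thresholds = qc_thresholds()) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(thresholds, "qc_thresholds"))
  v <- g$values
  keep <- rep(TRUE, ncol(v))
  report <- data.frame(rule = c("call_rate", "biallelic_sum", "maf",
                                "major_freq_sd"),
                       removed = 0L, retained = NA_integer_)

  call_rate <- 1 - colMeans(is.na(v))
  drop1 <- keep & call_rate < thresholds$call_rate_min
  keep <- keep & !drop1

  top2 <- g$markers$top2_sum[match(colnames(v), g$markers$marker_id)]
  drop2 <- keep & top2 < thresholds$biallelic_sum_min
  keep <- keep & !drop2

  mean_major <- colMeans(v, na.rm = TRUE)
  drop3 <- keep & mean_major > 1 - thresholds$maf_min
  keep <- keep & !drop3

  sd_major <- apply(v, 2, sd, na.rm = TRUE)
  drop4 <- keep & (is.na(sd_major) | sd_major < thresholds$major_freq_sd_min)
  keep <- keep & !drop4

  report$removed <- c(sum(drop1), sum(drop2), sum(drop3), sum(drop4))
  report$retained <- ncol(v) - cumsum(report$removed)
  if (!any(keep)) warning("no markers survive the SNP selection filters")
  out <- genotype_matrix(v[, keep, drop = FALSE], g$markers[keep, , drop = FALSE])
  list(genotypes = out, report = report)
}

#' VanRaden genomic relationship matrix
#'
#' Treats twice the pooled major-allele proportion as an allele dosage on the
#' usual 0-2 scale, centers each marker at twice its panel-mean frequency,
#' and scales the cross-product by `2 * sum(p_j * (1 - p_j))`.  Monomorphic
#' markers (panel mean 0 or 1) are excluded from both the product and the
#' scaling sum.
#'
#' @param g A [genotype_matrix()] or a plain accession x marker frequency
#'   matrix without missing values.
#' @return Symmetric positive semi-definite accession x accession matrix.
#' @export
compute_kinship <- function(g) {
  v <- if (inherits(g, "genotype_matrix")) g$values else as.matrix(g)
  if (anyNA(v)) stop("kinship requires a complete (filtered) genotype matrix")
  if (nrow(v) < 2) stop("kinship needs at least 2 accessions")
  if (ncol(v) < 2) stop("kinship needs at least 2 markers")
  p <- colMeans(v)
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all markers are monomorphic")
  dose <- 2 * v[, poly, drop = FALSE]
  Z <- sweep(dose, 2, 2 * p[poly])
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  K <- tcrossprod(Z) / denom
  (K + t(K)) / 2
}

#' Effective number of independent markers (Li-Ji)
#'
#' Within each scaffold, markers (ordered by position) are split into
#' windows of at most `window` markers; for each window the eigenvalues
#' `lambda_i` of the marker correlation matrix give the block contribution
#' `sum_i [ 1(lambda_i >= 1) + (lambda_i - floor(lambda_i)) ]`, and block
#' contributions are summed over the genome.
#'
#' @param g A [genotype_matrix()] (post-filter: complete, non-constant).
#' @param window Maximum markers per correlation block (default 200).
#' @return `M_eff`, bounded by `1 <= M_eff <= M`.
#' @export
effective_marker_number <- function(g, window = 200L) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (window < 1) stop("window must be >= 1")
  v <- g$values
  info <- g$markers
  m_eff <- 0
  for (sc in unique(info$scaffold)) {
    ids <- info$marker_id[info$scaffold == sc]
    ids <- ids[order(info$position[match(ids, info$marker_id)])]
    chunks <- split(ids, ceiling(seq_along(ids) / window))
    for (ch in chunks) {
      if (length(ch) == 1) { m_eff <- m_eff + 1; next }
      lam <- eigen(cor(v[, ch, drop = FALSE]), symmetric = TRUE,
                   only.values = TRUE)$values
      # rounding keeps the integer-valued eigenvalues of perfectly collinear
      # blocks on the correct side of the formula's floor() discontinuity
      lam <- round(pmax(lam, 0), 10)
      m_eff <- m_eff + sum((lam >= 1) + (lam - floor(lam)))
    }
  }
  min(max(m_eff, 1), ncol(v))
}

# Parse "scaffold<k>_<pos>" / "C<k>_<pos>" marker ids into scaffold and
# position (the part after the last underscore).
parse_marker_ids <- function(ids, strict = TRUE) {
  ok <- grepl("^.+_[0-9]+$", ids)
  if (strict && any(!ok))
    stop("marker ids do not parse to (scaffold, position): ",
         paste(ids[!ok], collapse = ", "))
  scaffold <- ifelse(ok, sub("_[0-9]+$", "", ids), NA_character_)
  position <- ifelse(ok, as.integer(sub("^.+_", "", ids)), NA_integer_)
  data.frame(marker_id = ids, scaffold = scaffold, position = position,
             stringsAsFactors = FALSE)
}
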