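# Readers and writers for the pipeline's tabular formats (TSV/CSV with
# headers), FASTA and annotation inputs, the truth record, and the structured
# configuration file.

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a genotype matrix as TSV
#'
#' The values file has accessions as rows (first column `accession_id`) and
#' marker ids as columns; the marker metadata file has one row per marker.
#'
#' @param g A [genotype_matrix()].
#' @param values_path,markers_path Output/input file paths.
#' @return `write_genotypes` the paths, invisibly; `read_genotypes` a
#'   [genotype_matrix()].
#' @export
write_genotypes <- function(g, values_path, markers_path) {
  stopifnot(inherits(g, "genotype_matrix"))
  df <- data.frame(accession_id = rownames(g$values), g$values,
                   check.names = FALSE)
  write_tsv(df, values_path)
  write_tsv(g$markers, markers_path)
  invisible(c(values_path, markers_path))
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(values_path, markers_path) {
  df <- read.delim(values_path, check.names = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$accession_id
  markers <- read.delim(markers_path, stringsAsFactors = FALSE)
  genotype_matrix(values, markers)
}

#' Write / read a trait table as TSV
#' @param tt A `trait_table` from [aggregate_plots()].
#' @param path File path.
#' @return The path / a `trait_table`.
#' @export
write_trait_table <- function(tt, path) write_tsv(tt, path)

#' @rdname write_trait_table
#' @export
read_trait_table <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("trait_table", "data.frame")
  out
}

# Extract one trait as the named phenotype vector of a location.
#' Phenotype vector of one trait at one location
#' @param tt A `trait_table`.
#' @param trait Column name (`FL_Begin`, `FL_Full`, `VEG`, `Sex_det`).
#' @param location Location id.
#' @return Named numeric vector keyed by accession.
#' @export
trait_vector <- function(tt, trait, location) {
  sel <- tt$location_id == location
  setNames(tt[[trait]][sel], tt$accession_id[sel])
}

#' Write / read temperature series as CSV
#'
#' One CSV with columns `location_id`, `date`, `tmean_c` holding one or more
#' locations.
#'
#' @param temps A [temperature_series()] or a (named) list of them.
#' @param path File path.
#' @return The path / a named list of [temperature_series()].
#' @export
write_temperature <- function(temps, path) {
  temps <- as_series_list(temps)
  df <- do.call(rbind, lapply(names(temps), function(l)
    data.frame(location_id = l, date = temps[[l]]$date,
               tmean_c = temps[[l]]$tmean_c)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_temperature
#' @export
read_temperature <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$location_id), function(d)
    temperature_series(d$location_id[1], as.Date(d$date), d$tmean_c))
  out[unique(df$location_id)]
}

#' Write / read plot phenology records as CSV
#' @param records Plot phenology data frame (see
#'   [compute_flowering_traits()]); missing dates are written as empty
#'   fields.
#' @param path File path.
#' @return The path / the records data frame with `Date` columns.
#' @export
write_phenology <- function(records, path) {
  write.csv(records, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_phenology
#' @export
read_phenology <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  for (col in c("sowing_date", "emergence_date", "begin_flowering_date",
                "full_flowering_date"))
    if (col %in% names(df)) df[[col]] <- as.Date(df[[col]])
  validate_phenology(df)
  df
}

#' Write / read a truth record as structured text (JSON)
#' @param truth A `truth_record` from [simulate_panel()].
#' @param path File path.
#' @return The path / a `truth_record` (the configuration is restored as a
#'   plain list).
#' @export
write_truth <- function(truth, path) {
  x <- truth
  x$config <- unclass(x$config)
  x$config$planted_qtls <- lapply(x$config$planted_qtls, unclass)
  x$freq_true <- list(accessions = rownames(truth$freq_true),
                      markers = colnames(truth$freq_true),
                      values = unname(truth$freq_true))
  x$allele1_counts <- unname(truth$allele1_counts)
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       na = "null", matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  f <- x$freq_true
  x$freq_true <- matrix(unlist(f$values), length(f$accessions),
                        length(f$markers), byrow = FALSE,
                        dimnames = list(f$accessions, f$markers))
  if (!is.null(x$allele1_counts))
    x$allele1_counts <- matrix(unlist(x$allele1_counts),
                               nrow(x$freq_true), ncol(x$freq_true),
                               dimnames = dimnames(x$freq_true))
  x$subpop <- setNames(unlist(x$subpop), f$accessions)
  x$blocks <- setNames(unlist(x$blocks), f$markers)
  if (length(x$qtls) == 0) {
    x$qtls <- data.frame(marker_id = character(), trait = character(),
                         variance_fraction = numeric(), shared = logical(),
                         block = character(), scaffold = character(),
                         stringsAsFactors = FALSE)
  } else if ("location" %in% names(x$qtls)) {
    x$qtls$location <- as.character(x$qtls$location)
  }
  structure(x, class = "truth_record")
}

#' Write / read an association scan as TSV
#' @param scan An [association_scan()] result.
#' @param path File path.
#' @return The path / an `assoc_scan` data frame (threshold and `m_eff`
#'   restored from header comments).
#' @export
write_scan <- function(scan, path) {
  con <- file(path, "w")
  writeLines(sprintf("# threshold=%.10g m_eff=%.10g",
                     attr(scan, "threshold"), attr(scan, "m_eff")), con)
  write.table(scan, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_scan
#' @export
read_scan <- function(path) {
  hdr <- readLines(path, n = 1)
  out <- read.delim(path, skip = 1, stringsAsFactors = FALSE)
  attr(out, "threshold") <- as.numeric(sub(".*threshold=([^ ]+).*", "\\1", hdr))
  attr(out, "m_eff") <- as.numeric(sub(".*m_eff=([^ ]+).*", "\\1", hdr))
  class(out) <- c("assoc_scan", "data.frame")
  out
}

#' Write / read a MultiQTL model as TSV
#'
#' One row per QTL: order, representative, `;`-joined member markers and the
#' incremental explained variance, plus trait, location and the full-model
#' r-squared repeated per row.
#'
#' @param model A `multiqtl_model`.
#' @param path File path.
#' @return The path / a `multiqtl_model`.
#' @export
write_multiqtl <- function(model, path) {
  q <- model$qtls
  if (nrow(q) == 0) {
    df <- data.frame(trait = character(), location_id = character(),
                     order = integer(), representative = character(),
                     members = character(), incremental_r2 = numeric(),
                     full_r2 = numeric())
  } else {
    df <- data.frame(trait = model$trait, location_id = model$location_id,
                     order = q$order, representative = q$representative,
                     members = vapply(model$members[q$representative],
                                      paste, character(1), collapse = ";"),
                     incremental_r2 = q$incremental_r2,
                     full_r2 = model$full_r2, row.names = NULL)
  }
  write_tsv(df, path)
}

#' @rdname write_multiqtl
#' @export
read_multiqtl <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0)
    return(structure(list(trait = NA_character_, location_id = NA_character_,
                          qtls = data.frame(order = integer(),
                                            representative = character(),
                                            n_members = integer(),
                                            incremental_r2 = numeric()),
                          members = list(), full_r2 = NA_real_),
                     class = "multiqtl_model"))
  members <- lapply(strsplit(as.character(df$members), ";", fixed = TRUE),
                    function(x) x[nzchar(x)])
  names(members) <- df$representative
  structure(list(trait = df$trait[1], location_id = df$location_id[1],
                 qtls = data.frame(order = df$order,
                                   representative = df$representative,
                                   n_members = lengths(members),
                                   incremental_r2 = df$incremental_r2,
                                   row.names = NULL),
                 members = members, full_r2 = df$full_r2[1]),
            class = "multiqtl_model")
}

#' Write cross-location QTLs as a wide TSV
#'
#' One row per cross-location QTL with one column per location holding the
#' `;`-joined representative markers and `-` where the QTL is absent.
#'
#' @param crossloc List from [consolidate_across_locations()].
#' @param path File path.
#' @param locations Column order; defaults to the union of locations seen.
#' @return The path, invisibly.
#' @export
write_crossloc <- function(crossloc, path, locations = NULL) {
  if (is.null(locations))
    locations <- sort(unique(unlist(lapply(crossloc, function(q)
      names(q$locations)))))
  rows <- lapply(crossloc, function(q) {
    cells <- vapply(locations, function(l) {
      if (l %in% names(q$locations)) paste(q$locations[[l]], collapse = ";")
      else "-"
    }, character(1))
    c(qtl = q$name, trait = q$trait, cells)
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  if (length(rows) == 0)
    df <- data.frame(qtl = character(), trait = character())
  write_tsv(df, path)
}

#' Read scaffold sequences from FASTA
#' @param path FASTA file (multi-record, wrapped lines allowed).
#' @return A `Biostrings::DNAStringSet`.
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Read a candidate-gene annotation table
#'
#' TSV files must carry columns `scaffold_id`, `transcript_id`,
#' `description` (optional `start`, `end`, `tags`).  BED and GFF3 files are
#' mapped into the same structure (BED's half-open 0-based intervals are
#' converted to 1-based inclusive; the BED `name` / GFF3 `ID` attribute
#' becomes the transcript id).
#'
#' @param path Annotation file; format chosen by extension (`.tsv`/`.txt`,
#'   `.bed`, `.gff`/`.gff3`).
#' @return Annotation data frame for [candidate_genes_for_qtls()].
#' @export
read_annotations <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tsv", "txt")) {
    out <- read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("scaffold_id", "transcript_id", "description") %in%
                    names(out)))
    return(out)
  }
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading ", ext, " annotations requires the rtracklayer package")
  gr <- rtracklayer::import(path)
  md <- as.data.frame(gr)
  id <- if ("name" %in% names(md)) md$name
        else if ("ID" %in% names(md)) md$ID
        else paste0("feature", seq_along(gr))
  desc <- if ("description" %in% names(md)) md$description else NA_character_
  data.frame(scaffold_id = as.character(md$seqnames), transcript_id = id,
             description = desc, start = md$start, end = md$end,
             stringsAsFactors = FALSE)
}

#' Write motif hits as TSV
#' @param hits Data frame from [find_motif()].
#' @param path File path.
#' @param table1_style If `TRUE`, write `end = start + motif length` instead
#'   of the package's 1-based inclusive `end = start + length - 1` (some
#'   published coordinate tables use the former convention).
#' @return The path, invisibly.
#' @export
write_motif_hits <- function(hits, path, table1_style = FALSE) {
  if (table1_style && nrow(hits) > 0) hits$end <- hits$end + 1L
  write_tsv(hits, path)
}

#' Read a structured configuration file
#'
#' A YAML file with optional top-level sections `simulation`, `analysis` and
#' `qc`, whose keys override the defaults of [sim_config()],
#' [analysis_config()] and [qc_thresholds()].
#'
#' @param path YAML file.
#' @param seed Optional seed overriding the file's.
#' @return List with elements `simulation`, `analysis`, `qc`.
#' @export
read_config <- function(path, seed = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  sim_args <- raw$simulation %||% list()
  if (!is.null(sim_args$planted_qtls))
    sim_args$planted_qtls <- lapply(sim_args$planted_qtls, function(q)
      do.call(planted_qtl, q))
  if (!is.null(sim_args$heritability))
    sim_args$heritability <- unlist(sim_args$heritability)
  if (!is.null(sim_args$markers_per_scaffold))
    sim_args$markers_per_scaffold <- as.integer(unlist(sim_args$markers_per_scaffold))
  if (!is.null(seed)) sim_args$seed <- as.integer(seed)
  ana_args <- raw$analysis %||% list()
  if (!is.null(seed)) ana_args$seed <- as.integer(seed)
  list(simulation = do.call(sim_config, sim_args),
       analysis = do.call(analysis_config, ana_args),
       qc = do.call(qc_thresholds, raw$qc %||% list()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
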