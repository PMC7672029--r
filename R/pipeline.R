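# End-to-end pipeline and the command-line entry point.

#' Run the full simulation-to-QTL pipeline
#'
#' Simulates a pooled-frequency panel, temperature series and phenology
#' records, computes trait means, applies the SNP filters, builds the
#' kinship, scans every trait at every location with the kinship mixed
#' model, fits the forward-selection MultiQTL models, and consolidates QTLs
#' across locations per trait.  With an `out_dir`, every intermediate is
#' written in its tabular format.
#'
#' @param config List as returned by [read_config()]; missing parts take the
#'   defaults.
#' @param out_dir Optional output directory.
#' @param traits Traits to scan (default all four).
#' @return List with the simulated objects, the filtered genotypes and
#'   report, kinship, `m_eff`, per trait x location `scans` and `models`,
#'   and per-trait `crossloc` consolidations.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL,
                         traits = c("FL_Begin", "FL_Full", "VEG", "Sex_det")) {
  sim <- config$simulation %||% sim_config()
  ana <- config$analysis %||% analysis_config()
  qc <- config$qc %||% qc_thresholds()

  panel <- simulate_panel(sim)
  locs <- paste0("LOC", seq_len(sim$n_locations))
  temps <- lapply(seq_along(locs), function(l)
    simulate_temperature(locs[l], mean_temp = 14 + 2 * l,
                         seed = substream_seed(sim$seed, 100L + l)))
  names(temps) <- locs
  phe <- simulate_phenotypes(panel$genotypes, panel$truth, sim, temps)

  filt <- filter_snps(panel$genotypes, qc)
  K <- compute_kinship(filt$genotypes)
  m_eff <- effective_marker_number(filt$genotypes, ana$meff_window)

  scans <- list()
  models <- list()
  for (tr in traits) {
    for (l in locs) {
      y <- trait_vector(phe$traits, tr, l)
      sc <- association_scan(y, filt$genotypes, K, ana, m_eff = m_eff,
                             trait = tr, location_id = l)
      key <- paste(tr, l, sep = ".")
      scans[[key]] <- sc
      models[[key]] <- forward_select(sc, filt$genotypes, y, ana)
    }
  }
  crossloc <- list()
  for (tr in traits) {
    ms <- models[paste(tr, locs, sep = ".")]
    crossloc[[tr]] <- consolidate_across_locations(ms, filt$genotypes, ana)
  }

  res <- list(config = list(simulation = sim, analysis = ana, qc = qc),
              genotypes = panel$genotypes, truth = phe$truth, temps = temps,
              records = phe$records, traits = phe$traits,
              filtered = filt$genotypes, filter_report = filt$report,
              kinship = K, m_eff = m_eff, scans = scans, models = models,
              crossloc = crossloc)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  write_genotypes(res$genotypes, fp("genotypes.tsv"), fp("markers.tsv"))
  write_truth(res$truth, fp("truth.json"))
  write_temperature(res$temps, fp("temperature.csv"))
  write_phenology(res$records, fp("phenology.csv"))
  write_trait_table(res$traits, fp("traits.tsv"))
  write_genotypes(res$filtered, fp("genotypes_filtered.tsv"),
                  fp("markers_filtered.tsv"))
  write_tsv(res$filter_report, fp("filter_report.tsv"))
  write_tsv(data.frame(accession_id = rownames(res$kinship), res$kinship,
                       check.names = FALSE), fp("kinship.tsv"))
  for (key in names(res$scans)) {
    write_scan(res$scans[[key]], fp(paste0("scan_", key, ".tsv")))
    write_multiqtl(res$models[[key]], fp(paste0("multiqtl_", key, ".tsv")))
  }
  summ <- do.call(rbind, lapply(res$models, function(m)
    data.frame(trait = m$trait, location_id = m$location_id,
               n_qtls = nrow(m$qtls),
               explained_variance = round(100 * m$full_r2, 2))))
  write_tsv(summ, fp("multiqtl_summary.tsv"))
  for (tr in names(res$crossloc))
    write_crossloc(res$crossloc[[tr]], fp(paste0("crossloc_", tr, ".tsv")),
                   locations = names(res$temps))
  invisible(out_dir)
}

#' Command-line interface
#'
#' Thin shell over the package functions, installed as
#' `system.file("cli", "poolqtl.R", package = "poolqtl")`.  Subcommands:
#' `simulate`, `phenotype`, `qc`, `kinship`, `gwas`, `multiqtl`, `crossloc`,
#' `annotate`, `motif`, `all`.  Global flags: `--config FILE`, `--seed N`,
#' `--out-dir DIR`, `--verbose`; see the script's `--help`.
#'
#' @param args Character vector of command-line arguments.
#' @return Invisibly, the subcommand's result.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0 || args[1] %in% c("-h", "--help")) {
    cli_usage()
    return(invisible(NULL))
  }
  cmd <- args[1]
  opts <- parse_cli_opts(args[-1])
  verbose <- isTRUE(opts$verbose)
  log_msg <- function(...) if (verbose) message(...)
  out_dir <- opts[["out-dir"]] %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- read_config(opts$config, seed = opts$seed)
  if (!is.null(opts[["base-temp"]])) base_temp <- as.numeric(opts[["base-temp"]])
  else base_temp <- 1
  if (!is.null(opts[["alpha"]])) cfg$analysis$alpha <- as.numeric(opts[["alpha"]])
  if (!is.null(opts[["r-threshold"]]))
    cfg$analysis$r_threshold <- as.numeric(opts[["r-threshold"]])
  fp <- function(...) file.path(out_dir, ...)

  res <- switch(cmd,
    simulate = {
      log_msg("simulating panel and phenology")
      sim <- cfg$simulation
      panel <- simulate_panel(sim)
      locs <- paste0("LOC", seq_len(sim$n_locations))
      temps <- lapply(seq_along(locs), function(l)
        simulate_temperature(locs[l], mean_temp = 14 + 2 * l,
                             seed = substream_seed(sim$seed, 100L + l)))
      names(temps) <- locs
      phe <- simulate_phenotypes(panel$genotypes, panel$truth, sim, temps)
      write_genotypes(panel$genotypes, fp("genotypes.tsv"), fp("markers.tsv"))
      write_truth(phe$truth, fp("truth.json"))
      write_temperature(temps, fp("temperature.csv"))
      write_phenology(phe$records, fp("phenology.csv"))
      invisible(phe)
    },
    phenotype = {
      records <- read_phenology(opts$records %||% fp("phenology.csv"))
      temps <- read_temperature(opts$temperature %||% fp("temperature.csv"))
      tt <- aggregate_plots(records, temps, base_temp = base_temp)
      write_trait_table(tt, fp("traits.tsv"))
      invisible(tt)
    },
    qc = {
      g <- read_genotypes(opts$genotypes %||% fp("genotypes.tsv"),
                          opts$markers %||% fp("markers.tsv"))
      filt <- filter_snps(g, cfg$qc)
      write_genotypes(filt$genotypes, fp("genotypes_filtered.tsv"),
                      fp("markers_filtered.tsv"))
      write_tsv(filt$report, fp("filter_report.tsv"))
      invisible(filt)
    },
    kinship = {
      g <- read_genotypes(opts$genotypes %||% fp("genotypes_filtered.tsv"),
                          opts$markers %||% fp("markers_filtered.tsv"))
      K <- compute_kinship(g)
      write_tsv(data.frame(accession_id = rownames(K), K,
                           check.names = FALSE), fp("kinship.tsv"))
      invisible(K)
    },
    gwas = , multiqtl = , crossloc = {
      g <- read_genotypes(opts$genotypes %||% fp("genotypes_filtered.tsv"),
                          opts$markers %||% fp("markers_filtered.tsv"))
      tt <- read_trait_table(opts$traits %||% fp("traits.tsv"))
      K <- compute_kinship(g)
      m_eff <- if (!is.null(opts$meff)) as.numeric(opts$meff)
               else effective_marker_number(g, cfg$analysis$meff_window)
      locs <- unique(tt$location_id)
      traits <- strsplit(opts$trait %||% "FL_Begin,FL_Full,VEG,Sex_det", ",")[[1]]
      scans <- list(); models <- list()
      for (tr in traits) for (l in locs) {
        y <- trait_vector(tt, tr, l)
        sc <- association_scan(y, g, K, cfg$analysis, m_eff = m_eff,
                               exact_per_marker = isTRUE(opts[["exact-per-marker"]]),
                               trait = tr, location_id = l)
        key <- paste(tr, l, sep = ".")
        scans[[key]] <- sc
        write_scan(sc, fp(paste0("scan_", key, ".tsv")))
        if (cmd %in% c("multiqtl", "crossloc")) {
          models[[key]] <- forward_select(sc, g, y, cfg$analysis)
          write_multiqtl(models[[key]], fp(paste0("multiqtl_", key, ".tsv")))
        }
      }
      if (cmd == "crossloc") {
        for (tr in traits) {
          cl <- consolidate_across_locations(models[paste(tr, locs, sep = ".")],
                                             g, cfg$analysis)
          write_crossloc(cl, fp(paste0("crossloc_", tr, ".tsv")),
                         locations = locs)
        }
      }
      invisible(list(scans = scans, models = models))
    },
    annotate = {
      ann <- read_annotations(opts$annotations)
      model <- read_multiqtl(opts$model)
      sets <- map_qtl_scaffolds(model,
                                include_members = isTRUE(opts[["include-members"]]))
      tab <- candidate_genes_for_qtls(sets, ann)
      write_tsv(tab, fp("candidate_genes.tsv"))
      invisible(tab)
    },
    motif = {
      hits <- find_motif(opts$fasta, opts$motif,
                         max_mismatch = as.integer(opts[["max-mismatch"]] %||% 0),
                         motif_id = opts[["motif-id"]] %||% opts$motif)
      write_motif_hits(hits, fp("motif_hits.tsv"),
                       table1_style = isTRUE(opts[["table1-style"]]))
      invisible(hits)
    },
    all = {
      log_msg("running the full pipeline")
      invisible(run_pipeline(cfg, out_dir = out_dir))
    },
    stop("unknown subcommand: ", cmd)
  )
  invisible(res)
}

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  flags <- c("verbose", "exact-per-marker", "include-members", "table1-style")
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3)
    if (key %in% flags) {
      opts[[key]] <- TRUE
      i <- i + 1L
    } else {
      if (i == length(args)) stop("missing value for --", key)
      opts[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  if (!is.null(opts$seed)) opts$seed <- as.integer(opts$seed)
  opts
}

cli_usage <- function() {
  cat("usage: poolqtl.R <subcommand> [--config FILE] [--seed N] [--out-dir DIR]\n",
      "subcommands: simulate | phenotype | qc | kinship | gwas | multiqtl |\n",
      "             crossloc | annotate | motif | all\n",
      "common flags: --verbose, --alpha A, --r-threshold R, --meff M,\n",
      "  --base-temp T, --exact-per-marker, --trait T1,T2, --genotypes F,\n",
      "  --markers F, --traits F, --records F, --temperature F,\n",
      "  --annotations F, --model F, --fasta F, --motif SEQ, --max-mismatch K,\n",
      "  --motif-id ID, --include-members, --table1-style\n", sep = "")
}
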