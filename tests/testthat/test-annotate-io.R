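toy_model <- function() {
  structure(list(trait = "FL_Begin", location_id = "CRA",
                 qtls = data.frame(order = 1:2,
                                   representative = c("scaffold82158_8091",
                                                      "scaffold73915_9581"),
                                   n_members = c(2L, 1L),
                                   incremental_r2 = c(0.2, 0.1)),
                 members = list(scaffold82158_8091 = c("scaffold82158_102",
                                                       "scaffold11_5"),
                                scaffold73915_9581 = "scaffold73915_77"),
                 full_r2 = 0.3), class = "multiqtl_model")
}

test_that("QTL scaffolds are parsed, deduplicated and sorted", {
  m <- toy_model()
  sets <- map_qtl_scaffolds(m)
  expect_equal(sets$scaffold82158_8091, "scaffold82158")
  expect_equal(sets$scaffold73915_9581, "scaffold73915")
  with_members <- map_qtl_scaffolds(m, include_members = TRUE)
  expect_equal(with_members$scaffold82158_8091,
               sort(c("scaffold11", "scaffold82158")))  # dedup: rep + member
  expect_equal(with_members$scaffold73915_9581, "scaffold73915")
  bad <- m
  bad$qtls$representative[1] <- "noposition"
  bad$members <- list(noposition = character(0),
                      scaffold73915_9581 = character(0))
  expect_error(map_qtl_scaffolds(bad), "noposition")
})

test_that("scaffold mapping matches a brute-force parse-and-union oracle", {
  set.seed(3)
  ids <- sprintf("scaffold%d_%d", sample(1:20, 30, replace = TRUE),
                 sample(1e5, 30))
  m <- structure(list(trait = "VEG", location_id = "VDS",
                      qtls = data.frame(order = 1:3,
                                        representative = ids[1:3],
                                        n_members = c(10L, 10L, 7L),
                                        incremental_r2 = 0.1),
                      members = list(ids[4:13], ids[14:23], ids[24:30]),
                      full_r2 = 0.4), class = "multiqtl_model")
  names(m$members) <- ids[1:3]
  sets <- map_qtl_scaffolds(m, include_members = TRUE)
  for (k in 1:3) {
    all_ids <- c(ids[k], m$members[[k]])
    expect_equal(sets[[k]], sort(unique(sub("_[0-9]+$", "", all_ids))))
  }
})

test_that("candidate-gene join returns exactly the matching rows", {
  ann <- data.frame(scaffold_id = c("scaffold82158", "scaffold82158",
                                    "scaffold999"),
                    transcript_id = c("PK1.1", "PK2.1", "PK3.1"),
                    description = c("florigen-like", "MADS-box", "unrelated"))
  sets <- map_qtl_scaffolds(toy_model())
  out <- candidate_genes_for_qtls(sets, ann)
  expect_equal(nrow(out), 2)
  expect_setequal(out$transcript_id, c("PK1.1", "PK2.1"))
  expect_equal(unique(out$qtl), "scaffold82158_8091")
  # empty join allowed
  none <- candidate_genes_for_qtls(sets,
                                   ann[ann$scaffold_id == "scaffold999", ])
  expect_equal(nrow(none), 0)
})

test_that("candidate-gene join row count equals a double-loop oracle on random fixtures", {
  set.seed(9)
  sets <- list(q1 = paste0("scaffold", sample(10, 4)),
               q2 = paste0("scaffold", sample(10, 5)))
  ann <- data.frame(scaffold_id = paste0("scaffold", sample(10, 12, replace = TRUE)),
                    transcript_id = sprintf("PK%02d.1", 1:12),
                    description = "x")
  out <- candidate_genes_for_qtls(sets, ann)
  brute <- 0
  for (q in names(sets)) for (i in seq_len(nrow(ann)))
    if (ann$scaffold_id[i] %in% sets[[q]]) brute <- brute + 1
  expect_equal(nrow(out), brute)
})

test_that("planted motifs are found on both strands with exact coordinates", {
  set.seed(2)
  motif <- "TGACAGAAGAGAGAGAGCAT"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
  bg <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  seq1 <- paste0(bg(100), motif, bg(80), rc, bg(50))
  scaf <- Biostrings::DNAStringSet(c(scafA = seq1))
  hits <- find_motif(scaf, motif, max_mismatch = 0)
  fw <- hits[hits$strand == "+", ]
  rv <- hits[hits$strand == "-", ]
  expect_true(nrow(fw) >= 1 && any(fw$start == 101 & fw$end == 120))
  expect_true(any(rv$start == 201 & rv$end == 220))
  expect_true(all(hits$end - hits$start + 1 == nchar(motif)))
  expect_true(all(hits$mismatches == 0))
  expect_error(find_motif(scaf, "ACGTNACGT"), "A, C, G, T")
  expect_error(find_motif(scaf, "ACGTACG"), ">= 8")
})

test_that("mismatch search equals the brute-force Hamming oracle, N never matches", {
  set.seed(15)
  motif <- "ACGTTGCAGGAT"
  s <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE,
                    prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
  substr(s, 5000, 5000) <- "N"
  scaf <- Biostrings::DNAStringSet(c(chr = s))
  for (mm in 0:1) {
    hits <- find_motif(scaf, motif, max_mismatch = mm)
    oracle <- oracle_hamming_hits(s, motif, mm)
    expect_equal(nrow(hits), nrow(oracle))
    expect_equal(hits[, c("start", "end", "strand", "mismatches")], oracle,
                 ignore_attr = TRUE)
  }
})

test_that("tabular readers and writers round-trip every object", {
  sp <- small_panel(seed = 16L, n_accessions = 20L, n_scaffolds = 10L,
                    planted = list(planted_qtl("FL_Begin", 0.1)))
  td <- withr::local_tempdir()
  fp <- function(x) file.path(td, x)

  write_genotypes(sp$genotypes, fp("g.tsv"), fp("m.tsv"))
  g2 <- read_genotypes(fp("g.tsv"), fp("m.tsv"))
  expect_equal(g2$values, sp$genotypes$values, tolerance = 1e-12)
  expect_equal(g2$markers, sp$genotypes$markers)

  write_trait_table(sp$traits, fp("t.tsv"))
  t2 <- read_trait_table(fp("t.tsv"))
  expect_equal(as.data.frame(t2), as.data.frame(sp$traits), tolerance = 1e-12)

  write_temperature(sp$temps, fp("temp.csv"))
  temps2 <- read_temperature(fp("temp.csv"))
  expect_equal(temps2, sp$temps, ignore_attr = TRUE, tolerance = 1e-12)

  write_phenology(sp$records, fp("ph.csv"))
  rec2 <- read_phenology(fp("ph.csv"))
  expect_equal(rec2, sp$records, tolerance = 1e-12)

  K <- compute_kinship(sp$genotypes)
  y <- trait_vector(sp$traits, "FL_Begin", "LOC1")
  sc <- association_scan(y, sp$genotypes, K, m_eff = 20, trait = "FL_Begin",
                         location_id = "LOC1")
  write_scan(sc, fp("scan.tsv"))
  sc2 <- read_scan(fp("scan.tsv"))
  expect_equal(as.data.frame(sc2), as.data.frame(sc), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(attr(sc2, "threshold"), attr(sc, "threshold"), tolerance = 1e-8)
  expect_equal(attr(sc2, "m_eff"), attr(sc, "m_eff"))

  model <- toy_model()
  write_multiqtl(model, fp("mq.tsv"))
  m2 <- read_multiqtl(fp("mq.tsv"))
  expect_equal(m2$qtls, model$qtls)
  expect_equal(m2$members, model$members)
  expect_equal(m2$full_r2, model$full_r2)

  write_truth(sp$truth, fp("truth.json"))
  tr2 <- read_truth(fp("truth.json"))
  expect_equal(tr2$freq_true, sp$truth$freq_true, tolerance = 1e-12)
  expect_equal(tr2$subpop, sp$truth$subpop)
  expect_equal(tr2$qtls, sp$truth$qtls)
})

test_that("FASTA reading and motif-hit writing honor conventions", {
  td <- withr::local_tempdir()
  fa <- file.path(td, "scaf.fasta")
  writeLines(c(">scafA desc", "ACGTACGTACGTACGT", "GGGGCCCC",
               ">scafB", "TTTTAAAACCCCGGGG"), fa)
  seqs <- read_fasta(fa)
  expect_equal(length(seqs), 2)
  expect_equal(as.character(seqs[[1]]),
               paste0("ACGTACGTACGTACGT", "GGGGCCCC"))
  hits <- find_motif(fa, "ACGTACGT", max_mismatch = 0,
                     search_both_strands = FALSE)
  expect_equal(hits$start, c(1, 5, 9))
  out <- file.path(td, "hits.tsv")
  write_motif_hits(hits, out, table1_style = TRUE)
  re <- read.delim(out)
  expect_equal(re$end - re$start, rep(8L, 3))   # end = start + motif length
})

test_that("annotation TSV reader validates columns; config reader applies overrides", {
  td <- withr::local_tempdir()
  ann_path <- file.path(td, "ann.tsv")
  write.table(data.frame(scaffold_id = "scaffold1", transcript_id = "PK1.1",
                         description = "phyA"),
              ann_path, sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- read_annotations(ann_path)
  expect_equal(ann$transcript_id, "PK1.1")

  cfg_path <- file.path(td, "cfg.yaml")
  writeLines(c("simulation:",
               "  n_accessions: 40",
               "  n_scaffolds: 12",
               "  planted_qtls:",
               "    - trait: FL_Begin",
               "      variance_fraction: 0.1",
               "analysis:",
               "  alpha: 0.01",
               "qc:",
               "  maf_min: 0.05"), cfg_path)
  cfg <- read_config(cfg_path, seed = 7)
  expect_equal(cfg$simulation$n_accessions, 40L)
  expect_equal(cfg$simulation$seed, 7L)
  expect_equal(cfg$simulation$planted_qtls[[1]]$variance_fraction, 0.1)
  expect_equal(cfg$analysis$alpha, 0.01)
  expect_equal(cfg$qc$maf_min, 0.05)
})

test_that("the CLI pipeline is reproducible end to end from a seeded config", {
  td1 <- withr::local_tempdir()
  td2 <- withr::local_tempdir()
  cfg_path <- file.path(td1, "cfg.yaml")
  writeLines(c("simulation:",
               "  n_accessions: 30",
               "  n_scaffolds: 12",
               "  n_locations: 2"), cfg_path)
  suppressMessages(cli_main(c("all", "--config", cfg_path, "--seed", "5",
                              "--out-dir", file.path(td1, "out"))))
  suppressMessages(cli_main(c("all", "--config", cfg_path, "--seed", "5",
                              "--out-dir", file.path(td2, "out"))))
  f1 <- list.files(file.path(td1, "out"), full.names = TRUE)
  f2 <- list.files(file.path(td2, "out"), full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  expect_true(length(f1) > 10)
  for (k in seq_along(f1))
    expect_identical(readLines(f1[k]), readLines(f2[k]))
})
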