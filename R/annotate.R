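# Candidate-gene joins on QTL scaffolds and short-motif (miRNA) search in
# scaffold sequences.

#' Scaffolds underlying each QTL
#'
#' Parses the marker ids of a MultiQTL model or a cross-location QTL set into
#' scaffold ids and returns, per QTL, the deduplicated, sorted set of
#' scaffolds carrying its representative marker(s) (and its collinear member
#' markers when `include_members = TRUE`).
#'
#' @param x A `multiqtl_model` or the list returned by
#'   [consolidate_across_locations()].
#' @param include_members Also include the scaffolds of member markers
#'   (MultiQTL models only).
#' @return Named list of character vectors of scaffold ids.
#' @export
map_qtl_scaffolds <- function(x, include_members = FALSE) {
  if (inherits(x, "multiqtl_model")) {
    sets <- lapply(seq_len(nrow(x$qtls)), function(i) {
      ids <- x$qtls$representative[i]
      if (include_members) ids <- c(ids, x$members[[ids]])
      ids
    })
    names(sets) <- x$qtls$representative
  } else if (inherits(x, "crossloc_set") || (is.list(x) && length(x) > 0 &&
             inherits(x[[1]], "cross_location_qtl"))) {
    sets <- lapply(x, function(q) unlist(q$locations, use.names = FALSE))
    names(sets) <- vapply(x, function(q) q$name, character(1))
  } else stop("unsupported QTL object")
  lapply(sets, function(ids) sort(unique(parse_marker_ids(ids)$scaffold)))
}

#' Candidate genes on QTL scaffolds
#'
#' Inner join of the scaffolds underlying each QTL with a candidate-gene
#' annotation table.
#'
#' @param scaffold_sets Named list from [map_qtl_scaffolds()].
#' @param annotations Data frame with columns `scaffold_id`, `transcript_id`,
#'   `description` and optionally `start`, `end`, `tags`.
#' @return Data frame (`qtl`, `scaffold_id`, `transcript_id`, `description`,
#'   plus any optional columns); zero rows when nothing joins.
#' @export
candidate_genes_for_qtls <- function(scaffold_sets, annotations) {
  stopifnot(all(c("scaffold_id", "transcript_id", "description") %in%
                  names(annotations)))
  if ("start" %in% names(annotations) && "end" %in% names(annotations)) {
    both <- !is.na(annotations$start) & !is.na(annotations$end)
    if (any(annotations$start[both] > annotations$end[both]))
      stop("annotation intervals with start > end")
  }
  qtl <- rep(names(scaffold_sets), lengths(scaffold_sets))
  long <- data.frame(qtl = qtl,
                     scaffold_id = unlist(scaffold_sets, use.names = FALSE),
                     stringsAsFactors = FALSE)
  out <- merge(long, annotations, by = "scaffold_id", sort = FALSE)
  out <- out[, c("qtl", setdiff(names(out), "qtl"))]
  out <- out[order(out$qtl, out$scaffold_id, out$transcript_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Locate a short nucleotide motif in scaffold sequences
#'
#' Hamming-distance (ungapped) search of a motif, e.g. a mature miRNA
#' sequence, against a set of scaffolds: every window at Hamming distance at
#' most `max_mismatch` is reported, on both strands when requested, with
#' 1-based inclusive coordinates on the forward strand.  An `N` in the
#' subject never matches (it counts as a mismatch).
#'
#' @param scaffolds A `Biostrings::DNAStringSet` or the path of a FASTA file.
#' @param motif Nucleotide string over ACGT, length >= 8.
#' @param max_mismatch Maximum Hamming distance (default 0).
#' @param search_both_strands Also search the reverse complement (default
#'   `TRUE`); minus-strand hits keep forward-strand coordinates.
#' @param motif_id Label copied into the output.
#' @return Data frame (`motif_id`, `scaffold_id`, `start`, `end`, `strand`,
#'   `mismatches`) ordered by scaffold (input order), start, strand.
#' @export
find_motif <- function(scaffolds, motif, max_mismatch = 0L,
                       search_both_strands = TRUE, motif_id = motif) {
  if (is.character(scaffolds) && length(scaffolds) == 1)
    scaffolds <- read_fasta(scaffolds)
  stopifnot(methods::is(scaffolds, "DNAStringSet"))
  motif <- toupper(motif)
  if (!grepl("^[ACGT]+$", motif))
    stop("motif must contain only A, C, G, T")
  if (nchar(motif) < 8) stop("motif length must be >= 8")
  len <- nchar(motif)
  pats <- list(`+` = Biostrings::DNAString(motif))
  if (search_both_strands)
    pats$`-` <- Biostrings::reverseComplement(pats$`+`)
  hits <- list()
  for (i in seq_along(scaffolds)) {
    subj <- scaffolds[[i]]
    sid <- names(scaffolds)[i]
    for (strand in names(pats)) {
      mt <- Biostrings::matchPattern(pats[[strand]], subj,
                                     max.mismatch = max_mismatch,
                                     with.indels = FALSE, fixed = TRUE)
      # drop windows overhanging the scaffold ends
      inb <- Biostrings::start(mt) >= 1 & Biostrings::end(mt) <= length(subj)
      mt <- mt[inb]
      if (length(mt) == 0) next
      mm <- vapply(seq_along(mt), function(k) {
        sum(strsplit(as.character(mt[[k]]), "")[[1]] !=
              strsplit(as.character(pats[[strand]]), "")[[1]])
      }, integer(1))
      hits[[length(hits) + 1L]] <-
        data.frame(motif_id = motif_id, scaffold_id = sid,
                   start = Biostrings::start(mt), end = Biostrings::end(mt),
                   strand = strand, mismatches = mm,
                   stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0)
    return(data.frame(motif_id = character(), scaffold_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out <- out[order(match(out$scaffold_id, names(scaffolds)), out$start,
                   out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
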