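#' Similarity score of an alignment hit
#'
#' Coverage-times-identity score of a hit: `alignment_length * identity /
#' query_length`, capped at 1. "Identity" here is the fractional percent
#' identity of the alignment — the density of matching columns — so the
#' score combines how much of the query aligns with how well it aligns.
#'
#' @param alignment_length Aligned length (same units as `query_length`).
#' @param identity Fractional identity of the alignment in [0, 1].
#' @param query_length Full query length (> 0).
#' @return Score in [0, 1], vectorized.
#' @export
similarity <- function(alignment_length, identity, query_length) {
  if (any(query_length <= 0)) stop_bad_field("query_length", "must be > 0")
  if (any(identity < 0 | identity > 1)) stop_bad_field("identity", "must be in [0, 1]")
  if (any(alignment_length < 0)) stop_bad_field("alignment_length", "must be >= 0")
  pmin(alignment_length * identity / query_length, 1)
}

#' Build a gene-sharing network from reciprocal alignment hits
#'
#' Nodes are genes; an undirected edge joins two genes when the better of
#' the two directed similarity scores ([similarity()]) reaches `threshold`.
#' Hits failing the E-value cutoff are discarded first and self-hits are
#' dropped. Connected components of the resulting graph are the gene
#' families.
#'
#' @param hits data.frame in BLAST tabular (outfmt-6) dialect: columns
#'   `qseqid`, `sseqid`, `pident` (percent, 0-100), `length`, `evalue`
#'   (other outfmt-6 columns are ignored).
#' @param query_lengths Named numeric vector or data.frame
#'   (`gene_id`, `length`) giving every gene's full length.
#' @param threshold Similarity threshold, conventionally one of 0.4, 0.5,
#'   0.6, 0.7, 0.8.
#' @param e_cutoff E-value cutoff (default 1e-5).
#' @param edge_rule `"max"` (default, lenient) or `"min"` of the two
#'   directed scores.
#' @param genes Optional gene universe; genes without qualifying edges
#'   become singleton families.
#' @return List with `graph` (igraph), `edges` (data.frame gene_a, gene_b,
#'   score) and `families` (data.frame gene_id, family).
#' @export
build_network <- function(hits, query_lengths, threshold = 0.4,
                          e_cutoff = 1e-5, edge_rule = c("max", "min"),
                          genes = NULL) {
  edge_rule <- match.arg(edge_rule)
  check_number(threshold, "threshold", min = 0, max = 1)
  if (is.data.frame(query_lengths)) {
    query_lengths <- stats::setNames(query_lengths$length, query_lengths$gene_id)
  }
  genes <- genes %||% sort(unique(c(hits$qseqid, hits$sseqid, names(query_lengths))))

  h <- hits[hits$evalue <= e_cutoff & hits$qseqid != hits$sseqid, , drop = FALSE]
  if (nrow(h) > 0) {
    missing <- setdiff(h$qseqid, names(query_lengths))
    if (length(missing) > 0) {
      stop("no query length for gene(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    score <- similarity(h$length, h$pident / 100, query_lengths[h$qseqid])
    a <- pmin(h$qseqid, h$sseqid)
    b <- pmax(h$qseqid, h$sseqid)
    key <- paste(a, b, sep = "\r")
    agg_fun <- if (edge_rule == "max") max else min
    # max rule: best directed score per unordered pair; min rule: worst
    pair_score <- tapply(score, key, agg_fun)
    pairs <- do.call(rbind, strsplit(names(pair_score), "\r", fixed = TRUE))
    edges <- data.frame(gene_a = pairs[, 1], gene_b = pairs[, 2],
                        score = as.numeric(pair_score),
                        stringsAsFactors = FALSE)
    edges <- edges[edges$score >= threshold, , drop = FALSE]
  } else {
    edges <- data.frame(gene_a = character(), gene_b = character(),
                        score = numeric())
  }

  g <- igraph::graph_from_data_frame(edges[, c("gene_a", "gene_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = genes))
  comp <- igraph::components(g)
  families <- data.frame(gene_id = names(comp$membership),
                         family = sprintf("fam%04d", comp$membership),
                         stringsAsFactors = FALSE)
  rownames(families) <- NULL
  list(graph = g, edges = edges, families = families)
}

#' Extract rare gene families (gene-loss / transfer candidates)
#'
#' Families whose members span at most `max_genomes` distinct genomes are
#' candidates for gene loss in the remaining genomes or recent horizontal
#' acquisition, and are exported for downstream phylogenetic screening.
#'
#' @param families data.frame with `gene_id`, `family` (from
#'   [build_network()]).
#' @param gene_to_genome Named character vector or data.frame
#'   (`gene_id`, `genome_id`) mapping every gene to its genome.
#' @param max_genomes Maximum number of genomes a candidate family may span
#'   (default 2).
#' @return data.frame: `family`, `n_genomes`, `genomes`
#'   (comma-separated), `genes` (comma-separated), one row per candidate.
#' @export
rare_genes <- function(families, gene_to_genome, max_genomes = 2L) {
  max_genomes <- check_count(max_genomes, "max_genomes", min = 1L)
  if (is.data.frame(gene_to_genome)) {
    gene_to_genome <- stats::setNames(gene_to_genome$genome_id,
                                      gene_to_genome$gene_id)
  }
  unmapped <- setdiff(families$gene_id, names(gene_to_genome))
  if (length(unmapped) > 0) {
    stop("gene(s) not mapped to a genome: ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(split(families$gene_id, families$family), function(gs) {
    gn <- sort(unique(gene_to_genome[gs]))
    if (length(gn) <= max_genomes) {
      data.frame(n_genomes = length(gn),
                 genomes = paste(gn, collapse = ","),
                 genes = paste(sort(gs), collapse = ","),
                 stringsAsFactors = FALSE)
    }
  })
  keep <- !vapply(rows, is.null, logical(1))
  out <- do.call(rbind, rows[keep])
  if (is.null(out)) {
    return(data.frame(family = character(), n_genomes = integer(),
                      genomes = character(), genes = character()))
  }
  out <- cbind(data.frame(family = names(rows)[keep], stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}
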