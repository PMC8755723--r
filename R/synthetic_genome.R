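#' Generate a synthetic circular bacterial genome with known ground truth
#'
#' Builds a circular genome carrying `n_genes` protein-coding genes, of which
#' `ribosomal_count` are flagged ribosomal. Ribosomal genes are the
#' constitutively expressed set whose codon usage downstream growth-rate
#' estimation contrasts against the remaining gene pool: their synonymous
#' codon frequencies interpolate between the uniform background and the
#' fixed preferred-codon table ([preferred_codons()]) with weight
#' `bias_strength`. The replication origin sits at position 0 and the
#' terminus at `length %/% 2`, the maximally distant point on the circle.
#'
#' @param seed Integer seed; identical seeds give byte-identical genomes.
#' @param length Genome length in bp (>= 50000).
#' @param gc GC content of intergenic sequence, in (0, 1).
#' @param n_genes Number of genes (>= `ribosomal_count`).
#' @param ribosomal_count Number of ribosomal genes (>= 1).
#' @param bias_strength Codon-bias injection weight in [0, 1].
#' @param true_ptr Ground-truth origin/terminus coverage ratio (>= 1) used
#'   when simulating coverage for this genome.
#' @param lineage Character vector of up to seven ranked taxonomy labels
#'   (superkingdom down to species).
#' @param genome_id Identifier; defaults to a seed-derived name.
#' @param mean_gene_codons Average gene length in codons (excluding the
#'   start and stop codon).
#' @return An object of class `synthetic_genome`: a list with the sequence,
#'   gene table (0-based half-open coordinates), ori/ter positions and the
#'   ground-truth `true_ptr` and `true_bias`.
#' @export
generate_genome <- function(seed, length = 150000L, gc = 0.5, n_genes = 30L,
                            ribosomal_count = 6L, bias_strength = 0,
                            true_ptr = 1, lineage = character(),
                            genome_id = NULL, mean_gene_codons = 250L) {
  check_count(seed, "seed")
  check_number(length, "length", min = 50000)
  check_number(gc, "gc", min = 0.01, max = 0.99)
  n_genes <- check_count(n_genes, "n_genes", min = 1L)
  ribosomal_count <- check_count(ribosomal_count, "ribosomal_count", min = 1L)
  if (ribosomal_count > n_genes) {
    stop_bad_field("ribosomal_count", "must be <= n_genes")
  }
  check_number(bias_strength, "bias_strength", min = 0, max = 1)
  check_number(true_ptr, "true_ptr", min = 1)
  length <- as.integer(length)
  genome_id <- genome_id %||% sprintf("synth_g%d", seed)

  withr::with_seed(seed, {
    bg_probs <- codon_sampling_probs(0)
    ribo_probs <- codon_sampling_probs(bias_strength)
    stops <- stop_codons()

    is_ribo <- seq_len(n_genes) %in% sample.int(n_genes, ribosomal_count)
    n_codons <- pmax(30L, stats::rpois(n_genes, mean_gene_codons))
    cds <- character(n_genes)
    for (i in seq_len(n_genes)) {
      p <- if (is_ribo[i]) ribo_probs else bg_probs
      body <- sample(names(p), n_codons[i], replace = TRUE, prob = p)
      cds[i] <- paste0("ATG", paste(body, collapse = ""), sample(stops, 1L))
    }
    gene_bp <- nchar(cds)
    if (sum(gene_bp) > 0.9 * length) {
      stop_bad_field("n_genes", "gene content exceeds 90% of genome length")
    }

    # distribute the intergenic budget over n_genes + 1 spacers
    spare <- length - sum(gene_bp)
    spacer <- as.vector(stats::rmultinom(1L, spare, rep(1, n_genes + 1L)))
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)

    acgt <- c("A", "C", "G", "T")
    p_nt <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    pieces <- character(2L * n_genes + 1L)
    starts <- integer(n_genes)
    pos <- 0L
    for (i in seq_len(n_genes)) {
      pieces[2L * i - 1L] <- paste(sample(acgt, spacer[i], replace = TRUE,
                                          prob = p_nt), collapse = "")
      pos <- pos + spacer[i]
      starts[i] <- pos
      placed <- if (strand[i] == "-") {
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds[i])))
      } else cds[i]
      pieces[2L * i] <- placed
      pos <- pos + gene_bp[i]
    }
    pieces[2L * n_genes + 1L] <- paste(sample(acgt, spacer[n_genes + 1L],
                                              replace = TRUE, prob = p_nt),
                                       collapse = "")
    sequence <- paste(pieces, collapse = "")

    genes <- data.frame(
      gene_id = sprintf("%s_gene%03d", genome_id, seq_len(n_genes)),
      start = starts,
      end = starts + gene_bp,
      strand = strand,
      is_ribosomal = is_ribo,
      protein_lineage = paste(lineage, collapse = ";"),
      enzyme_label = NA_character_,
      stringsAsFactors = FALSE
    )

    structure(
      list(genome_id = genome_id, sequence = sequence, length = length,
           ori_position = 0L, ter_position = length %/% 2L, genes = genes,
           true_ptr = true_ptr, true_bias = bias_strength, lineage = lineage),
      class = "synthetic_genome"
    )
  })
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("<synthetic_genome> %s: %d bp, %d genes (%d ribosomal), true PTR %.3f, bias %.2f\n",
              x$genome_id, x$length, nrow(x$genes), sum(x$genes$is_ribosomal),
              x$true_ptr, x$true_bias))
  invisible(x)
}

#' Extract coding sequences of a synthetic genome
#'
#' Returns each gene's coding sequence in reading frame (minus-strand genes
#' are reverse-complemented).
#'
#' @param genome A `synthetic_genome`.
#' @param ribosomal_only If `TRUE`, only ribosomal genes; if `FALSE`, only
#'   non-ribosomal genes; if `NA` (default), all genes.
#' @return Named character vector of coding sequences.
#' @export
gene_sequences <- function(genome, ribosomal_only = NA) {
  stopifnot(inherits(genome, "synthetic_genome"))
  g <- genome$genes
  if (!is.na(ribosomal_only)) g <- g[g$is_ribosomal == ribosomal_only, , drop = FALSE]
  out <- vapply(seq_len(nrow(g)), function(i) {
    s <- substr(genome$sequence, g$start[i] + 1L, g$end[i])
    if (g$strand[i] == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    s
  }, character(1))
  names(out) <- g$gene_id
  out
}

#' Simulate a per-position coverage profile under the replication-fork model
#'
#' A population in which a fraction of cells carries an active pair of
#' replication forks over-represents sequence near the origin. The expected
#' depth at circular distance `d` from the origin (measured both ways,
#' `d` in `[0, L/2]`) is proportional to `true_ptr^(1 - 2d/L)`, so the
#' origin-to-terminus depth ratio equals `true_ptr` exactly. The profile is
#' rescaled so its genome-wide mean equals `mean_depth` exactly; with
#' `noise = "poisson"` each position is an independent Poisson draw around
#' that expectation (reads as counts; no GC bias is modelled).
#'
#' @param genome A `synthetic_genome`, or an integer genome length.
#' @param mean_depth Target genome-wide mean depth (> 0).
#' @param true_ptr Origin/terminus ratio (>= 1); defaults to the genome's
#'   ground truth when a `synthetic_genome` is supplied.
#' @param seed Integer seed (required when `noise = "poisson"`).
#' @param noise `"poisson"` or `"none"` (returns the expectation exactly).
#' @param genome_id Identifier used when `genome` is a bare length.
#' @return A `coverage_profile`: list with `genome_id`, numeric `depth` of
#'   length L (position 1 of the vector is genome position 0) and `length`.
#' @export
simulate_coverage <- function(genome, mean_depth = 50, true_ptr = NULL,
                              seed = NULL, noise = c("poisson", "none"),
                              genome_id = "genome") {
  noise <- match.arg(noise)
  if (inherits(genome, "synthetic_genome")) {
    L <- genome$length
    true_ptr <- true_ptr %||% genome$true_ptr
    genome_id <- genome$genome_id
  } else {
    L <- as.integer(check_number(genome, "genome", min = 1000))
    true_ptr <- true_ptr %||% 1
  }
  check_number(mean_depth, "mean_depth", min = .Machine$double.eps)
  check_number(true_ptr, "true_ptr", min = 1)

  d <- circular_ori_distance(seq_len(L) - 1L, L)
  expected <- true_ptr^(1 - 2 * d / L)
  expected <- expected * (mean_depth / mean(expected))

  depth <- if (noise == "none") {
    expected
  } else {
    if (is.null(seed)) stop_bad_field("seed", "required for poisson noise")
    withr::with_seed(seed, stats::rpois(L, expected))
  }
  structure(list(genome_id = genome_id, depth = as.numeric(depth), length = L),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("<coverage_profile> %s: %d bp, mean depth %.2fx\n",
              x$genome_id, x$length, mean(x$depth)))
  invisible(x)
}
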