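#' Pooled synonymous codon usage of a gene set
#'
#' Counts in-frame codons pooled over all supplied coding sequences and
#' normalizes within each synonymous family (the 59 informative codons;
#' Met, Trp and stop codons carry no synonymous choice and are excluded
#' from the profile). Sequences are trimmed to a multiple of three before
#' counting. Internal stop codons are counted and flagged but do not enter
#' the profile.
#'
#' @param genes Character vector or `Biostrings::DNAStringSet` of coding
#'   sequences (>= 1).
#' @return A `codon_usage_profile`: per-family frequency vectors, raw codon
#'   counts, total codon count, flags for families with zero observations
#'   (which carry a uniform prior) and the internal-stop count.
#' @export
codon_usage <- function(genes) {
  if (length(genes) < 1L) stop_bad_field("genes", "at least one sequence required")
  dna <- if (inherits(genes, "DNAStringSet")) genes else {
    Biostrings::DNAStringSet(toupper(as.character(genes)))
  }
  # frame trim to whole codons
  w <- Biostrings::width(dna)
  dna <- Biostrings::subseq(dna, 1L, w - (w %% 3L))

  counts_m <- Biostrings::trinucleotideFrequency(dna, step = 3)
  counts <- colSums(counts_m)

  # internal stops: stops anywhere except a sequence's final codon
  stop_total <- sum(counts[stop_codons()])
  last_codon <- as.character(Biostrings::subseq(
    dna, Biostrings::width(dna) - 2L, Biostrings::width(dna)))
  internal_stops <- stop_total - sum(last_codon %in% stop_codons())

  fam <- codon_families()
  freq <- lapply(fam, function(cods) {
    x <- counts[cods]
    tot <- sum(x)
    if (tot == 0) stats::setNames(rep(1 / length(cods), length(cods)), cods)
    else x / tot
  })
  observed <- vapply(fam, function(cods) sum(counts[cods]) > 0, logical(1))

  structure(
    list(freq = freq, counts = counts[unlist(fam, use.names = FALSE)],
         codon_count = sum(counts), family_observed = observed,
         uniform_prior = !observed, internal_stops = as.integer(internal_stops)),
    class = "codon_usage_profile"
  )
}

#' @export
print.codon_usage_profile <- function(x, ...) {
  cat(sprintf("<codon_usage_profile> %d codons, %d/%d families observed%s\n",
              x$codon_count, sum(x$family_observed), length(x$family_observed),
              if (x$internal_stops > 0)
                sprintf(" (%d internal stops)", x$internal_stops) else ""))
  invisible(x)
}

#' Codon-usage bias between highly expressed genes and the gene pool
#'
#' The bias statistic is the mean, over amino-acid families with at least
#' two synonymous codons observed in both gene sets, of half the L1
#' distance between the two family frequency vectors. It ranges from 0
#' (identical usage) to 1 (disjoint synonym choices in every family) and
#' grows with translational optimization of the highly expressed set.
#'
#' @param highly_expressed `codon_usage_profile` of the constitutively
#'   expressed genes (ribosomal proteins by convention).
#' @param background `codon_usage_profile` of the remaining gene pool.
#' @return Bias scalar in [0, 1].
#' @export
codon_bias <- function(highly_expressed, background) {
  stopifnot(inherits(highly_expressed, "codon_usage_profile"),
            inherits(background, "codon_usage_profile"))
  shared <- highly_expressed$family_observed & background$family_observed
  if (!any(shared)) {
    stop("no amino-acid family observed in both gene sets", call. = FALSE)
  }
  fams <- names(shared)[shared]
  d <- vapply(fams, function(aa) {
    sum(abs(highly_expressed$freq[[aa]] - background$freq[[aa]])) / 2
  }, numeric(1))
  mean(d)
}

#' Predict the minimal generation time from codon-usage bias
#'
#' Maps the bias statistic to a minimal (fastest attainable) generation
#' time through a log-linear calibration, `ln(hours) = a - b * bias`, with
#' defaults `a = ln(40)`, `b = ln(100)` (~4.6): an unoptimized genome
#' (bias 0) is predicted at 40 h and a maximally optimized one (bias 1) at
#' 0.4 h, a hundred-fold dynamic range. The
#' constants are this package's calibration, exposed for refitting; they
#' are not any external tool's fitted values, so comparisons should rest on
#' ordering, not absolute hours. The reported SD is the calibration's
#' residual scale on the log scale (default 0.25), delta-method transformed
#' to hours. Growth temperature is recorded as metadata and has no
#' numerical effect by default.
#'
#' @param bias Bias statistic in [0, 1] (see [codon_bias()]).
#' @param calibration List with `a`, `b` (and optionally `sd_ln`).
#' @param temperature_C Optional growth temperature, recorded only.
#' @param genome_id Identifier.
#' @return A `growth_prediction`: `bias`, `min_generation_time` (hours),
#'   `sd` (hours), `temperature_C`.
#' @export
predict_min_generation_time <- function(bias,
                                        calibration = list(a = log(40), b = log(100),
                                                           sd_ln = 0.25),
                                        temperature_C = NULL,
                                        genome_id = "genome") {
  check_number(bias, "bias", min = 0, max = 1)
  check_number(calibration$a, "calibration$a")
  check_number(calibration$b, "calibration$b", min = 0)
  sd_ln <- calibration$sd_ln %||% 0.25
  hours <- exp(calibration$a - calibration$b * bias)
  structure(
    list(genome_id = genome_id, bias = bias, min_generation_time = hours,
         sd = hours * sd_ln, temperature_C = temperature_C),
    class = "growth_prediction"
  )
}

#' @export
print.growth_prediction <- function(x, ...) {
  cat(sprintf("<growth_prediction> %s: bias %.3f -> minimal generation time %.2f h (sd %.2f h)\n",
              x$genome_id, x$bias, x$min_generation_time, x$sd))
  invisible(x)
}

#' End-to-end growth prediction for a synthetic genome
#'
#' Splits the genome's genes into the ribosomal and background sets,
#' computes both codon-usage profiles, the bias statistic, and the
#' predicted minimal generation time.
#'
#' @param genome A `synthetic_genome`.
#' @param ... Passed to [predict_min_generation_time()].
#' @return A `growth_prediction`.
#' @export
genome_growth_prediction <- function(genome, ...) {
  ribo <- codon_usage(gene_sequences(genome, ribosomal_only = TRUE))
  bg <- codon_usage(gene_sequences(genome, ribosomal_only = FALSE))
  predict_min_generation_time(codon_bias(ribo, bg),
                              genome_id = genome$genome_id, ...)
}

#' Compare minimal generation times of two clades
#'
#' Two-sided Mann-Whitney U comparison of predicted generation times
#' between two groups of genomes (e.g. a biofilm-forming versus a
#' planktonic clade of the same phylum).
#'
#' @param group_a,group_b Numeric vectors of generation times (n >= 3 each).
#' @return List with `u` (the U statistic for `group_a` vs `group_b`) and
#'   two-sided `p`.
#' @export
compare_clades <- function(group_a, group_b) {
  if (length(group_a) < 3L || length(group_b) < 3L) {
    stop_bad_field("group sizes", "need n >= 3 in both groups")
  }
  res <- group_tests(group_a, group_b, kind = "mann_whitney_u")
  list(u = unname(res$statistic), p = res$p)
}
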