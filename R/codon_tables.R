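#' Synonymous codon families of the standard genetic code
#'
#' The 59 informative codons are the 61 sense codons minus the two
#' single-codon families (ATG/Met, TGG/Trp); stop codons are excluded.
#' Codon-usage bias is only measurable within families offering a choice
#' of synonyms, which is why Met, Trp and stops carry no signal.
#'
#' @return Named list mapping each amino acid (one-letter code) with >= 2
#'   synonymous codons to the character vector of its codons.
#' @export
codon_families <- function() {
  gc <- Biostrings::GENETIC_CODE
  sense <- gc[gc != "*"]
  fam <- split(names(sense), sense)
  fam[vapply(fam, length, 1L) >= 2L]
}

#' Preferred-codon table used for bias injection
#'
#' A fixed "translationally optimized" usage table: one preferred codon per
#' amino-acid family, chosen deterministically as the alphabetically first
#' codon of each family. The synthetic-genome generator interpolates
#' ribosomal-gene codon usage between the uniform background and this table;
#' it is a modelling device, not an organism's measured optimum.
#'
#' @return Named character vector: amino acid -> preferred codon.
#' @export
preferred_codons <- function() {
  vapply(codon_families(), function(cods) sort(cods)[1L], character(1))
}

# All 61 sense codons (used when sampling coding sequence).
sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc[gc != "*"])
}

stop_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc[gc == "*"])
}

# Per-codon sampling probabilities for one gene: uniform within each family,
# shifted toward the preferred codon with weight `bias` for biased genes.
# Families are equally likely per codon slot (weights prop. to family size
# under the uniform background), which keeps the background exchangeable.
codon_sampling_probs <- function(bias = 0) {
  fam <- codon_families()
  pref <- preferred_codons()
  probs <- numeric(0)
  for (aa in names(fam)) {
    cods <- fam[[aa]]
    k <- length(cods)
    p <- rep((1 - bias) / k, k)
    names(p) <- cods
    p[pref[[aa]]] <- p[pref[[aa]]] + bias
    # each family contributes in proportion to its size so that the
    # unbiased background is uniform over the 59 informative codons
    probs <- c(probs, p * k)
  }
  # Met and Trp appear at their background (single-codon) rate
  probs["ATG"] <- 1
  probs["TGG"] <- 1
  probs / sum(probs)
}
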