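#' Library-size-normalized scaffold abundance
#'
#' Scaffold coverage adjusted for unequal sequencing depth by dividing by
#' the library size: coverage per Gbp sequenced. The Gbp unit only sets
#' readable magnitudes; any positive constant cancels in the Z-scaled view.
#'
#' @param scaffold_coverage Mean read depth of the scaffold (>= 0),
#'   vectorized.
#' @param total_bp Total bp sequenced in the library (> 0).
#' @return Normalized abundance (coverage per Gbp).
#' @export
normalize_abundance <- function(scaffold_coverage, total_bp) {
  if (any(scaffold_coverage < 0)) stop_bad_field("scaffold_coverage", "must be >= 0")
  check_number(total_bp, "total_bp", min = .Machine$double.eps)
  scaffold_coverage / (total_bp / 1e9)
}

#' Select the representative key enzyme of a pathway
#'
#' When a pathway is diagnosed by several key enzymes in one assembly, the
#' enzyme with the highest frequency of hits represents it. Frequency is
#' the count of distinct scaffold hits by default (`count = "scaffolds"`);
#' `count = "coverage"` instead ranks enzymes by summed scaffold coverage.
#' Ties break lexicographically by enzyme name, so selection is
#' deterministic.
#'
#' @param hits data.frame of hits for ONE pathway in one assembly with
#'   columns `enzyme`, `scaffold_id` (and `scaffold_coverage` for the
#'   coverage mode).
#' @param count `"scaffolds"` or `"coverage"`.
#' @return The chosen enzyme name.
#' @export
select_key_enzyme <- function(hits, count = c("scaffolds", "coverage")) {
  count <- match.arg(count)
  if (nrow(hits) < 1L) stop_bad_field("hits", "at least one hit required")
  score <- if (count == "scaffolds") {
    tapply(hits$scaffold_id, hits$enzyme, function(s) length(unique(s)))
  } else {
    tapply(hits$scaffold_coverage, hits$enzyme, sum)
  }
  cand <- names(score)[score == max(score)]
  sort(cand)[1L]
}

#' Pathway-by-sample abundance matrix from key-enzyme hits
#'
#' For every sample and pathway the representative enzyme is selected
#' ([select_key_enzyme()]) and the normalized abundances of its hit-bearing
#' scaffolds are summed, yielding the pathway's total relative abundance in
#' that sample; pathways without hits in a sample score 0. With
#' `mode = "all_enzymes"` the sum runs over every key enzyme of the pathway
#' instead of the selected one only.
#'
#' @param hits data.frame with `scaffold_id`, `enzyme`, `pathway`,
#'   `sample_id`, `scaffold_coverage`.
#' @param libraries data.frame with `sample_id`, `total_bp`.
#' @param pathways Optional pathway universe (rows of the matrix); defaults
#'   to pathways present in `hits`. Hits carrying a pathway outside the
#'   universe raise an error.
#' @param mode `"selected_enzyme"` (default) or `"all_enzymes"`.
#' @param count Hit-frequency definition for enzyme selection.
#' @return A `pathway_abundance_matrix`: list with `raw` (pathways x
#'   samples), `z` (row-Z-scaled view), `chosen` (enzyme chosen per pathway
#'   and sample) and `zero_variance` flags.
#' @export
pathway_matrix <- function(hits, libraries, pathways = NULL,
                           mode = c("selected_enzyme", "all_enzymes"),
                           count = "scaffolds") {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(hits), is.data.frame(libraries))
  need <- c("scaffold_id", "enzyme", "pathway", "sample_id", "scaffold_coverage")
  if (!all(need %in% names(hits))) {
    stop_bad_field("hits", paste("needs columns:", paste(need, collapse = ", ")))
  }
  pathways <- pathways %||% sort(unique(hits$pathway))
  bad <- setdiff(unique(hits$pathway), pathways)
  if (length(bad) > 0) {
    stop("unknown pathway label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  samples <- libraries$sample_id
  m <- matrix(0, nrow = length(pathways), ncol = length(samples),
              dimnames = list(pathways, samples))
  chosen <- list()
  for (s in samples) {
    total_bp <- libraries$total_bp[libraries$sample_id == s][1]
    hs <- hits[hits$sample_id == s, , drop = FALSE]
    for (p in unique(hs$pathway)) {
      hp <- hs[hs$pathway == p, , drop = FALSE]
      enz <- select_key_enzyme(hp, count = count)
      use <- if (mode == "selected_enzyme") hp[hp$enzyme == enz, , drop = FALSE] else hp
      m[p, s] <- sum(normalize_abundance(use$scaffold_coverage, total_bp))
      chosen[[length(chosen) + 1L]] <- data.frame(
        sample_id = s, pathway = p, chosen_enzyme = enz,
        stringsAsFactors = FALSE)
    }
  }
  z <- zscore_rows(m)
  structure(
    list(raw = m, z = z,
         chosen = if (length(chosen)) do.call(rbind, chosen) else
           data.frame(sample_id = character(), pathway = character(),
                      chosen_enzyme = character()),
         zero_variance = attr(z, "zero_variance")),
    class = "pathway_abundance_matrix"
  )
}

#' @export
print.pathway_abundance_matrix <- function(x, ...) {
  cat(sprintf("<pathway_abundance_matrix> %d pathways x %d samples\n",
              nrow(x$raw), ncol(x$raw)))
  print(round(x$raw, 3))
  invisible(x)
}

#' Z-scale the rows of an abundance matrix
#'
#' Centers and scales each row (pathway) to mean 0 and sample SD 1
#' (n - 1 denominator), the per-metabolism scaling used for heatmap views.
#' Zero-variance rows become all-zero and are flagged.
#'
#' @param m Numeric matrix with >= 2 columns.
#' @return Matrix of the same shape with attribute `zero_variance`.
#' @export
zscore_rows <- function(m) {
  if (!is.matrix(m)) stop_bad_field("m", "must be a matrix")
  if (ncol(m) < 2L) stop_bad_field("m", "needs at least 2 columns to Z-scale")
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  flat <- sd < .Machine$double.eps
  z <- (m - mu) / ifelse(flat, 1, sd)
  z[flat, ] <- 0
  attr(z, "zero_variance") <- stats::setNames(flat, rownames(m))
  z
}

#' Shannon-Wiener diversity from marker-scaffold abundances
#'
#' Community diversity of one assembly from the relative abundances of its
#' ribosomal-protein-S3-carrying scaffolds: `H = -sum(p * ln p)` over the
#' normalized abundance vector (zero entries drop out).
#'
#' @param abundances Non-negative abundances with positive sum.
#' @return Shannon-Wiener index (nats).
#' @export
rps3_diversity <- function(abundances) {
  if (any(abundances < 0)) stop_bad_field("abundances", "must be >= 0")
  if (sum(abundances) <= 0) stop_bad_field("abundances", "must have positive sum")
  p <- abundances / sum(abundances)
  p <- p[p > 0]
  -sum(p * log(p))
}
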