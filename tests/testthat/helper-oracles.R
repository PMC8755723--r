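# Independent brute-force oracles, written deliberately low-tech (explicit
# loops, no shared code with the package internals) so that equivalence
# tests compare two independent routes to the same answer.

oracle_vote <- function(df, count_unannotated = TRUE) {
  ranks <- c("superkingdom", "phylum", "class", "order", "family",
             "genus", "species")
  out <- rep(NA_character_, length(ranks))
  names(out) <- ranks
  n <- nrow(df)
  if (n == 0) return(out)
  for (ri in seq_along(ranks)) {
    r <- ranks[ri]
    labs <- if (r %in% names(df)) as.character(df[[r]]) else rep(NA, n)
    labs[!is.na(labs) & labs == ""] <- NA
    uniq <- unique(labs[!is.na(labs)])
    denom <- if (count_unannotated) n else sum(!is.na(labs))
    best <- NA_character_
    best_count <- 0
    for (u in sort(uniq)) {
      cnt <- 0
      for (l in labs) if (!is.na(l) && l == u) cnt <- cnt + 1
      if (cnt > best_count) { best <- u; best_count <- cnt }
    }
    if (!is.na(best) && best_count * 2 > denom) out[ri] <- best else break
  }
  out
}

oracle_pathway_matrix <- function(hits, libs, mode = "selected_enzyme") {
  pathways <- sort(unique(hits$pathway))
  samples <- libs$sample_id
  m <- matrix(0, length(pathways), length(samples),
              dimnames = list(pathways, samples))
  for (s in samples) {
    tb <- libs$total_bp[libs$sample_id == s][1]
    for (p in pathways) {
      rows <- which(hits$sample_id == s & hits$pathway == p)
      if (length(rows) == 0) next
      enz <- unique(hits$enzyme[rows])
      nhit <- sapply(enz, function(e)
        length(unique(hits$scaffold_id[rows][hits$enzyme[rows] == e])))
      pick <- sort(enz[nhit == max(nhit)])[1]
      use <- if (mode == "selected_enzyme") {
        rows[hits$enzyme[rows] == pick]
      } else rows
      total <- 0
      for (i in use) total <- total + hits$scaffold_coverage[i] / (tb / 1e9)
      m[p, s] <- total
    }
  }
  m
}

oracle_rare_genes <- function(families, gene_to_genome, max_genomes = 2) {
  keep <- character(0)
  for (f in unique(families$family)) {
    gs <- families$gene_id[families$family == f]
    genomes <- character(0)
    for (g in gs) genomes <- union(genomes, gene_to_genome[[g]])
    if (length(genomes) <= max_genomes) keep <- c(keep, f)
  }
  sort(keep)
}

oracle_quality_gate <- function(df) {
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    keep[i] <- df$completeness[i] >= 70 && df$contamination[i] <= 10
  }
  df[keep, , drop = FALSE]
}

# Random fixture builders --------------------------------------------------

random_lineage_table <- function(n_scaffolds = 5, max_proteins = 8) {
  ranks <- c("superkingdom", "phylum", "class", "order", "family",
             "genus", "species")
  rows <- list()
  pid <- 0
  for (s in seq_len(n_scaffolds)) {
    np <- sample.int(max_proteins, 1)
    for (p in seq_len(np)) {
      pid <- pid + 1
      row <- list(protein_id = sprintf("p%04d", pid),
                  scaffold_id = sprintf("sc%02d", s))
      # labels drawn from small pools so ties and majorities both occur;
      # annotation truncates at a random depth (no gaps below)
      depth <- sample(0:7, 1)
      for (ri in seq_along(ranks)) {
        row[[ranks[ri]]] <- if (ri <= depth) {
          paste0(substr(ranks[ri], 1, 2), sample.int(3, 1))
        } else NA_character_
      }
      rows[[length(rows) + 1]] <- as.data.frame(row, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

random_hits_table <- function(n_samples = 3, n_pathways = 4) {
  pathways <- paste0("pw", seq_len(n_pathways))
  enz <- paste0("enz", seq_len(2 * n_pathways))
  map <- data.frame(enzyme = enz,
                    pathway = rep(pathways, each = 2),
                    stringsAsFactors = FALSE)
  n <- sample(10:40, 1)
  hits <- data.frame(
    scaffold_id = sprintf("sc%02d", sample.int(15, n, replace = TRUE)),
    enzyme = sample(enz, n, replace = TRUE),
    sample_id = sprintf("s%d", sample.int(n_samples, n, replace = TRUE)),
    scaffold_coverage = round(runif(n, 1, 50), 2),
    stringsAsFactors = FALSE
  )
  hits$pathway <- map$pathway[match(hits$enzyme, map$enzyme)]
  libs <- data.frame(sample_id = sprintf("s%d", seq_len(n_samples)),
                     total_bp = runif(n_samples, 1e9, 9e9))
  list(hits = hits, libs = libs)
}
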