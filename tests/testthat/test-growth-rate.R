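# Codon-usage profiling, the bias statistic, and the generation-time map.

test_that("codon counting on hand-built genes is exact", {
  u <- codon_usage("ATGAAAAAATAA")
  expect_equal(u$freq$K, c(AAA = 1, AAG = 0))
  expect_equal(u$internal_stops, 0L)

  u2 <- codon_usage(c("ATGAAAAAATAA", "ATGAAGAAGTAA"))
  expect_equal(u2$freq$K, c(AAA = 0.5, AAG = 0.5))

  # internal stop flagged but counted
  u3 <- codon_usage("ATGTAAAAATAA")
  expect_equal(u3$internal_stops, 1L)
})

test_that("pooled profile equals the count-weighted mean of per-gene counts", {
  withr::with_seed(77, {
    g <- generate_genome(seed = 13, length = 50000, n_genes = 12,
                         ribosomal_count = 2)
    genes <- gene_sequences(g)
    pooled <- codon_usage(genes)
    # brute-force oracle: count codons per gene via substring
    counts <- integer(0)
    for (s in genes) {
      for (i in seq(1, nchar(s) - 2, by = 3)) {
        cod <- substr(s, i, i + 2)
        counts[cod] <- (if (cod %in% names(counts)) counts[cod] else 0L) + 1L
      }
    }
    for (aa in names(codon_families())) {
      cods <- codon_families()[[aa]]
      raw <- sapply(cods, function(cd) if (cd %in% names(counts)) counts[[cd]] else 0L)
      if (sum(raw) > 0) {
        expect_equal(unname(pooled$freq[[aa]]), unname(raw / sum(raw)))
      }
    }
  })
})

test_that("pooling invariance: duplicating the gene set changes nothing", {
  g <- generate_genome(seed = 19, length = 50000, n_genes = 8,
                       ribosomal_count = 2)
  genes <- gene_sequences(g)
  expect_equal(codon_usage(genes)$freq, codon_usage(c(genes, genes))$freq)
  expect_equal(codon_usage(genes)$freq, codon_usage(rev(genes))$freq)
})

test_that("bias statistic attains its bounds and is symmetric", {
  u <- codon_usage("ATGAAAAAATAA")
  expect_equal(codon_bias(u, u), 0)

  # single informative family (Lys), disjoint synonym choice -> bias 1
  a <- codon_usage("ATGAAAAAAAAATAA")
  b <- codon_usage("ATGAAGAAGAAGTAA")
  expect_equal(codon_bias(a, b), 1)
  expect_equal(codon_bias(a, b), codon_bias(b, a))
})

test_that("measured bias matches the generator's closed-form expectation", {
  # interpolating toward one preferred codon per family moves each k-codon
  # family by b*(1 - 1/k) in half-L1, so the expected statistic is the
  # family-size-weighted mean of that expression
  fam_sizes <- vapply(codon_families(), length, 1L)
  expected_at <- function(b) mean(b * (1 - 1 / fam_sizes))
  for (b in c(0.5, 1)) {
    g <- generate_genome(seed = 31, length = 120000, n_genes = 60,
                         ribosomal_count = 20, bias_strength = b)
    measured <- codon_bias(codon_usage(gene_sequences(g, TRUE)),
                           codon_usage(gene_sequences(g, FALSE)))
    expect_lt(abs(measured - expected_at(b)), 0.05)
  }
})

test_that("generation-time calibration maps bias 0 to 40 h and bias 1 to 0.4 h", {
  expect_equal(predict_min_generation_time(0)$min_generation_time, 40)
  expect_equal(predict_min_generation_time(1)$min_generation_time, 0.4,
               tolerance = 1e-10)
  expect_error(predict_min_generation_time(1.5), "bias")
  grid <- seq(0, 1, by = 0.1)
  times <- vapply(grid, function(b)
    predict_min_generation_time(b)$min_generation_time, numeric(1))
  expect_true(all(diff(times) < 0))
  p <- predict_min_generation_time(0.5, temperature_C = 18)
  expect_equal(p$temperature_C, 18)
  expect_equal(p$sd, p$min_generation_time * 0.25)
})

test_that("injected bias strength orders predicted generation times perfectly", {
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  times <- vapply(grid, function(b) {
    g <- generate_genome(seed = 11, length = 60000, n_genes = 40,
                         ribosomal_count = 8, bias_strength = b)
    genome_growth_prediction(g)$min_generation_time
  }, numeric(1))
  expect_equal(stats::cor(grid, times, method = "spearman"), -1)
})

test_that("clade comparison: U statistic and degenerate inputs", {
  expect_equal(compare_clades(c(1, 2, 3), c(10, 11, 12))$u, 0)
  # brute-force U: count pairs where a > b (plus half-ties)
  a <- c(3, 7, 9, 12); b <- c(2, 5, 8)
  u_brute <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  expect_equal(compare_clades(a, b)$u, u_brute)
  expect_equal(compare_clades(c(1, 2, 3), c(1, 2, 3))$p, 1)
})

test_that("separating the clades further can only lower the U-test p-value", {
  withr::with_seed(42, {
    a <- rnorm(10)
    b <- a + 2          # already shifted past the crossing point
    ps <- vapply(c(0, 1, 2, 4), function(shift)
      compare_clades(a, b + shift)$p, numeric(1))
    expect_true(all(diff(ps) <= 1e-9))
  })
})
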