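# Generators with known ground truth: determinism, injected signal,
# conservation properties.

test_that("generators are deterministic for a fixed seed", {
  g1 <- generate_genome(seed = 42, length = 50000, n_genes = 10,
                        ribosomal_count = 2, bias_strength = 0.3, true_ptr = 1.5)
  g2 <- generate_genome(seed = 42, length = 50000, n_genes = 10,
                        ribosomal_count = 2, bias_strength = 0.3, true_ptr = 1.5)
  expect_identical(g1$sequence, g2$sequence)
  expect_identical(g1$genes, g2$genes)

  c1 <- simulate_coverage(60000, 30, true_ptr = 1.4, seed = 7)
  c2 <- simulate_coverage(60000, 30, true_ptr = 1.4, seed = 7)
  expect_identical(c1$depth, c2$depth)

  p1 <- generate_site_panel(seed = 5, n_sites = 4, genomes_per_site = 2,
                            coverage = "skip")
  p2 <- generate_site_panel(seed = 5, n_sites = 4, genomes_per_site = 2,
                            coverage = "skip")
  expect_identical(p1$metadata, p2$metadata)
  expect_identical(p1$truth, p2$truth)

  b1 <- generate_biogeo_panel(seed = 3, n_genomes = 3, genome_length = 12000)
  b2 <- generate_biogeo_panel(seed = 3, n_genomes = 3, genome_length = 12000)
  expect_identical(b1$genomes, b2$genomes)
})

test_that("genome generator validates parameters naming the field", {
  expect_error(generate_genome(seed = 1, length = 1000), "length")
  expect_error(generate_genome(seed = 1, bias_strength = 1.2), "bias_strength")
  expect_error(generate_genome(seed = 1, true_ptr = 0.5), "true_ptr")
  expect_error(generate_genome(seed = 1, n_genes = 2, ribosomal_count = 5),
               "ribosomal_count")
})

test_that("genome invariants hold: ter opposite ori, genes inside sequence", {
  g <- generate_genome(seed = 9, length = 50000, n_genes = 15,
                       ribosomal_count = 3)
  expect_equal(g$ter_position, g$length %/% 2)
  expect_true(all(g$genes$start >= 0))
  expect_true(all(g$genes$end <= g$length))
  expect_true(all(g$genes$end > g$genes$start))
  expect_equal(nchar(g$sequence), g$length)
  expect_equal(sum(g$genes$is_ribosomal), 3)
})

test_that("zero bias leaves expected ribosomal and background usage identical", {
  expect_equal(codon_sampling_probs(0), codon_sampling_probs(0))
  p0 <- codon_sampling_probs(0)
  fam <- codon_families()
  for (aa in names(fam)) {
    expect_equal(unname(p0[fam[[aa]]]), rep(p0[[fam[[aa]][1]]], length(fam[[aa]])))
  }
})

test_that("full bias reproduces the preferred-codon table (chi-square GOF)", {
  g <- generate_genome(seed = 21, length = 50000, n_genes = 16,
                       ribosomal_count = 15, bias_strength = 1,
                       mean_gene_codons = 700)
  ribo <- gene_sequences(g, ribosomal_only = TRUE)
  counts <- colSums(Biostrings::trinucleotideFrequency(
    Biostrings::DNAStringSet(ribo), step = 3))
  expect_gt(sum(counts), 10000)
  target <- codon_sampling_probs(1)
  pos <- names(target)[target > 0]
  # non-preferred synonyms must be absent entirely at bias 1
  informative <- setdiff(unlist(codon_families()), pos)
  expect_true(all(counts[informative] == 0))
  # sampled codons follow the target distribution (stops excluded)
  obs <- counts[pos]
  gof <- suppressWarnings(stats::chisq.test(obs, p = target[pos]))
  expect_gt(gof$p.value, 0.01)
})

test_that("coverage expectation: conservation, flatness, exact ori/ter ratio", {
  flat <- simulate_coverage(60000, 25, true_ptr = 1, noise = "none")
  expect_true(all(abs(flat$depth - 25) < 1e-9))

  cov <- simulate_coverage(60000, 25, true_ptr = 2, noise = "none")
  expect_lt(abs(mean(cov$depth) - 25), 25 * 0.001)
  expect_equal(cov$depth[1] / cov$depth[30001], 2.0)  # ori (pos 0) vs ter (L/2)
  expect_error(simulate_coverage(60000, 25, true_ptr = 0.9), "true_ptr")
})

test_that("poisson noise has unit index of dispersion", {
  cov <- simulate_coverage(100000, 50, true_ptr = 1, seed = 11)
  disp <- stats::var(cov$depth) / mean(cov$depth)
  expect_gt(disp, 0.8)
  expect_lt(disp, 1.2)
})

test_that("site panel encodes the linear depth model for true replication", {
  p <- generate_site_panel(seed = 2, n_sites = 5, irep_slope = 0,
                           irep_noise_sd = 0, n_high_co2 = 0,
                           genomes_per_site = 2, coverage = "skip")
  expect_true(all(p$truth$true_ptr == p$truth$true_ptr[1]))

  p2 <- generate_site_panel(seed = 2, n_sites = 7, depth_range = c(0, 3000),
                            irep_slope = -1e-4, irep_noise_sd = 0,
                            n_high_co2 = 0, genomes_per_site = 1,
                            coverage = "skip")
  expect_equal(max(p2$truth$true_ptr) - min(p2$truth$true_ptr), 0.3)
  expect_equal(p2$truth$true_ptr,
               pmax(1, 1.6 - 1e-4 * p2$truth$depth_m))
})

test_that("high-CO2 sites carry the replication offset", {
  p <- generate_site_panel(seed = 8, n_sites = 6, irep_slope = 0,
                           irep_noise_sd = 0, high_co2_offset = 0.25,
                           n_high_co2 = 2, genomes_per_site = 1,
                           coverage = "skip")
  hi <- p$truth$true_ptr[p$truth$high_co2]
  lo <- p$truth$true_ptr[!p$truth$high_co2]
  expect_equal(unique(hi) - unique(lo), 0.25)
})

test_that("biogeo panel: zero decay gives identical genomes", {
  b <- generate_biogeo_panel(seed = 4, n_genomes = 3, ani_decay = 0,
                             genome_length = 12000)
  expect_identical(unname(b$genomes[1]), unname(b$genomes[2]))
  expect_true(all(b$expected_ani == 100))
})

test_that("biogeo panel: expected identity follows the linear decay law", {
  coords <- data.frame(latitude = c(50, 50 - 1000 / 111.13), longitude = c(7, 7))
  b <- generate_biogeo_panel(seed = 4, n_genomes = 2, coordinates = coords,
                             ani_decay = 0.005, genome_length = 20000)
  d12 <- geodesic_distance(geo_point(coords$latitude[1], coords$longitude[1]),
                           geo_point(coords$latitude[2], coords$longitude[2]))
  expect_equal(b$expected_ani[1, 2], 100 - 0.005 * d12, tolerance = 1e-10)
  expect_equal(b$expected_ani[1, 2], 95, tolerance = 0.05)
})

test_that("biogeo substitutions realize the expected divergence", {
  b <- generate_biogeo_panel(seed = 6, n_genomes = 4, ani_decay = 0.003,
                             genome_length = 20000, span_km = 1500)
  for (i in 2:4) {
    realized <- sum(strsplit(b$genomes[1], "")[[1]] !=
                      strsplit(b$genomes[i], "")[[1]]) / 20000
    expected <- (100 - b$expected_ani[1, i]) / 100
    expect_lt(abs(realized - expected), 1e-4)  # rounding of the count only
  }
})

test_that("injected codon bias is monotone in the measured statistic", {
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  measured <- vapply(grid, function(b) {
    g <- generate_genome(seed = 11, length = 60000, n_genes = 40,
                         ribosomal_count = 8, bias_strength = b)
    codon_bias(codon_usage(gene_sequences(g, TRUE)),
               codon_usage(gene_sequences(g, FALSE)))
  }, numeric(1))
  expect_true(all(diff(measured) > 0))
})
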