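# Similarity scoring, gene-sharing graphs, rare-gene extraction.

random_hits_fixture <- function(n_genes = 12, n_hits = 30) {
  genes <- sprintf("g%02d", seq_len(n_genes))
  lens <- stats::setNames(sample(100:500, n_genes, replace = TRUE), genes)
  q <- sample(genes, n_hits, replace = TRUE)
  s <- sample(genes, n_hits, replace = TRUE)
  data.frame(qseqid = q, sseqid = s,
             pident = runif(n_hits, 30, 100),
             length = pmax(30, round(lens[q] * runif(n_hits, 0.2, 1.2))),
             evalue = 10^runif(n_hits, -30, -3),
             stringsAsFactors = FALSE) -> hits
  list(hits = hits, lens = lens, genes = genes)
}

test_that("similarity is coverage times identity, capped at one", {
  expect_equal(similarity(100, 0.9, 100), 0.9)
  expect_equal(similarity(50, 1.0, 100), 0.5)
  expect_equal(similarity(100, 1.0, 100), 1.0)   # self-hit
  expect_equal(similarity(150, 1.0, 100), 1.0)   # gapped overhang capped
  expect_error(similarity(100, 0.9, 0), "query_length")
  expect_error(similarity(100, 1.5, 100), "identity")
})

test_that("components form families; no hits above threshold means singletons", {
  lens <- c(A = 100, B = 100, C = 100, D = 100)
  hits <- data.frame(qseqid = c("A", "B"), sseqid = c("B", "C"),
                     pident = c(90, 95), length = c(100, 100),
                     evalue = c(1e-10, 1e-10), stringsAsFactors = FALSE)
  net <- build_network(hits, lens, threshold = 0.4)
  fam <- split(net$families$gene_id, net$families$family)
  expect_true(any(vapply(fam, function(g) setequal(g, c("A", "B", "C")),
                         logical(1))))
  expect_equal(nrow(net$edges), 2)

  net_hi <- build_network(hits, lens, threshold = 0.99)
  expect_equal(length(unique(net_hi$families$family)), 4)  # all singletons
})

test_that("hits failing the E-value cutoff and self-hits are dropped", {
  lens <- c(A = 100, B = 100)
  hits <- data.frame(qseqid = c("A", "A"), sseqid = c("B", "A"),
                     pident = c(99, 100), length = c(100, 100),
                     evalue = c(1e-3, 1e-50), stringsAsFactors = FALSE)
  net <- build_network(hits, lens, threshold = 0.4)
  expect_equal(nrow(net$edges), 0)
  expect_equal(length(unique(net$families$family)), 2)
})

test_that("raising the threshold never merges families (subgraph monotonicity)", {
  withr::with_seed(22, {
    for (rep in 1:10) {
      fx <- random_hits_fixture()
      n_prev <- 0
      for (thr in c(0.4, 0.5, 0.6, 0.7, 0.8)) {
        net <- build_network(fx$hits, fx$lens, threshold = thr)
        n_fam <- length(unique(net$families$family))
        expect_gte(n_fam, n_prev)
        n_prev <- n_fam
        # partition property: every gene in exactly one family
        expect_setequal(net$families$gene_id, fx$genes)
        expect_equal(anyDuplicated(net$families$gene_id), 0)
      }
    }
  })
})

test_that("graph is identical whether hits come as q->s, s->q, or both", {
  withr::with_seed(33, {
    fx <- random_hits_fixture()
    lens <- fx$lens
    h <- fx$hits
    # symmetrize: reverse hits reuse the subject's length as query length
    rev <- data.frame(qseqid = h$sseqid, sseqid = h$qseqid,
                      pident = h$pident, length = h$length, evalue = h$evalue)
    net_fwd <- build_network(h, lens, threshold = 0.5)
    net_both <- build_network(rbind(h, rev), lens, threshold = 0.5)
    # max edge rule: adding the reverse direction cannot remove edges, and
    # every forward edge survives
    key <- function(e) paste(e$gene_a, e$gene_b)
    expect_true(all(key(net_fwd$edges) %in% key(net_both$edges)))
  })
})

test_that("rare-gene extraction matches the per-family genome-count oracle", {
  withr::with_seed(44, {
    for (rep in 1:10) {
      fx <- random_hits_fixture()
      net <- build_network(fx$hits, fx$lens, threshold = 0.5)
      g2g <- stats::setNames(sprintf("genome%d", sample.int(4, length(fx$genes),
                                                            replace = TRUE)),
                             fx$genes)
      rare <- rare_genes(net$families, g2g, max_genomes = 2)
      expect_equal(sort(rare$family),
                   oracle_rare_genes(net$families, as.list(g2g), 2))
      expect_true(all(rare$n_genomes <= 2))
    }
  })
})

test_that("rare-gene families spanning more genomes than allowed are excluded", {
  fams <- data.frame(gene_id = c("a", "b", "c", "d"),
                     family = c("f1", "f1", "f1", "f2"))
  map <- c(a = "g1", b = "g2", c = "g3", d = "g1")
  rare <- rare_genes(fams, map, max_genomes = 2)
  expect_equal(rare$family, "f2")
  expect_error(rare_genes(fams, map[1:3]), "not mapped")
})
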