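#' Key-enzyme to pathway map used by the synthetic panels
#'
#' A compact set of diagnostic enzymes for chemolithoautotrophic carbon,
#' nitrogen and sulfur metabolisms. The map is many-to-one: several marker
#' enzymes may diagnose the same pathway, which exercises the
#' highest-hit-frequency enzyme selection rule downstream.
#'
#' @return data.frame with columns `enzyme`, `pathway`.
#' @export
key_enzyme_map <- function() {
  data.frame(
    enzyme  = c("acsB", "cooS", "aclB", "rbcL", "soxB", "dsrA", "aprA",
                "nifH", "amoA", "nirK", "nirS", "hyaB"),
    pathway = c("Wood-Ljungdahl", "Wood-Ljungdahl", "rTCA", "CBB",
                "Sulfur oxidation", "Sulfate reduction", "Sulfate reduction",
                "Nitrogen fixation", "Ammonia oxidation", "Nitrite reduction",
                "Nitrite reduction", "Hydrogen oxidation"),
    stringsAsFactors = FALSE
  )
}

#' Generate a multi-site synthetic ecosystem panel
#'
#' Emulates a comparative survey of subsurface ecosystems of varying depth:
#' each site carries several bacterial genomes whose ground-truth replication
#' index follows a linear depth model,
#' `true_ptr = base_irep + irep_slope * depth (+ high_co2_offset at flagged
#' sites) + N(0, irep_noise_sd)`, floored at 1 (a population cannot have a
#' negative fraction of replicating cells). Sites flagged `high_co2`
#' represent mantle-degassing ecosystems whose communities replicate faster
#' than their depth alone predicts. Per-genome Poisson coverage profiles and
#' a per-site key-enzyme hit table are generated alongside.
#'
#' @param seed Integer seed.
#' @param n_sites Number of sites (>= 3); depths are evenly spaced over
#'   `depth_range`.
#' @param depth_range Length-2 numeric, metres below ground.
#' @param irep_slope Change in true replication index per metre of depth.
#' @param irep_noise_sd SD of the Gaussian genome-level scatter.
#' @param high_co2_offset Additive replication offset at high-CO2 sites.
#' @param n_high_co2 Number of sites flagged as degassing-impacted.
#' @param genomes_per_site Genomes per site.
#' @param genome_length Genome length in bp used for coverage simulation.
#' @param mean_depth Mean sequencing depth per genome (x).
#' @param base_irep Replication index at 0 m without offsets.
#' @param coverage `"poisson"`, `"none"`, or `"skip"` (no profiles; fast
#'   metadata-only panels).
#' @return List with `sites` (one `site_panel` per site), `metadata`
#'   (one row per site) and `truth` (genome-level ground-truth table).
#' @export
generate_site_panel <- function(seed, n_sites = 12L, depth_range = c(0, 3000),
                                irep_slope = -1.3e-4, irep_noise_sd = 0.1,
                                high_co2_offset = 0.25, n_high_co2 = 2L,
                                genomes_per_site = 3L, genome_length = 150000L,
                                mean_depth = 50, base_irep = 1.6,
                                coverage = c("poisson", "none", "skip")) {
  check_count(seed, "seed")
  n_sites <- check_count(n_sites, "n_sites", min = 3L)
  if (!is.numeric(depth_range) || length(depth_range) != 2L ||
      any(depth_range < 0) || depth_range[2] < depth_range[1]) {
    stop_bad_field("depth_range", "must be an increasing non-negative pair")
  }
  check_number(irep_slope, "irep_slope", min = -1, max = 1)
  check_number(irep_noise_sd, "irep_noise_sd", min = 0)
  check_number(high_co2_offset, "high_co2_offset", min = -5, max = 5)
  n_high_co2 <- check_count(n_high_co2, "n_high_co2")
  if (n_high_co2 > n_sites) stop_bad_field("n_high_co2", "must be <= n_sites")
  genomes_per_site <- check_count(genomes_per_site, "genomes_per_site", min = 1L)
  coverage <- match.arg(coverage)

  enz_map <- key_enzyme_map()
  withr::with_seed(seed, {
    depths <- seq(depth_range[1], depth_range[2], length.out = n_sites)
    high_co2 <- seq_len(n_sites) %in% sample.int(n_sites, n_high_co2)
    meta <- data.frame(
      site_id = sprintf("site%02d", seq_len(n_sites)),
      depth_m = depths,
      latitude = stats::runif(n_sites, -60, 70),
      longitude = stats::runif(n_sites, -180, 180),
      sample_type = sample(c("fluid", "sediment", "soil", "rock"),
                           n_sites, replace = TRUE),
      oxygen = ifelse(depths < 100, sample(c("oxic", "anoxic"), n_sites,
                                           replace = TRUE), "anoxic"),
      high_co2 = high_co2,
      total_bp = round(stats::runif(n_sites, 2e9, 8e9)),
      stringsAsFactors = FALSE
    )

    sites <- vector("list", n_sites)
    truth <- vector("list", n_sites)
    for (s in seq_len(n_sites)) {
      gid <- sprintf("%s_bin%02d", meta$site_id[s], seq_len(genomes_per_site))
      ptr <- base_irep + irep_slope * depths[s] +
        ifelse(high_co2[s], high_co2_offset, 0) +
        stats::rnorm(genomes_per_site, 0, irep_noise_sd)
      ptr <- pmax(1, ptr)
      cov <- NULL
      if (coverage != "skip") {
        cov <- lapply(seq_len(genomes_per_site), function(i) {
          simulate_coverage(genome_length, mean_depth = mean_depth,
                            true_ptr = ptr[i],
                            seed = seed + 1000L * s + i,
                            noise = if (coverage == "none") "none" else "poisson",
                            genome_id = gid[i])
        })
        names(cov) <- gid
      }
      n_hits <- stats::rpois(1, 3 * genomes_per_site) + 1L
      hits <- data.frame(
        scaffold_id = sample(gid, n_hits, replace = TRUE),
        enzyme = sample(enz_map$enzyme, n_hits, replace = TRUE),
        sample_id = meta$site_id[s],
        scaffold_coverage = round(stats::runif(n_hits, 5, 60), 2),
        score = round(stats::runif(n_hits, 50, 500), 1),
        stringsAsFactors = FALSE
      )
      hits$pathway <- enz_map$pathway[match(hits$enzyme, enz_map$enzyme)]
      sites[[s]] <- structure(
        c(as.list(meta[s, ]),
          list(genomes = data.frame(genome_id = gid, true_ptr = ptr,
                                    stringsAsFactors = FALSE),
               coverage = cov, enzyme_hits = hits)),
        class = "site_panel"
      )
      truth[[s]] <- data.frame(genome_id = gid, site_id = meta$site_id[s],
                               depth_m = depths[s], high_co2 = high_co2[s],
                               true_ptr = ptr, stringsAsFactors = FALSE)
    }
    list(sites = sites, metadata = meta, truth = do.call(rbind, truth))
  })
}

#' @export
print.site_panel <- function(x, ...) {
  cat(sprintf("<site_panel> %s: depth %.0f m, %s, %s%s, %d genomes\n",
              x$site_id, x$depth_m, x$sample_type, x$oxygen,
              if (isTRUE(x$high_co2)) ", high-CO2" else "",
              nrow(x$genomes)))
  invisible(x)
}

#' Generate a biogeography panel: related genomes along a distance gradient
#'
#' Derives `n_genomes` genomes from one ancestor by nested substitution so
#' that expected pairwise nucleotide identity decays linearly with
#' geographic distance: `identity% = 100 - ani_decay * distance_km`,
#' clamped at 75%. By default sites lie on a meridian transect anchored at
#' the Geyser Andernach reference point; meridians are geodesics, so
#' pairwise distances are additive along the transect and the linear decay
#' law holds exactly for every pair. For user-supplied coordinates genomes
#' are ordered by distance from the first site and the achieved
#' expected-identity matrix (returned as ground truth) is exact for the
#' generator but matches the linear law only when sites are collinear.
#'
#' @param seed Integer seed.
#' @param n_genomes Number of genomes (>= 2).
#' @param coordinates Optional data.frame with `latitude`, `longitude`
#'   (decimal degrees, WGS84), one row per genome; distinct rows required.
#' @param ani_decay Identity loss in percentage points per km (>= 0).
#' @param genome_length Ancestor length in bp.
#' @param gc Ancestor GC content.
#' @param span_km Transect span used for the default coordinate layout.
#' @return List with `genomes` (named character vector), `coordinates`
#'   (site table), `expected_ani` (ground-truth expected identity matrix, %)
#'   and `substitutions` (per-genome substitution counts vs the ancestor).
#' @export
generate_biogeo_panel <- function(seed, n_genomes = 6L, coordinates = NULL,
                                  ani_decay = 0.002, genome_length = 30000L,
                                  gc = 0.5, span_km = 2000) {
  check_count(seed, "seed")
  n_genomes <- check_count(n_genomes, "n_genomes", min = 2L)
  check_number(ani_decay, "ani_decay", min = 0)
  check_number(genome_length, "genome_length", min = 10000)
  L <- as.integer(genome_length)

  if (is.null(coordinates)) {
    anchor <- geyser_andernach()
    coordinates <- data.frame(
      site_id = sprintf("bio%02d", seq_len(n_genomes)),
      latitude = anchor$latitude -
        seq(0, span_km, length.out = n_genomes) / 111.13,
      longitude = rep(anchor$longitude, n_genomes)
    )
  }
  if (nrow(coordinates) != n_genomes) {
    stop_bad_field("coordinates", "must have one row per genome")
  }
  if (anyDuplicated(coordinates[, c("latitude", "longitude")])) {
    stop_bad_field("coordinates", "must be distinct")
  }
  if (is.null(coordinates$site_id)) {
    coordinates$site_id <- sprintf("bio%02d", seq_len(n_genomes))
  }

  d_anchor <- vapply(seq_len(n_genomes), function(i) {
    geodesic_distance(geo_point(coordinates$latitude[1], coordinates$longitude[1]),
                      geo_point(coordinates$latitude[i], coordinates$longitude[i]))
  }, numeric(1))
  q <- pmin(ani_decay * d_anchor / 100, 0.25)

  withr::with_seed(seed, {
    acgt <- c("A", "C", "G", "T")
    p_nt <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    ancestor <- sample(acgt, L, replace = TRUE, prob = p_nt)
    perm <- sample.int(L)          # shared substitution order (nested sets)
    alt <- vapply(ancestor, function(b) sample(setdiff(acgt, b), 1L),
                  character(1), USE.NAMES = FALSE)

    n_sub <- round(L * q)
    genomes <- vapply(seq_len(n_genomes), function(i) {
      g <- ancestor
      if (n_sub[i] > 0) {
        idx <- perm[seq_len(n_sub[i])]
        g[idx] <- alt[idx]
      }
      paste(g, collapse = "")
    }, character(1))
    names(genomes) <- sprintf("biogeo_g%02d", seq_len(n_genomes))

    expected_ani <- 100 * (1 - abs(outer(q, q, "-")))
    dimnames(expected_ani) <- list(names(genomes), names(genomes))

    list(genomes = genomes, coordinates = coordinates,
         expected_ani = expected_ani,
         substitutions = stats::setNames(n_sub, names(genomes)))
  })
}
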