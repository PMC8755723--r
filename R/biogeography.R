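#' Construct a validated WGS84 point
#'
#' @param latitude Decimal degrees in [-90, 90].
#' @param longitude Decimal degrees in [-180, 180].
#' @return A `geo_point` list.
#' @export
geo_point <- function(latitude, longitude) {
  check_number(latitude, "latitude", min = -90, max = 90)
  check_number(longitude, "longitude", min = -180, max = 180)
  structure(list(latitude = latitude, longitude = longitude),
            class = "geo_point")
}

#' The Geyser Andernach reference point
#'
#' Coordinates of the cold-water, CO2-driven Geyser Andernach in the Middle
#' Rhine valley, the anchor site of the comparative analyses.
#'
#' @return A `geo_point` (50.448588 N, 7.375355 E).
#' @export
geyser_andernach <- function() geo_point(50.448588, 7.375355)

#' Ellipsoidal geodesic distance between two sites
#'
#' Length of the geodesic connecting two points on the WGS84 ellipsoid
#' (Karney-style solver via `geosphere::distGeo`), in kilometres. An
#' ellipsoidal solver is used rather than spherical haversine because
#' site-to-site distances feed a correlation with genomic divergence and
#' the flattening correction is not negligible at continental scale.
#'
#' @param a,b `geo_point` objects (or lists with `latitude`, `longitude`).
#' @return Distance in km.
#' @export
geodesic_distance <- function(a, b) {
  d <- geosphere::distGeo(c(a$longitude, a$latitude),
                          c(b$longitude, b$latitude))
  d / 1000
}

#' Fragment-based average nucleotide identity between two genomes
#'
#' Chops genome A into non-overlapping fragments of `fragment_bp`, finds
#' each fragment's best match in genome B by k-mer seeding (exact seed
#' words looked up at the fragment's start, middle and end) followed by
#' gap-tolerant alignment of the candidate window
#' (`Biostrings::pairwiseAlignment`), keeps matches with identity >=
#' `min_identity` over >= `min_aln_fraction` of the fragment, and averages
#' the kept identities. The reported ANI is the mean of the A->B and B->A
#' direction values, in percent.
#'
#' @param genome_a,genome_b DNA sequences (character or
#'   `Biostrings::DNAString`); each must yield >= 10 fragments.
#' @param fragment_bp Fragment size (default 1000).
#' @param min_identity Identity floor for keeping a fragment match.
#' @param min_aln_fraction Aligned-fraction floor.
#' @param k Seed word size (default 15; unrelated sequences almost never
#'   share an exact 15-mer at these genome sizes, so they return
#'   no-alignment rather than a spurious identity).
#' @return An `ani_result`: `ani` (percent, NA when no fragment passes),
#'   `aligned_fraction`, `n_fragments_used`, `status`.
#' @export
fragment_ani <- function(genome_a, genome_b, fragment_bp = 1000L,
                         min_identity = 0.7, min_aln_fraction = 0.7,
                         k = 15L) {
  check_number(fragment_bp, "fragment_bp", min = 100)
  check_number(min_identity, "min_identity", min = 0, max = 1)
  check_number(min_aln_fraction, "min_aln_fraction", min = 0, max = 1)
  a <- if (inherits(genome_a, "DNAString")) genome_a else Biostrings::DNAString(genome_a)
  b <- if (inherits(genome_b, "DNAString")) genome_b else Biostrings::DNAString(genome_b)
  if (length(a) < 10 * fragment_bp || length(b) < 10 * fragment_bp) {
    stop_bad_field("genomes", "each genome must span at least 10 fragments")
  }

  dir_ab <- ani_one_direction(a, b, fragment_bp, min_identity,
                              min_aln_fraction, k)
  dir_ba <- ani_one_direction(b, a, fragment_bp, min_identity,
                              min_aln_fraction, k)
  n_used <- dir_ab$n_used + dir_ba$n_used
  if (n_used == 0L) {
    return(structure(list(ani = NA_real_, aligned_fraction = 0,
                          n_fragments_used = 0L, status = "no-alignment"),
                     class = "ani_result"))
  }
  ani <- if (dir_ab$n_used > 0L && dir_ba$n_used > 0L) {
    (dir_ab$mean_identity + dir_ba$mean_identity) / 2 * 100
  } else if (dir_ab$n_used > 0L) dir_ab$mean_identity * 100
    else dir_ba$mean_identity * 100
  structure(
    list(ani = ani,
         aligned_fraction = n_used / (dir_ab$n_total + dir_ba$n_total),
         n_fragments_used = n_used, status = "ok"),
    class = "ani_result"
  )
}

#' @export
print.ani_result <- function(x, ...) {
  if (x$status == "no-alignment") {
    cat("<ani_result> no fragment passed the alignment floors\n")
  } else {
    cat(sprintf("<ani_result> ANI %.2f%% (%d fragments, %.0f%% aligned)\n",
                x$ani, x$n_fragments_used, 100 * x$aligned_fraction))
  }
  invisible(x)
}

# One direction of the fragment search: fragments of `a` against target `b`.
ani_one_direction <- function(a, b, fragment_bp, min_identity,
                              min_aln_fraction, k) {
  n_frag <- length(a) %/% fragment_bp
  kept <- numeric(0)
  slack <- ceiling(0.2 * fragment_bp)
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
  for (i in seq_len(n_frag)) {
    frag <- Biostrings::subseq(a, (i - 1L) * fragment_bp + 1L, i * fragment_bp)
    # seed at start, middle, end of the fragment
    offsets <- unique(c(1L, fragment_bp %/% 2L, fragment_bp - k + 1L))
    hit_start <- NA_integer_
    for (o in offsets) {
      seed <- Biostrings::subseq(frag, o, o + k - 1L)
      m <- Biostrings::matchPattern(seed, b)
      if (length(m) > 0) {
        hit_start <- BiocGenerics::start(m)[1L] - o + 1L
        break
      }
    }
    if (is.na(hit_start)) next
    w_start <- max(1L, hit_start - slack)
    w_end <- min(length(b), hit_start + fragment_bp - 1L + slack)
    window <- Biostrings::subseq(b, w_start, w_end)
    aln <- Biostrings::pairwiseAlignment(frag, window, type = "global-local",
                                         substitutionMatrix = sub_mat,
                                         gapOpening = 5, gapExtension = 2)
    aln_len <- Biostrings::nchar(aln)
    if (aln_len < 1) next
    ident <- Biostrings::nmatch(aln) / aln_len
    covered <- Biostrings::width(Biostrings::pattern(aln)@range) / fragment_bp
    if (ident >= min_identity && covered >= min_aln_fraction) {
      kept <- c(kept, ident)
    }
  }
  list(mean_identity = if (length(kept)) mean(kept) else NA_real_,
       n_used = length(kept), n_total = n_frag)
}

#' Distance-decay test: nucleotide identity versus geographic distance
#'
#' Correlates pairwise geodesic distance with pairwise ANI over all
#' unordered genome pairs (Pearson, two-sided p from the t transform).
#' A significant negative r is the classic signature of distance decay /
#' isolation by distance.
#'
#' @param points data.frame with `latitude`, `longitude` per genome, rows
#'   aligned with the ANI matrix.
#' @param ani_matrix Symmetric matrix of pairwise identities (percent).
#' @return List with `r`, `p`, `n_pairs`, plus the per-pair table.
#' @export
distance_decay <- function(points, ani_matrix) {
  n <- nrow(points)
  if (!is.matrix(ani_matrix) || nrow(ani_matrix) != n || ncol(ani_matrix) != n) {
    stop_bad_field("ani_matrix", "must be an n x n matrix matching `points`")
  }
  pairs <- utils::combn(n, 2)
  if (ncol(pairs) < 4L) stop_bad_field("points", "need at least 4 genome pairs")
  dist_km <- apply(pairs, 2, function(ij) {
    geodesic_distance(geo_point(points$latitude[ij[1]], points$longitude[ij[1]]),
                      geo_point(points$latitude[ij[2]], points$longitude[ij[2]]))
  })
  ani <- ani_matrix[t(pairs)]
  ct <- pearson(dist_km, ani)
  list(r = ct$r, p = ct$p, n_pairs = ncol(pairs),
       pairs = data.frame(i = pairs[1, ], j = pairs[2, ],
                          distance_km = dist_km, ani = ani))
}
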