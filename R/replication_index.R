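#' Window a coverage profile circularly
#'
#' Tiles the genome with windows of `window_bp` every `slide_bp` (windows
#' wrap around the circular end) and returns the arithmetic mean depth per
#' window, in genome order.
#'
#' @param profile A `coverage_profile` (or bare numeric depth vector).
#' @param window_bp Window size in bp (<= genome length).
#' @param slide_bp Step between window starts (<= `window_bp`).
#' @return Numeric vector of window mean depths.
#' @export
window_coverage <- function(profile, window_bp = 5000L, slide_bp = window_bp) {
  depth <- if (inherits(profile, "coverage_profile")) profile$depth else profile
  L <- length(depth)
  check_number(window_bp, "window_bp", min = 1)
  check_number(slide_bp, "slide_bp", min = 1)
  if (window_bp > L) stop_bad_field("window_bp", "larger than the genome")
  if (slide_bp > window_bp) stop_bad_field("slide_bp", "must be <= window_bp")
  window_bp <- as.integer(window_bp); slide_bp <- as.integer(slide_bp)

  starts <- seq.int(0L, L - 1L, by = slide_bp)
  csum <- c(0, cumsum(depth))
  total <- csum[L + 1L]
  ends <- starts + window_bp            # half-open [start, end), may wrap
  vapply(seq_along(starts), function(i) {
    a <- starts[i]; b <- ends[i]
    s <- if (b <= L) csum[b + 1L] - csum[a + 1L]
         else (total - csum[a + 1L]) + csum[b - L + 1L]
    s / window_bp
  }, numeric(1))
}

#' Estimate the in situ replication index from window coverages
#'
#' Implements the origin-to-terminus coverage-trend estimator: window means
#' are sorted ascending, the extreme `trim_fraction` of windows at each tail
#' is discarded, and `log2(mean depth)` is regressed by ordinary least
#' squares on the rank fraction of each window within the full sorted set
#' (`(rank - 0.5) / n`). Under the replication-fork model the sorted
#' log-depths are linear in rank fraction with slope `log2(PTR)`, so the
#' index is `2^slope`. Trimmed windows retain their original rank fraction;
#' re-ranking after trimming would shrink the slope by `1 - 2 * trim` and
#' bias the estimator. Because windows are sorted, origin and terminus
#' positions need not be known and scaffold fragments may be pooled.
#'
#' The estimator applies only to bacteria: archaea can initiate replication
#' from multiple origins, which distorts the coverage trend, so archaeal
#' input is refused unless `force = TRUE`.
#'
#' @param windows Numeric vector of window mean depths (or a
#'   `coverage_profile`, windowed with `window_bp`/`slide_bp`).
#' @param trim_fraction Fraction of windows discarded at each tail.
#' @param min_r2 QC floor on the regression r-squared.
#' @param min_retained QC floor on the fraction of windows retained
#'   (zero-coverage windows are excluded before the log and count against
#'   retention).
#' @param genome_id,sample_id Identifiers recorded in the result.
#' @param domain `"Bacteria"` or `"Archaea"`.
#' @param force Override the archaeal guard.
#' @param mismatch_tolerance Read-filter provenance recorded with the
#'   estimate: the upstream mapping's allowed mismatch fraction relative to
#'   read length (default 0.02, i.e. 2%). Metadata only; reads are filtered
#'   upstream of this package.
#' @param window_bp,slide_bp Windowing used when a profile is supplied.
#' @return A `replication_estimate` with fields `irep`, `r_squared`,
#'   `n_windows`, `windows_retained_fraction`, `qc_pass`, `status`.
#' @export
estimate_irep <- function(windows, trim_fraction = 0.05, min_r2 = 0.90,
                          min_retained = 0.75, genome_id = "genome",
                          sample_id = NA_character_, domain = "Bacteria",
                          force = FALSE, mismatch_tolerance = 0.02,
                          window_bp = 5000L, slide_bp = window_bp) {
  check_number(trim_fraction, "trim_fraction", min = 0, max = 0.25)
  check_number(min_r2, "min_r2", min = 0, max = 1)
  check_number(min_retained, "min_retained", min = 0, max = 1)
  check_choice(domain, "domain", c("Bacteria", "Archaea"))
  if (domain == "Archaea" && !isTRUE(force)) {
    stop("replication-index estimation refused for archaeal genomes: ",
         "multiple replication origins distort the coverage trend ",
         "(use force = TRUE to override)", call. = FALSE)
  }
  if (inherits(windows, "coverage_profile")) {
    genome_id <- windows$genome_id
    windows <- window_coverage(windows, window_bp, slide_bp)
  }
  if (!is.numeric(windows) || length(windows) < 1L) {
    stop_bad_field("windows", "must be a non-empty numeric vector")
  }

  n_total <- length(windows)
  result <- function(irep, r2, n_used, status, qc) {
    structure(list(genome_id = genome_id, sample_id = sample_id, irep = irep,
                   r_squared = r2, n_windows = n_total,
                   windows_retained_fraction = n_used / n_total,
                   qc_pass = qc, status = status,
                   mismatch_tolerance = mismatch_tolerance),
              class = "replication_estimate")
  }

  nz <- windows[windows > 0]
  if (length(nz) == 0L) {
    return(result(NA_real_, NA_real_, 0L, "no-coverage", FALSE))
  }
  sorted <- sort(nz)
  n <- length(sorted)
  frac <- (seq_len(n) - 0.5) / n        # rank fraction over the full set
  k <- floor(trim_fraction * n)
  keep <- if (k > 0) seq.int(k + 1L, n - k) else seq_len(n)
  if (length(keep) < 20L) {
    stop_bad_field("windows", "fewer than 20 windows remain after trimming")
  }
  y <- log2(sorted[keep])
  x <- frac[keep]

  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- fit$coefficients[2]
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot < .Machine$double.eps) 1.0 else 1 - sum(fit$residuals^2) / ss_tot
  irep <- unname(2^slope)
  n_used <- length(keep)
  qc <- (r2 >= min_r2) && (n_used / n_total >= min_retained)
  result(irep, r2, n_used, "ok", qc)
}

#' @export
print.replication_estimate <- function(x, ...) {
  cat(sprintf("<replication_estimate> %s: irep %.3f (r2 %.3f, %d windows, %.0f%% retained, QC %s)\n",
              x$genome_id, x$irep, x$r_squared, x$n_windows,
              100 * x$windows_retained_fraction,
              if (isTRUE(x$qc_pass)) "pass" else "fail"))
  invisible(x)
}

#' Average replication estimates for one genome across samples
#'
#' When a genome was observed in several samples of one ecosystem, its
#' per-sample index values are averaged to a single comparable value; only
#' QC-passing estimates enter the mean.
#'
#' @param estimates List of `replication_estimate` objects for one genome.
#' @return Mean index over QC-passing estimates, or `NA` if none pass.
#' @export
average_irep <- function(estimates) {
  if (inherits(estimates, "replication_estimate")) estimates <- list(estimates)
  ok <- vapply(estimates, function(e) isTRUE(e$qc_pass) && is.finite(e$irep),
               logical(1))
  if (!any(ok)) return(NA_real_)
  mean(vapply(estimates[ok], `[[`, numeric(1), "irep"))
}

#' Fraction of a population inferred to be replicating
#'
#' Interprets a replication index as the excess fraction of the population
#' carrying an active pair of replication forks: an index of 1 means no
#' cell is replicating, 1.4 means 40% are, 2 means on average one full
#' extra fork per cell. Values below 1 (possible on noisy fits) are
#' reported as 0% and flagged via the `sub_unity` attribute.
#'
#' @param irep Numeric vector of replication index values.
#' @return Percent of the population replicating, with attribute
#'   `sub_unity` marking inputs below 1.
#' @export
fraction_replicating <- function(irep) {
  if (!is.numeric(irep) || any(!is.finite(irep))) {
    stop_bad_field("irep", "must be finite numeric")
  }
  sub <- irep < 1
  out <- pmax(irep - 1, 0) * 100
  attr(out, "sub_unity") <- sub
  out
}

#' Estimate replication indices for every genome of a site panel
#'
#' Convenience wrapper applying [window_coverage()] and [estimate_irep()]
#' to each genome's coverage profile in each site of a synthetic panel.
#'
#' @param panel Result of [generate_site_panel()] (needs coverage profiles).
#' @param ... Passed to [estimate_irep()].
#' @return data.frame: genome_id, site_id, depth_m, high_co2, irep,
#'   r_squared, qc_pass.
#' @export
panel_irep <- function(panel, ...) {
  rows <- lapply(panel$sites, function(site) {
    if (is.null(site$coverage)) {
      stop("panel was generated with coverage = \"skip\"", call. = FALSE)
    }
    ests <- lapply(site$coverage, estimate_irep, sample_id = site$site_id, ...)
    data.frame(
      genome_id = vapply(ests, `[[`, character(1), "genome_id"),
      site_id = site$site_id,
      depth_m = site$depth_m,
      high_co2 = site$high_co2,
      irep = vapply(ests, `[[`, numeric(1), "irep"),
      r_squared = vapply(ests, `[[`, numeric(1), "r_squared"),
      qc_pass = vapply(ests, `[[`, logical(1), "qc_pass"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
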