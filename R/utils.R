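# Internal validation helpers. Every generator / estimator funnels its
# argument checks through these so error messages always name the field.

stop_bad_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_number <- function(x, field, min = -Inf, max = Inf, allow_na = FALSE) {
  if (allow_na && (is.null(x) || all(is.na(x)))) return(invisible(x))
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_bad_field(field, "must be a single finite number")
  }
  if (x < min) stop_bad_field(field, sprintf("must be >= %s", min))
  if (x > max) stop_bad_field(field, sprintf("must be <= %s", max))
  invisible(x)
}

check_count <- function(x, field, min = 0L) {
  check_number(x, field, min = min)
  if (x != as.integer(x)) stop_bad_field(field, "must be a whole number")
  invisible(as.integer(x))
}

check_flag <- function(x, field) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_bad_field(field, "must be TRUE or FALSE")
  }
  invisible(x)
}

check_choice <- function(x, field, choices) {
  if (!is.character(x) || length(x) != 1L || !(x %in% choices)) {
    stop_bad_field(field, paste("must be one of:", paste(choices, collapse = ", ")))
  }
  invisible(x)
}

# Circular distance from the origin for 0-based positions on a genome of
# length L with ori at 0 (ter then sits at L/2, the farthest point).
circular_ori_distance <- function(positions, length) {
  pmin(positions, length - positions)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
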