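# Internal helpers shared across modules.

# Condition classes are stable API for callers that need to branch on the
# kind of failure (schema vs validation vs numeric degeneracy).
abort_schema <- function(msg, ...) abort(msg, class = "combindex_schema_error", ...)
abort_validation <- function(msg, ...) abort(msg, class = "combindex_validation_error", ...)
abort_normalization <- function(msg, ...) abort(msg, class = "combindex_normalization_error", ...)
abort_insufficient <- function(msg, ...) abort(msg, class = "combindex_insufficient_data_error", ...)
abort_degenerate <- function(msg, ...) abort(msg, class = "combindex_degenerate_data_error", ...)
abort_domain <- function(msg, ...) abort(msg, class = "combindex_domain_error", ...)
abort_range <- function(msg, ...) abort(msg, class = "combindex_range_error", ...)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Full-precision numeric formatting so write -> read round-trips are
# bit-identical for the canonical CSV dialect.
num_chr <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    s <- sprintf("%.17g", v)
    # prefer the shortest representation that still round-trips
    for (d in 1:16) {
      cand <- sprintf("%.*g", d, v)
      if (as.numeric(cand) == v) return(cand)
    }
    s
  }, character(1))
  out
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# strtod-based numeric parsing; keeps character values (and their NA
# positions) distinguishable from unparseable entries for validation
parse_strict <- function(x) {
  if (is.numeric(x)) return(x)
  suppressWarnings(as.numeric(x))
}

`%||%` <- rlang::`%||%`
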