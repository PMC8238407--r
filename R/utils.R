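# Internal helpers: classed conditions, deterministic number formatting,
# and seeded random streams that never leak into the caller's RNG state.

txc_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "txc_error"), ...)
}

# Fixed rendering contract for reals in reports: 6 significant digits,
# "." decimal separator, no scientific notation for the magnitudes we emit.
fmt6 <- function(x) {
  out <- formatC(x, format = "g", digits = 6)
  gsub(" ", "", out)
}

# Polynomial string hash on [0, 2^31 - 2]; used to partition random streams
# by (platform, batch) tag so adding one platform never perturbs another's
# draws.
hash_string <- function(s) {
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483646
  h
}

stream_seed <- function(seed, ...) {
  tags <- paste(c(...), collapse = "\x1f")
  (as.numeric(seed) %% 2147483646 * 48271 + hash_string(tags)) %% 2147483646 + 1
}

# Run `code` under a fixed, fully specified RNG stream and restore whatever
# RNG state the caller had (including none).
with_stream <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

assert_comparator <- function(comparator) {
  if (!is.character(comparator) || length(comparator) != 1L ||
      !comparator %in% c("strictly_greater", "greater_or_equal")) {
    txc_abort(
      "`comparator` must be \"strictly_greater\" or \"greater_or_equal\".",
      "txc_validation_error"
    )
  }
  comparator
}

assert_cutoffs <- function(cutoffs) {
  if (!is.numeric(cutoffs) || length(cutoffs) == 0L || anyNA(cutoffs) ||
      any(cutoffs < 0)) {
    txc_abort("`cutoffs` must be non-negative numbers.", "txc_validation_error")
  }
  if (is.unsorted(cutoffs, strictly = TRUE)) {
    txc_abort("`cutoffs` must be strictly increasing.", "txc_validation_error")
  }
  as.numeric(cutoffs)
}

#' Default expression cutoff ladder
#'
#' The ladder of detection thresholds commonly recommended for calling a gene
#' expressed: 0, 0.1, 1, 5 and 10, each applied in the platform's native unit
#' (RPKM for short reads, normalized counts for long reads, an abundance score
#' for qPCR).
#'
#' @return A numeric vector of cutoffs.
#' @export
#' @examples
#' default_cutoffs()
default_cutoffs <- function() c(0, 0.1, 1, 5, 10)
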