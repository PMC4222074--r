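# Internal helpers shared across modules.

#' Derive a reproducible substream seed from a master seed and a label
#'
#' All stage-level randomness in the package fans out from one master seed
#' through this map, so individual stages can be rerun independently with
#' identical results. The result is always a valid 32-bit integer seed.
#'
#' @param seed master integer seed.
#' @param label character tag naming the substream (e.g. `"segmentation"`).
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  codes <- utf8ToInt(label)
  h <- sum(codes * seq_along(codes)) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 48271 + h * 7919 + 1) %% 2147483647)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG state is restored afterwards. `seed = NULL` leaves the
# current stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  ge <- globalenv()
  had <- exists(".Random.seed", envir = ge, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = ge) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = ge)
    else if (exists(".Random.seed", envir = ge, inherits = FALSE))
      rm(".Random.seed", envir = ge)
  })
  set.seed(seed)
  code
}

# Conventional half-up rounding (base round() is round-half-even).
round_half_up <- function(x) floor(x + 0.5)

# Row standard deviations of a numeric matrix (denominator n - 1).
row_sds <- function(x) {
  n <- ncol(x)
  if (n < 2L) stop("need at least 2 columns to compute a standard deviation")
  m <- rowMeans(x)
  sqrt(rowSums((x - m)^2) / (n - 1))
}
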