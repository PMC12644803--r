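#' @keywords internal
"_PACKAGE"

# Euclidean distance between 2D points given as length-2 numerics.
dist2 <- function(p, q) sqrt(sum((p - q)^2))

# Distances from one point to the rows of an n x 2 matrix.
dist_to <- function(p, m) sqrt((m[, 1] - p[1])^2 + (m[, 2] - p[2])^2)

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the R random number generator to a reproducible state, runs `code`,
#' and restores the caller's RNG state afterwards, so that seeded package
#' functions never disturb the user's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}

# Derive a stream-specific child seed from a parent seed; stays within the
# 32-bit integer range.
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 9973) %% 2147483629L) + 1L
}

# Canonical order of target kinds used everywhere (tie-breaks, factors).
TARGET_KINDS <- c("single", "jointA", "jointB")

kind_index <- function(kind) match(kind, TARGET_KINDS)
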