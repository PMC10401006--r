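#' @importFrom rlang abort warn .data :=
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom tidyr pivot_wider pivot_longer
#' @importFrom purrr map map_dbl map2 pmap imap list_rbind
NULL

# Clamp to the admissible estimate range (risk estimates live on 0-100).
clip_unit_interval <- function(x, lo = 0, hi = 100) {
  pmin(pmax(x, lo), hi)
}

#' Derive a child RNG seed from a master seed
#'
#' Deterministic integer stream-splitting: each (master seed, stream index)
#' pair maps to one seed in `[1, 2^31 - 2]` through a small multiplicative
#' hash. Child streams are independent of how many other streams are drawn,
#' so adding trials to a study never perturbs the seeds of earlier trials.
#'
#' @param master Integer master seed.
#' @param index Non-negative integer stream index (vectorised).
#' @return Integer vector of seeds, same length as `index`.
#' @export
#' @examples
#' split_seed(42L, 0:3)
split_seed <- function(master, index) {
  stopifnot(is.numeric(master), length(master) == 1, is.numeric(index))
  m <- 2147483647 # 2^31 - 1, Mersenne prime modulus
  h <- (abs(as.double(master)) %% m)
  out <- vapply(as.double(index), function(i) {
    x <- (h + 1) %% m
    for (k in 1:3) {
      x <- (x * 48271 + (i + 1) * 16807 + 12345) %% m
    }
    x
  }, numeric(1))
  as.integer(out %% (m - 2) + 1)
}

# FNV-1a 32-bit hash of a character scalar, returned as 8-char hex.
# Used for provenance manifests (config fingerprinting), not cryptography.
fnv1a_hash <- function(text) {
  stopifnot(is.character(text))
  bytes <- as.integer(charToRaw(paste(text, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^30) + 2^30, b) # keep in int range
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

# Shared argument checks ------------------------------------------------

check_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > hi) {
    abort(
      sprintf("`%s` must be a single number in [%s, %s].", name, lo, hi),
      class = "netwisdom_invalid_parameters"
    )
  }
  invisible(x)
}
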