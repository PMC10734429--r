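#' @keywords internal
"_PACKAGE"

## 32-bit FNV-1a over a character string. The multiply is split into two
## 16-bit halves so every intermediate stays below 2^53 and the arithmetic
## is exact in double precision.
fnv1a <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwxor_dbl(h, b)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- ((hi * 16777619) %% 65536) * 65536 + lo * 16777619
    h <- h %% 4294967296
  }
  h
}

bitwxor_dbl <- function(a, b) {
  ## base bitwXor is limited to 32-bit signed ints; do two 16-bit halves
  a_lo <- a %% 65536; a_hi <- (a - a_lo) / 65536
  b_lo <- b %% 65536; b_hi <- (b - b_lo) / 65536
  bitwXor(a_hi %% 65536, b_hi %% 65536) * 65536 + bitwXor(a_lo, b_lo)
}

#' Derive the seed for a named pipeline stage
#'
#' Every stochastic stage draws from its own stream, derived
#' deterministically from the run seed and the stage name, so stages are
#' reproducible independently of execution order.
#'
#' @param seed integer run-level seed.
#' @param stage character stage name.
#' @return An integer in `[0, 2^31 - 1)` suitable for [set.seed()].
#' @export
#' @examples
#' stage_seed(17072020, "taxa_sharing")
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage),
            length(stage) == 1L)
  as.integer((abs(seed) + fnv1a(stage)) %% 2147483647)
}

## short stable hash of an R object (config fingerprinting in manifests)
config_hash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "\n")
  h <- fnv1a(s)
  lo <- h %% 65536
  sprintf("%04x%04x", (h - lo) / 65536, lo)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_val <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
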