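#' Derive a per-sample seed from a master seed
#'
#' Deterministic integer hash mapping `(master_seed, index)` to a seed
#' below 2^31, so datasets are bit-reproducible from one master seed while
#' samples get independent streams. All arithmetic stays within exact
#' double-precision integer range.
#'
#' @param master_seed integer master seed.
#' @param index sample index (1-based).
#' @return integer seed.
#' @export
derive_seed <- function(master_seed, index) {
  m <- as.double(master_seed) %% 2147483629
  h <- (m * 48271 + as.double(index) * 16807 + 12345) %% 2147483629
  h <- (h * 69621) %% 2147483629
  as.integer(h)
}
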