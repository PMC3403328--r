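#' Decimal encoding of Boolean states and controls
#'
#' A network state is the bit vector `(v_1, ..., v_n)` of the internal nodes;
#' its decimal representation is `z = 1 + sum_i 2^(n-i) v_i`, so the first
#' bit is the most significant and states are 1-based integers in
#' `[1, 2^n]`. Controls use the same encoding over the `m` control bits,
#' giving `u` in `[1, 2^m]`. `decode_state()` and `decode_control()` invert
#' the maps.
#'
#' @param bits Integer vector of 0/1 values; the first entry is the most
#'   significant bit. May have length 0 (a network with no control nodes has
#'   the single control value `u = 1`).
#' @param z,u 1-based integer code.
#' @param n,m Number of internal (resp. control) nodes.
#' @return `encode_state()`/`encode_control()` return a single integer;
#'   `decode_state()`/`decode_control()` return an integer vector of bits.
#' @examples
#' encode_state(c(1, 0)) # 3
#' decode_state(3, 2) # c(1, 0)
#' encode_control(integer(0)) # 1 (no control nodes)
#' @export
encode_state <- function(bits) {
  check_bits(bits)
  n <- length(bits)
  if (n == 0L) {
    return(1L)
  }
  as.integer(1 + sum(bits * 2^(n - seq_len(n))))
}

#' @rdname encode_state
#' @export
decode_state <- function(z, n) {
  if (length(z) != 1L || is.na(z) || z != as.integer(z)) {
    stop_input("`z` must be a single integer, got %s", deparse(z))
  }
  if (z < 1 || z > 2^n) {
    stop_input("state %d out of range [1, 2^%d]", as.integer(z), n)
  }
  if (n == 0L) {
    return(integer(0))
  }
  bitwAnd(bitwShiftR(as.integer(z) - 1L, (n - 1L):0L), 1L)
}

#' @rdname encode_state
#' @export
encode_control <- function(bits) encode_state(bits)

#' @rdname encode_state
#' @export
decode_control <- function(u, m) decode_state(u, m)

check_bits <- function(bits) {
  if (length(bits) && (anyNA(bits) || !all(bits %in% c(0, 1)))) {
    stop_input("bit vector must contain only 0s and 1s")
  }
  invisible(bits)
}

# All 2^n states as an S x n 0/1 matrix, row s = decode_state(s, n).
state_bits_matrix <- function(n) {
  if (n == 0L) {
    return(matrix(integer(0), nrow = 1L, ncol = 0L))
  }
  s <- 0:(2^n - 1)
  vapply(seq_len(n), function(i) bitwAnd(bitwShiftR(s, n - i), 1L), integer(2^n))
}
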