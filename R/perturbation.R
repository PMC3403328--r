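#' Random gene perturbation model
#'
#' With per-gene flip probability `p`, each step the state either follows
#' the Boolean update (probability `(1-p)^n`, no gene flips) or jumps to a
#' uniformly perturbed state. The single-gene kernel is
#' `Q = [[1-p, p], [p, 1-p]]`; the perturbation matrix is the n-fold
#' Kronecker power of `Q` minus its diagonal part,
#' `P = Q %x% ... %x% Q - (1-p)^n I`, whose entry between states at Hamming
#' distance `h >= 1` is `p^h (1-p)^(n-h)` and whose every row and column sum
#' is `xi = 1 - (1-p)^n`. The perturbed transition matrix is
#' `Atilde = (1-p)^n A + P`, again column stochastic.
#'
#' Gene 1 is the outermost Kronecker factor, matching the decimal state
#' encoding (first bit most significant), so entries can be addressed by
#' state index directly.
#'
#' @param p Single-gene flip probability in `[0, 1)`.
#' @param n Number of genes (`n <= 12`; the matrix is materialised densely).
#' @param A A `2^n x 2^n` column-stochastic matrix (sparse or dense).
#' @return `build_single_gene_kernel()`: a 2x2 matrix.
#'   `build_perturbation_matrix()`: a dense `2^n x 2^n` matrix with zero
#'   diagonal. `build_perturbed_matrix()`: a dense column-stochastic matrix.
#' @examples
#' build_single_gene_kernel(0.1)
#' rowSums(build_perturbation_matrix(2, 0.1)) # both 0.19
#' @export
build_single_gene_kernel <- function(p) {
  check_p(p)
  matrix(c(1 - p, p, p, 1 - p), nrow = 2)
}

#' @rdname build_single_gene_kernel
#' @export
build_perturbation_matrix <- function(n, p) {
  check_p(p)
  if (n < 1) stop_input("`n` must be at least 1")
  if (n > 12) stop_too_large("dense perturbation matrix limited to n <= 12 (got %d)", n)
  # entrywise by Hamming distance: the Kronecker power of Q has entry
  # p^h (1-p)^(n-h) between states differing in h bits, so subtracting the
  # diagonal part (1-p)^n I leaves exactly these off-diagonal entries. This
  # is algebraically identical to the repeated Kronecker product but exact:
  # no accumulated rounding, a hard zero diagonal, and no negative residues.
  S <- 2^n
  pc <- rowSums(state_bits_matrix(n)) # popcounts of 0 .. S-1
  h <- matrix(pc[bitwXor(rep(0:(S - 1), S), rep(0:(S - 1), each = S)) + 1L], S, S)
  P <- p^h * (1 - p)^(n - h)
  diag(P) <- 0
  P
}

#' @rdname build_single_gene_kernel
#' @export
build_perturbed_matrix <- function(A, n, p) {
  check_p(p)
  A <- as.matrix(A)
  if (!all(dim(A) == 2^n)) {
    stop_input("`A` is %dx%d but n = %d requires %dx%d", nrow(A), ncol(A), n, 2^n, 2^n)
  }
  if (p == 0) {
    return(A)
  }
  (1 - p)^n * A + build_perturbation_matrix(n, p)
}

#' Perturbation threshold xi
#'
#' The probability that at least one of `n` genes flips in a step,
#' `xi = 1 - (1-p)^n`: the row sum of the perturbation matrix, used as the
#' deletion threshold in [reduce_network()].
#'
#' @inheritParams build_single_gene_kernel
#' @return A number in `[0, 1)`.
#' @export
perturbation_threshold <- function(n, p) {
  check_p(p)
  1 - (1 - p)^n
}

check_p <- function(p) {
  if (length(p) != 1L || is.na(p) || p < 0 || p >= 1) {
    stop_input("perturbation probability must lie in [0, 1)")
  }
  invisible(p)
}
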