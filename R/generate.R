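#' Random PBN generator
#'
#' Builds a PBN of `N` equiprobable constituent Boolean networks
#' (`q_j = 1/N`) over `n` internal and `m` control nodes. For each gene in
#' each constituent: the in-degree is drawn uniformly from `1..K` (so `K`
#' is a maximum in-degree), that many distinct parents are drawn uniformly
#' from the `n + m` nodes, and the truth table is drawn uniformly from all
#' `2^(2^k)` tables (constant functions can occur). The same seed yields a
#' bit-identical network.
#'
#' @param n Number of internal genes.
#' @param m Number of control nodes.
#' @param N Number of constituent networks.
#' @param K Maximum in-degree (`K <= n + m`).
#' @param p Perturbation probability attached to the network.
#' @param seed Optional integer seed; the caller's RNG state is untouched.
#' @return A [pbn()] in explicit form.
#' @examples
#' net <- generate_random_pbn(6, N = 4, K = 2, seed = 1)
#' @export
generate_random_pbn <- function(n, m = 0, N = 4, K = 2, p = 0, seed = NULL) {
  if (K > n + m) stop_input("K = %d exceeds the %d available nodes", K, n + m)
  if (N < 1) stop_input("`N` must be at least 1")
  draw <- function() {
    constituents <- lapply(seq_len(N), function(j) {
      lapply(seq_len(n), function(i) {
        k <- sample.int(K, 1L)
        parents <- sort(sample.int(n + m, k))
        boolean_function(parents, sample(0:1, 2^k, replace = TRUE))
      })
    })
    pbn_explicit(constituents, q = rep(1 / N, N), m = m, p = p, K = K)
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

# Derive independent replicate seeds from a master seed without touching
# the caller's RNG state.
replicate_seeds <- function(seed, k) {
  if (is.null(seed)) {
    return(rep(list(NULL), k))
  }
  as.list(withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max, k)))
}
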