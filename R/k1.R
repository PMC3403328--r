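#' The in-degree-one Boolean network ensemble
#'
#' When every gene is regulated by exactly one gene, each gene's update is
#' one of `2n` literal functions: copy or negate one of the `n` genes
#' (constant functions are excluded; the ensemble counts parent-polarity
#' choices only). There are therefore `(2n)^n` networks in total.
#' `enumerate_k1_bns()` lists them all in a fixed order, the last gene's
#' choice varying fastest.
#'
#' @param n Number of genes (guarded to `n <= 6` for exhaustive work).
#' @return A tibble with one row per network: `bn` (index), `parent` and
#'   `negate` (list-columns of length-`n` integer vectors).
#' @examples
#' nrow(enumerate_k1_bns(2)) # 16
#' @export
enumerate_k1_bns <- function(n) {
  k1_guard(n)
  ch <- k1_choice_matrix(n)
  tibble(
    bn = seq_len(nrow(ch)),
    parent = lapply(seq_len(nrow(ch)), function(b) as.integer((ch[b, ] + 1L) %/% 2L)),
    negate = lapply(seq_len(nrow(ch)), function(b) as.integer(ch[b, ] %% 2L == 0L))
  )
}

# (2n)^n x n matrix of choices in 1..2n; choice c = parent ceiling(c/2),
# polarity: odd = copy, even = negate. Last gene varies fastest.
k1_choice_matrix <- function(n) {
  B <- (2 * n)^n
  out <- matrix(0L, nrow = B, ncol = n)
  for (g in seq_len(n)) {
    out[, g] <- as.integer(((0:(B - 1)) %/% (2 * n)^(n - g)) %% (2 * n)) + 1L
  }
  out
}

k1_guard <- function(n) {
  if (n < 1) stop_input("`n` must be at least 1")
  if (n > 6) stop_too_large("exhaustive K = 1 enumeration limited to n <= 6 (got %d)", n)
  invisible(n)
}

#' Distribution of nonzero rows over the K = 1 ensemble
#'
#' For every in-degree-one Boolean network on `n` genes, builds the
#' deterministic one-step map on the `2^n` states and counts the states
#' with at least one predecessor (the nonzero rows of the transition
#' matrix, i.e. the image size of the map). Returns how many of the
#' `(2n)^n` networks attain each image size. Image sizes are always powers
#' of two: `2^d` where `d` is the number of distinct genes used as parents.
#'
#' @inheritParams enumerate_k1_bns
#' @param chunk_size Networks processed per block.
#' @return A tibble with columns `nonzero_rows` and `n_networks`, plus
#'   attributes `n` and `total` (`= (2n)^n`).
#' @examples
#' image_distribution(2) # 8 networks with 2 nonzero rows, 8 with 4
#' @export
image_distribution <- function(n, chunk_size = 65536L) {
  k1_guard(n)
  ch <- k1_choice_matrix(n)
  B <- nrow(ch)
  S <- 2^n
  bits_t <- t(state_bits_matrix(n)) # n x S
  counts <- integer(0)
  for (start in seq(1L, B, by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1L, B)
    C <- length(idx)
    par <- (ch[idx, , drop = FALSE] + 1L) %/% 2L
    neg <- ch[idx, , drop = FALSE] %% 2L == 0L
    nxt <- matrix(0L, nrow = C, ncol = S)
    for (g in seq_len(n)) {
      pb <- bits_t[par[, g], , drop = FALSE] # C x S parent bits
      pb[neg[, g], ] <- 1L - pb[neg[, g], ]
      nxt <- nxt * 2L + pb
    }
    # distinct next states per network, fully vectorised
    key <- (rep(seq_len(C), times = S) - 1) * S + as.vector(nxt) + 1
    imgs <- tabulate((unique(key) - 1) %/% S + 1, nbins = C)
    counts <- c(counts, imgs)
  }
  tab <- table(counts)
  out <- tibble(
    nonzero_rows = as.integer(names(tab)),
    n_networks = as.integer(tab)
  )
  attr(out, "n") <- n
  attr(out, "total") <- B
  out
}

#' Closed-form counts for the K = 1 ensemble
#'
#' `count_full_image(n)` is the number of in-degree-one networks whose
#' one-step map is a bijection on the `2^n` states (no zero row in the
#' transition matrix): the `n` genes must use `n` distinct parents (`n!`
#' arrangements) with free polarities (`2^n`), giving `n! * 2^n`.
#' `full_image_ratio(n)` is that count divided by the ensemble size
#' `(2n)^n`, i.e. `n!/n^n`; it is strictly decreasing and tends to 0, which
#' is what makes state reduction effective for large ensembles.
#'
#' @param n Number of genes.
#' @return A number.
#' @examples
#' count_full_image(2) # 8
#' full_image_ratio(3) # 6/27
#' @export
count_full_image <- function(n) {
  if (n < 1) stop_input("`n` must be at least 1")
  factorial(n) * 2^n
}

#' @rdname count_full_image
#' @export
full_image_ratio <- function(n) {
  if (any(n < 1)) stop_input("`n` must be at least 1")
  factorial(n) / n^n
}
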