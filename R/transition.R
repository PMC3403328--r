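#' Build the one-step transition matrix of a PBN
#'
#' For control value `u`, the entry `A(u)[i, j]` is the probability that the
#' internal state moves from `j` to `i` in one step: the sum of the
#' selection probabilities `q_k` of the constituent networks whose function
#' set maps state `j` (with the control bits of `u`) to state `i`. Every
#' column of `A(u)` sums to 1.
#'
#' @param x A [pbn()].
#' @param u Control value in `[1, 2^m]`.
#' @return A sparse `2^n x 2^n` column-stochastic matrix (`dgCMatrix`).
#' @examples
#' net <- pbn(list(list(
#'   boolean_function(1, c(0, 1), c = 0.6),
#'   boolean_function(1, c(1, 0), c = 0.4)
#' )))
#' build_transition_matrix(net, 1)
#' @export
build_transition_matrix <- function(x, u = 1) {
  stopifnot(inherits(x, "pbn"))
  if (length(u) != 1L || u < 1 || u > 2^x$m) {
    stop_input("control value %s out of range [1, 2^%d]", deparse(u), x$m)
  }
  ex <- as_constituents(x)
  S <- 2^ex$n
  bits <- state_bits_matrix(ex$n)
  ubits <- decode_control(u, ex$m)
  combined <- if (ex$m > 0) {
    cbind(bits, matrix(ubits, nrow = S, ncol = ex$m, byrow = TRUE))
  } else {
    bits
  }
  N <- length(ex$constituents)
  ii <- integer(0)
  xx <- numeric(0)
  for (j in seq_len(N)) {
    nxt <- next_state_map(ex$constituents[[j]], combined, ex$n)
    ii <- c(ii, nxt)
    xx <- c(xx, rep(ex$q[j], S))
  }
  A <- sparseMatrix(i = ii, j = rep(seq_len(S), N), x = xx, dims = c(S, S))
  cs <- Matrix::colSums(A)
  if (any(abs(cs - 1) > .stoch_tol)) {
    stop_model("transition matrix column sums deviate from 1 by up to %g", max(abs(cs - 1)))
  }
  A
}

# Deterministic next-state index for every row of `combined` under a single
# constituent (one boolean_function per gene). First gene = most significant.
next_state_map <- function(bn, combined, n) {
  S <- nrow(combined)
  nxt <- integer(S)
  for (g in seq_len(n)) {
    f <- bn[[g]]
    k <- length(f$parents)
    idx <- as.vector(combined[, f$parents, drop = FALSE] %*% 2^((k - 1):0))
    nxt <- nxt * 2L + f$table[idx + 1L]
  }
  nxt + 1L
}

#' Controlled transition model of a PBN
#'
#' Assembles `A(u)` for every control value `u = 1, ..., 2^m` (and, when the
#' PBN's perturbation probability is positive, the perturbed matrices
#' `Atilde(u) = (1-p)^n A(u) + P`; the same perturbation matrix applies
#' under every control).
#'
#' @param x A [pbn()].
#' @return An object of class `pbn_tm` with elements `n`, `m`, `p`,
#'   `matrices` (list over `u`) and `perturbed` (list over `u`, or `NULL`
#'   when `p = 0`).
#' @export
transition_model <- function(x) {
  stopifnot(inherits(x, "pbn"))
  U <- 2^x$m
  matrices <- lapply(seq_len(U), function(u) build_transition_matrix(x, u))
  perturbed <- NULL
  if (x$p > 0) {
    P <- build_perturbation_matrix(x$n, x$p)
    perturbed <- lapply(matrices, function(A) (1 - x$p)^x$n * as.matrix(A) + P)
  }
  structure(
    list(
      n = x$n, m = x$m, p = x$p,
      matrices = matrices, perturbed = perturbed,
      state_labels = seq_len(2^x$n)
    ),
    class = "pbn_tm"
  )
}

#' @export
print.pbn_tm <- function(x, ...) {
  cat(sprintf(
    "<pbn_tm> %d states, %d control value(s), p = %g%s\n",
    2^x$n, 2^x$m, x$p, if (is.null(x$perturbed)) "" else " (perturbed matrices attached)"
  ))
  invisible(x)
}

#' One-step reachable set F(z, u)
#'
#' The set of states the network can enter in one step from state `z` under
#' control `u`: the support of column `z` of the *unperturbed* `A(u)`
#' (entries above `1e-12`). Under the perturbed chain every state is
#' reachable from every state, so the reachable set that drives worst-case
#' control is always taken from the unperturbed dynamics.
#'
#' @param model A [transition_model()].
#' @param z State in `[1, 2^n]`.
#' @param u Control value in `[1, 2^m]`.
#' @return Increasing integer vector of states; never empty.
#' @export
reachable_set <- function(model, z, u = 1) {
  stopifnot(inherits(model, "pbn_tm"))
  if (z < 1 || z > 2^model$n) stop_input("state %d out of range", z)
  if (u < 1 || u > 2^model$m) stop_input("control %d out of range", u)
  col <- model$matrices[[u]][, z]
  out <- which(col > .support_tol)
  if (!length(out)) {
    abort(sprintf("state %d has empty successor support under control %d", z, u),
      class = "pbnred_internal"
    )
  }
  out
}

# Support lists for all (state, u) restricted to `states`; errors if any
# successor escapes `states` (an unsound reduction).
support_lists <- function(model, states) {
  U <- 2^model$m
  lookup <- integer(2^model$n)
  lookup[states] <- seq_along(states)
  lapply(seq_len(U), function(u) {
    A <- model$matrices[[u]][, states, drop = FALSE]
    lapply(seq_along(states), function(jl) {
      supp <- which(A[, jl] > .support_tol)
      loc <- lookup[supp]
      if (any(loc == 0L)) {
        abort(
          sprintf(
            "state %d reaches state(s) %s outside the supplied state set: unsound reduction",
            states[jl], paste(supp[loc == 0L], collapse = ", ")
          ),
          class = "pbnred_reduced_model_inconsistency"
        )
      }
      loc
    })
  })
}
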