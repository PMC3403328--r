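#' Boolean predictor functions
#'
#' A predictor for one gene: an ordered list of parent nodes and a truth
#' table over them. Parents are 1-based indices into the combined node
#' vector, internal nodes first (`1..n`) then control nodes (`n+1..n+m`).
#' The truth table has one entry per parent-value combination, with the
#' first listed parent as the most significant bit of the row index — the
#' same convention as the decimal state encoding.
#'
#' @param parents Integer vector of parent node indices (ordered).
#' @param table 0/1 vector of length `2^length(parents)`.
#' @param c Selection probability of this predictor within its gene's
#'   function set (in `[0, 1]`; the per-gene probabilities must sum to 1).
#' @return An object of class `pbn_function`.
#' @examples
#' boolean_function(1, c(0, 1)) # copy of node 1
#' boolean_function(1, c(1, 0)) # negation of node 1
#' boolean_function(c(2, 1), c(0, 1, 1, 0)) # XOR, node 2 most significant
#' @export
boolean_function <- function(parents, table, c = 1) {
  parents <- as.integer(parents)
  if (length(parents) < 1L || anyNA(parents) || any(parents < 1L)) {
    stop_input("`parents` must be positive node indices")
  }
  if (anyDuplicated(parents)) {
    stop_input("`parents` must be distinct")
  }
  if (length(table) != 2^length(parents)) {
    stop_input(
      "truth table has length %d but %d parents require length %d",
      length(table), length(parents), 2^length(parents)
    )
  }
  check_bits(table)
  if (length(c) != 1L || is.na(c) || c < 0 || c > 1) {
    stop_input("selection probability `c` must be a single value in [0, 1]")
  }
  structure(
    list(parents = parents, table = as.integer(table), c = as.numeric(c)),
    class = "pbn_function"
  )
}

#' @export
print.pbn_function <- function(x, ...) {
  cat(sprintf(
    "<pbn_function> parents (%s) table [%s] c = %g\n",
    paste(x$parents, collapse = ","), paste(x$table, collapse = ""), x$c
  ))
  invisible(x)
}

#' Evaluate a Boolean predictor on a network state
#'
#' Looks up the truth-table row selected by the parents' current values.
#' Parent indices above `length(internal_bits)` refer to control bits.
#'
#' @param f A [boolean_function()].
#' @param internal_bits 0/1 vector of internal node values.
#' @param control_bits 0/1 vector of control node values (may be empty).
#' @return 0 or 1.
#' @export
evaluate_function <- function(f, internal_bits, control_bits = integer(0)) {
  check_bits(internal_bits)
  check_bits(control_bits)
  combined <- c(internal_bits, control_bits)
  if (any(f$parents > length(combined))) {
    stop_input(
      "parent index %d out of range for %d internal + %d control nodes",
      max(f$parents), length(internal_bits), length(control_bits)
    )
  }
  vals <- combined[f$parents]
  k <- length(f$parents)
  f$table[[1 + sum(vals * 2^(k - seq_len(k)))]]
}

#' Probabilistic Boolean networks
#'
#' A PBN over `n` internal genes and `m` external (control) nodes, in one of
#' two equivalent representations:
#'
#' * **per-gene** (`pbn()`): each gene `i` carries a list of predictor
#'   functions with selection probabilities `c_j^(i)` summing to 1; at every
#'   step each gene independently selects one of its predictors. The
#'   constituent Boolean networks are all combinations of one predictor per
#'   gene, with selection probability equal to the product of the per-gene
#'   probabilities.
#' * **explicit** (`pbn_explicit()`): a list of `N` constituent Boolean
#'   networks (one function per gene each) with selection probabilities
#'   `q_j` summing to 1.
#'
#' `p` is the random gene perturbation probability: independently of the
#' Boolean update, each step the state is perturbed with probability
#' `1 - (1-p)^n` (see [build_perturbed_matrix()]).
#'
#' @param functions List over genes; element `i` is a list of
#'   [boolean_function()]s for gene `i`.
#' @param constituents List of `N` constituent networks; each is a list of
#'   `n` [boolean_function()]s (one per gene; their `c` slots are ignored).
#' @param q Numeric vector of `N` constituent selection probabilities.
#' @param m Number of control nodes.
#' @param p Perturbation probability in `[0, 1)`.
#' @param K Declared maximum in-degree (defaults to the largest observed).
#' @return An object of class `pbn`.
#' @examples
#' # one gene, copy itself w.p. 0.6, negate w.p. 0.4
#' net <- pbn(list(list(
#'   boolean_function(1, c(0, 1), c = 0.6),
#'   boolean_function(1, c(1, 0), c = 0.4)
#' )))
#' @export
pbn <- function(functions, m = 0, p = 0, K = NULL) {
  n <- length(functions)
  if (n < 1L) stop_input("a PBN needs at least one gene")
  for (i in seq_len(n)) {
    fl <- functions[[i]]
    if (!length(fl)) stop_input("gene %d has no predictor functions", i)
    if (!all(vapply(fl, inherits, logical(1), "pbn_function"))) {
      stop_input("gene %d: every predictor must be a boolean_function", i)
    }
    cs <- vapply(fl, `[[`, numeric(1), "c")
    if (abs(sum(cs) - 1) > 1e-8) {
      stop_model("gene %d: selection probabilities sum to %g, not 1", i, sum(cs))
    }
  }
  new_pbn(
    n = n, m = as.integer(m), p = p, K = K,
    representation = "per_gene", genes = functions
  )
}

#' @rdname pbn
#' @export
pbn_explicit <- function(constituents, q, m = 0, p = 0, K = NULL) {
  N <- length(constituents)
  if (N < 1L) stop_input("need at least one constituent network")
  if (length(q) != N) stop_input("`q` must have one entry per constituent")
  if (any(q < 0) || abs(sum(q) - 1) > 1e-8) {
    stop_model("constituent probabilities must be nonnegative and sum to 1 (got %g)", sum(q))
  }
  n <- length(constituents[[1L]])
  for (j in seq_len(N)) {
    bn <- constituents[[j]]
    if (length(bn) != n) {
      stop_input("constituent %d assigns %d functions; expected one per gene (%d)", j, length(bn), n)
    }
    if (!all(vapply(bn, inherits, logical(1), "pbn_function"))) {
      stop_input("constituent %d: every entry must be a boolean_function", j)
    }
  }
  new_pbn(
    n = n, m = as.integer(m), p = p, K = K,
    representation = "constituents", constituents = constituents, q = as.numeric(q)
  )
}

new_pbn <- function(n, m, p, K, representation, genes = NULL, constituents = NULL, q = NULL) {
  if (m < 0L) stop_input("`m` must be nonnegative")
  if (length(p) != 1L || is.na(p) || p < 0 || p >= 1) {
    stop_input("perturbation probability `p` must lie in [0, 1)")
  }
  funs <- if (representation == "per_gene") unlist(genes, recursive = FALSE) else unlist(constituents, recursive = FALSE)
  indeg <- vapply(funs, function(f) length(f$parents), integer(1))
  maxpar <- max(vapply(funs, function(f) max(f$parents), integer(1)))
  if (maxpar > n + m) {
    stop_input("a parent index %d exceeds the %d internal + %d control nodes", maxpar, n, m)
  }
  K <- if (is.null(K)) max(indeg) else as.integer(K)
  if (any(indeg > K)) {
    stop_input("a function has in-degree %d above the declared maximum K = %d", max(indeg), K)
  }
  structure(
    list(
      n = as.integer(n), m = m, p = as.numeric(p), K = K,
      representation = representation,
      genes = genes, constituents = constituents, q = q
    ),
    class = "pbn"
  )
}

#' @export
print.pbn <- function(x, ...) {
  cat(sprintf(
    "<pbn> %d internal + %d control nodes, K = %d, p = %g (%s form",
    x$n, x$m, x$K, x$p, x$representation
  ))
  if (x$representation == "constituents") {
    cat(sprintf(", N = %d constituent BNs)\n", length(x$constituents)))
  } else {
    cat(sprintf(", %s functions per gene)\n",
                paste(vapply(x$genes, length, integer(1)), collapse = "/")))
  }
  invisible(x)
}

#' Expand a PBN into its constituent Boolean networks
#'
#' For a per-gene PBN the constituents are the Cartesian product of the
#' per-gene function lists; constituent `j = (j_1, ..., j_n)` has selection
#' probability `q_j = prod_i c_{j_i}^{(i)}`. An explicit-form PBN is
#' returned unchanged.
#'
#' @param x A [pbn()].
#' @return A `pbn` in explicit (`constituents`) form, with `q` summing to 1
#'   and `N = prod_i l(i)` constituents; the enumeration varies the last
#'   gene's index fastest.
#' @export
as_constituents <- function(x) {
  stopifnot(inherits(x, "pbn"))
  if (x$representation == "constituents") {
    return(x)
  }
  l <- vapply(x$genes, length, integer(1))
  N <- prod(l)
  if (N > 1e6) stop_too_large("PBN has %g constituent networks; too many to expand", N)
  idx <- expand_indices_last_fastest(l)
  constituents <- vector("list", N)
  q <- numeric(N)
  for (j in seq_len(N)) {
    pick <- idx[j, ]
    bn <- lapply(seq_len(x$n), function(i) x$genes[[i]][[pick[i]]])
    constituents[[j]] <- bn
    q[j] <- prod(vapply(seq_len(x$n), function(i) x$genes[[i]][[pick[i]]]$c, numeric(1)))
  }
  pbn_explicit(constituents, q, m = x$m, p = x$p, K = x$K)
}

# Row j of the result gives the per-gene function choice for constituent j,
# with the last gene's choice varying fastest.
expand_indices_last_fastest <- function(l) {
  n <- length(l)
  N <- prod(l)
  out <- matrix(1L, nrow = N, ncol = n)
  rep_each <- 1L
  for (i in rev(seq_len(n))) {
    out[, i] <- rep(rep(seq_len(l[i]), each = rep_each), length.out = N)
    rep_each <- rep_each * l[i]
  }
  out
}
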