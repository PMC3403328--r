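#' Attractor states and critical states
#'
#' The recurrent states of the unperturbed dynamics: states lying in a
#' bottom (terminal) strongly connected component of the support digraph of
#' `A(u)`, unioned over all control values. For a deterministic Boolean
#' network this is the classical attractor set. The initial state `z0`, if
#' given, is added; these "critical" states are never deleted by the
#' reduction.
#'
#' @param model A [transition_model()].
#' @param z0 Optional initial state to preserve.
#' @return Increasing integer vector of states.
#' @examples
#' net <- pbn(list(list(boolean_function(1, c(1, 0))))) # 1-gene negation
#' critical_states(transition_model(net)) # the 2-cycle {1, 2}
#' @export
critical_states <- function(model, z0 = NULL) {
  stopifnot(inherits(model, "pbn_tm"))
  S <- 2^model$n
  supp <- Reduce(`|`, lapply(model$matrices, function(A) {
    as.matrix(A) > .support_tol
  }))
  # edge j -> i whenever A[i, j] > 0
  g <- igraph::graph_from_adjacency_matrix(t(supp), mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  memb <- comp$membership
  el <- igraph::as_edgelist(g, names = FALSE)
  leaving <- unique(memb[el[, 1]][memb[el[, 1]] != memb[el[, 2]]])
  bottom <- setdiff(seq_len(comp$no), leaving)
  out <- which(memb %in% bottom)
  if (!is.null(z0)) {
    if (z0 < 1 || z0 > S) stop_input("z0 = %d out of range", z0)
    out <- union(out, as.integer(z0))
  }
  sort(out)
}

#' Truncated inflow of a state
#'
#' For each control value `u`, the total one-step probability of entering
#' state `i` from the states in `kept`: `sum_{j in kept} M(u)[i, j]`, where
#' `M` is the perturbed matrix when the model carries perturbation and the
#' plain transition matrix otherwise.
#'
#' @param model A [transition_model()].
#' @param i State whose inflow is measured.
#' @param kept States still present (columns summed over).
#' @return Numeric vector with one entry per control value.
#' @export
inflow <- function(model, i, kept = seq_len(2^model$n)) {
  stopifnot(inherits(model, "pbn_tm"))
  mats <- reduction_matrices(model)
  vapply(mats, function(M) sum(M[i, kept]), numeric(1))
}

reduction_matrices <- function(model) {
  if (!is.null(model$perturbed)) model$perturbed else model$matrices
}

#' States deletable at the current truncation
#'
#' A non-critical state is deletable when its truncated inflow is at or
#' below the threshold `xi` under *every* control value; otherwise some
#' control could steer the network into a deleted state and the reduced
#' control problem would differ from the original. With `p = 0` and
#' `xi = 0` the test reduces to zero inflow: the network can never enter
#' the state from the surviving states.
#'
#' @param model A [transition_model()].
#' @param kept States currently surviving.
#' @param xi Deletion threshold; defaults to the perturbation threshold
#'   `1 - (1-p)^n` (0 when `p = 0`).
#' @param preserve States never to delete.
#' @return Increasing integer vector (possibly empty) of deletable states.
#' @export
deletable_states <- function(model, kept = seq_len(2^model$n), xi = NULL,
                             preserve = integer(0)) {
  stopifnot(inherits(model, "pbn_tm"))
  if (is.null(xi)) xi <- perturbation_threshold(model$n, model$p)
  mats <- reduction_matrices(model)
  kept <- sort(kept)
  infl <- vapply(
    mats,
    function(M) Matrix::rowSums(M[kept, kept, drop = FALSE]),
    numeric(length(kept))
  )
  if (length(kept) == 1L) infl <- matrix(infl, nrow = 1L)
  low <- rowSums(infl <= xi + .support_tol) == length(mats)
  sort(setdiff(kept[low], preserve))
}

#' Transition-probability-based state reduction
#'
#' Iteratively deletes transient states: in each round, every non-critical
#' state whose truncated inflow (row sum of the perturbed matrix over the
#' surviving columns, under every control) is at or below the threshold
#' `xi = 1 - (1-p)^n` is removed, the corresponding rows and columns are
#' dropped, and the inflows are recomputed, until no state is deletable.
#' The threshold stays fixed while the truncated sums shrink. Critical
#' states (attractors and the initial state) are always preserved.
#'
#' @param model A [transition_model()].
#' @param z0 Optional initial state, preserved along with the attractors.
#' @param xi Deletion threshold; default `1 - (1-p)^n`.
#' @param preserve States to preserve; default [critical_states()] of the
#'   model plus `z0`. Must contain the critical states if supplied.
#' @param order `"batch"` deletes all simultaneously-deletable states per
#'   round (deterministic, order-independent); `"sequential"` deletes one
#'   state at a time in ascending index, recomputing after each.
#' @param max_iterations Safety cap on deletion rounds.
#' @return An object of class `pbn_reduction`: `kept` (ordered surviving
#'   state set `R`), `deleted` (tibble with columns `state`, `iteration`),
#'   `matrices` (the `|R| x |R|` restrictions `B(u)` of the unperturbed
#'   `A(u)`), `perturbed` (restrictions of the perturbed matrices, when
#'   present), `index_map` (original state -> reduced index; 0 for deleted),
#'   `xi`, `preserve`, and `n`, `m`, `p`.
#' @examples
#' # both genes copy gene 1: states 01 and 10 are never entered
#' net <- pbn(list(
#'   list(boolean_function(1, c(0, 1))),
#'   list(boolean_function(1, c(0, 1)))
#' ))
#' reduce_network(transition_model(net), z0 = 1)$kept # 1 and 4
#' @export
reduce_network <- function(model, z0 = NULL, xi = NULL, preserve = NULL,
                           order = c("batch", "sequential"),
                           max_iterations = 2^model$n + 1L) {
  stopifnot(inherits(model, "pbn_tm"))
  order <- match.arg(order)
  S <- 2^model$n
  if (is.null(xi)) xi <- perturbation_threshold(model$n, model$p)
  if (xi < 0) stop_input("`xi` must be nonnegative")
  if (is.null(preserve)) preserve <- critical_states(model, z0)
  preserve <- sort(unique(as.integer(c(preserve, z0))))
  if (length(preserve) && (min(preserve) < 1 || max(preserve) > S)) {
    stop_input("`preserve` contains states outside [1, %d]", S)
  }
  kept <- seq_len(S)
  deleted_state <- integer(0)
  deleted_iter <- integer(0)
  iter <- 0L
  repeat {
    del <- deletable_states(model, kept, xi = xi, preserve = preserve)
    if (!length(del)) break
    iter <- iter + 1L
    if (iter > max_iterations) {
      abort("state reduction failed to terminate", class = "pbnred_nontermination")
    }
    if (order == "sequential") del <- del[1L]
    kept <- setdiff(kept, del)
    deleted_state <- c(deleted_state, del)
    deleted_iter <- c(deleted_iter, rep(iter, length(del)))
  }
  kept <- sort(kept)
  index_map <- integer(S)
  index_map[kept] <- seq_along(kept)
  matrices <- lapply(model$matrices, function(A) A[kept, kept, drop = FALSE])
  perturbed <- if (!is.null(model$perturbed)) {
    lapply(model$perturbed, function(M) M[kept, kept, drop = FALSE])
  }
  structure(
    list(
      kept = kept,
      deleted = tibble(state = deleted_state, iteration = deleted_iter),
      matrices = matrices, perturbed = perturbed,
      index_map = index_map, xi = xi, preserve = preserve,
      n = model$n, m = model$m, p = model$p, iterations = iter
    ),
    class = "pbn_reduction"
  )
}

#' @export
print.pbn_reduction <- function(x, ...) {
  cat(sprintf(
    "<pbn_reduction> %d of %d states kept (%.1f%% deleted in %d round(s), xi = %g)\n",
    length(x$kept), 2^x$n, reduction_rate(x), x$iterations, x$xi
  ))
  invisible(x)
}

#' Percentage of states deleted by a reduction
#'
#' @param result A [reduce_network()] result.
#' @return `100 * (2^n - |R|) / 2^n`.
#' @export
reduction_rate <- function(result) {
  stopifnot(inherits(result, "pbn_reduction"))
  S <- 2^result$n
  100 * (S - length(result$kept)) / S
}

#' @export
tidy.pbn_reduction <- function(x, ...) {
  dplyr::arrange(x$deleted, .data$iteration, .data$state)
}

#' @export
glance.pbn_reduction <- function(x, ...) {
  tibble(
    n_states = 2^x$n,
    n_kept = length(x$kept),
    n_deleted = nrow(x$deleted),
    rate = reduction_rate(x),
    iterations = x$iterations,
    xi = x$xi
  )
}

#' @export
autoplot.pbn_reduction <- function(object, ...) {
  S <- 2^object$n
  trace <- tidy(object)
  counts <- dplyr::count(trace, .data$iteration)
  df <- tibble(
    iteration = c(0L, counts$iteration),
    kept = S - cumsum(c(0L, counts$n))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$kept)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "deletion round", y = "surviving states",
      title = sprintf("State reduction: %d of %d states kept", length(object$kept), S)
    )
}
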