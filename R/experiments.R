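#' State-reduction experiment on random PBNs
#'
#' Replicates the random-ensemble reduction study: for each replicate,
#' generate a random PBN (equiprobable constituents), build its transition
#' matrix, attach the perturbation model, reduce with the threshold
#' `xi = 1 - (1-p)^n`, and record the percentage of states deleted.
#'
#' @param n Number of genes.
#' @param N Number of constituent networks.
#' @param K Maximum in-degree.
#' @param p Perturbation probability.
#' @param replicates Number of random networks.
#' @param seed Optional master seed; each replicate's derived seed is
#'   reported so any row can be replayed in isolation.
#' @return A tibble with one row per replicate (`replicate`, `seed`,
#'   `n_states`, `n_kept`, `rate`) of class `pbn_experiment`; `glance()`
#'   gives the means.
#' @export
run_reduction_experiment <- function(n = 6, N = 4, K = 2, p = 0.01,
                                     replicates = 10, seed = NULL) {
  seeds <- replicate_seeds(seed, replicates)
  rows <- purrr::map_dfr(seq_len(replicates), function(r) {
    net <- generate_random_pbn(n, m = 0, N = N, K = K, p = p, seed = seeds[[r]])
    red <- reduce_network(transition_model(net))
    tibble(
      replicate = r,
      seed = if (is.null(seeds[[r]])) NA_integer_ else seeds[[r]],
      n_states = 2^n,
      n_kept = length(red$kept),
      rate = reduction_rate(red)
    )
  })
  structure(rows, class = c("pbn_experiment", class(rows)),
            params = list(n = n, N = N, K = K, p = p))
}

#' @export
glance.pbn_experiment <- function(x, ...) {
  pars <- attr(x, "params")
  out <- dplyr::summarise(
    as_tibble(x),
    replicates = dplyr::n(),
    dplyr::across(dplyr::any_of(c(
      "n_kept", "rate", "size_reduced", "value_original", "value_reduced",
      "time_original", "time_reduced"
    )), mean),
    equal_all = if ("equal" %in% names(x)) all(.data$equal) else NA
  )
  dplyr::bind_cols(as_tibble(pars), out)
}

#' Minimax-control experiment on random PBNs
#'
#' Replicates the controlled study design: a network of `n` total nodes of
#' which `m` are controls (`n - m` internal genes, so the state space has
#' `2^(n-m)` states), horizon `M`, terminal cost `C(z) = z`. Each replicate
#' generates a random PBN, reduces it, solves the minimax problem on both
#' the original and the reduced state space and records both values; the
#' two agree whenever the reduction is sound.
#'
#' @param n Total number of nodes (internal + control).
#' @param m Number of control nodes.
#' @inheritParams run_reduction_experiment
#' @param M Horizon.
#' @param z0 Initial state.
#' @return A tibble of class `pbn_experiment`, one row per replicate, with
#'   the sizes, both minimax values, the equality flag and wall times.
#' @export
run_control_experiment <- function(n = 6, m = 1, N = 4, K = 2, p = 0,
                                   M = 20, z0 = 1, replicates = 10, seed = NULL) {
  if (m < 1 || m >= n) stop_input("need 1 <= m < n (got m = %d, n = %d)", m, n)
  seeds <- replicate_seeds(seed, replicates)
  rows <- purrr::map_dfr(seq_len(replicates), function(r) {
    net <- generate_random_pbn(n - m, m = m, N = N, K = K, p = p, seed = seeds[[r]])
    rep_row <- compare_original_reduced(net, M = M, z0 = z0)
    dplyr::bind_cols(
      tibble(
        replicate = r,
        seed = if (is.null(seeds[[r]])) NA_integer_ else seeds[[r]]
      ),
      rep_row
    )
  })
  structure(rows, class = c("pbn_experiment", class(rows)),
            params = list(n = n, m = m, N = N, K = K, p = p, M = M))
}

#' @export
autoplot.pbn_experiment <- function(object, ...) {
  df <- as_tibble(object)
  if ("rate" %in% names(df)) {
    ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$replicate), y = .data$rate)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = "replicate", y = "% states deleted", title = "Reduction rates")
  } else {
    long <- tidyr_pivot(df)
    ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$replicate), y = .data$value,
                                       fill = .data$network)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(x = "replicate", y = "minimax cost", title = "Original vs reduced")
  }
}

# small reshape helper (avoids importing tidyr for one call)
tidyr_pivot <- function(df) {
  dplyr::bind_rows(
    tibble(replicate = df$replicate, network = "original", value = df$value_original),
    tibble(replicate = df$replicate, network = "reduced", value = df$value_reduced)
  )
}
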