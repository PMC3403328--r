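#' Read and write PBNs as JSON
#'
#' The on-disk format mirrors the two in-memory representations. Top level:
#' `n`, `m`, `K`, `p`, `representation` (`"per_gene"` or `"constituents"`)
#' and either `genes` — a list (one entry per gene) of predictor objects
#' `{parents, table, c}` — or `constituents` — a list of
#' `{q, functions: [{parents, table}, ...]}`. A machine-readable schema
#' ships with the package (`system.file("extdata", "pbn-schema.json",
#' package = "pbnred")`). Files are validated on load and violations are
#' reported with their JSON path.
#'
#' @param x A [pbn()].
#' @param path File path.
#' @return `read_pbn()` returns a [pbn()]; `write_pbn()` returns `path`
#'   invisibly. The round trip is lossless.
#' @export
write_pbn <- function(x, path) {
  stopifnot(inherits(x, "pbn"))
  fun_json <- function(f, with_c = TRUE) {
    out <- list(parents = f$parents, table = f$table)
    if (with_c) out$c <- f$c
    out
  }
  doc <- list(n = x$n, m = x$m, K = x$K, p = x$p, representation = x$representation)
  if (x$representation == "per_gene") {
    doc$genes <- lapply(x$genes, function(fl) lapply(fl, fun_json))
  } else {
    doc$constituents <- lapply(seq_along(x$constituents), function(j) {
      list(
        q = x$q[j],
        functions = lapply(x$constituents[[j]], fun_json, with_c = FALSE)
      )
    })
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_pbn
#' @export
read_pbn <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  bad <- function(where, msg, ...) {
    abort(sprintf("invalid PBN file at %s: %s", where, sprintf(msg, ...)),
      class = "pbnred_parse_error"
    )
  }
  need_int <- function(v, where, min = 0) {
    if (is.null(v) || length(v) != 1 || !is.numeric(v) || v != as.integer(v) || v < min) {
      bad(where, "expected an integer >= %d", min)
    }
    as.integer(v)
  }
  n <- need_int(doc$n, "$.n", min = 1)
  m <- need_int(doc$m, "$.m", min = 0)
  K <- need_int(doc$K, "$.K", min = 1)
  p <- doc$p
  if (is.null(p) || !is.numeric(p) || p < 0 || p >= 1) bad("$.p", "expected a number in [0, 1)")
  repres <- doc$representation
  if (!identical(repres, "per_gene") && !identical(repres, "constituents")) {
    bad("$.representation", "must be \"per_gene\" or \"constituents\"")
  }
  parse_fun <- function(obj, where, with_c) {
    parents <- unlist(obj$parents)
    table <- unlist(obj$table)
    if (is.null(parents) || !length(parents)) bad(paste0(where, ".parents"), "missing or empty")
    if (any(parents > n + m)) bad(paste0(where, ".parents"), "index beyond %d nodes", n + m)
    if (is.null(table)) bad(paste0(where, ".table"), "missing")
    if (length(table) != 2^length(parents)) {
      bad(
        paste0(where, ".table"), "length %d does not match %d parents (need %d)",
        length(table), length(parents), 2^length(parents)
      )
    }
    if (!all(table %in% c(0, 1))) bad(paste0(where, ".table"), "entries must be 0/1")
    if (length(parents) > K) bad(paste0(where, ".parents"), "in-degree exceeds K = %d", K)
    cc <- if (with_c) {
      if (is.null(obj$c) || !is.numeric(obj$c)) bad(paste0(where, ".c"), "missing selection probability")
      obj$c
    } else {
      1
    }
    boolean_function(parents, table, c = cc)
  }
  if (repres == "per_gene") {
    if (is.null(doc$genes) || length(doc$genes) != n) {
      bad("$.genes", "expected a list of %d genes", n)
    }
    genes <- lapply(seq_len(n), function(i) {
      fl <- doc$genes[[i]]
      if (!length(fl)) bad(sprintf("$.genes[%d]", i), "gene has no functions")
      lapply(seq_along(fl), function(j) {
        parse_fun(fl[[j]], sprintf("$.genes[%d][%d]", i, j), with_c = TRUE)
      })
    })
    pbn(genes, m = m, p = p, K = K)
  } else {
    if (is.null(doc$constituents) || !length(doc$constituents)) {
      bad("$.constituents", "expected a nonempty list")
    }
    q <- numeric(0)
    constituents <- lapply(seq_along(doc$constituents), function(j) {
      cj <- doc$constituents[[j]]
      where <- sprintf("$.constituents[%d]", j)
      if (is.null(cj$q) || !is.numeric(cj$q)) bad(paste0(where, ".q"), "missing probability")
      q[j] <<- cj$q
      if (is.null(cj$functions) || length(cj$functions) != n) {
        bad(paste0(where, ".functions"), "expected one function per gene (%d)", n)
      }
      lapply(seq_len(n), function(i) {
        parse_fun(cj$functions[[i]], sprintf("%s.functions[%d]", where, i), with_c = FALSE)
      })
    })
    pbn_explicit(constituents, q, m = m, p = p, K = K)
  }
}

#' Export transition matrices in MatrixMarket format
#'
#' Writes one coordinate-format `.mtx` file (1-based indices) per control
#' value: `A_u1.mtx`, `A_u2.mtx`, ... and, when requested and available,
#' the perturbed matrices as `Atilde_u<u>.mtx`.
#'
#' @param model A [transition_model()].
#' @param dir Output directory (created if needed).
#' @param perturbed Also write the perturbed matrices, if present.
#' @return Character vector of the files written, invisibly.
#' @export
write_transition_matrices <- function(model, dir, perturbed = FALSE) {
  stopifnot(inherits(model, "pbn_tm"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  for (u in seq_along(model$matrices)) {
    f <- file.path(dir, sprintf("A_u%d.mtx", u))
    Matrix::writeMM(methods::as(model$matrices[[u]], "CsparseMatrix"), f)
    files <- c(files, f)
  }
  if (perturbed && !is.null(model$perturbed)) {
    for (u in seq_along(model$perturbed)) {
      f <- file.path(dir, sprintf("Atilde_u%d.mtx", u))
      Matrix::writeMM(methods::as(Matrix(model$perturbed[[u]], sparse = TRUE), "CsparseMatrix"), f)
      files <- c(files, f)
    }
  }
  invisible(files)
}
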