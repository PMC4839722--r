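#' Expression matrix container
#'
#' A `coex_expr` is a tibble whose first column `gene` holds gene identifiers
#' and whose remaining columns are numeric per-sample expression values. Two
#' attributes track provenance: `level` ("single_cell" or "bulk") and `state`,
#' the processing state, which may only advance along
#' `raw_rpkm -> log2 -> centered -> quantile_normalized`.
#'
#' @param values numeric matrix (genes x samples, rownames = gene IDs) or a
#'   data frame with a `gene` column followed by numeric sample columns.
#' @param level `"single_cell"` or `"bulk"`.
#' @param state processing state of the values.
#' @return a `coex_expr` tibble.
#' @export
expression_matrix <- function(values,
                              level = c("single_cell", "bulk"),
                              state = c("raw_rpkm", "log2", "centered",
                                        "quantile_normalized")) {
  level <- match.arg(level)
  state <- match.arg(state)
  if (is.matrix(values)) {
    if (is.null(rownames(values))) {
      stop("matrix input must carry gene IDs as rownames", call. = FALSE)
    }
    tb <- tibble::as_tibble(values, rownames = "gene")
  } else {
    tb <- tibble::as_tibble(values)
    if (names(tb)[1] != "gene") {
      stop("first column must be named 'gene'", call. = FALSE)
    }
  }
  new_coex_expr(tb, level, state, validate = TRUE)
}

new_coex_expr <- function(tb, level, state, validate = FALSE) {
  if (validate) {
    if (anyDuplicated(tb$gene)) stop("duplicate gene IDs", call. = FALSE)
    if (anyDuplicated(names(tb))) stop("duplicate sample IDs", call. = FALSE)
    vals <- as.matrix(tb[, -1, drop = FALSE])
    if (!is.numeric(vals)) stop("sample columns must be numeric", call. = FALSE)
    if (state == "raw_rpkm" && any(vals < 0, na.rm = TRUE)) {
      stop("raw RPKM values must be non-negative", call. = FALSE)
    }
  }
  structure(tb,
            class = c("coex_expr", class(tibble::tibble())),
            level = level, state = state)
}

#' @export
print.coex_expr <- function(x, ...) {
  cat(sprintf("<coex_expr: %d genes x %d samples, level=%s, state=%s>\n",
              nrow(x), ncol(x) - 1L, expr_level(x), expr_state(x)))
  NextMethod()
}

#' Accessors for `coex_expr` objects
#'
#' `expr_values()` returns the genes x samples numeric matrix, `expr_genes()`
#' and `expr_samples()` the identifier vectors, `expr_level()` and
#' `expr_state()` the provenance attributes.
#'
#' @param m a `coex_expr`.
#' @return matrix or character vector as described.
#' @export
expr_values <- function(m) {
  v <- as.matrix(as.data.frame(m)[, -1, drop = FALSE])
  rownames(v) <- m$gene
  v
}

#' @rdname expr_values
#' @export
expr_genes <- function(m) m$gene

#' @rdname expr_values
#' @export
expr_samples <- function(m) names(m)[-1]

#' @rdname expr_values
#' @export
expr_level <- function(m) attr(m, "level")

#' @rdname expr_values
#' @export
expr_state <- function(m) attr(m, "state")

.state_order <- c(raw_rpkm = 1L, log2 = 2L, centered = 3L,
                  quantile_normalized = 4L)

check_expr <- function(m, state = NULL, level = NULL, arg = "m") {
  if (!inherits(m, "coex_expr")) {
    stop(sprintf("`%s` must be a coex_expr (see expression_matrix())", arg),
         call. = FALSE)
  }
  if (!is.null(state) && !expr_state(m) %in% state) {
    stop(sprintf("`%s` must be in state %s, got '%s'", arg,
                 paste(state, collapse = "/"), expr_state(m)), call. = FALSE)
  }
  if (!is.null(level) && !expr_level(m) %in% level) {
    stop(sprintf("`%s` must be at level %s, got '%s'", arg,
                 paste(level, collapse = "/"), expr_level(m)), call. = FALSE)
  }
  invisible(m)
}

advance_state <- function(m, new_state) {
  if (.state_order[new_state] != .state_order[expr_state(m)] + 1L) {
    stop(sprintf("invalid state transition %s -> %s",
                 expr_state(m), new_state), call. = FALSE)
  }
  attr(m, "state") <- new_state
  m
}

replace_values <- function(m, vals) {
  tb <- tibble::as_tibble(vals, rownames = NA)
  tb <- tibble::tibble(gene = rownames(vals), tb)
  names(tb) <- c("gene", colnames(vals))
  new_coex_expr(tb, expr_level(m), expr_state(m))
}

#' Read / write expression matrices as TSV
#'
#' Rows are genes; the first column (`gene`) holds gene IDs and the header the
#' sample IDs. `write_expression_tsv()` also writes a `<path>.json` sidecar
#' recording `level` and `state` so a round trip preserves provenance;
#' `read_expression_tsv()` uses the sidecar when present unless `level`/`state`
#' are given explicitly.
#'
#' @param path TSV file path.
#' @param level,state override provenance (required if no sidecar exists).
#' @param m a `coex_expr` to write.
#' @return `read_expression_tsv()` a `coex_expr`; `write_expression_tsv()` the
#'   input, invisibly.
#' @export
read_expression_tsv <- function(path, level = NULL, state = NULL) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(tb)[1] <- "gene"
  sidecar <- paste0(path, ".json")
  if ((is.null(level) || is.null(state)) && file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    level <- level %||% meta$level
    state <- state %||% meta$state
  }
  if (is.null(level) || is.null(state)) {
    stop("no sidecar metadata found; supply `level` and `state`", call. = FALSE)
  }
  new_coex_expr(tb, level, state, validate = TRUE)
}

#' @rdname read_expression_tsv
#' @export
write_expression_tsv <- function(m, path) {
  check_expr(m)
  readr::write_tsv(as.data.frame(m), path, progress = FALSE)
  jsonlite::write_json(list(level = expr_level(m), state = expr_state(m)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
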