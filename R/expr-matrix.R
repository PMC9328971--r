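#' Expression matrix container
#'
#' A thin genes-by-samples container for linear-scale, non-negative
#' expression values (FPKM/TPM-like), with an optional per-sample
#' tumor/normal condition label. All downstream pair encoding is invariant
#' to any strictly increasing per-sample transform of these values, so no
#' particular normalisation is assumed.
#'
#' @param values Numeric matrix, genes in rows (unique rownames), samples in
#'   columns (unique colnames). All values must be finite and `>= 0`.
#' @param condition Optional character/factor vector of per-sample labels in
#'   `c("tumor", "normal")`. Either unnamed and in column order, or named by
#'   sample id.
#' @return An object of class `expr_matrix`.
#' @examples
#' m <- matrix(1:6, nrow = 3, dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' expr_matrix(m, condition = c("tumor", "normal"))
#' @export
expr_matrix <- function(values, condition = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must have gene rownames and sample colnames.")
  }
  if (anyDuplicated(rownames(values))) {
    abort("duplicate gene ids in expression matrix.")
  }
  if (anyDuplicated(colnames(values))) {
    abort("duplicate sample ids in expression matrix.")
  }
  if (any(!is.finite(values))) abort("expression values must be finite.")
  if (any(values < 0)) abort("expression values must be >= 0.")
  if (!is.null(condition)) {
    condition <- as.character(condition)
    if (!is.null(names(condition))) {
      missing <- setdiff(colnames(values), names(condition))
      if (length(missing) > 0) {
        abort(paste0("condition missing for sample(s): ",
                     paste(head(missing, 5), collapse = ", ")))
      }
      condition <- condition[colnames(values)]
    } else if (length(condition) != ncol(values)) {
      abort("`condition` must have one label per sample.")
    }
    bad <- setdiff(unique(condition), c("tumor", "normal"))
    if (length(bad) > 0) {
      abort(paste0("condition labels must be 'tumor' or 'normal', got: ",
                   paste(bad, collapse = ", ")))
    }
    names(condition) <- colnames(values)
  }
  structure(list(values = values, condition = condition),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$condition)) {
    tab <- table(x$condition)
    cat("  condition:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  } else {
    cat("  condition: <none>\n")
  }
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Gene and sample ids of an expression matrix
#' @param x An `expr_matrix`.
#' @return Character vector of ids.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Subset an expression matrix by genes and/or samples
#'
#' @param x An `expr_matrix`.
#' @param genes,samples Character vectors of ids to keep (default: all).
#' @return An `expr_matrix`.
#' @export
subset_expr <- function(x, genes = NULL, samples = NULL) {
  genes <- genes %||% gene_ids(x)
  samples <- samples %||% sample_ids(x)
  missing_g <- setdiff(genes, gene_ids(x))
  if (length(missing_g) > 0) {
    abort(paste0("unknown gene id(s): ", paste(head(missing_g, 5), collapse = ", ")))
  }
  missing_s <- setdiff(samples, sample_ids(x))
  if (length(missing_s) > 0) {
    abort(paste0("unknown sample id(s): ", paste(head(missing_s, 5), collapse = ", ")))
  }
  expr_matrix(x$values[genes, samples, drop = FALSE],
              condition = if (!is.null(x$condition)) x$condition[samples])
}

#' Tumor-only view of an expression matrix
#' @param x An `expr_matrix` with condition labels.
#' @return An `expr_matrix` restricted to tumor samples.
#' @export
tumor_samples <- function(x) {
  if (is.null(x$condition)) abort("expression matrix has no condition labels.")
  subset_expr(x, samples = sample_ids(x)[x$condition == "tumor"])
}

#' @export
as_tibble.expr_matrix <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "sample_id",
                        values_to = "expression") |>
    dplyr::left_join(
      tibble::tibble(sample_id = sample_ids(x),
                     condition = if (is.null(x$condition)) NA_character_
                                 else unname(x$condition)),
      by = "sample_id"
    )
}

# log2(x + 1); the scale on which correlations are computed
log2p1 <- function(x) log2(x + 1)
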