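#' Build the within-sample 0/1 pair indicator matrix
#'
#' For every unordered pair of candidate genes, each sample is scored 1
#' when the first gene's expression is greater than or equal to the second
#' gene's (ties score 1), and 0 when it is strictly lower. Pairs are stored
#' in the canonical orientation `gene_a < gene_b` (lexicographic), so the
#' encoding — and everything fitted on it — is fully reproducible and
#' invariant to any strictly increasing per-sample transformation of the
#' expression values.
#'
#' @param expr An [expr_matrix()].
#' @param gene_ids Character vector (or `gene_set`) of candidate genes,
#'   typically the differentially expressed ferroptosis-related lncRNAs.
#'   At least 2, all present in `expr`.
#' @return A `pair_matrix`: list with `pairs` (tibble `pair_id`, `gene_a`,
#'   `gene_b`, `frequency`) and `indicators` (pairs x samples 0/1 integer
#'   matrix, rownames `GENEA|GENEB`).
#' @examples
#' m <- matrix(c(1, 9, 2, 8, 3, 7), nrow = 3, byrow = TRUE,
#'             dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' build_pair_matrix(expr_matrix(m), c("A", "B", "C"))
#' @export
build_pair_matrix <- function(expr, gene_ids) {
  if (inherits(gene_ids, "gene_set")) gene_ids <- gene_ids$members
  gene_ids <- unique(as.character(gene_ids))
  if (length(gene_ids) < 2) abort("need >= 2 genes to form pairs.")
  unknown <- setdiff(gene_ids, rownames(expr$values))
  if (length(unknown) > 0) {
    abort(paste0("unknown gene id(s): ", paste(head(unknown, 5), collapse = ", ")))
  }
  genes <- sort(gene_ids)
  v <- expr$values[genes, , drop = FALSE]
  idx <- combn(length(genes), 2)
  gene_a <- genes[idx[1, ]]
  gene_b <- genes[idx[2, ]]
  ind <- (v[idx[1, ], , drop = FALSE] >= v[idx[2, ], , drop = FALSE]) * 1L
  storage.mode(ind) <- "integer"
  rownames(ind) <- paste(gene_a, gene_b, sep = "|")
  colnames(ind) <- colnames(v)
  new_pair_matrix(ind)
}

# internal constructor from an indicator matrix with `A|B` rownames
new_pair_matrix <- function(ind) {
  if (any(!ind %in% c(0L, 1L))) abort("indicators must be 0/1.")
  parts <- strsplit(rownames(ind), "|", fixed = TRUE)
  pairs <- tibble(
    pair_id = rownames(ind),
    gene_a = vapply(parts, `[[`, character(1), 1L),
    gene_b = vapply(parts, `[[`, character(1), 2L),
    frequency = unname(rowMeans(ind))
  )
  structure(list(pairs = pairs, indicators = ind), class = "pair_matrix")
}

#' @export
print.pair_matrix <- function(x, ...) {
  cat(sprintf("<pair_matrix> %d pairs x %d samples\n",
              nrow(x$indicators), ncol(x$indicators)))
  invisible(x)
}

#' @export
dim.pair_matrix <- function(x) dim(x$indicators)

#' @export
as_tibble.pair_matrix <- function(x, ...) x$pairs

#' Drop pairs with a near-constant indicator
#'
#' Pairs whose indicator is 0 (or 1) in almost every sample carry no
#' class information for prognosis. Only pairs whose indicator frequency
#' lies strictly inside `(low, high)` are retained; frequencies exactly at
#' a bound are removed. The retained/removed counts are attached as the
#' `filter_counts` attribute.
#'
#' @param pm A `pair_matrix`.
#' @param low,high Frequency bounds, default 0.20 and 0.80.
#' @return A filtered `pair_matrix`.
#' @export
filter_pairs <- function(pm, low = 0.20, high = 0.80) {
  if (low >= high) abort("`low` must be smaller than `high`.")
  keep <- pm$pairs$frequency > low & pm$pairs$frequency < high
  out <- new_pair_matrix(pm$indicators[keep, , drop = FALSE])
  attr(out, "filter_counts") <- c(retained = sum(keep), removed = sum(!keep))
  out
}

#' Subset a pair matrix to named pairs
#' @param pm A `pair_matrix`.
#' @param pair_ids Character vector of `GENEA|GENEB` ids to keep.
#' @return A `pair_matrix`.
#' @export
subset_pairs <- function(pm, pair_ids) {
  unknown <- setdiff(pair_ids, rownames(pm$indicators))
  if (length(unknown) > 0) {
    abort(paste0("unknown pair id(s): ", paste(head(unknown, 5), collapse = ", ")))
  }
  new_pair_matrix(pm$indicators[pair_ids, , drop = FALSE])
}
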