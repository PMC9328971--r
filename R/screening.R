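#' Coexpression screen of lncRNAs against ferroptosis-related genes
#'
#' Pearson correlation between every candidate lncRNA and every
#' ferroptosis-related gene (FRG), computed on `log2(x + 1)` values across
#' all samples. The p-value comes from the usual t transform of r with
#' `n - 2` degrees of freedom. A lncRNA is flagged ferroptosis-related
#' (FRlncRNA) when it has at least one FRG partner with `r > r_min` and
#' `p < p_max`. Correlation is signed by default (positive coexpression
#' only); set `absolute_r = TRUE` to screen on `|r|`. Constant-expression
#' genes have no defined correlation and are skipped with a warning.
#'
#' @param expr An [expr_matrix()] with at least 3 samples.
#' @param lnc_ids,frg_ids Disjoint, non-empty gene id sets present in `expr`.
#' @param r_min Correlation threshold (default 0.4).
#' @param p_max p-value threshold (default 0.001), unadjusted.
#' @param absolute_r Screen on `|r|` instead of signed `r`.
#' @return A tibble of class `coexpression_result` with columns `lncRNA`,
#'   `frg`, `r`, `p`, `passes`. The selected lncRNA ids are in
#'   `attr(, "selected")` and via [selected_genes()].
#' @export
pearson_screen <- function(expr, lnc_ids, frg_ids,
                           r_min = 0.4, p_max = 0.001, absolute_r = FALSE) {
  if (inherits(lnc_ids, "gene_set")) lnc_ids <- lnc_ids$members
  if (inherits(frg_ids, "gene_set")) frg_ids <- frg_ids$members
  lnc_ids <- unique(as.character(lnc_ids))
  frg_ids <- unique(as.character(frg_ids))
  if (length(lnc_ids) == 0 || length(frg_ids) == 0) {
    abort("lnc_ids and frg_ids must be non-empty.")
  }
  if (length(intersect(lnc_ids, frg_ids)) > 0) {
    abort("lnc_ids and frg_ids must be disjoint.")
  }
  n <- ncol(expr$values)
  if (n < 3) abort("need >= 3 samples for the correlation screen.")
  unknown <- setdiff(c(lnc_ids, frg_ids), rownames(expr$values))
  if (length(unknown) > 0) {
    abort(paste0("unknown gene id(s): ", paste(head(unknown, 5), collapse = ", ")))
  }
  lv <- log2p1(t(expr$values[lnc_ids, , drop = FALSE]))
  fv <- log2p1(t(expr$values[frg_ids, , drop = FALSE]))
  const_l <- lnc_ids[apply(lv, 2, function(x) diff(range(x)) == 0)]
  const_f <- frg_ids[apply(fv, 2, function(x) diff(range(x)) == 0)]
  if (length(const_l) + length(const_f) > 0) {
    warn(paste0("skipping ", length(const_l) + length(const_f),
                " constant-expression gene(s): ",
                paste(head(c(const_l, const_f), 5), collapse = ", ")))
    lnc_ids <- setdiff(lnc_ids, const_l)
    frg_ids <- setdiff(frg_ids, const_f)
    lv <- lv[, lnc_ids, drop = FALSE]
    fv <- fv[, frg_ids, drop = FALSE]
  }
  rmat <- cor(lv, fv)
  # guard |r| slightly below 1 so the t transform stays finite
  tstat <- rmat * sqrt((n - 2) / pmax(1 - rmat^2, .Machine$double.eps))
  pmat <- 2 * pt(-abs(tstat), df = n - 2)
  res <- tibble(
    lncRNA = rep(lnc_ids, times = length(frg_ids)),
    frg = rep(frg_ids, each = length(lnc_ids)),
    r = as.vector(rmat),
    p = as.vector(pmat)
  )
  rr <- if (absolute_r) abs(res$r) else res$r
  res$passes <- rr > r_min & res$p < p_max
  res <- structure(res, class = c("coexpression_result", class(res)))
  attr(res, "selected") <- sort(unique(res$lncRNA[res$passes]))
  res
}

#' Genes selected by a screening step
#' @param x A `coexpression_result` or `differential_result`.
#' @return Character vector of selected gene ids.
#' @export
selected_genes <- function(x) attr(x, "selected")

#' Tumor-versus-normal differential expression
#'
#' Per-gene two-sided Wilcoxon rank-sum test of tumor versus normal
#' samples, with the fold change computed on linear-scale group means with
#' a pseudocount of 1: `log2FC = log2((mean_tumor + 1) / (mean_normal + 1))`.
#' p-values are adjusted with Benjamini-Hochberg ([bh_adjust()]); a gene is
#' differentially expressed when `q < fdr_max` and `|log2FC| >= lfc_min`.
#'
#' @param expr An [expr_matrix()] with condition labels; each condition
#'   needs >= 2 samples.
#' @param gene_ids Genes to test (default: all). May be empty, giving an
#'   empty result.
#' @param fdr_max FDR threshold (default 0.05).
#' @param lfc_min Absolute log2 fold-change threshold (default 1.5).
#' @return A tibble of class `differential_result` with columns `gene_id`,
#'   `log2fc`, `p`, `q`, `direction`, `de`; selected ids in
#'   `attr(, "selected")`.
#' @export
differential_expression <- function(expr, gene_ids = NULL,
                                    fdr_max = 0.05, lfc_min = 1.5) {
  if (is.null(expr$condition)) abort("expression matrix has no condition labels.")
  if (inherits(gene_ids, "gene_set")) gene_ids <- gene_ids$members
  gene_ids <- if (is.null(gene_ids)) rownames(expr$values)
              else unique(as.character(gene_ids))
  is_tumor <- expr$condition == "tumor"
  if (sum(is_tumor) < 2 || sum(!is_tumor) < 2) {
    abort("each condition needs >= 2 samples.")
  }
  if (length(gene_ids) == 0) {
    res <- tibble(gene_id = character(), log2fc = double(), p = double(),
                  q = double(), direction = character(), de = logical())
    res <- structure(res, class = c("differential_result", class(res)))
    attr(res, "selected") <- character()
    return(res)
  }
  unknown <- setdiff(gene_ids, rownames(expr$values))
  if (length(unknown) > 0) {
    abort(paste0("unknown gene id(s): ", paste(head(unknown, 5), collapse = ", ")))
  }
  vt <- expr$values[gene_ids, is_tumor, drop = FALSE]
  vn <- expr$values[gene_ids, !is_tumor, drop = FALSE]
  log2fc <- log2((rowMeans(vt) + 1) / (rowMeans(vn) + 1))
  p <- vapply(seq_along(gene_ids), function(i) {
    suppressWarnings(wilcox.test(vt[i, ], vn[i, ])$p.value)
  }, double(1))
  p[is.na(p)] <- 1  # fully tied groups carry no evidence
  q <- bh_adjust(p)
  res <- tibble(
    gene_id = gene_ids,
    log2fc = unname(log2fc),
    p = p,
    q = q,
    direction = dplyr::case_when(log2fc > 0 ~ "up",
                                 log2fc < 0 ~ "down",
                                 TRUE ~ "none"),
    de = q < fdr_max & abs(log2fc) >= lfc_min
  )
  res <- structure(res, class = c("differential_result", class(res)))
  attr(res, "selected") <- res$gene_id[res$de]
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment:
#' `q_i = min_{j: p_(j) >= p_(i)} m * p_(j) / j`, clipped at 1, returned in
#' the input order.
#'
#' @param pvals Numeric vector of p-values in `(0, 1]`.
#' @return Adjusted q-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric())
  if (any(is.na(pvals)) || any(pvals <= 0 | pvals > 1)) {
    abort("p-values must lie in (0, 1].")
  }
  p.adjust(pvals, method = "BH")
}
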