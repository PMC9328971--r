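#' Run the full pair-signature pipeline
#'
#' Chains every stage: coexpression screen of lncRNAs against the
#' ferroptosis-related gene list, tumor-versus-normal differential
#' expression of the coexpressed lncRNAs, all-pairs 0/1 encoding on the
#' tumor samples with the 20-80% frequency filter, univariate Cox
#' screening, seeded LASSO-Cox selection, stepwise multivariate Cox
#' fitting, risk scoring, time-dependent ROC at the requested horizons,
#' AIC-based cutoff selection, group assignment, and Kaplan-Meier/log-rank
#' evaluation. If any selection stage comes up empty (too few
#' differentially expressed lncRNAs, no significant pairs, an empty LASSO
#' selection), the pipeline stops gracefully and returns what it has, with
#' `empty = TRUE` and the stage that emptied in `reason`.
#'
#' @param expr An [expr_matrix()] with tumor/normal condition labels.
#' @param clinical A clinical tibble (`sample_id`, `time`, `event`, ...)
#'   for the tumor samples.
#' @param lnc_ids lncRNA gene ids, or an annotation tibble with `gene_id`
#'   and `biotype` columns (lncRNAs are taken from it).
#' @param frg The ferroptosis-related `gene_set` (or id vector).
#' @param r_min,p_max_cor Coexpression screen thresholds.
#' @param fdr_max,lfc_min Differential-expression thresholds.
#' @param low,high Pair-frequency filter bounds.
#' @param p_max_cox Univariate Cox retention threshold.
#' @param n_folds,seed LASSO cross-validation settings.
#' @param stepwise Run stepwise AIC in the multivariate fit.
#' @param horizons ROC horizons in days (default 1/3/5 years).
#' @return A `ferropair_result` list; see Details in the vignette.
#' @export
ferropair_pipeline <- function(expr, clinical, lnc_ids, frg,
                               r_min = 0.4, p_max_cor = 0.001,
                               fdr_max = 0.05, lfc_min = 1.5,
                               low = 0.20, high = 0.80,
                               p_max_cox = 0.05, n_folds = 10, seed = 1,
                               stepwise = TRUE,
                               horizons = c(1, 3, 5) * 365.25) {
  if (is.data.frame(lnc_ids)) {
    lnc_ids <- lnc_ids$gene_id[lnc_ids$biotype == "lncRNA"]
  }
  if (inherits(frg, "gene_set")) frg <- frg$members
  frg <- intersect(frg, rownames(expr$values))
  lnc_ids <- intersect(lnc_ids, rownames(expr$values))
  surv <- survival_data(clinical)
  res <- list(empty = FALSE, reason = NULL)
  done <- function(res, reason) {
    res$empty <- TRUE
    res$reason <- reason
    structure(res, class = "ferropair_result")
  }

  res$coexpression <- pearson_screen(expr, lnc_ids, frg,
                                     r_min = r_min, p_max = p_max_cor)
  res$frlnc <- selected_genes(res$coexpression)
  if (length(res$frlnc) < 2) return(done(res, "fewer than 2 coexpressed lncRNAs"))

  res$differential <- differential_expression(expr, res$frlnc,
                                              fdr_max = fdr_max,
                                              lfc_min = lfc_min)
  res$defrlnc <- selected_genes(res$differential)
  if (length(res$defrlnc) < 2) {
    return(done(res, "fewer than 2 differentially expressed lncRNAs"))
  }

  tum <- tumor_samples(expr)
  keep <- intersect(surv$sample_id, sample_ids(tum))
  surv <- surv[surv$sample_id %in% keep, ]
  pm <- build_pair_matrix(subset_expr(tum, samples = keep), res$defrlnc)
  res$pair_matrix <- filter_pairs(pm, low = low, high = high)
  if (nrow(res$pair_matrix$indicators) == 0) {
    return(done(res, "no pairs survived the frequency filter"))
  }

  res$univariate <- univariate_cox_screen(res$pair_matrix, surv,
                                          p_max = p_max_cox)
  retained <- res$univariate$pair_id[res$univariate$retained]
  if (length(retained) < 2) {
    return(done(res, "fewer than 2 univariate-significant pairs"))
  }

  res$lasso <- lasso_cox_select(res$pair_matrix, surv, pairs = retained,
                                n_folds = n_folds, seed = seed)
  if (nrow(res$lasso) == 0) return(done(res, "LASSO selected no pairs"))

  res$model <- multivariate_cox_fit(res$pair_matrix, surv,
                                    res$lasso$pair_id, stepwise = stepwise)
  if (nrow(res$model$pairs) == 0) {
    return(done(res, "stepwise selection emptied the model"))
  }

  res$scores <- risk_score(res$model, res$pair_matrix)
  res$roc <- purrr::map(horizons, function(h) {
    tryCatch(time_dependent_roc(res$scores, surv, h), error = function(e) NULL)
  })
  names(res$roc) <- paste0("t", round(horizons))
  res$cutoff <- choose_cutoff(res$scores, surv)
  res$profile <- assign_groups(res$scores, res$cutoff)
  res$km <- km_estimate(surv, res$profile)
  if (length(unique(res$profile$group)) == 2) {
    res$logrank <- logrank_test(surv, res$profile)
  }
  res$surv <- surv
  structure(res, class = "ferropair_result")
}

#' @export
print.ferropair_result <- function(x, ...) {
  if (x$empty) {
    cat("<ferropair_result> empty model:", x$reason, "\n")
    return(invisible(x))
  }
  cat("<ferropair_result>\n")
  cat(sprintf("  FRlncRNAs: %d, DEFRlncRNAs: %d\n",
              length(x$frlnc), length(x$defrlnc)))
  cat(sprintf("  pairs after frequency filter: %d\n",
              nrow(x$pair_matrix$indicators)))
  cat(sprintf("  univariate-significant: %d, LASSO candidates: %d, final: %d\n",
              sum(x$univariate$retained), nrow(x$lasso), nrow(x$model$pairs)))
  aucs <- purrr::map_dbl(x$roc, ~ if (is.null(.x)) NA_real_ else roc_auc(.x))
  cat(sprintf("  AUC: %s\n",
              paste(sprintf("%s=%.3f", names(aucs), aucs), collapse = ", ")))
  cat(sprintf("  cutoff: %.4g; high/low: %d/%d\n", x$cutoff$cutoff,
              sum(x$profile$group == "high"), sum(x$profile$group == "low")))
  if (!is.null(x$logrank)) {
    cat(sprintf("  log-rank: chisq = %.2f, p = %.3g\n",
                x$logrank$statistic, x$logrank$p))
  }
  invisible(x)
}
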