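#' Univariate Cox screen of pair indicators
#'
#' Fits one single-covariate Cox proportional-hazards model (Efron tie
#' handling) per pair indicator and flags the pairs with `p < p_max`.
#' Constant indicators cannot be fitted and are skipped with a warning —
#' they cannot occur when the pair matrix was frequency-filtered on the
#' same cohort.
#'
#' @param pm A `pair_matrix`.
#' @param surv A survival tibble (`sample_id`, `time`, `event`); sample ids
#'   must be a subset of the pair matrix columns.
#' @param p_max Retention threshold on the Wald p-value (default 0.05).
#' @return A tibble with columns `pair_id`, `beta`, `hr`, `se`, `z`, `p`,
#'   `retained`.
#' @export
univariate_cox_screen <- function(pm, surv, p_max = 0.05) {
  surv <- survival_data(surv)
  missing <- setdiff(surv$sample_id, colnames(pm$indicators))
  if (length(missing) > 0) {
    abort(paste0("sample(s) absent from pair matrix: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  if (sum(surv$event) == 0) abort("no events in the survival data.")
  if (sum(surv$event) < 10) {
    warn("fewer than 10 events; univariate Cox estimates will be unstable.")
  }
  ind <- pm$indicators[, surv$sample_id, drop = FALSE]
  const <- apply(ind, 1, function(x) length(unique(x)) == 1)
  if (any(const)) {
    warn(paste0("skipping ", sum(const), " constant pair indicator(s)."))
    ind <- ind[!const, , drop = FALSE]
  }
  y <- survival::Surv(surv$time, surv$event)
  fit_one <- function(x) {
    fit <- suppressWarnings(
      survival::coxph(y ~ x, ties = "efron",
                      data = data.frame(x = x))
    )
    s <- summary(fit)$coefficients
    c(beta = s[1, "coef"], se = s[1, "se(coef)"],
      z = s[1, "z"], p = s[1, "Pr(>|z|)"])
  }
  stats_mat <- t(apply(ind, 1, fit_one))
  tibble(
    pair_id = rownames(ind),
    beta = stats_mat[, "beta"],
    hr = exp(stats_mat[, "beta"]),
    se = stats_mat[, "se"],
    z = stats_mat[, "z"],
    p = stats_mat[, "p"],
    retained = stats_mat[, "p"] < p_max
  )
}

#' Cross-validated LASSO-Cox selection of candidate pairs
#'
#' L1-penalised Cox regression over the candidate pair indicators, with
#' the penalty chosen by cross-validated partial-likelihood deviance at
#' `lambda.min` (or `lambda.1se`). Fold assignment is derived from `seed`,
#' so the selection is reproducible. Setting `lambda = 0` bypasses the
#' penalty entirely and returns every candidate (the unpenalised limit).
#'
#' @param pm A `pair_matrix`.
#' @param surv A survival tibble.
#' @param pairs Candidate pair ids (default: all pairs in `pm`); >= 2.
#' @param n_folds Number of CV folds (default 10); needs at least that
#'   many events.
#' @param seed Integer seed for the fold split.
#' @param rule `"min"` (default) or `"1se"`.
#' @param lambda Optional fixed penalty overriding cross-validation.
#' @return A tibble (`pair_id`, `coefficient`) of pairs with nonzero
#'   LASSO coefficient; the chosen penalty is in `attr(, "lambda")`.
#' @export
lasso_cox_select <- function(pm, surv, pairs = NULL, n_folds = 10, seed = 1,
                             rule = c("min", "1se"), lambda = NULL) {
  rule <- match.arg(rule)
  surv <- survival_data(surv)
  pairs <- pairs %||% rownames(pm$indicators)
  if (length(pairs) < 2) abort("need >= 2 candidate pairs for LASSO.")
  pm <- subset_pairs(pm, pairs)
  x <- t(pm$indicators[, surv$sample_id, drop = FALSE])
  if (nrow(unique(t(x))) == 1) {
    abort("degenerate design: all candidate indicators are identical.")
  }
  if (!is.null(lambda) && lambda == 0) {
    out <- tibble(pair_id = pairs, coefficient = NA_real_)
    attr(out, "lambda") <- 0
    return(out)
  }
  if (sum(surv$event) < n_folds) {
    abort(paste0("need >= ", n_folds, " events for ", n_folds, "-fold CV."))
  }
  y <- survival::Surv(surv$time, surv$event)
  if (is.null(lambda)) {
    set.seed(seed)
    foldid <- sample(rep(seq_len(n_folds), length.out = nrow(x)))
    cv <- glmnet::cv.glmnet(x, y, family = "cox", foldid = foldid)
    lambda <- if (rule == "min") cv$lambda.min else cv$lambda.1se
    fit <- cv$glmnet.fit
  } else {
    fit <- glmnet::glmnet(x, y, family = "cox")
  }
  cf <- as.matrix(predict(fit, type = "coefficients", s = lambda))[, 1]
  nz <- cf != 0
  out <- tibble(pair_id = names(cf)[nz], coefficient = unname(cf[nz]))
  attr(out, "lambda") <- lambda
  out
}

# refit helper used by the stepwise search; returns the coxph fit
cox_fit_on <- function(df, vars) {
  fml <- if (length(vars) == 0) "survival::Surv(time, event) ~ 1"
         else paste("survival::Surv(time, event) ~",
                    paste(vars, collapse = " + "))
  survival::coxph(as.formula(fml), data = df, ties = "efron",
                  x = FALSE, y = TRUE)
}

cox_aic <- function(fit) {
  # AIC on the partial likelihood; the null model has 0 parameters
  k <- length(coef(fit))
  ll <- if (k == 0) fit$loglik[1] else fit$loglik[2]
  2 * k - 2 * ll
}

#' Multivariate Cox fit with stepwise AIC selection
#'
#' Starting from the model containing every candidate pair, repeatedly
#' applies the single drop or add that most reduces
#' `AIC = 2k - 2 logPL`, until no move improves it. With
#' `stepwise = FALSE` the full multivariate fit is returned unchanged.
#'
#' @param pm A `pair_matrix` containing the candidates.
#' @param surv A survival tibble.
#' @param candidates Candidate pair ids (>= 1); a `lasso_cox_select()`
#'   result is also accepted.
#' @param stepwise Run the AIC search (default `TRUE`).
#' @param max_steps Safety bound on the number of moves.
#' @return A `signature_model`: selected pairs with their multivariate
#'   Cox coefficients and training metadata. Supports [tidy()] and
#'   [glance()].
#' @export
multivariate_cox_fit <- function(pm, surv, candidates, stepwise = TRUE,
                                 max_steps = 200) {
  if (is.data.frame(candidates)) candidates <- candidates$pair_id
  candidates <- unique(as.character(candidates))
  if (length(candidates) < 1) abort("need >= 1 candidate pair.")
  surv <- survival_data(surv)
  pm <- subset_pairs(pm, candidates)
  n_events <- sum(surv$event)
  caution <- n_events <= length(candidates)
  if (caution) {
    warn("events do not exceed the number of candidates; fit may be unstable.")
  }
  ind <- pm$indicators[, surv$sample_id, drop = FALSE]
  vars <- paste0("p", seq_along(candidates))
  df <- data.frame(time = surv$time, event = surv$event, t(ind))
  names(df) <- c("time", "event", vars)

  current <- vars
  fits <- new.env(parent = emptyenv())
  fit_for <- function(set) {
    key <- paste(sort(set), collapse = "+")
    if (is.null(fits[[key]])) fits[[key]] <- cox_fit_on(df, set)
    fits[[key]]
  }
  best_fit <- fit_for(current)
  if (stepwise && length(candidates) > 1) {
    for (step in seq_len(max_steps)) {
      best_aic <- cox_aic(best_fit)
      moves <- c(
        lapply(current, function(v) setdiff(current, v)),
        lapply(setdiff(vars, current), function(v) c(current, v))
      )
      move_fits <- lapply(moves, fit_for)
      aics <- vapply(move_fits, cox_aic, double(1))
      if (length(aics) == 0 || min(aics) >= best_aic - 1e-8) break
      i <- which.min(aics)
      current <- moves[[i]]
      best_fit <- move_fits[[i]]
    }
  }
  sel <- match(current, vars)
  sel <- sort(sel)
  current <- vars[sel]
  final <- fit_for(current)
  cf <- coef(final)[current]
  pair_ids <- candidates[sel]
  pairs_tbl <- pm$pairs[match(pair_ids, pm$pairs$pair_id),
                        c("pair_id", "gene_a", "gene_b")]
  pairs_tbl$coefficient <- unname(cf)
  structure(list(
    pairs = pairs_tbl,
    n = nrow(surv), n_events = n_events,
    aic = cox_aic(final), loglik = if (length(cf)) final$loglik[2]
                                   else final$loglik[1],
    stepwise = stepwise, caution = caution,
    n_candidates = length(candidates)
  ), class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("<signature_model> %d pair(s), n = %d (%d events), AIC = %.2f\n",
              nrow(x$pairs), x$n, x$n_events, x$aic))
  print(x$pairs)
  invisible(x)
}

#' @rdname multivariate_cox_fit
#' @param x A `signature_model`.
#' @param ... Unused.
#' @export
tidy.signature_model <- function(x, ...) x$pairs

#' @rdname multivariate_cox_fit
#' @export
glance.signature_model <- function(x, ...) {
  tibble(n_pairs = nrow(x$pairs), n = x$n, n_events = x$n_events,
         aic = x$aic, loglik = x$loglik, stepwise = x$stepwise,
         caution = x$caution)
}

#' Per-sample risk scores from a fitted signature
#'
#' The risk score is the Cox linear predictor over the signature's pair
#' indicators: `score_s = sum_i beta_i * indicator_is`. Because the
#' indicators only compare two genes within the same sample, the score is
#' unchanged by any strictly increasing per-sample transformation of the
#' expression values.
#'
#' @param model A `signature_model`.
#' @param pm A `pair_matrix` containing every model pair.
#' @return A tibble (`sample_id`, `score`).
#' @export
risk_score <- function(model, pm) {
  missing <- setdiff(model$pairs$pair_id, rownames(pm$indicators))
  if (length(missing) > 0) {
    abort(paste0("pair(s) missing from indicator matrix: ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(model$pairs) == 0) {
    return(tibble(sample_id = colnames(pm$indicators), score = 0))
  }
  ind <- pm$indicators[model$pairs$pair_id, , drop = FALSE]
  tibble(sample_id = colnames(ind),
         score = as.vector(crossprod(ind, model$pairs$coefficient)))
}

#' Score a new cohort from raw expression
#'
#' Re-derives the signature's pair indicators directly from an expression
#' matrix (no normalisation required) and returns the risk scores. This is
#' the frozen-model application path for external cohorts.
#'
#' @param model A `signature_model`.
#' @param expr An [expr_matrix()] containing every gene used by the model.
#' @return A tibble (`sample_id`, `score`).
#' @export
score_cohort <- function(model, expr) {
  genes <- unique(c(model$pairs$gene_a, model$pairs$gene_b))
  missing <- setdiff(genes, rownames(expr$values))
  if (length(missing) > 0) {
    abort(paste0("gene(s) missing from expression matrix: ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(model$pairs) == 0) {
    return(tibble(sample_id = colnames(expr$values), score = 0))
  }
  ind <- (expr$values[model$pairs$gene_a, , drop = FALSE] >=
            expr$values[model$pairs$gene_b, , drop = FALSE]) * 1
  tibble(sample_id = colnames(expr$values),
         score = as.vector(crossprod(ind, model$pairs$coefficient)))
}

# evaluate a right-continuous step function (KM survival, Breslow cumulative
# hazard) at time t; `left` takes the left limit, `before` is the value
# before the first jump (1 for survival, 0 for cumulative hazard)
km_eval <- function(times, surv_vals, t, left = FALSE, before = 1) {
  keep <- if (left) times < t else times <= t
  if (!any(keep)) return(before)
  surv_vals[max(which(keep))]
}

#' Time-dependent ROC under right censoring
#'
#' Cumulative-case/dynamic-control ROC at a fixed horizon: cases are
#' subjects with an observed event by the horizon, controls those still
#' at risk beyond it. Censoring is handled by weighting each case with the
#' inverse Kaplan-Meier estimate of the censoring survival function at its
#' event time (and each control at the horizon), which keeps the
#' sensitivity/specificity sweep monotone. The AUC is the trapezoidal
#' integral over the threshold sweep; with no censoring it reduces exactly
#' to the empirical probability that a case outranks a control (ties
#' counted 1/2).
#'
#' @param scores A tibble (`sample_id`, `score`).
#' @param surv A survival tibble for the same samples.
#' @param horizon Horizon in the same time units as `surv$time` (e.g.
#'   `5 * 365.25` days); must lie within follow-up and have >= 1 prior
#'   event.
#' @return A `td_roc` tibble (`threshold`, `sensitivity`, `specificity`)
#'   with attributes `auc`, `horizon`; see [glance()].
#' @export
time_dependent_roc <- function(scores, surv, horizon) {
  surv <- survival_data(surv)
  d <- dplyr::inner_join(scores, surv, by = "sample_id")
  if (nrow(d) == 0) abort("no shared samples between scores and survival data.")
  if (horizon <= 0 || horizon > max(d$time)) {
    abort("horizon must be positive and within the follow-up range.")
  }
  is_case <- d$time <= horizon & d$event == 1
  is_control <- d$time > horizon
  if (!any(is_case)) abort("no events before the horizon.")
  if (!any(is_control)) abort("no controls at risk beyond the horizon.")
  # KM of the censoring distribution
  cfit <- survival::survfit(survival::Surv(d$time, 1 - d$event) ~ 1)
  g_case <- vapply(d$time[is_case],
                   function(t) km_eval(cfit$time, cfit$surv, t, left = TRUE),
                   double(1))
  g_ctrl <- km_eval(cfit$time, cfit$surv, horizon)
  if (any(g_case <= 0) || g_ctrl <= 0) {
    abort("censoring survival reaches 0 before the horizon; ROC undefined.")
  }
  w_case <- 1 / g_case
  x_case <- d$score[is_case]
  x_ctrl <- d$score[is_control]
  thr <- c(-Inf, sort(unique(d$score)))
  sens <- vapply(thr, function(c) sum(w_case[x_case > c]) / sum(w_case),
                 double(1))
  spec <- vapply(thr, function(c) mean(x_ctrl <= c), double(1))
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(ord)]) / 2)
  out <- tibble(threshold = thr, sensitivity = sens, specificity = spec)
  out <- structure(out, class = c("td_roc", class(out)))
  attr(out, "horizon") <- horizon
  attr(out, "auc") <- auc
  attr(out, "n_cases") <- sum(is_case)
  attr(out, "n_controls") <- sum(is_control)
  out
}

#' @export
glance.td_roc <- function(x, ...) {
  tibble(horizon = attr(x, "horizon"), auc = attr(x, "auc"),
         n_cases = attr(x, "n_cases"), n_controls = attr(x, "n_controls"))
}

#' AUC of a time-dependent ROC
#' @param roc A `td_roc`.
#' @return The AUC as a single number.
#' @export
roc_auc <- function(roc) attr(roc, "auc")

#' Risk-score cutoff by AIC minimisation
#'
#' For every candidate threshold (the midpoints between consecutive sorted
#' unique scores), the scores are dichotomised and a one-covariate Cox
#' model is fitted on the binary group; the returned cutoff minimises the
#' model AIC (ties broken towards the smallest threshold). This
#' operationalises choosing the best "inflection point" of the AIC profile
#' along the risk-score ROC sweep. The full AIC-versus-threshold profile
#' is kept for plotting.
#'
#' @param scores A tibble (`sample_id`, `score`) with >= 2 distinct scores.
#' @param surv A survival tibble.
#' @return An `aic_cutoff`: list with `cutoff` and `profile`
#'   (tibble `threshold`, `aic`).
#' @export
choose_cutoff <- function(scores, surv) {
  surv <- survival_data(surv)
  d <- dplyr::inner_join(scores, surv, by = "sample_id")
  u <- sort(unique(d$score))
  if (length(u) < 2) abort("need >= 2 distinct scores to choose a cutoff.")
  cand <- (u[-1] + u[-length(u)]) / 2
  y <- survival::Surv(d$time, d$event)
  aics <- vapply(cand, function(c) {
    grp <- as.integer(d$score > c)
    fit <- suppressWarnings(
      survival::coxph(y ~ grp, data = data.frame(grp = grp), ties = "efron"))
    cox_aic(fit)
  }, double(1))
  best <- which.min(aics)  # which.min takes the first minimum: smallest c
  structure(list(cutoff = cand[best],
                 profile = tibble(threshold = cand, aic = aics)),
            class = "aic_cutoff")
}

#' @export
print.aic_cutoff <- function(x, ...) {
  cat(sprintf("<aic_cutoff> cutoff = %.4g (over %d candidate thresholds)\n",
              x$cutoff, nrow(x$profile)))
  invisible(x)
}

#' Assign high/low risk groups at a cutoff
#'
#' A sample is high-risk iff its score is strictly greater than the
#' cutoff (a score exactly at the cutoff is low-risk).
#'
#' @param scores A tibble (`sample_id`, `score`).
#' @param cutoff A finite number, or an [choose_cutoff()] result.
#' @return A `risk_profile` tibble (`sample_id`, `score`, `group`) with the
#'   cutoff in `attr(, "cutoff")`.
#' @export
assign_groups <- function(scores, cutoff) {
  if (inherits(cutoff, "aic_cutoff")) cutoff <- cutoff$cutoff
  if (!is.finite(cutoff)) abort("cutoff must be finite.")
  out <- tibble(sample_id = scores$sample_id, score = scores$score,
                group = ifelse(scores$score > cutoff, "high", "low"))
  out <- structure(out, class = c("risk_profile", class(out)))
  attr(out, "cutoff") <- cutoff
  out
}
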