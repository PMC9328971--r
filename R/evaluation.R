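#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimator with right censoring, computed per group via
#' [survival::survfit()]. Censoring tied with an event at the same time is
#' handled after the event, as usual.
#'
#' @param surv A survival tibble (`sample_id`, `time`, `event`).
#' @param groups Either a character/factor vector aligned with `surv`
#'   rows, or a tibble (`sample_id`, `group`) such as a `risk_profile`.
#' @return A `km_curve` tibble: `group`, `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`.
#' @export
km_estimate <- function(surv, groups) {
  surv <- survival_data(surv)
  grp <- align_groups(surv, groups)
  if (any(table(grp) == 0) || anyNA(grp)) abort("each group must be non-empty.")
  fit <- survival::survfit(survival::Surv(surv$time, surv$event) ~ grp)
  if (is.null(fit$strata)) {
    group_lab <- rep(as.character(unique(grp)), length(fit$time))
  } else {
    group_lab <- rep(sub("^grp=", "", names(fit$strata)), fit$strata)
  }
  out <- tibble(group = group_lab, time = fit$time, n_risk = fit$n.risk,
                n_event = fit$n.event, n_censor = fit$n.censor,
                survival = fit$surv)
  structure(out, class = c("km_curve", class(out)))
}

# accepts a vector aligned to surv rows, or a (sample_id, group) tibble
align_groups <- function(surv, groups) {
  if (is.data.frame(groups)) {
    if (!all(c("sample_id", "group") %in% names(groups))) {
      abort("`groups` data frame needs columns sample_id and group.")
    }
    m <- match(surv$sample_id, groups$sample_id)
    if (anyNA(m)) abort("some survival samples have no group assignment.")
    as.character(groups$group[m])
  } else {
    if (length(groups) != nrow(surv)) {
      abort("`groups` must have one label per survival row.")
    }
    as.character(groups)
  }
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-squared statistic with 1 degree of freedom, via
#' [survival::survdiff()].
#'
#' @inheritParams km_estimate
#' @return A tibble (`statistic`, `df`, `p`).
#' @export
logrank_test <- function(surv, groups) {
  surv <- survival_data(surv)
  grp <- align_groups(surv, groups)
  if (length(unique(grp)) != 2) abort("log-rank test needs exactly 2 groups.")
  fit <- survival::survdiff(survival::Surv(surv$time, surv$event) ~ grp)
  tibble(statistic = fit$chisq, df = 1,
         p = pchisq(fit$chisq, df = 1, lower.tail = FALSE))
}

#' Association between risk group/score and clinical features
#'
#' Per clinical feature: a chi-squared test (no continuity correction) of
#' risk group against the feature's categories, and a rank-sum test of the
#' risk score across the feature's strata (Wilcoxon for two strata,
#' Kruskal-Wallis for more). `unknown`/missing categories are excluded per
#' feature; features left with a single category are skipped with a
#' warning. Age is dichotomised at 65.
#'
#' @param profile A `risk_profile` ([assign_groups()]).
#' @param clinical A clinical tibble sharing `sample_id`.
#' @param features Clinical columns to test (defaults to the standard set,
#'   intersected with what is present).
#' @return A tibble (`feature`, `test`, `statistic`, `p`).
#' @export
clinical_association <- function(profile, clinical,
                                 features = c("age_group", "gender", "grade",
                                              "stage", "t_stage", "n_stage",
                                              "m_stage")) {
  d <- dplyr::inner_join(tibble::as_tibble(profile), clinical, by = "sample_id")
  if (nrow(d) < 10) abort("need >= 10 shared samples.")
  if ("age" %in% names(d) && !"age_group" %in% names(d)) {
    d$age_group <- ifelse(d$age <= 65, "<=65", ">65")
  }
  features <- intersect(features, names(d))
  rows <- purrr::map(features, function(f) {
    v <- as.character(d[[f]])
    keep <- !is.na(v) & v != "unknown"
    v <- v[keep]
    if (length(unique(v)) < 2) {
      warn(paste0("feature '", f, "' has a single category; skipped."))
      return(NULL)
    }
    chisq <- suppressWarnings(chisq.test(table(d$group[keep], v),
                                         correct = FALSE))
    if (length(unique(v)) == 2) {
      lv <- sort(unique(v))
      rs <- suppressWarnings(wilcox.test(d$score[keep][v == lv[1]],
                                         d$score[keep][v == lv[2]]))
      rank_row <- tibble(feature = f, test = "rank-sum",
                         statistic = unname(rs$statistic), p = rs$p.value)
    } else {
      kw <- kruskal.test(d$score[keep], factor(v))
      rank_row <- tibble(feature = f, test = "kruskal-wallis",
                         statistic = unname(kw$statistic), p = kw$p.value)
    }
    dplyr::bind_rows(
      tibble(feature = f, test = "chi-squared",
             statistic = unname(chisq$statistic), p = chisq$p.value),
      rank_row
    )
  })
  dplyr::bind_rows(rows)
}

# shared model-frame builder for the independence Cox models; numeric
# covariates stay continuous, everything else becomes a factor with
# "unknown" treated as missing
cox_clinical_frame <- function(profile, clinical, covariates = NULL) {
  d <- dplyr::inner_join(tibble::as_tibble(profile), clinical, by = "sample_id")
  covs <- intersect(unique(c("age", "gender", "grade", "stage",
                             "t_stage", "n_stage", "m_stage", covariates)),
                    names(d))
  for (f in covs) {
    if (is.numeric(d[[f]])) next
    v <- as.character(d[[f]])
    v[v == "unknown"] <- NA
    d[[f]] <- factor(v)
  }
  list(d = d, covs = covs)
}

#' Univariate and multivariate independence Cox models
#'
#' Confirms whether the risk score predicts survival independently of the
#' clinical covariates: each covariate (and the continuous risk score) is
#' fitted alone, then all are fitted jointly. Categorical covariates use
#' their first level as reference; `unknown` values are treated as missing
#' and dropped per model. Covariates that are constant after
#' unknown-removal are dropped with a warning, and aliased (collinear)
#' terms in the joint model are flagged.
#'
#' @param profile A `risk_profile`.
#' @param clinical A clinical tibble with survival columns.
#' @param covariates Extra clinical columns to include beyond the standard
#'   set (numeric columns enter continuously).
#' @return A tibble (`analysis`, `term`, `beta`, `hr`, `ci_low`, `ci_high`,
#'   `p`).
#' @export
independence_cox <- function(profile, clinical, covariates = NULL) {
  cc <- cox_clinical_frame(profile, clinical, covariates)
  d <- cc$d
  if (sum(d$event) <= length(cc$covs) + 1) {
    warn("few events relative to covariates; estimates may be unstable.")
  }
  keep <- character()
  for (f in cc$covs) {
    v <- d[[f]]
    if (length(unique(v[!is.na(v)])) < 2) {
      warn(paste0("covariate '", f, "' constant after unknown-removal; dropped."))
    } else {
      keep <- c(keep, f)
    }
  }
  terms <- c("score", keep)
  one_fit <- function(vars, label) {
    fml <- as.formula(paste("survival::Surv(time, event) ~",
                            paste(vars, collapse = " + ")))
    fit <- suppressWarnings(survival::coxph(fml, data = d, ties = "efron"))
    if (any(is.na(coef(fit)))) {
      warn(paste0(label, " Cox model has aliased (collinear) term(s): ",
                  paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")))
    }
    s <- summary(fit)
    tibble(analysis = label,
           term = rownames(s$coefficients),
           beta = unname(s$coefficients[, "coef"]),
           hr = unname(s$coefficients[, "exp(coef)"]),
           ci_low = unname(s$conf.int[, "lower .95"]),
           ci_high = unname(s$conf.int[, "upper .95"]),
           p = unname(s$coefficients[, "Pr(>|z|)"]))
  }
  uni <- dplyr::bind_rows(purrr::map(terms, ~ one_fit(.x, "univariate")))
  multi <- one_fit(terms, "multivariate")
  dplyr::bind_rows(uni, multi)
}

#' Decision-curve analysis at a survival horizon
#'
#' Predicted event risk at the horizon comes from a one-covariate Cox fit
#' on the risk score (`risk = 1 - S0(t)^exp(beta * score)`, Breslow
#' baseline). For each threshold probability `p_t`, samples with predicted
#' risk above `p_t` are "treated"; the event/no-event split among them at
#' the horizon is estimated with Kaplan-Meier (so censoring is handled),
#' and the net benefit is `TP/n - FP/n * p_t / (1 - p_t)`. Treat-all and
#' treat-none reference curves are included.
#'
#' @param profile A `risk_profile` or a (`sample_id`, `score`) tibble.
#' @param surv A survival tibble.
#' @param horizon Evaluation horizon (same units as `surv$time`).
#' @param grid Threshold probabilities in (0, 1); must be non-empty.
#' @return A `net_benefit` tibble (`threshold`, `nb_model`, `nb_all`,
#'   `nb_none`).
#' @export
decision_curve <- function(profile, surv, horizon,
                           grid = seq(0.01, 0.99, by = 0.01)) {
  if (length(grid) == 0) abort("threshold grid must be non-empty.")
  if (any(grid <= 0 | grid >= 1)) abort("thresholds must lie in (0, 1).")
  surv <- survival_data(surv)
  d <- dplyr::inner_join(tibble::as_tibble(profile)[c("sample_id", "score")],
                         surv, by = "sample_id")
  if (horizon <= 0 || horizon > max(d$time)) {
    abort("horizon must be positive and within the follow-up range.")
  }
  fit <- survival::coxph(survival::Surv(time, event) ~ score, data = d,
                         ties = "efron")
  bh <- survival::basehaz(fit, centered = FALSE)
  s0 <- exp(-km_eval(bh$time, bh$hazard, horizon, before = 0))
  d$risk <- 1 - s0^exp(coef(fit)[1] * d$score)
  km_event_frac <- function(idx) {
    # 1 - S(horizon) within the subset, by KM
    if (sum(idx) == 0) return(0)
    f <- survival::survfit(survival::Surv(d$time[idx], d$event[idx]) ~ 1)
    1 - km_eval(f$time, f$surv, horizon)
  }
  n <- nrow(d)
  prev <- km_event_frac(rep(TRUE, n))
  nb <- vapply(grid, function(pt) {
    pos <- d$risk > pt
    npos <- sum(pos)
    if (npos == 0) return(0)
    ev <- km_event_frac(pos)
    tp <- ev * npos / n
    fp <- (1 - ev) * npos / n
    tp - fp * pt / (1 - pt)
  }, double(1))
  nb_all <- prev - (1 - prev) * grid / (1 - grid)
  out <- tibble(threshold = grid, nb_model = nb, nb_all = nb_all, nb_none = 0)
  structure(out, class = c("net_benefit", class(out)))
}

#' Nomogram from a multivariate Cox model
#'
#' Fits a multivariate Cox model on the risk score plus clinical
#' covariates, and converts it into nomogram coordinates: each covariate's
#' contribution `beta * (x - reference)` is mapped linearly to points so
#' that the covariate with the widest observed contribution spans 100
#' points, and total points map to predicted survival at the requested
#' horizons through the Breslow baseline evaluated at the reference
#' profile: `S(t | x) = S_ref(t)^exp(lp - lp_ref)`. At the reference
#' profile every covariate contributes 0 points and the prediction equals
#' the baseline survival.
#'
#' @param profile A `risk_profile`.
#' @param clinical A clinical tibble with survival columns.
#' @param horizons Prediction horizons (default 1/3/5 years in days).
#' @return A `nomogram`: list with `points` (tibble `term`, `value`,
#'   `points`), `baseline` (tibble `horizon`, `surv_ref`), `scale`
#'   (points-to-log-hazard factor), and `reference`.
#' @export
build_nomogram <- function(profile, clinical,
                           horizons = c(1, 3, 5) * 365.25) {
  cc <- cox_clinical_frame(profile, clinical)
  d <- cc$d
  last_event <- max(d$time[d$event == 1])
  bad <- horizons > last_event
  if (any(bad)) {
    warn(paste0("horizon(s) beyond the last event time refused: ",
                paste(round(horizons[bad]), collapse = ", ")))
    horizons <- horizons[!bad]
    if (length(horizons) == 0) abort("no usable horizons.")
  }
  keep <- character()
  for (f in cc$covs) {
    v <- d[[f]]
    if (length(unique(v[!is.na(v)])) < 2) {
      warn(paste0("covariate '", f, "' constant after unknown-removal; dropped."))
    } else {
      keep <- c(keep, f)
    }
  }
  covs <- c("score", keep)
  d <- d[complete.cases(d[covs]), ]
  for (f in keep) if (is.factor(d[[f]])) d[[f]] <- droplevels(d[[f]])
  single <- keep[vapply(keep, function(f) length(unique(d[[f]])) < 2,
                        logical(1))]
  if (length(single) > 0) {
    warn(paste0("covariate(s) constant on complete cases; dropped: ",
                paste(single, collapse = ", ")))
    covs <- setdiff(covs, single)
  }
  fml <- as.formula(paste("survival::Surv(time, event) ~",
                          paste(covs, collapse = " + ")))
  fit <- survival::coxph(fml, data = d, ties = "efron", x = TRUE)
  beta <- coef(fit)
  if (anyNA(beta)) {
    warn("aliased term(s) dropped from the nomogram.")
    keep_cols <- !is.na(beta)
    beta <- beta[keep_cols]
    fit$x <- fit$x[, keep_cols, drop = FALSE]
  }
  mm <- fit$x
  # reference: continuous covariates at their observed minimum, factor
  # dummy columns at 0 (their first level)
  ref <- apply(mm, 2, min)
  contrib <- sweep(mm, 2, ref) * rep(beta, each = nrow(mm))
  scale <- max(abs(contrib))  # widest single-covariate swing = 100 points
  if (scale == 0) abort("all covariates are constant; nomogram undefined.")
  points_tbl <- purrr::map_dfr(colnames(mm), function(cn) {
    vals <- sort(unique(mm[, cn]))
    tibble(term = cn, value = vals,
           points = 100 * beta[cn] * (vals - ref[cn]) / scale)
  })
  lp_ref <- sum(beta * ref)
  bh <- survival::basehaz(fit, centered = FALSE)
  s_ref <- vapply(horizons, function(t) {
    exp(-km_eval(bh$time, bh$hazard, t, before = 0))^exp(lp_ref)
  }, double(1))
  structure(list(
    points = points_tbl,
    baseline = tibble(horizon = horizons, surv_ref = s_ref),
    scale = scale, reference = ref, beta = beta
  ), class = "nomogram")
}

#' Predicted survival from a nomogram
#'
#' @param nomogram A [build_nomogram()] result.
#' @param total_points Numeric vector of total points.
#' @return A tibble (`total_points`, `horizon`, `survival`), with
#'   `survival = surv_ref^exp(scale * total_points / 100)`.
#' @export
predict_nomogram <- function(nomogram, total_points) {
  tidyr::expand_grid(total_points = total_points,
                     nomogram$baseline) |>
    dplyr::mutate(survival = .data$surv_ref ^
                    exp(nomogram$scale * .data$total_points / 100)) |>
    dplyr::select("total_points", "horizon", "survival")
}

#' @export
print.nomogram <- function(x, ...) {
  cat(sprintf("<nomogram> %d term(s), %d horizon(s); 100 points = %.3f log-hazard units\n",
              length(x$beta), nrow(x$baseline), x$scale))
  invisible(x)
}

#' Compare a gene panel between risk groups
#'
#' Two-sided rank-sum test per panel gene between high- and low-risk
#' samples, with Benjamini-Hochberg adjustment across the panel. Used for
#' immune-checkpoint and m6A regulator panels. Panel genes absent from
#' the expression matrix are reported in `attr(, "missing")`.
#'
#' @param expr An [expr_matrix()].
#' @param panel A `gene_set` or character vector of gene ids; may be empty
#'   (empty result).
#' @param profile A `risk_profile`; each group needs >= 3 samples among
#'   the expression columns.
#' @return A tibble (`gene_id`, `p`, `q`, `direction`) where `direction`
#'   is the sign of the high-minus-low median difference.
#' @export
panel_group_compare <- function(expr, panel, profile) {
  members <- if (inherits(panel, "gene_set")) panel$members
             else as.character(panel)
  prof <- tibble::as_tibble(profile)
  shared <- intersect(prof$sample_id, colnames(expr$values))
  grp <- setNames(prof$group[match(shared, prof$sample_id)], shared)
  if (sum(grp == "high") < 3 || sum(grp == "low") < 3) {
    abort("need >= 3 samples per risk group.")
  }
  missing <- setdiff(members, rownames(expr$values))
  members <- setdiff(members, missing)
  if (length(missing) > 0) {
    warn(paste0(length(missing), " panel gene(s) absent from expression: ",
                paste(head(missing, 5), collapse = ", ")))
  }
  if (length(members) == 0) {
    out <- tibble(gene_id = character(), p = double(), q = double(),
                  direction = character())
    attr(out, "missing") <- missing
    return(out)
  }
  hi <- expr$values[members, names(grp)[grp == "high"], drop = FALSE]
  lo <- expr$values[members, names(grp)[grp == "low"], drop = FALSE]
  p <- vapply(seq_along(members), function(i) {
    suppressWarnings(wilcox.test(hi[i, ], lo[i, ])$p.value)
  }, double(1))
  p[is.na(p)] <- 1
  delta <- apply(hi, 1, median) - apply(lo, 1, median)
  out <- tibble(gene_id = members, p = p, q = bh_adjust(p),
                direction = dplyr::case_when(delta > 0 ~ "up",
                                             delta < 0 ~ "down",
                                             TRUE ~ "none"))
  attr(out, "missing") <- missing
  out
}
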