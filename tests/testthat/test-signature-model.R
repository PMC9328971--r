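test_that("the Cox fitter agrees with grid-searched partial likelihood", {
  set.seed(21)
  for (rep in 1:5) {
    n <- 25
    x <- rbinom(n, 1, 0.5)
    time <- round(rexp(n, 0.01 * exp(0.8 * x)), 4) + rep * 0.001 * seq_len(n)
    event <- rbinom(n, 1, 0.8)
    if (sum(event) < 3 || length(unique(x)) == 1) next
    ind <- matrix(as.integer(x), nrow = 1,
                  dimnames = list("a|b", sprintf("S%02d", 1:n)))
    path <- withr::local_tempfile(fileext = ".tsv")
    readr::write_tsv(tibble::as_tibble(ind, rownames = "pair_id"), path)
    pm <- read_pair_matrix(path)
    uni <- suppressWarnings(
      univariate_cox_screen(pm, make_surv(time, event), p_max = 0.05))
    grid <- seq(-5, 5, by = 1e-3)
    ll <- vapply(grid, bf_cox_loglik, double(1),
                 time = time, event = event, x = x)
    expect_lt(abs(uni$beta - grid[which.max(ll)]), 2e-3)
  }
})

test_that("an early-vs-late split yields a strong positive effect", {
  # group 1 events mostly early, group 0 mostly late, with enough overlap
  # that the partial likelihood has a finite maximum
  time <- c(1:20, 15:34)
  x <- rep(c(1L, 0L), each = 20)
  ind <- matrix(x, nrow = 1,
                dimnames = list("a|b", sprintf("S%02d", 1:40)))
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::as_tibble(ind, rownames = "pair_id"), path)
  uni <- univariate_cox_screen(read_pair_matrix(path),
                               make_surv(time, rep(1, 40)))
  expect_gt(uni$beta, 0)
  expect_lt(uni$p, 0.01)
})

test_that("constant indicators are skipped and no-event data rejected", {
  ind <- rbind("a|b" = rep(1L, 10), "a|c" = rep(c(0L, 1L), 5))
  colnames(ind) <- sprintf("S%02d", 1:10)
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::as_tibble(ind, rownames = "pair_id"), path)
  pm <- read_pair_matrix(path)
  surv <- make_surv(1:10, rep(1, 10))
  expect_warning(uni <- univariate_cox_screen(pm, surv), "constant")
  expect_equal(uni$pair_id, "a|c")
  expect_error(
    suppressWarnings(univariate_cox_screen(pm, make_surv(1:10, rep(0, 10)))),
    "no events"
  )
})

simulate_pm_surv <- function(seed, n_extra = 10) {
  # planted pairs among the first six lncRNAs plus null pairs
  cf <- sim_config(n_lnc = 30, n_mrna = 20, n_frg = 5,
                   coexpressed_fraction = 0.4, de_fraction = 0.4, seed = seed)
  coh <- simulate_cohort(cf)
  surv <- survival_data(coh$clinical)
  pm <- filter_pairs(build_pair_matrix(tumor_samples(coh$expr),
                                       sprintf("LNC%03d", 1:12)))
  list(pm = pm, surv = surv,
       planted = paste(cf$planted_pairs$gene_a, cf$planted_pairs$gene_b,
                       sep = "|"))
}

test_that("LASSO selection is seeded, and lambda = 0 keeps everything", {
  d <- simulate_pm_surv(17)
  retained <- univariate_cox_screen(d$pm, d$surv)$pair_id
  s1 <- lasso_cox_select(d$pm, d$surv, retained, seed = 4)
  s2 <- lasso_cox_select(d$pm, d$surv, retained, seed = 4)
  expect_identical(s1$pair_id, s2$pair_id)
  expect_identical(attr(s1, "lambda"), attr(s2, "lambda"))
  all_in <- lasso_cox_select(d$pm, d$surv, retained, lambda = 0)
  expect_identical(all_in$pair_id, retained)
  expect_true(all(d$planted %in% s1$pair_id))
})

test_that("LASSO rejects degenerate designs", {
  ind <- rbind("a|b" = rep(c(0L, 1L), 10), "a|c" = rep(c(0L, 1L), 10))
  colnames(ind) <- sprintf("S%02d", 1:20)
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::as_tibble(ind, rownames = "pair_id"), path)
  pm <- read_pair_matrix(path)
  expect_error(lasso_cox_select(pm, make_surv(1:20, rep(1, 20))),
               "degenerate")
  expect_error(lasso_cox_select(pm, make_surv(1:20, rep(1, 20)),
                                pairs = "a|b"), ">= 2 candidate")
})

test_that("multivariate fit reduces to the univariate fit for one pair", {
  d <- simulate_pm_surv(23)
  pair <- d$planted[1]
  uni <- univariate_cox_screen(subset_pairs(d$pm, pair), d$surv)
  fit <- multivariate_cox_fit(d$pm, d$surv, pair)
  expect_equal(fit$pairs$coefficient, uni$beta, tolerance = 1e-6)
  expect_equal(nrow(fit$pairs), 1)
})

test_that("stepwise = FALSE returns the full multivariate fit", {
  d <- simulate_pm_surv(29)
  cand <- d$planted
  full <- multivariate_cox_fit(d$pm, d$surv, cand, stepwise = FALSE)
  expect_setequal(full$pairs$pair_id, cand)
  # cross-check coefficients against a direct coxph fit
  ind <- t(d$pm$indicators[cand, d$surv$sample_id])
  df <- data.frame(time = d$surv$time, event = d$surv$event, ind)
  ref <- survival::coxph(
    survival::Surv(time, event) ~ ., data = df, ties = "efron")
  expect_equal(sort(full$pairs$coefficient), sort(unname(coef(ref))),
               tolerance = 1e-8)
})

test_that("stepwise AIC drops a pure-noise candidate", {
  hits <- vapply(c(37, 41, 43), function(s) {
    cf <- sim_config(n_tumor = 500, n_normal = 20, n_lnc = 30, n_mrna = 20,
                     n_frg = 5, coexpressed_fraction = 0.4, de_fraction = 0.4,
                     planted_pairs = data.frame(
                       gene_a = c("LNC001", "LNC003"),
                       gene_b = c("LNC002", "LNC004"), beta = 1),
                     seed = s)
    coh <- simulate_cohort(cf)
    surv <- survival_data(coh$clinical)
    pm <- build_pair_matrix(tumor_samples(coh$expr), sprintf("LNC%03d", 1:12))
    cand <- c("LNC001|LNC002", "LNC003|LNC004", "LNC007|LNC008")
    fit <- multivariate_cox_fit(pm, surv, cand)
    all(c("LNC001|LNC002", "LNC003|LNC004") %in% fit$pairs$pair_id) &&
      !"LNC007|LNC008" %in% fit$pairs$pair_id
  }, logical(1))
  expect_gte(sum(hits), 2)
})

test_that("risk scores are the linear predictor over indicators", {
  ind <- rbind("a|b" = c(1L, 0L), "c|d" = c(1L, 1L))
  colnames(ind) <- c("S01", "S02")
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::as_tibble(ind, rownames = "pair_id"), path)
  pm <- read_pair_matrix(path)
  model <- structure(list(pairs = tibble::tibble(
    pair_id = c("a|b", "c|d"), gene_a = c("a", "c"), gene_b = c("b", "d"),
    coefficient = c(0.5, -1.0))), class = "signature_model")
  sc <- risk_score(model, pm)
  expect_equal(sc$score, c(-0.5, -1.0))
  model0 <- model
  model0$pairs$coefficient <- c(0, 0)
  expect_equal(risk_score(model0, pm)$score, c(0, 0))
  bad <- model
  bad$pairs$pair_id[1] <- "x|y"
  expect_error(risk_score(bad, pm), "x\\|y")
})

test_that("score_cohort re-derives indicators from raw expression", {
  toy <- worked_toy()
  pm <- build_pair_matrix(toy$expr, c("L1", "L2", "L3"))
  model <- structure(list(pairs = tibble::tibble(
    pair_id = c("L1|L2", "L1|L3"), gene_a = c("L1", "L1"),
    gene_b = c("L2", "L3"), coefficient = c(1.2, -0.7))),
    class = "signature_model")
  expect_equal(score_cohort(model, toy$expr)$score,
               risk_score(model, pm)$score)
  # per-sample monotone transform leaves scores identical
  tv <- toy$expr$values^3
  expect_equal(score_cohort(model, make_expr(tv))$score,
               risk_score(model, pm)$score)
})

test_that("time-dependent ROC has the right limiting behaviour", {
  # perfect separation, no censoring: cases all score above controls
  surv <- make_surv(c(1, 2, 3, 10, 11, 12), c(1, 1, 1, 0, 0, 0))
  sc <- tibble::tibble(sample_id = surv$sample_id,
                       score = c(5, 6, 7, 1, 2, 3))
  roc <- time_dependent_roc(sc, surv, horizon = 5)
  expect_equal(roc_auc(roc), 1.0)
  # constant scores: AUC 1/2 by the tie convention
  sc2 <- tibble::tibble(sample_id = surv$sample_id, score = rep(2, 6))
  expect_equal(roc_auc(time_dependent_roc(sc2, surv, 5)), 0.5)
  expect_error(time_dependent_roc(sc, surv, 0.5), "no events")
})

test_that("without censoring the AUC equals the case-control pair count", {
  set.seed(13)
  for (rep in 1:5) {
    n <- 30
    time <- sample(1:100, n)
    score <- round(rnorm(n), 1)
    surv <- make_surv(time, rep(1, n))
    sc <- tibble::tibble(sample_id = surv$sample_id, score = score)
    h <- median(time) + 0.5
    roc <- time_dependent_roc(sc, surv, h)
    expect_equal(roc_auc(roc),
                 bf_auc(score[time <= h], score[time > h]),
                 tolerance = 1e-10)
    # sweep is monotone
    expect_true(all(diff(roc$sensitivity) <= 1e-12))
    expect_true(all(diff(roc$specificity) >= -1e-12))
  }
})

test_that("AIC cutoff equals exhaustive search and separates clusters", {
  set.seed(19)
  for (rep in 1:5) {
    n <- 30
    score <- round(rnorm(n), 2)
    time <- rexp(n, 0.01 * exp(score))
    event <- rbinom(n, 1, 0.7)
    if (sum(event) < 5) next
    surv <- make_surv(time, event)
    sc <- tibble::tibble(sample_id = surv$sample_id, score = score)
    got <- choose_cutoff(sc, surv)
    u <- sort(unique(score))
    cand <- (u[-1] + u[-length(u)]) / 2
    aic <- vapply(cand, function(c) {
      g <- as.integer(score > c)
      fit <- suppressWarnings(
        survival::coxph(survival::Surv(time, event) ~ g, ties = "efron"))
      k <- length(coef(fit))
      2 * k - 2 * fit$loglik[2]
    }, double(1))
    expect_equal(got$cutoff, cand[which.min(aic)])
    expect_equal(got$profile$aic, aic, tolerance = 1e-10)
  }
  # two separated clusters, high cluster dies first -> cutoff in the gap
  score <- c(rep(0.1, 10) + runif(10, 0, 0.05), rep(2, 10) + runif(10, 0, 0.05))
  time <- c(101:110, 1:10)
  surv <- make_surv(time, rep(1, 20))
  sc <- tibble::tibble(sample_id = surv$sample_id, score = score)
  cut <- choose_cutoff(sc, surv)$cutoff
  expect_gt(cut, 0.15)
  expect_lt(cut, 2)
  # a rank-preserving transform maps to the same partition
  sc3 <- tibble::tibble(sample_id = surv$sample_id, score = exp(score))
  cut3 <- choose_cutoff(sc3, surv)$cutoff
  expect_identical(score > cut, exp(score) > cut3)
  expect_error(choose_cutoff(tibble::tibble(sample_id = surv$sample_id,
                                            score = rep(1, 20)), surv),
               "distinct")
})

test_that("group assignment follows the strict-cutoff convention", {
  sc <- tibble::tibble(sample_id = c("a", "b"), score = c(0.1, 0.5))
  prof <- assign_groups(sc, 0.302)
  expect_equal(prof$group, c("low", "high"))
  expect_equal(attr(prof, "cutoff"), 0.302)
  # exact tie goes low; all-low is legal for a frozen external model
  prof2 <- assign_groups(tibble::tibble(sample_id = "a", score = 0.302), 0.302)
  expect_equal(prof2$group, "low")
  expect_error(assign_groups(sc, Inf), "finite")
})
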