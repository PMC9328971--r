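#' Simulation configuration for a synthetic tumor/normal cohort
#'
#' Defines the statistical structure the pipeline assumes of its input:
#' lncRNA-FRG coexpression blocks at a target Pearson correlation,
#' tumor-versus-normal fold-change shifts on a subset of lncRNAs, and
#' survival times for tumor samples drawn from an exponential
#' proportional-hazards model whose hazard depends on planted pair
#' indicators, with independent exponential censoring calibrated to a
#' target censoring fraction.
#'
#' The defaults are the package's reference recovery conditions: a
#' 300-tumor/30-normal cohort (mirroring the heavy tumor/normal imbalance
#' of public tumor cohorts), 300 lncRNAs of which a quarter are coexpressed
#' with one of 60 ferroptosis-related mRNAs at r = 0.6, 4% carrying a
#' 3-log2-unit tumor shift, and three planted pairs with log hazard ratio
#' 1.0 among the first six lncRNAs (which are coexpressed and shifted by
#' construction, so they survive both screens).
#'
#' @param n_tumor,n_normal Tumor/normal sample counts.
#' @param n_lnc,n_mrna lncRNA and mRNA gene counts.
#' @param n_frg Number of ferroptosis-related genes among the mRNAs.
#' @param coexpressed_fraction Fraction of lncRNAs linearly tied to an FRG.
#' @param target_r Population Pearson correlation for coexpressed lncRNAs,
#'   in (0, 1).
#' @param de_fraction Fraction of lncRNAs with a tumor shift.
#' @param de_log2fc Tumor shift in log2 units.
#' @param planted_pairs Data frame with columns `gene_a`, `gene_b`, `beta`
#'   (log hazard ratio of the pair indicator `expr[a] >= expr[b]`), or
#'   `NULL` for the default three pairs among the first six lncRNAs.
#' @param baseline_hazard Constant baseline hazard per day.
#' @param censoring_rate Target fraction of censored tumor samples, in
#'   `[0, 1)`.
#' @param seed Integer seed; a fixed seed makes the cohort bit-identical.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_tumor = 300, n_normal = 30,
                       n_lnc = 300, n_mrna = 300, n_frg = 60,
                       coexpressed_fraction = 0.25, target_r = 0.6,
                       de_fraction = 0.04, de_log2fc = 3,
                       planted_pairs = NULL,
                       baseline_hazard = 4e-4, censoring_rate = 0.3,
                       seed = 1) {
  counts <- c(n_tumor = n_tumor, n_normal = n_normal, n_lnc = n_lnc,
              n_mrna = n_mrna, n_frg = n_frg)
  if (any(counts <= 0)) abort("all counts must be positive.")
  if (n_frg > n_mrna) abort("n_frg cannot exceed n_mrna.")
  fracs <- c(coexpressed_fraction, de_fraction)
  if (any(fracs < 0 | fracs > 1)) abort("fractions must lie in [0, 1].")
  if (target_r <= 0 || target_r >= 1) abort("target_r must lie in (0, 1).")
  if (censoring_rate < 0 || censoring_rate >= 1) {
    abort("censoring_rate must lie in [0, 1).")
  }
  if (baseline_hazard <= 0) abort("baseline_hazard must be positive.")
  lnc_names <- sprintf("LNC%03d", seq_len(n_lnc))
  if (is.null(planted_pairs)) {
    if (n_lnc >= 6) {
      planted_pairs <- tibble(gene_a = lnc_names[c(1, 3, 5)],
                              gene_b = lnc_names[c(2, 4, 6)],
                              beta = 1.0)
    } else {
      planted_pairs <- tibble(gene_a = character(), gene_b = character(),
                              beta = double())
    }
  }
  planted_pairs <- tibble::as_tibble(planted_pairs)
  unknown <- setdiff(c(planted_pairs$gene_a, planted_pairs$gene_b), lnc_names)
  if (length(unknown) > 0) {
    abort(paste0("planted pair references nonexistent gene(s): ",
                 paste(unknown, collapse = ", ")))
  }
  structure(list(
    n_tumor = n_tumor, n_normal = n_normal, n_lnc = n_lnc, n_mrna = n_mrna,
    n_frg = n_frg, coexpressed_fraction = coexpressed_fraction,
    target_r = target_r, de_fraction = de_fraction, de_log2fc = de_log2fc,
    planted_pairs = planted_pairs, baseline_hazard = baseline_hazard,
    censoring_rate = censoring_rate, seed = as.integer(seed)
  ), class = "sim_config")
}

# deterministic per-stage sub-seed so adding a stage never perturbs others
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1009 + stage * 101) %% 2147483647)
}

#' Simulate a tumor/normal cohort with planted prognostic pairs
#'
#' Expression is the exponential of a Gaussian log2-scale model
#' (per-gene base mean + per-sample effect + noise). Each coexpressed
#' lncRNA equals its partner FRG's log2 signal plus calibrated noise, so
#' its population correlation with the FRG is `target_r`. Shifted lncRNAs
#' gain `de_log2fc` log2 units in tumor samples. Tumor survival times are
#' exponential with hazard `baseline_hazard * exp(sum(beta * I(pair)))`
#' over the planted pairs; censoring is an independent exponential time
#' whose rate is solved numerically so the expected censored fraction
#' equals `censoring_rate`. Clinical covariates are drawn from categorical
#' distributions matching a typical head-and-neck tumor cohort. Normal
#' samples carry no survival data.
#'
#' @param config A [sim_config()].
#' @return A list with `expr` ([expr_matrix()] with condition labels),
#'   `annotation` (tibble `gene_id`, `biotype`), `frg` (`gene_set`), and
#'   `clinical` (tibble with survival and covariates for tumor samples).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  n_s <- cf$n_tumor + cf$n_normal
  lnc <- sprintf("LNC%03d", seq_len(cf$n_lnc))
  mrna <- sprintf("MRNA%03d", seq_len(cf$n_mrna))
  frg <- mrna[seq_len(cf$n_frg)]
  samples <- c(sprintf("T%03d", seq_len(cf$n_tumor)),
               sprintf("N%03d", seq_len(cf$n_normal)))
  condition <- c(rep("tumor", cf$n_tumor), rep("normal", cf$n_normal))
  is_tumor <- condition == "tumor"

  sigma_sample <- 0.2
  sigma_noise <- 1.0

  # stage 1: per-gene base means (log2 scale)
  set.seed(stage_seed(cf$seed, 1))
  mu <- setNames(rnorm(cf$n_lnc + cf$n_mrna, mean = 4, sd = 1), c(lnc, mrna))
  # planted pairs get a common base mean so their indicator is balanced
  for (i in seq_len(nrow(cf$planted_pairs))) {
    g <- c(cf$planted_pairs$gene_a[i], cf$planted_pairs$gene_b[i])
    mu[g] <- mean(mu[g])
  }

  # stage 2: log2-scale expression
  set.seed(stage_seed(cf$seed, 2))
  b_s <- rnorm(n_s, 0, sigma_sample)
  y_mrna <- matrix(mu[mrna], cf$n_mrna, n_s) +
    matrix(b_s, cf$n_mrna, n_s, byrow = TRUE) +
    matrix(rnorm(cf$n_mrna * n_s, 0, sigma_noise), cf$n_mrna, n_s)
  rownames(y_mrna) <- mrna
  n_coex <- round(cf$coexpressed_fraction * cf$n_lnc)
  v_frg <- sigma_sample^2 + sigma_noise^2
  sd_eps <- sqrt(v_frg * (1 - cf$target_r^2) / cf$target_r^2)
  y_lnc <- matrix(NA_real_, cf$n_lnc, n_s, dimnames = list(lnc, NULL))
  for (i in seq_len(cf$n_lnc)) {
    if (i <= n_coex) {
      partner <- frg[((i - 1) %% cf$n_frg) + 1]
      y_lnc[i, ] <- mu[lnc[i]] + (y_mrna[partner, ] - mu[partner]) +
        rnorm(n_s, 0, sd_eps)
    } else {
      y_lnc[i, ] <- mu[lnc[i]] + b_s + rnorm(n_s, 0, sigma_noise)
    }
  }
  n_de <- round(cf$de_fraction * cf$n_lnc)
  if (n_de > 0) y_lnc[seq_len(n_de), is_tumor] <-
      y_lnc[seq_len(n_de), is_tumor] + cf$de_log2fc

  values <- 2^rbind(y_lnc, y_mrna)
  colnames(values) <- samples
  expr <- expr_matrix(values, condition = condition)

  # stage 3: survival for tumor samples
  set.seed(stage_seed(cf$seed, 3))
  lp <- rep(0, cf$n_tumor)
  tumor_vals <- values[, is_tumor, drop = FALSE]
  for (i in seq_len(nrow(cf$planted_pairs))) {
    a <- cf$planted_pairs$gene_a[i]
    b <- cf$planted_pairs$gene_b[i]
    lp <- lp + cf$planted_pairs$beta[i] * (tumor_vals[a, ] >= tumor_vals[b, ])
  }
  rate <- cf$baseline_hazard * exp(lp)
  t_event <- rexp(cf$n_tumor, rate = rate)

  # stage 4: independent censoring calibrated to the target fraction
  set.seed(stage_seed(cf$seed, 4))
  if (cf$censoring_rate > 0) {
    f <- function(lc) mean(lc / (lc + rate)) - cf$censoring_rate
    lam_c <- uniroot(f, lower = 1e-12, upper = 1e6, tol = 1e-12)$root
    t_cens <- rexp(cf$n_tumor, rate = lam_c)
  } else {
    t_cens <- rep(Inf, cf$n_tumor)
  }
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)

  # stage 5: clinical covariates from typical HNSCC cohort proportions
  set.seed(stage_seed(cf$seed, 5))
  n <- cf$n_tumor
  draw <- function(levels, counts) {
    sample(levels, n, replace = TRUE, prob = counts / sum(counts))
  }
  older <- runif(n) < 174 / 497
  age <- ifelse(older, sample(66:90, n, replace = TRUE),
                sample(30:65, n, replace = TRUE))
  clinical <- tibble(
    sample_id = samples[is_tumor],
    time = time,
    event = event,
    age = as.integer(age),
    gender = draw(c("female", "male"), c(133, 364)),
    grade = draw(c("G1", "G2", "G3", "G4", "unknown"), c(61, 297, 118, 2, 19)),
    stage = draw(c("I", "II", "III", "IV", "unknown"), c(25, 69, 78, 258, 67)),
    t_stage = draw(c("T1", "T2", "T3", "T4", "unknown"), c(45, 131, 96, 170, 55)),
    n_stage = draw(c("N0", "N1", "N2", "N3", "unknown"), c(168, 65, 164, 7, 93)),
    m_stage = draw(c("M0", "M1", "unknown"), c(183, 1, 313))
  )

  annotation <- tibble(
    gene_id = c(lnc, mrna),
    biotype = c(rep("lncRNA", cf$n_lnc), rep("protein_coding", cf$n_mrna))
  )
  list(expr = expr, annotation = annotation,
       frg = gene_set("FRG", frg), clinical = clinical)
}

#' A fixed, hand-checkable toy cohort
#'
#' An 8-gene by 10-sample dataset (4 lncRNAs, 4 mRNAs of which M1 and M2
#' are the ferroptosis-related genes; 6 tumor and 4 normal samples) whose
#' answers at every stage — correlations, differential-expression calls,
#' all pair indicators and pair frequencies — can be worked out by hand.
#' Values are of the form `2^k - 1` so that `log2(x + 1)` is integer:
#' L1 copies M1 (r = 1, tumor-shifted, hence a DEFRlncRNA), L2 tracks M1
#' with r = 31/33 and is tumor-shifted (DEFRlncRNA), L3 copies M2 (r = 1,
#' not shifted), and L4 is unrelated noise. The (L1, L2) indicator
#' alternates 0/1 across samples, so its frequency is exactly 0.5.
#'
#' @return A list with `expr`, `annotation`, `frg`, `clinical`, as
#'   [simulate_cohort()].
#' @export
worked_toy <- function() {
  y <- rbind(
    L1 = c(5, 6, 7, 8, 9, 10, 1, 2, 3, 4),
    L2 = c(6, 5, 8, 7, 10, 9, 2, 1, 4, 3),
    L3 = c(1, 3, 2, 5, 4, 6, 2, 4, 3, 6),
    L4 = c(2, 7, 1, 4, 6, 3, 7, 2, 5, 1),
    M1 = c(5, 6, 7, 8, 9, 10, 1, 2, 3, 4),
    M2 = c(1, 3, 2, 5, 4, 6, 2, 4, 3, 6),
    M3 = c(3, 3, 3, 3, 3, 3, 3, 3, 3, 3),
    M4 = c(4, 2, 6, 1, 5, 3, 2, 6, 4, 1)
  )
  values <- 2^y - 1
  colnames(values) <- c(sprintf("T%d", 1:6), sprintf("N%d", 1:4))
  expr <- expr_matrix(values,
                      condition = c(rep("tumor", 6), rep("normal", 4)))
  annotation <- tibble(
    gene_id = rownames(values),
    biotype = c(rep("lncRNA", 4), rep("protein_coding", 4))
  )
  clinical <- tibble(
    sample_id = sprintf("T%d", 1:6),
    time = c(100, 200, 300, 400, 500, 600),
    event = c(1L, 1L, 1L, 0L, 1L, 0L),
    age = c(55L, 70L, 60L, 65L, 45L, 75L),
    gender = c("male", "female", "male", "male", "female", "male"),
    grade = c("G2", "G3", "G2", "G1", "G2", "unknown"),
    stage = c("IV", "III", "IV", "II", "IV", "I"),
    t_stage = c("T4", "T3", "T2", "T4", "T1", "T2"),
    n_stage = c("N2", "N0", "N1", "N2", "N0", "unknown"),
    m_stage = c("M0", "M0", "unknown", "M0", "unknown", "M0")
  )
  list(expr = expr, annotation = annotation,
       frg = gene_set("FRG", c("M1", "M2")), clinical = clinical)
}
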