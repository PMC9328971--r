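# small constructors and independent oracles shared across test files

# expr_matrix from a plain matrix, inventing ids when absent
make_expr <- function(values, condition = NULL) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("G%02d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("S%02d", seq_len(ncol(values)))
  }
  expr_matrix(values, condition = condition)
}

# expression whose log2(x + 1) equals the given values exactly
expr_from_log2 <- function(y) {
  v <- 2^y - 1
  make_expr(v)
}

# brute-force pair indicator matrix: double loop over ordered gene pairs
bf_pair_matrix <- function(values, genes) {
  genes <- sort(genes)
  n <- length(genes)
  rows <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- genes[i]; b <- genes[j]
      ind <- integer(ncol(values))
      for (s in seq_len(ncol(values))) {
        ind[s] <- if (values[a, s] < values[b, s]) 0L else 1L
      }
      rows[[paste(a, b, sep = "|")]] <- ind
    }
  }
  out <- do.call(rbind, rows)
  colnames(out) <- colnames(values)
  out
}

# brute-force BH step-up: q_i = min_{j: p_(j) >= p_(i)} m p_(j) / j
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    js <- which(p[o] >= p[o][i])
    q[o][i] <- min(1, min(m * p[o][js] / js))
  }
  q
}

# binary AUC with ties counted 1/2
bf_auc <- function(cases, controls) {
  tot <- 0
  for (x in cases) for (y in controls) {
    tot <- tot + (x > y) + 0.5 * (x == y)
  }
  tot / (length(cases) * length(controls))
}

# Cox partial log-likelihood for a single covariate, tie-free data
bf_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    at_risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[at_risk])))
  }
  ll
}

# survival tibble with generated sample ids
make_surv <- function(time, event, ids = sprintf("S%02d", seq_along(time))) {
  tibble::tibble(sample_id = ids, time = time, event = as.integer(event))
}
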