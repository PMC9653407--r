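# Independent scalar oracles, written from the textbook formulas so they share
# no code path with the package implementations.

pearson_oracle <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  sxx <- sum(x^2) - sum(x)^2 / n
  syy <- sum(y^2) - sum(y)^2 / n
  if (sxx <= 0 || syy <= 0) return(NA_real_)
  sxy / sqrt(sxx * syy)
}

welch_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- sum((x - mean(x))^2) / (n1 - 1)
  v2 <- sum((y - mean(y))^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t_stat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t_stat, df = df, p = 2 * pt(-abs(t_stat), df))
}

# Benjamini-Hochberg step-up, as the procedure is written: sort ascending,
# q_i = p_i * m / i, enforce monotonicity from the largest rank down.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

# reduced-size configuration for fast unit tests (not the study conditions)
small_cfg <- function(seed = 42, ...) {
  defaults <- list(seed = seed, n_cid = 24, n_killed = 4, n_cid_tracked = 30,
                   n_single_nk = 10, n_single_cancer = 10,
                   excluded_counts = c(empty = 2, cancer_to_empty = 2,
                                       nk_to_empty = 2, nk_start_cid = 1,
                                       cid_to_cancer = 2),
                   n_genes = 300, module_sizes = c(8, 7, 6, 5),
                   n_lr_pairs_coordinated = 3, n_lr_pairs_null = 5,
                   n_de_genes = 6)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))

# adjusted Rand index between two label vectors (Hubert & Arabie),
# implemented from the contingency-table formula
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_i <- sum(choose2(rowSums(tab)))
  sum_j <- sum(choose2(colSums(tab)))
  n <- length(a)
  expected <- sum_i * sum_j / choose2(n)
  (sum_ij - expected) / ((sum_i + sum_j) / 2 - expected)
}
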