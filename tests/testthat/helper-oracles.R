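# Independent oracles used to check the package's estimators, kept free of
# any package internals.

# Weighted median by exhaustive cumulative-weight scan with linear
# interpolation at the 0.5 crossing.
oracle_weighted_median <- function(b, w) {
  o <- order(b)
  b <- b[o]
  w <- w[o] / sum(w)
  cum <- cumsum(w)
  s <- cum - w / 2
  if (s[1] >= 0.5) return(b[1])
  if (s[length(s)] <= 0.5) return(b[length(b)])
  below <- which(s < 0.5)
  k <- below[length(below)]
  b[k] + (b[k + 1] - b[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
}

# AUC by exhaustive enumeration of case-control pairs, ties counting 1/2.
oracle_auc_pairs <- function(pred, y) {
  cases <- pred[y == 1]
  controls <- pred[y == 0]
  total <- 0
  for (a in cases) for (b in controls) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(cases) * length(controls))
}

# Trapezoidal integration of an ROC curve given (fpr, tpr) points.
oracle_auc_trapezoid <- function(fpr, tpr) {
  o <- order(fpr, tpr)
  fpr <- c(fpr[o], 1)
  tpr <- c(tpr[o], 1)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# Convenience builder for instrument sets in tests.
make_instruments <- function(beta_exp, beta_out, se_exp = 0.02,
                             se_out = 0.02, n_exp = 50000, n_out = 50000) {
  j <- length(beta_exp)
  instrument_set(data.frame(
    snp = sprintf("rs%d", seq_len(j)),
    effect_allele = "A", other_allele = "G",
    beta_exp = beta_exp, se_exp = rep_len(se_exp, j),
    pval_exp = rep(1e-20, j), n_exp = rep_len(n_exp, j),
    beta_out = beta_out, se_out = rep_len(se_out, j),
    pval_out = rep(0.5, j), n_out = rep_len(n_out, j),
    stringsAsFactors = FALSE))
}

# Instruments whose per-SNP Wald ratios and weights are set directly.
make_ratio_instruments <- function(ratios, weights) {
  beta_exp <- rep(1, length(ratios))
  se_out <- sqrt(1 / weights)   # w = beta_exp^2 / se_out^2
  make_instruments(beta_exp, ratios, se_out = se_out)
}
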