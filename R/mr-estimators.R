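#' Instrument set
#'
#' Harmonized exposure/outcome effect pairs used by all two-sample MR
#' estimators.
#'
#' @param data data.frame with columns `snp`, `effect_allele`,
#'   `other_allele`, `beta_exp`, `se_exp`, `pval_exp`, `n_exp`,
#'   `beta_out`, `se_out`, `pval_out`, `n_out`.
#' @param exposure,outcome trait names.
#' @param log drop log.
#' @return An `instrument_set` data.frame.
#' @export
instrument_set <- function(data, exposure = "exposure", outcome = "outcome",
                           log = .empty_log()) {
  required <- c("snp", "effect_allele", "other_allele", "beta_exp", "se_exp",
                "pval_exp", "n_exp", "beta_out", "se_out", "pval_out",
                "n_out")
  stopifnot(all(required %in% names(data)))
  if (anyDuplicated(data$snp)) stop("duplicate SNPs in instrument set")
  rownames(data) <- NULL
  structure(as.data.frame(data)[required], exposure = exposure,
            outcome = outcome, log = log,
            class = c("instrument_set", "data.frame"))
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("Instrument set: %d SNP(s), %s -> %s\n", nrow(x),
              attr(x, "exposure"), attr(x, "outcome")))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}

#' Harmonize exposure and outcome summary statistics into instruments
#'
#' Clumps the exposure at the instrument p-value threshold (genome-wide
#' significance by default, guarding against weak-instrument bias),
#' aligns the outcome effects to the exposure's effect allele (sign flips
#' for allele swaps, complements for strand mismatches, ambiguous
#' palindromic SNPs dropped, unambiguous ones aligned by frequency) and
#' drops SNPs missing from the outcome with a logged reason.
#'
#' @param exposure,outcome [gwas_sumstats()] objects.
#' @param panel `genotype_matrix` LD reference panel.
#' @param instrument_p exposure p-value threshold for instruments.
#' @param r2_threshold,window_kb clumping parameters (see [ld_clump()]).
#' @return An [instrument_set()].
#' @export
harmonize_two_sample <- function(exposure, outcome, panel,
                                 instrument_p = 5e-8, r2_threshold = 0.001,
                                 window_kb = 10000) {
  def <- suppressWarnings(ld_clump(exposure, panel,
                                   p_threshold = instrument_p,
                                   r2_threshold = r2_threshold,
                                   window_kb = window_kb))
  log <- attr(def, "log")
  if (!nrow(def)) stop("no instruments: no exposure SNP passes p <= ",
                       format(instrument_p))
  exp_rows <- as.data.frame(exposure)[match(def$snp, exposure$snp), ]
  out_idx <- match(def$snp, outcome$snp)
  keep <- logical(nrow(def))
  mult <- rep(NA_real_, nrow(def))
  for (i in seq_len(nrow(def))) {
    if (is.na(out_idx[i])) {
      log <- rbind(log, .log_row(def$snp[i], "absent from outcome study"))
      next
    }
    o <- outcome[out_idx[i], ]
    al <- .align_alleles(o$effect_allele, o$other_allele,
                         exp_rows$effect_allele[i], exp_rows$other_allele[i],
                         o$eaf, exp_rows$eaf[i])
    if (is.na(al$mult)) {
      log <- rbind(log, .log_row(def$snp[i], al$reason))
      next
    }
    keep[i] <- TRUE
    mult[i] <- al$mult
  }
  if (!any(keep)) stop("no instruments: all SNPs dropped in harmonization")
  o <- as.data.frame(outcome)[out_idx[keep], ]
  e <- exp_rows[keep, ]
  instrument_set(data.frame(snp = e$snp, effect_allele = e$effect_allele,
                            other_allele = e$other_allele,
                            beta_exp = e$beta, se_exp = e$se,
                            pval_exp = e$pval, n_exp = e$n,
                            beta_out = o$beta * mult[keep], se_out = o$se,
                            pval_out = o$pval, n_out = o$n,
                            stringsAsFactors = FALSE),
                 exposure = attr(exposure, "trait"),
                 outcome = attr(outcome, "trait"), log = log)
}

.mr_estimate <- function(method, estimate, se, p, nsnp, ...) {
  extra <- list(...)
  base <- data.frame(method = method, estimate = estimate, se = se, p = p,
                     nsnp = nsnp, Q = NA_real_, Q_df = NA_real_,
                     Q_p = NA_real_, intercept = NA_real_,
                     intercept_se = NA_real_, intercept_p = NA_real_,
                     stringsAsFactors = FALSE)
  for (nm in names(extra)) base[[nm]] <- extra[[nm]]
  structure(base, class = c("mr_estimate", "data.frame"))
}

#' Wald ratio
#'
#' Single-SNP causal estimate: outcome effect divided by exposure effect,
#' with the first-order standard error `se_out / |beta_exp|`.
#'
#' @param beta_exp,se_exp exposure effect and SE.
#' @param beta_out,se_out outcome effect and SE.
#' @return A one-row `mr_estimate` data.frame.
#' @export
wald_ratio <- function(beta_exp, se_exp, beta_out, se_out) {
  if (beta_exp == 0) stop("Wald ratio undefined: exposure effect is zero")
  est <- beta_out / beta_exp
  se <- se_out / abs(beta_exp)
  .mr_estimate("wald_ratio", est, se, .two_sided_p(est / se), 1L)
}

.ratio_weights <- function(instr) {
  list(ratio = instr$beta_out / instr$beta_exp,
       w = instr$beta_exp^2 / instr$se_out^2)
}

#' Inverse-variance weighted (IVW) estimator
#'
#' Weighted regression of outcome effects on exposure effects through the
#' origin with weights `1/se_out^2`:
#' `estimate = sum(bx*by/se^2) / sum(bx^2/se^2)`. Cochran's Q (the
#' weighted sum of squared deviations of per-SNP Wald ratios from the
#' pooled estimate) is reported as the heterogeneity diagnostic; under
#' the default multiplicative random-effects model the fixed-effect SE is
#' inflated by `max(1, sqrt(Q/(J-1)))`.
#'
#' @param instr an [instrument_set()] with at least 2 SNPs.
#' @param model `"random"` (multiplicative random effects, default) or
#'   `"fixed"`.
#' @return A one-row `mr_estimate` data.frame including `Q`, `Q_df`,
#'   `Q_p`.
#' @export
mr_ivw <- function(instr, model = c("random", "fixed")) {
  model <- match.arg(model)
  if (nrow(instr) < 2) {
    stop("IVW needs >= 2 instruments; use wald_ratio() for a single SNP")
  }
  rw <- .ratio_weights(instr)
  est <- sum(rw$w * rw$ratio) / sum(rw$w)
  se_fixed <- sqrt(1 / sum(rw$w))
  Q <- sum(rw$w * (rw$ratio - est)^2)
  Q_df <- nrow(instr) - 1L
  Q_p <- stats::pchisq(Q, Q_df, lower.tail = FALSE)
  se <- if (model == "random") se_fixed * max(1, sqrt(Q / Q_df)) else se_fixed
  .mr_estimate(paste0("ivw_", model), est, se, .two_sided_p(est / se),
               nrow(instr), Q = Q, Q_df = Q_df, Q_p = Q_p)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome effects on exposure effects with a free
#' intercept (weights `1/se_out^2`), after orienting every SNP so its
#' exposure effect is non-negative. The slope is the causal estimate; the
#' intercept estimates the average directional pleiotropic effect, and a
#' nonzero intercept indicates directional pleiotropy. SEs use the
#' multiplicative residual inflation `max(1, residual scale)`; p-values
#' use a t distribution with J - 2 df.
#'
#' @param instr an [instrument_set()] with at least 3 SNPs.
#' @return A one-row `mr_estimate` data.frame including `intercept`,
#'   `intercept_se`, `intercept_p`.
#' @export
mr_egger <- function(instr) {
  if (nrow(instr) < 3) stop("MR-Egger needs >= 3 instruments")
  flip <- sign(instr$beta_exp)
  flip[flip == 0] <- 1
  bx <- instr$beta_exp * flip
  by <- instr$beta_out * flip
  fit <- .wls_fit(cbind(intercept = 1, slope = bx), by, 1 / instr$se_out^2)
  tvals <- fit$coef / fit$se
  p <- 2 * stats::pt(-abs(tvals), fit$rdf)
  .mr_estimate("egger", fit$coef["slope"], fit$se["slope"], p["slope"],
               nrow(instr), intercept = fit$coef["intercept"],
               intercept_se = fit$se["intercept"],
               intercept_p = p["intercept"])
}

# Weighted median of values `b` with weights `w`: sort, form cumulative
# midpoints S_j = cumsum(w) - w/2 on normalized weights, interpolate where
# S crosses 1/2.
.weighted_median <- function(b, w) {
  ord <- order(b)
  b <- b[ord]
  w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(b[1])
  if (s[length(s)] <= 0.5) return(b[length(b)])
  k <- max(which(s < 0.5))
  b[k] + (b[k + 1] - b[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
}

.boot_se <- function(instr, estimator, n_boot, seed) {
  if (!is.null(seed)) set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(i) {
    bx <- stats::rnorm(nrow(instr), instr$beta_exp, instr$se_exp)
    by <- stats::rnorm(nrow(instr), instr$beta_out, instr$se_out)
    estimator(bx, by)
  }, numeric(1))
  stats::sd(reps)
}

#' Weighted median estimator
#'
#' The weighted median of per-SNP Wald ratios with inverse-variance
#' weights, consistent when at least half the weight comes from valid
#' instruments. The SE comes from a parametric bootstrap resampling the
#' exposure and outcome effects from normal distributions with their
#' reported SEs.
#'
#' @param instr an [instrument_set()] with at least 3 SNPs.
#' @param n_boot bootstrap replicates.
#' @param seed seed for the bootstrap (or `NULL`).
#' @return A one-row `mr_estimate` data.frame.
#' @export
mr_weighted_median <- function(instr, n_boot = 1000, seed = NULL) {
  if (nrow(instr) < 3) stop("weighted median needs >= 3 instruments")
  rw <- .ratio_weights(instr)
  est <- .weighted_median(rw$ratio, rw$w)
  se <- .boot_se(instr, function(bx, by) {
    .weighted_median(by / bx, bx^2 / instr$se_out^2)
  }, n_boot, seed)
  p <- if (se > 0) .two_sided_p(est / se) else as.numeric(est == 0)
  .mr_estimate("weighted_median", est, se, p, nrow(instr))
}

.weighted_mode_point <- function(b, w, phi) {
  j <- length(b)
  spread <- min(stats::sd(b), stats::IQR(b) / 1.349)
  h <- phi * 0.9 * spread * j^(-1 / 5)
  if (!is.finite(h) || h <= 0) return(list(mode = b[1], h = 0))
  grid <- seq(min(b) - 3 * h, max(b) + 3 * h, length.out = 512)
  dens <- vapply(grid, function(x) sum(w * stats::dnorm(x, b, h)),
                 numeric(1))
  list(mode = grid[which.max(dens)], h = h)
}

#' Weighted mode estimator
#'
#' The mode of the weighted Gaussian-kernel density over per-SNP Wald
#' ratios (inverse-variance weights), consistent when the largest group
#' of instruments sharing the same ratio is valid. Bandwidth is
#' `phi * 0.9 * min(sd, IQR/1.349) * J^(-1/5)`; the density is maximized
#' on a 512-point grid spanning the ratio range plus three bandwidths.
#' SE from the same parametric bootstrap as the weighted median.
#'
#' @param instr an [instrument_set()] with at least 3 SNPs.
#' @param phi bandwidth multiplier.
#' @param n_boot,seed bootstrap settings.
#' @return A one-row `mr_estimate` data.frame. When all ratios coincide
#'   the common value is returned with SE 0.
#' @export
mr_weighted_mode <- function(instr, phi = 1, n_boot = 1000, seed = NULL) {
  if (nrow(instr) < 3) stop("weighted mode needs >= 3 instruments")
  rw <- .ratio_weights(instr)
  pt <- .weighted_mode_point(rw$ratio, rw$w, phi)
  if (pt$h == 0) {
    return(.mr_estimate("weighted_mode", rw$ratio[1], 0,
                        as.numeric(rw$ratio[1] == 0), nrow(instr)))
  }
  se <- .boot_se(instr, function(bx, by) {
    .weighted_mode_point(by / bx, bx^2 / instr$se_out^2, phi)$mode
  }, n_boot, seed)
  p <- if (se > 0) .two_sided_p(pt$mode / se) else as.numeric(pt$mode == 0)
  .mr_estimate("weighted_mode", pt$mode, se, p, nrow(instr))
}

#' Steiger directionality filtering
#'
#' Per SNP, converts the exposure and outcome t statistics into the
#' variance explained in each trait, `r2 = t^2 / (t^2 + n - 2)`, and
#' retains instruments explaining more variance in the exposure than in
#' the outcome — i.e. SNPs consistent with acting on the outcome through
#' the exposure.
#'
#' @param instr an [instrument_set()]; sample sizes must be present.
#' @return A list with `instruments` (the filtered [instrument_set()])
#'   and `verdicts` (per-SNP r-squared values and retain flags).
#' @export
steiger_filter <- function(instr) {
  missing_n <- instr$snp[!is.finite(instr$n_exp) | !is.finite(instr$n_out)]
  if (length(missing_n)) {
    stop("sample size missing for SNP(s): ", paste(missing_n, collapse = ", "))
  }
  t_exp <- instr$beta_exp / instr$se_exp
  t_out <- instr$beta_out / instr$se_out
  r2_exp <- t_exp^2 / (t_exp^2 + instr$n_exp - 2)
  r2_out <- t_out^2 / (t_out^2 + instr$n_out - 2)
  retain <- r2_exp > r2_out
  verdicts <- data.frame(snp = instr$snp, r2_exposure = r2_exp,
                         r2_outcome = r2_out, retained = retain,
                         stringsAsFactors = FALSE)
  log <- rbind(attr(instr, "log"),
               if (any(!retain)) .log_row(instr$snp[!retain],
                                          "removed by Steiger filter"))
  filtered <- instrument_set(as.data.frame(instr)[retain, , drop = FALSE],
                             exposure = attr(instr, "exposure"),
                             outcome = attr(instr, "outcome"),
                             log = log %||% .empty_log())
  list(instruments = filtered, verdicts = verdicts)
}

#' Leave-one-out IVW analysis
#'
#' Re-applies the IVW estimator after removing each SNP in turn, flagging
#' SNPs whose removal flips the estimate's sign or moves the p-value
#' across 0.05 — the signature of a single variant driving the
#' association.
#'
#' @param instr an [instrument_set()] with at least 3 SNPs.
#' @param model IVW model passed to [mr_ivw()].
#' @return data.frame with one row per removed SNP: estimate, se, p and
#'   an `influential` flag; the full-set estimate is kept in the
#'   `"full"` attribute.
#' @export
leave_one_out <- function(instr, model = "random") {
  if (nrow(instr) < 3) stop("leave-one-out needs >= 3 instruments")
  full <- mr_ivw(instr, model = model)
  rows <- lapply(seq_len(nrow(instr)), function(i) {
    sub <- instrument_set(as.data.frame(instr)[-i, , drop = FALSE],
                          exposure = attr(instr, "exposure"),
                          outcome = attr(instr, "outcome"))
    est <- mr_ivw(sub, model = model)
    data.frame(snp_removed = instr$snp[i], estimate = est$estimate,
               se = est$se, p = est$p,
               influential = sign(est$estimate) != sign(full$estimate) |
                 (est$p < 0.05) != (full$p < 0.05),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), full = full,
            class = c("loo_result", "data.frame"))
}
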