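# IVW when possible, Wald ratio for a single instrument.
.primary_estimate <- function(instr) {
  if (nrow(instr) >= 2) mr_ivw(instr)
  else wald_ratio(instr$beta_exp, instr$se_exp, instr$beta_out,
                  instr$se_out)
}

#' Three-step MR triage of a candidate association
#'
#' The systematic screening procedure for deciding whether a score-trait
#' association is a plausible causal effect:
#' \enumerate{
#'   \item IVW (with Cochran's Q). Weak evidence (`p >= alpha`) means a
#'     causal effect is unlikely: verdict `NOT_SUPPORTED`.
#'   \item In the presence of heterogeneity (`Q_p < alpha`), the weighted
#'     median and weighted mode must corroborate; if both give
#'     `p >= alpha` the verdict is `NOT_ROBUST`. (With
#'     `step2 = "always"` the two estimators run even without
#'     heterogeneity, but are then advisory.)
#'   \item Repeat on Steiger-filtered instruments and test the MR-Egger
#'     intercept. A nonzero intercept (`p < alpha`) or a reversal of the
#'     filtered conclusion gives `SENSITIVITY_FLAGGED`; otherwise
#'     `CAUSAL_CANDIDATE`.
#' }
#'
#' @param exposure,outcome [gwas_sumstats()] objects.
#' @param panel LD reference panel.
#' @param alpha evidence threshold per step.
#' @param instrument_p,r2_threshold instrument selection parameters.
#' @param step2 `"heterogeneity"` (step 2 decides only when Q flags
#'   heterogeneity, the default) or `"always"`.
#' @param n_boot,seed bootstrap settings for median/mode.
#' @return A `triage_verdict` list: `verdict`, per-step estimate tables,
#'   the instrument set and `alpha`.
#' @export
mr_triage <- function(exposure, outcome, panel, alpha = 0.05,
                      instrument_p = 5e-8, r2_threshold = 0.001,
                      step2 = c("heterogeneity", "always"), n_boot = 1000,
                      seed = NULL) {
  step2 <- match.arg(step2)
  instr <- harmonize_two_sample(exposure, outcome, panel,
                                instrument_p = instrument_p,
                                r2_threshold = r2_threshold)
  out <- list(alpha = alpha, instruments = instr, step1 = NULL,
              step2 = NULL, step3 = NULL, verdict = NA_character_)
  class(out) <- "triage_verdict"

  ivw <- .primary_estimate(instr)
  out$step1 <- ivw
  if (ivw$p >= alpha) {
    out$verdict <- "NOT_SUPPORTED"
    return(out)
  }

  heterogeneous <- !is.na(ivw$Q_p) && ivw$Q_p < alpha
  if ((heterogeneous || step2 == "always") && nrow(instr) >= 3) {
    med <- mr_weighted_median(instr, n_boot = n_boot, seed = seed)
    mode <- mr_weighted_mode(instr, n_boot = n_boot, seed = seed)
    out$step2 <- list(weighted_median = med, weighted_mode = mode,
                      decisive = heterogeneous)
    if (heterogeneous && med$p >= alpha && mode$p >= alpha) {
      out$verdict <- "NOT_ROBUST"
      return(out)
    }
  }

  flagged <- FALSE
  reasons <- character()
  sf <- steiger_filter(instr)
  filt <- sf$instruments
  if (nrow(filt) == 0) {
    flagged <- TRUE
    reasons <- c(reasons, "Steiger filter removed every instrument")
    filt_est <- NULL
  } else {
    filt_est <- .primary_estimate(filt)
    if (filt_est$p >= alpha) {
      flagged <- TRUE
      reasons <- c(reasons, "association lost after Steiger filtering")
    }
  }
  egger <- if (nrow(instr) >= 3) mr_egger(instr)
  if (!is.null(egger) && egger$intercept_p < alpha) {
    flagged <- TRUE
    reasons <- c(reasons, "Egger intercept indicates directional pleiotropy")
  }
  out$step3 <- list(steiger = sf$verdicts, filtered_estimate = filt_est,
                    egger = egger, reasons = reasons)
  out$verdict <- if (flagged) "SENSITIVITY_FLAGGED" else "CAUSAL_CANDIDATE"
  out
}

#' @export
print.triage_verdict <- function(x, ...) {
  cat(sprintf("MR triage: %s -> %s\n", attr(x$instruments, "exposure"),
              attr(x$instruments, "outcome")))
  cat(sprintf("  Step 1 (IVW): estimate %.4f, p = %.3g, Q_p = %.3g\n",
              x$step1$estimate, x$step1$p, x$step1$Q_p))
  if (!is.null(x$step2)) {
    cat(sprintf("  Step 2: median p = %.3g, mode p = %.3g%s\n",
                x$step2$weighted_median$p, x$step2$weighted_mode$p,
                if (x$step2$decisive) "" else " (advisory)"))
  }
  if (!is.null(x$step3) && !is.null(x$step3$egger)) {
    cat(sprintf("  Step 3: %d/%d retained by Steiger, Egger intercept p = %.3g\n",
                sum(x$step3$steiger$retained), nrow(x$step3$steiger),
                x$step3$egger$intercept_p))
  }
  cat("  Verdict: ", x$verdict, "\n", sep = "")
  invisible(x)
}

#' Bi-directional MR
#'
#' Runs the triage in both orientations — trait A as exposure of B, then
#' B as exposure of A — with instruments selected independently per
#' direction, to probe which direction of effect the data support.
#'
#' @param stats_a,stats_b [gwas_sumstats()] for the two traits.
#' @param panel LD reference panel.
#' @param ... further arguments passed to [mr_triage()].
#' @return A `bidirectional_mr` list with `forward` (A as exposure),
#'   `reverse` (B as exposure) and an `interpretation` label: one of
#'   `"both"`, `"forward_only"`, `"reverse_only"`, `"neither"`. A
#'   direction with no instruments is reported as such, the other still
#'   runs.
#' @export
mr_bidirectional <- function(stats_a, stats_b, panel, ...) {
  run <- function(e, o) {
    tryCatch(mr_triage(e, o, panel, ...), error = function(err) {
      structure(list(verdict = "NO_INSTRUMENTS",
                     error = conditionMessage(err)),
                class = "triage_verdict")
    })
  }
  fwd <- run(stats_a, stats_b)
  rev <- run(stats_b, stats_a)
  supports <- function(v) v$verdict %in% c("CAUSAL_CANDIDATE")
  interpretation <- if (supports(fwd) && supports(rev)) "both"
    else if (supports(fwd)) "forward_only"
    else if (supports(rev)) "reverse_only"
    else "neither"
  structure(list(forward = fwd, reverse = rev,
                 interpretation = interpretation),
            class = "bidirectional_mr")
}

#' Mediation MR along a causal chain
#'
#' Estimates each edge of an ordered trait chain with IVW (instruments
#' selected per edge from the upstream trait's GWAS), takes the indirect
#' effect as the product of the edge estimates, the total effect as the
#' IVW estimate of the first trait on the outcome, and reports the
#' proportion mediated `indirect / total`. The product's SE uses the
#' delta method. A total of zero (proportion undefined) and opposite
#' signs of indirect and total ("inconsistent mediation") are flagged.
#'
#' @param chain list of [gwas_sumstats()] for the ordered upstream traits
#'   (exposure first, then mediators).
#' @param outcome [gwas_sumstats()] for the outcome.
#' @param panel LD reference panel.
#' @param instrument_p,r2_threshold instrument selection parameters.
#' @param formula `"indirect_over_total"` (default) or `"complement"`,
#'   which reports `(total - indirect) / total` — the share of the total
#'   effect NOT carried by the chain.
#' @return A `mediation_result` list: per-edge estimates, `indirect`
#'   (with delta-method SE), `total`, `proportion_mediated` and `flags`.
#' @export
mr_mediation <- function(chain, outcome, panel, instrument_p = 5e-8,
                         r2_threshold = 0.001,
                         formula = c("indirect_over_total", "complement")) {
  formula <- match.arg(formula)
  stopifnot(length(chain) >= 1)
  nodes <- c(chain, list(outcome))
  edges <- vector("list", length(nodes) - 1)
  for (i in seq_along(edges)) {
    instr <- harmonize_two_sample(nodes[[i]], nodes[[i + 1]], panel,
                                  instrument_p = instrument_p,
                                  r2_threshold = r2_threshold)
    edges[[i]] <- .primary_estimate(instr)
    names(edges)[i] <- paste(attr(nodes[[i]], "trait"),
                             attr(nodes[[i + 1]], "trait"), sep = " -> ")
  }
  total_instr <- harmonize_two_sample(chain[[1]], outcome, panel,
                                      instrument_p = instrument_p,
                                      r2_threshold = r2_threshold)
  total <- .primary_estimate(total_instr)

  edge_est <- vapply(edges, function(e) e$estimate, numeric(1))
  edge_se <- vapply(edges, function(e) e$se, numeric(1))
  indirect <- prod(edge_est)
  indirect_se <- abs(indirect) * sqrt(sum((edge_se / edge_est)^2))

  flags <- character()
  if (total$estimate == 0) {
    flags <- c(flags, "total effect is zero: proportion undefined")
    proportion <- NA_real_
  } else {
    proportion <- switch(formula,
                         indirect_over_total = indirect / total$estimate,
                         complement = (total$estimate - indirect) /
                           total$estimate)
    if (sign(indirect) != sign(total$estimate)) {
      flags <- c(flags, "inconsistent mediation: indirect and total have opposite signs")
    }
    if (is.finite(proportion) && abs(proportion) > 1) {
      flags <- c(flags, "proportion outside [-1, 1]")
    }
  }
  structure(list(edges = edges, indirect = indirect,
                 indirect_se = indirect_se, total = total,
                 proportion_mediated = proportion, formula = formula,
                 flags = flags),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Mediation MR\n")
  for (nm in names(x$edges)) {
    cat(sprintf("  %s: %.4f (se %.4f)\n", nm, x$edges[[nm]]$estimate,
                x$edges[[nm]]$se))
  }
  cat(sprintf("  Indirect (product): %.4f (se %.4f)\n", x$indirect,
              x$indirect_se))
  cat(sprintf("  Total: %.4f (se %.4f)\n", x$total$estimate, x$total$se))
  cat(sprintf("  Proportion mediated: %.3f\n", x$proportion_mediated))
  for (f in x$flags) cat("  Flag: ", f, "\n", sep = "")
  invisible(x)
}

#' Multivariable MR
#'
#' Joint (conditional) causal estimates for several exposures on one
#' outcome from summary statistics. Instruments are the union of each
#' exposure's clumped genome-wide-significant SNPs, restricted to SNPs
#' with effects available in every study (drops are logged), harmonized
#' to a common effect allele. The outcome effects are regressed on the
#' matrix of exposure effects with no intercept and weights
#' `1/se_out^2`. Univariable IVW estimates are fitted alongside and an
#' attenuation ratio (conditional / univariable) is reported per
#' exposure.
#'
#' @param exposures named list of [gwas_sumstats()].
#' @param outcome [gwas_sumstats()].
#' @param panel LD reference panel.
#' @param instrument_p,r2_threshold instrument selection parameters.
#' @return A `mvmr_result` list: `estimates` data.frame (conditional
#'   estimate, se, p, univariable estimate, attenuation), instrument
#'   count and drop log. Errors when the exposure-effect matrix is rank
#'   deficient, naming the collinear exposures.
#' @export
mr_mvmr <- function(exposures, outcome, panel, instrument_p = 5e-8,
                    r2_threshold = 0.001) {
  stopifnot(length(exposures) >= 1)
  if (is.null(names(exposures))) {
    names(exposures) <- vapply(exposures, function(e)
      attr(e, "trait"), character(1))
  }
  log <- .empty_log()
  sel <- lapply(exposures, function(e) {
    suppressWarnings(ld_clump(e, panel, p_threshold = instrument_p,
                              r2_threshold = r2_threshold))$snp
  })
  union_snps <- Reduce(union, sel)
  if (!length(union_snps)) stop("no instruments across exposures")
  ref <- exposures[[1]]
  keep <- union_snps
  for (nm in names(exposures)) {
    absent <- setdiff(keep, exposures[[nm]]$snp)
    if (length(absent)) {
      log <- rbind(log, .log_row(absent, paste0("absent from exposure '", nm,
                                                "'")))
      keep <- setdiff(keep, absent)
    }
  }
  absent <- setdiff(keep, outcome$snp)
  if (length(absent)) {
    log <- rbind(log, .log_row(absent, "absent from outcome"))
    keep <- setdiff(keep, absent)
  }
  if (!length(keep)) stop("no instruments present in all studies")

  ref_rows <- as.data.frame(ref)[match(keep, ref$snp), ]
  align_to_ref <- function(stats) {
    idx <- match(keep, stats$snp)
    mult <- numeric(length(keep))
    for (i in seq_along(keep)) {
      s <- stats[idx[i], ]
      al <- .align_alleles(s$effect_allele, s$other_allele,
                           ref_rows$effect_allele[i],
                           ref_rows$other_allele[i], s$eaf, ref_rows$eaf[i])
      mult[i] <- al$mult
    }
    list(beta = stats$beta[idx] * mult, se = stats$se[idx], mult = mult)
  }
  aligned <- lapply(exposures, align_to_ref)
  out_al <- align_to_ref(outcome)
  ok <- !is.na(out_al$mult) &
    Reduce(`&`, lapply(aligned, function(a) !is.na(a$mult)))
  if (any(!ok)) {
    log <- rbind(log, .log_row(keep[!ok], "ambiguous alleles across studies"))
  }
  if (sum(ok) < length(exposures)) {
    stop("fewer usable instruments (", sum(ok), ") than exposures")
  }
  X <- do.call(cbind, lapply(aligned, function(a) a$beta[ok]))
  colnames(X) <- names(exposures)
  gy <- out_al$beta[ok]
  w <- 1 / outcome$se[match(keep, outcome$snp)][ok]^2
  if (qr(X)$rank < ncol(X)) {
    cc <- stats::cor(X)
    pairs <- which(abs(cc) > 0.999 & upper.tri(cc), arr.ind = TRUE)
    guilty <- if (nrow(pairs)) {
      unique(c(colnames(X)[pairs[, 1]], colnames(X)[pairs[, 2]]))
    } else colnames(X)
    stop("exposure-effect matrix is rank deficient; collinear exposures: ",
         paste(guilty, collapse = ", "))
  }
  fit <- .wls_fit(X, gy, w)
  z <- fit$coef / fit$se
  uni <- vapply(names(exposures), function(nm) {
    instr <- tryCatch(harmonize_two_sample(exposures[[nm]], outcome, panel,
                                           instrument_p = instrument_p,
                                           r2_threshold = r2_threshold),
                      error = function(e) NULL)
    if (is.null(instr)) return(NA_real_)
    .primary_estimate(instr)$estimate
  }, numeric(1))
  estimates <- data.frame(exposure = names(exposures),
                          estimate = unname(fit$coef), se = unname(fit$se),
                          p = unname(.two_sided_p(z)),
                          univariable = unname(uni),
                          attenuation = unname(fit$coef / uni),
                          stringsAsFactors = FALSE)
  structure(list(estimates = estimates, n_instruments = sum(ok),
                 snps = keep[ok], log = log),
            class = "mvmr_result")
}

#' @export
print.mvmr_result <- function(x, ...) {
  cat(sprintf("Multivariable MR: %d exposure(s), %d instrument(s)\n",
              nrow(x$estimates), x$n_instruments))
  print(format(x$estimates, digits = 4), row.names = FALSE)
  invisible(x)
}
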