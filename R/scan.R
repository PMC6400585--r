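#' McFadden pseudo R-squared
#'
#' `1 - ln(L_m) / ln(L_0)` for likelihood-based regression models, using
#' the log-likelihood of the fitted (score-only, covariate-unadjusted)
#' model and of the intercept-only model.
#'
#' @param loglik_model log-likelihood of the fitted model.
#' @param loglik_null log-likelihood of the intercept-only model; must be
#'   strictly negative.
#' @return The pseudo R-squared.
#' @export
mcfadden_r2 <- function(loglik_model, loglik_null) {
  loglik_model <- as.numeric(loglik_model)
  loglik_null <- as.numeric(loglik_null)
  if (!is.finite(loglik_null) || loglik_null == 0) {
    stop("null model log-likelihood must be strictly negative")
  }
  1 - loglik_model / loglik_null
}

#' Bonferroni-corrected p-value threshold
#'
#' @param n_tests number of tests (>= 1).
#' @return `0.05 / n_tests`.
#' @export
bonferroni_threshold <- function(n_tests) {
  if (length(n_tests) != 1 || !is.finite(n_tests) || n_tests < 1) {
    stop("n_tests must be a single number >= 1")
  }
  0.05 / n_tests
}

.as_score_numeric <- function(score) {
  if (inherits(score, "score_vector")) {
    out <- score$raw
    names(out) <- score$iid
    out
  } else {
    as.numeric(score)
  }
}

.empty_association <- function(score_name, trait_name, family, note,
                               covariates) {
  structure(data.frame(score = score_name, trait = trait_name,
                       family = family, estimate = NA_real_, se = NA_real_,
                       p = NA_real_, or = NA_real_, ci_lower = NA_real_,
                       ci_upper = NA_real_, n = NA_integer_, r2 = NA_real_,
                       converged = FALSE, note = note,
                       covariates = paste(covariates, collapse = ","),
                       stringsAsFactors = FALSE),
            class = c("association_result", "data.frame"))
}

#' Association between one score and one trait
#'
#' Fits the family-appropriate regression of a trait on a standardized
#' score with covariate adjustment: linear for continuous traits, logistic
#' for binary, proportional-odds (ordinal logistic) for ordered traits,
#' and multinomial logistic for unordered categorical traits (whose
#' headline p-value is the likelihood-ratio test of the score). The score
#' is standardized internally over the analysis rows, so effects are per
#' SD of score and invariant to affine rescaling of the raw score.
#' Variance explained is reported as R-squared (continuous) or McFadden
#' pseudo R-squared (other families), both from covariate-unadjusted
#' refits. Sex-restricted traits drop the sex covariate and restrict to
#' eligible individuals.
#'
#' @param score a `score_vector` or numeric vector.
#' @param trait trait values (numeric or factor per family).
#' @param covariates data.frame of covariates (or `NULL`).
#' @param spec a [trait_spec()] declaring the family, level ordering and
#'   sex restriction.
#' @param min_n minimum complete cases; below it the pair is skipped with
#'   a reason.
#' @return One-row `association_result` data.frame: estimate per SD of
#'   score (log odds for odds-scale families, with OR and 95% CI), se, p,
#'   n, r2, convergence flag and notes. Non-convergence is flagged, never
#'   silently dropped.
#' @export
fit_association <- function(score, trait, covariates = NULL, spec,
                            min_n = 50) {
  stopifnot(inherits(spec, "trait_spec"))
  x <- .as_score_numeric(score)
  score_name <- attr(score, "score_name") %||% "score"
  df <- data.frame(.score = x)
  df$.trait <- trait
  cov_names <- character()
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    cov_names <- names(covariates)
    df <- cbind(df, covariates)
  }
  if (!is.na(spec$sex_restriction) && "sex" %in% cov_names) {
    wanted <- if (spec$sex_restriction == "female") 1 else 0
    df <- df[df$sex == wanted, , drop = FALSE]
    df$sex <- NULL
    cov_names <- setdiff(cov_names, "sex")
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) < min_n) {
    return(.empty_association(score_name, spec$name, spec$family,
                              sprintf("skipped: %d complete cases < %d",
                                      nrow(df), min_n), cov_names))
  }
  df$.score <- .standardize(df$.score, "score")
  rhs <- paste(c(".score", cov_names), collapse = " + ")
  fml <- stats::as.formula(paste(".trait ~", rhs))
  fml_score_only <- stats::as.formula(".trait ~ .score")

  res <- .empty_association(score_name, spec$name, spec$family, "", cov_names)
  res$n <- nrow(df)
  fit_try <- function(expr) tryCatch(expr, error = function(e) e)

  if (spec$family == "continuous") {
    fit <- fit_try(stats::lm(fml, data = df))
    if (inherits(fit, "error")) { res$note <- conditionMessage(fit); return(res) }
    cf <- summary(fit)$coefficients
    res$estimate <- cf[".score", 1]; res$se <- cf[".score", 2]
    res$p <- max(cf[".score", 4], 1e-300)
    res$converged <- TRUE
    res$r2 <- summary(stats::lm(fml_score_only, data = df))$r.squared
  } else if (spec$family == "binary") {
    fit <- fit_try(stats::glm(fml, data = df, family = stats::binomial()))
    if (inherits(fit, "error")) { res$note <- conditionMessage(fit); return(res) }
    cf <- summary(fit)$coefficients
    res$estimate <- cf[".score", 1]; res$se <- cf[".score", 2]
    res$p <- max(cf[".score", 4], 1e-300)
    res$or <- exp(res$estimate)
    res$ci_lower <- exp(res$estimate - 1.96 * res$se)
    res$ci_upper <- exp(res$estimate + 1.96 * res$se)
    res$converged <- isTRUE(fit$converged)
    if (!res$converged) res$note <- "glm did not converge"
    f1 <- stats::glm(fml_score_only, data = df, family = stats::binomial())
    f0 <- stats::glm(.trait ~ 1, data = df, family = stats::binomial())
    res$r2 <- mcfadden_r2(stats::logLik(f1), stats::logLik(f0))
  } else if (spec$family == "ordinal") {
    df$.trait <- factor(df$.trait, levels = spec$levels, ordered = TRUE)
    observed <- droplevels(df$.trait)
    if (nlevels(observed) == 2) {
      # proportional odds with two realized levels is exactly the
      # logistic model for the upper level
      df$.trait <- as.integer(df$.trait == levels(observed)[2])
      bin_spec <- spec
      bin_spec$family <- "binary"
      out <- fit_association(df$.score, df$.trait,
                             if (length(cov_names)) df[cov_names], bin_spec,
                             min_n = min_n)
      out$family <- "ordinal"
      out$score <- score_name
      return(out)
    }
    fit <- fit_try(MASS::polr(fml, data = df, Hess = TRUE))
    if (inherits(fit, "error")) { res$note <- conditionMessage(fit); return(res) }
    cf <- summary(fit)$coefficients
    res$estimate <- cf[".score", 1]; res$se <- cf[".score", 2]
    res$p <- max(.two_sided_p(res$estimate / res$se), 1e-300)
    res$or <- exp(res$estimate)
    res$ci_lower <- exp(res$estimate - 1.96 * res$se)
    res$ci_upper <- exp(res$estimate + 1.96 * res$se)
    res$converged <- fit$convergence == 0
    if (!res$converged) res$note <- "polr did not converge"
    f1 <- MASS::polr(fml_score_only, data = df)
    f0 <- MASS::polr(.trait ~ 1, data = df)
    res$r2 <- mcfadden_r2(stats::logLik(f1), stats::logLik(f0))
  } else { # categorical: multinomial logits vs reference; headline p = LR test
    df$.trait <- factor(df$.trait, levels = spec$levels)
    fit <- fit_try(nnet::multinom(fml, data = df, trace = FALSE))
    if (inherits(fit, "error")) { res$note <- conditionMessage(fit); return(res) }
    fml0 <- stats::as.formula(paste(".trait ~",
                                    paste(c("1", cov_names), collapse = " + ")))
    fit0 <- nnet::multinom(fml0, data = df, trace = FALSE)
    lr <- 2 * (stats::logLik(fit) - stats::logLik(fit0))
    k <- length(spec$levels) - 1
    res$p <- max(stats::pchisq(as.numeric(lr), df = k, lower.tail = FALSE),
                 1e-300)
    cf <- stats::coef(fit)
    if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1,
                                       dimnames = list(spec$levels[2],
                                                       names(cf)))
    per_level <- cf[, ".score"]
    se_all <- tryCatch(summary(fit)$standard.errors[, ".score"],
                       error = function(e) rep(NA_real_, k))
    # per-level z: the headline estimate is the level with the largest |z|
    z <- per_level / se_all
    lead <- if (all(is.na(z))) which.max(abs(per_level)) else which.max(abs(z))
    res$estimate <- per_level[lead]
    res$se <- se_all[lead]
    res$converged <- fit$convergence == 0
    if (!res$converged) res$note <- "multinom did not converge"
    f1 <- nnet::multinom(fml_score_only, data = df, trace = FALSE)
    f0 <- nnet::multinom(.trait ~ 1, data = df, trace = FALSE)
    res$r2 <- mcfadden_r2(stats::logLik(f1), stats::logLik(f0))
    attr(res, "levels") <- data.frame(level = rownames(cf),
                                      estimate = per_level, se = se_all)
  }
  res
}

#' Top-versus-bottom decile odds-ratio contrast
#'
#' Stratifies the sample into deciles of the score (type-7 empirical
#' quantiles; boundary ties go to the lower decile) and contrasts disease
#' odds between the top and bottom deciles. Without covariates this is
#' the 2x2 contingency odds ratio; with covariates it is the coefficient
#' of the top-decile indicator in a logistic model restricted to the two
#' extreme deciles. Zero cells get the Haldane-Anscombe 0.5 correction
#' and are flagged.
#'
#' @param score numeric score or `score_vector`.
#' @param trait binary outcome in `{0, 1}`.
#' @param covariates optional covariate data.frame.
#' @param min_cases minimum cases across the two extreme deciles.
#' @return A list with `or`, log-odds `estimate`, `se`, `ci` (95%), `p`,
#'   decile case/control counts and a `corrected` flag.
#' @export
decile_contrast <- function(score, trait, covariates = NULL, min_cases = 20) {
  x <- .as_score_numeric(score)
  stopifnot(length(x) == length(trait), all(trait %in% 0:1))
  qs <- stats::quantile(x, probs = 0:10 / 10, type = 7, names = FALSE)
  qs[1] <- -Inf; qs[11] <- Inf
  decile <- cut(x, breaks = qs, labels = FALSE, right = TRUE)
  extreme <- decile %in% c(1L, 10L)
  top <- decile == 10L
  cases <- sum(trait[extreme])
  if (cases < min_cases) {
    stop("only ", cases, " case(s) across the extreme deciles (need >= ",
         min_cases, ")")
  }
  if (is.null(covariates)) {
    a <- sum(trait == 1 & top); b <- sum(trait == 0 & top)
    c_ <- sum(trait == 1 & decile == 1L); d <- sum(trait == 0 & decile == 1L)
    corrected <- any(c(a, b, c_, d) == 0)
    if (corrected) { a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5 }
    est <- log((a / b) / (c_ / d))
    se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
    counts <- c(top_cases = sum(trait == 1 & top),
                top_controls = sum(trait == 0 & top),
                bottom_cases = sum(trait == 1 & decile == 1L),
                bottom_controls = sum(trait == 0 & decile == 1L))
  } else {
    df <- data.frame(.trait = trait, .top = as.integer(top),
                     as.data.frame(covariates))[extreme, , drop = FALSE]
    fml <- stats::as.formula(paste(".trait ~ .top +",
                                   paste(names(covariates), collapse = " + ")))
    fit <- stats::glm(fml, data = df, family = stats::binomial())
    cf <- summary(fit)$coefficients
    est <- cf[".top", 1]; se <- cf[".top", 2]
    corrected <- FALSE
    counts <- c(top_cases = sum(df$.trait == 1 & df$.top == 1),
                top_controls = sum(df$.trait == 0 & df$.top == 1),
                bottom_cases = sum(df$.trait == 1 & df$.top == 0),
                bottom_controls = sum(df$.trait == 0 & df$.top == 0))
  }
  list(or = exp(est), estimate = est, se = se,
       ci = exp(est + c(-1.96, 1.96) * se), p = .two_sided_p(est / se),
       counts = counts, corrected = corrected)
}

#' ROC curve and AUC
#'
#' AUC is computed with the rank statistic: the probability that a random
#' case outranks a random control, ties counting one half. Curve points
#' (sensitivity, 1 - specificity) are reported at every distinct
#' threshold.
#'
#' @param predictor numeric predictor (e.g. a standardized score).
#' @param outcome binary outcome in `{0, 1}`; both classes must be
#'   present.
#' @return A `roc_curve` list with `auc` and a `points` data.frame
#'   (`threshold`, `tpr`, `fpr`).
#' @export
roc_auc <- function(predictor, outcome) {
  stopifnot(length(predictor) == length(outcome), all(outcome %in% 0:1))
  n1 <- sum(outcome == 1); n0 <- sum(outcome == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(predictor)
  auc <- (sum(r[outcome == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thresholds <- sort(unique(predictor), decreasing = TRUE)
  tpr <- vapply(thresholds, function(t) sum(predictor >= t & outcome == 1) / n1,
                numeric(1))
  fpr <- vapply(thresholds, function(t) sum(predictor >= t & outcome == 0) / n0,
                numeric(1))
  points <- data.frame(threshold = c(Inf, thresholds), tpr = c(0, tpr),
                       fpr = c(0, fpr))
  structure(list(auc = auc, points = points), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: AUC = %.4f (%d threshold points)\n",
              x$auc, nrow(x$points)))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "l",
                 xlab = "1 - specificity", ylab = "Sensitivity",
                 main = sprintf("AUC = %.3f", x$auc), ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}

#' Scan plan: the score-by-trait cross product
#'
#' Row-count bookkeeping for a phenome scan: one planned test per
#' score-trait pair.
#'
#' @param score_names,trait_names character vectors.
#' @return data.frame with columns `score` and `trait`, one row per test.
#' @export
scan_plan <- function(score_names, trait_names) {
  out <- expand.grid(trait = trait_names, score = score_names,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out[, c("score", "trait")]
}

#' Phenome-wide association scan
#'
#' Regresses every score on every trait with covariate adjustment and
#' assembles the atlas table: effects per SD of score, p-values, pseudo
#' R-squared, Bonferroni flags and signed -log10(p) (the p-value's
#' magnitude signed by the effect direction, as plotted in phenome
#' plots). Individual fit failures are recorded per pair and the scan
#' continues, so row counts stay auditable.
#'
#' @param scores named list of `score_vector` objects (or numeric
#'   vectors).
#' @param cohort a `synthetic_cohort`, or a list with `phenotypes` and
#'   `covariates` data.frames.
#' @param trait_specs list of [trait_spec()] objects (defaults to the
#'   cohort's own truth specs).
#' @param covariates character vector of covariate columns to adjust for
#'   (default: all cohort covariates, i.e. age, sex, 10 PCs, chip).
#' @param bonferroni_scope `"per_score"` (threshold 0.05 / n traits, the
#'   phenome-plot convention) or `"overall"` (0.05 / total tests).
#' @return A `scan_result` data.frame, sorted by p within score, with
#'   attributes `bonferroni` and `n_tests`.
#' @export
run_scan <- function(scores, cohort, trait_specs = NULL, covariates = NULL,
                     bonferroni_scope = c("per_score", "overall")) {
  bonferroni_scope <- match.arg(bonferroni_scope)
  trait_specs <- trait_specs %||% cohort$truth
  stopifnot(length(scores) >= 1, length(trait_specs) >= 1)
  if (is.null(names(scores))) {
    names(scores) <- paste0("score", seq_along(scores))
  }
  cov <- cohort$covariates
  if (!is.null(covariates)) cov <- cov[, covariates, drop = FALSE]
  rows <- vector("list", length(scores) * length(trait_specs))
  i <- 0
  for (sname in names(scores)) {
    for (spec in trait_specs) {
      i <- i + 1
      row <- tryCatch(
        fit_association(scores[[sname]], cohort$phenotypes[[spec$name]],
                        cov, spec),
        error = function(e) .empty_association(sname, spec$name, spec$family,
                                               conditionMessage(e),
                                               names(cov)))
      row$score <- sname
      attr(row, "levels") <- NULL
      rows[[i]] <- as.data.frame(row)
    }
  }
  out <- do.call(rbind, rows)
  n_tests <- nrow(out)
  thr <- switch(bonferroni_scope,
                per_score = bonferroni_threshold(length(trait_specs)),
                overall = bonferroni_threshold(n_tests))
  out$signed_log10p <- -log10(out$p) * sign(out$estimate)
  out$bonferroni_pass <- !is.na(out$p) & out$p < thr
  out <- out[order(out$score, out$p), ]
  rownames(out) <- NULL
  structure(out, bonferroni = thr, n_tests = n_tests,
            bonferroni_scope = bonferroni_scope,
            class = c("scan_result", "data.frame"))
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("Phenome scan: %d tests, Bonferroni threshold %.3g (%s), %d pass\n",
              attr(x, "n_tests"), attr(x, "bonferroni"),
              attr(x, "bonferroni_scope"), sum(x$bonferroni_pass)))
  print(utils::head(as.data.frame(x)[, c("score", "trait", "family",
                                         "estimate", "se", "p",
                                         "signed_log10p",
                                         "bonferroni_pass")], 10))
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}
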