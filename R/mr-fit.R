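#' Fit two-sample Mendelian randomization models
#'
#' The central fitting function for summary-data MR: applies the
#' requested estimators to a harmonized instrument set and returns a
#' classed model object. With a single instrument all methods reduce to
#' the Wald ratio.
#'
#' @param instruments an [instrument_set()] (or a data.frame with its
#'   columns).
#' @param methods estimators to run, from `"ivw"`, `"egger"`,
#'   `"weighted_median"`, `"weighted_mode"`. Methods whose minimum
#'   instrument count is not met are skipped with a note.
#' @param ivw_model `"random"` (default) or `"fixed"`.
#' @param n_boot,seed bootstrap settings for the median and mode SEs.
#' @param phi bandwidth multiplier for the weighted mode.
#' @return An object of class `mr_fit`: a list with `estimates` (one row
#'   per method), `instruments`, `heterogeneity` (Cochran's Q),
#'   `pleiotropy` (the Egger intercept) and `notes`. Supports `print()`,
#'   `summary()`, `coef()`, `confint()`, `plot()` and `residuals()`.
#' @export
mr_fit <- function(instruments,
                   methods = c("ivw", "egger", "weighted_median",
                               "weighted_mode"),
                   ivw_model = "random", n_boot = 1000, seed = NULL,
                   phi = 1) {
  if (!inherits(instruments, "instrument_set")) {
    instruments <- instrument_set(instruments)
  }
  methods <- match.arg(methods, several.ok = TRUE)
  j <- nrow(instruments)
  if (j < 1) stop("no instruments")
  notes <- character()
  rows <- list()
  if (j == 1) {
    rows$wald <- wald_ratio(instruments$beta_exp, instruments$se_exp,
                            instruments$beta_out, instruments$se_out)
    notes <- c(notes, "single instrument: all methods reduce to the Wald ratio")
  } else {
    if ("ivw" %in% methods) rows$ivw <- mr_ivw(instruments, model = ivw_model)
    if ("egger" %in% methods) {
      if (j >= 3) rows$egger <- mr_egger(instruments)
      else notes <- c(notes, "egger skipped: needs >= 3 instruments")
    }
    if ("weighted_median" %in% methods) {
      if (j >= 3) rows$wm <- mr_weighted_median(instruments, n_boot, seed)
      else notes <- c(notes, "weighted_median skipped: needs >= 3 instruments")
    }
    if ("weighted_mode" %in% methods) {
      if (j >= 3) rows$mo <- mr_weighted_mode(instruments, phi, n_boot, seed)
      else notes <- c(notes, "weighted_mode skipped: needs >= 3 instruments")
    }
  }
  estimates <- do.call(rbind, unname(rows))
  ivw_row <- estimates[grepl("^ivw", estimates$method), , drop = FALSE]
  egger_row <- estimates[estimates$method == "egger", , drop = FALSE]
  structure(list(
    estimates = estimates,
    instruments = instruments,
    heterogeneity = if (nrow(ivw_row)) ivw_row[, c("Q", "Q_df", "Q_p")],
    pleiotropy = if (nrow(egger_row)) {
      egger_row[, c("intercept", "intercept_se", "intercept_p")]
    },
    notes = notes,
    exposure = attr(instruments, "exposure"),
    outcome = attr(instruments, "outcome"),
    call = match.call()), class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Two-sample MR: %s -> %s (%d instrument(s))\n",
              x$exposure, x$outcome, nrow(x$instruments)))
  print(format(x$estimates[, c("method", "estimate", "se", "p")],
               digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, digits = 4, ...) {
  f <- x$fit
  print(f, digits = digits)
  if (!is.null(f$heterogeneity)) {
    cat(sprintf("Heterogeneity: Q = %.3f on %d df (p = %.3g)\n",
                f$heterogeneity$Q, f$heterogeneity$Q_df, f$heterogeneity$Q_p))
  }
  if (!is.null(f$pleiotropy)) {
    cat(sprintf("Egger intercept: %.4f (se %.4f, p = %.3g)\n",
                f$pleiotropy$intercept, f$pleiotropy$intercept_se,
                f$pleiotropy$intercept_p))
  }
  for (n in f$notes) cat("Note: ", n, "\n", sep = "")
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  stats::setNames(object$estimates$estimate, object$estimates$method)
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- object$estimates
  out <- cbind(est$estimate - z * est$se, est$estimate + z * est$se)
  dimnames(out) <- list(est$method,
                        sprintf("%.1f %%", c((1 - level) / 2,
                                             1 - (1 - level) / 2) * 100))
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
residuals.mr_fit <- function(object, ...) {
  est <- coef(object)
  slope <- if ("ivw_random" %in% names(est)) est[["ivw_random"]]
           else if ("ivw_fixed" %in% names(est)) est[["ivw_fixed"]]
           else est[[1]]
  instr <- object$instruments
  stats::setNames(instr$beta_out - slope * instr$beta_exp, instr$snp)
}

#' @export
plot.mr_fit <- function(x, ...) {
  instr <- x$instruments
  flip <- sign(instr$beta_exp)
  flip[flip == 0] <- 1
  bx <- instr$beta_exp * flip
  by <- instr$beta_out * flip
  graphics::plot(bx, by, pch = 19,
                 xlim = range(0, bx + instr$se_exp, bx - instr$se_exp),
                 xlab = sprintf("SNP effect on %s", x$exposure),
                 ylab = sprintf("SNP effect on %s", x$outcome), ...)
  graphics::arrows(bx, by - instr$se_out, bx, by + instr$se_out,
                   angle = 90, code = 3, length = 0.02, col = "grey40")
  graphics::arrows(bx - instr$se_exp, by, bx + instr$se_exp, by,
                   angle = 90, code = 3, length = 0.02, col = "grey40")
  est <- x$estimates
  cols <- seq_len(nrow(est)) + 1
  for (i in seq_len(nrow(est))) {
    if (est$method[i] == "egger") {
      graphics::abline(est$intercept[i], est$estimate[i], col = cols[i])
    } else {
      graphics::abline(0, est$estimate[i], col = cols[i])
    }
  }
  graphics::legend("topleft", legend = est$method, col = cols, lty = 1,
                   bty = "n", cex = 0.8)
  invisible(x)
}
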