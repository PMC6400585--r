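# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.BASES <- c("A", "C", "G", "T")

.complement <- function(a) chartr("ACGT", "TGCA", a)

# A/T and C/G pairs: strand orientation cannot be resolved from alleles alone.
.is_palindromic <- function(ea, oa) .complement(ea) == oa

.valid_allele <- function(a) a %in% .BASES

# Weighted least squares with the multiplicative random-effects convention
# used throughout summary-data MR: residual scale is floored at 1 so SEs are
# never deflated below the fixed-effect value.
.wls_fit <- function(X, y, w) {
  X <- as.matrix(X)
  sw <- sqrt(w)
  Xw <- X * sw
  yw <- y * sw
  qr_x <- qr(Xw)
  if (qr_x$rank < ncol(X)) {
    stop("design matrix is rank deficient (collinear columns: ",
         paste(colnames(X) %||% seq_len(ncol(X)), collapse = ", "), ")")
  }
  xtx_inv <- chol2inv(chol(crossprod(Xw)))
  beta <- drop(xtx_inv %*% crossprod(Xw, yw))
  resid <- drop(yw - Xw %*% beta)
  rdf <- nrow(X) - ncol(X)
  sigma <- if (rdf > 0) sqrt(sum(resid^2) / rdf) else NA_real_
  se_fixed <- sqrt(diag(xtx_inv))
  se <- if (rdf > 0) se_fixed * max(1, sigma) else se_fixed
  names(beta) <- names(se) <- names(se_fixed) <- colnames(X)
  list(coef = beta, se = se, se_fixed = se_fixed, sigma = sigma,
       rdf = rdf, rss = sum(resid^2))
}

# Sample-sd standardization used for every score: mean 0, sd 1 (n - 1).
.standardize <- function(x, label = "values") {
  if (length(x) < 2L) stop("need at least 2 ", label, " to standardize")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("cannot standardize '", label, "': zero variance")
  }
  (x - mean(x)) / s
}

.two_sided_p <- function(z) 2 * stats::pnorm(-abs(z))

# Structured drop log rows used by harmonization/clumping bookkeeping.
.log_row <- function(snp, reason) {
  data.frame(snp = as.character(snp), reason = as.character(reason),
             stringsAsFactors = FALSE)
}

.empty_log <- function() {
  data.frame(snp = character(), reason = character(), stringsAsFactors = FALSE)
}
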