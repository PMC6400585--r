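#' Score definition
#'
#' The clumped, harmonized SNP/weight list defining one polygenic risk
#' score.
#'
#' @param data data.frame with columns `snp`, `effect_allele`,
#'   `other_allele`, `eaf`, `weight`, `pval`, `source`.
#' @param weighted logical: `FALSE` for unweighted scores, whose weights
#'   must all be -1 or +1 (the sign of the reported beta).
#' @param p_threshold,r2_threshold thresholds used to build the
#'   definition.
#' @param log data.frame of dropped SNPs with reasons.
#' @return A `score_definition` data.frame.
#' @export
score_definition <- function(data, weighted = TRUE, p_threshold = NA,
                             r2_threshold = NA, log = .empty_log()) {
  required <- c("snp", "effect_allele", "other_allele", "eaf", "weight",
                "pval", "source")
  stopifnot(all(required %in% names(data)))
  if (anyDuplicated(data$snp)) stop("duplicate SNP ids in score definition")
  if (!weighted && nrow(data) && !all(data$weight %in% c(-1, 1))) {
    stop("unweighted score definitions must have weights in {-1, +1}")
  }
  rownames(data) <- NULL
  structure(as.data.frame(data)[required],
            weighted = isTRUE(weighted), p_threshold = p_threshold,
            r2_threshold = r2_threshold, log = log,
            class = c("score_definition", "data.frame"))
}

#' @export
print.score_definition <- function(x, ...) {
  cat(sprintf("Score definition: %d SNP(s), %s, p <= %s, r2 < %s\n",
              nrow(x), if (attr(x, "weighted")) "weighted" else "unweighted",
              format(attr(x, "p_threshold")), format(attr(x, "r2_threshold"))))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}

# Pairwise dosage correlation of the named SNPs in the panel.
.panel_cor <- function(panel, snps) {
  stats::cor(panel$dosages[, snps, drop = FALSE])
}

#' Greedy LD clumping
#'
#' Selects approximately independent SNPs: candidates at
#' `pval <= p_threshold` are ranked by ascending p (ties broken by
#' chromosome, position, then id); the best is accepted and all remaining
#' candidates within `window_kb` whose panel r-squared with any accepted
#' SNP is at or above `r2_threshold` are removed; repeat until exhausted.
#' GWAS betas become the score weights.
#'
#' @param stats a [gwas_sumstats()] object.
#' @param panel a `genotype_matrix` reference panel with positions.
#' @param p_threshold inclusion p-value threshold (the lenient scoring
#'   default; use 5e-8 for MR instruments).
#' @param r2_threshold LD pruning threshold.
#' @param window_kb clumping window in kilobases.
#' @return A [score_definition()] with the retained SNPs; empty (with a
#'   warning) when no SNP passes the threshold.
#' @export
ld_clump <- function(stats, panel, p_threshold = 5e-5, r2_threshold = 0.001,
                     window_kb = 10000) {
  stopifnot(inherits(stats, "gwas_sumstats"),
            inherits(panel, "genotype_matrix"))
  log <- .empty_log()
  cand <- as.data.frame(stats)[stats$pval <= p_threshold, , drop = FALSE]
  in_panel <- cand$snp %in% panel$map$snp
  if (any(!in_panel)) {
    log <- rbind(log, .log_row(cand$snp[!in_panel], "absent from LD panel"))
    cand <- cand[in_panel, , drop = FALSE]
  }
  empty <- function() {
    score_definition(data.frame(snp = character(), effect_allele = character(),
                                other_allele = character(), eaf = numeric(),
                                weight = numeric(), pval = numeric(),
                                source = character()),
                     p_threshold = p_threshold, r2_threshold = r2_threshold,
                     log = log)
  }
  if (!nrow(cand)) {
    warning("no SNP passes p <= ", format(p_threshold),
            "; returning an empty score definition")
    return(empty())
  }
  pos <- panel$map[match(cand$snp, panel$map$snp), c("chr", "pos")]
  ord <- order(cand$pval, pos$chr, pos$pos, cand$snp)
  cand <- cand[ord, , drop = FALSE]
  pos <- pos[ord, , drop = FALSE]
  r2 <- .panel_cor(panel, cand$snp)^2

  active <- rep(TRUE, nrow(cand))
  accepted <- integer()
  for (i in seq_len(nrow(cand))) {
    if (!active[i]) next
    accepted <- c(accepted, i)
    active[i] <- FALSE
    in_window <- pos$chr == pos$chr[i] &
      abs(pos$pos - pos$pos[i]) <= window_kb * 1000
    kill <- which(active & in_window & r2[i, ] >= r2_threshold)
    if (length(kill)) {
      log <- rbind(log, .log_row(cand$snp[kill],
                                 sprintf("clumped away by %s (r2 >= %s)",
                                         cand$snp[i], format(r2_threshold))))
      active[kill] <- FALSE
    }
  }
  kept <- cand[accepted, , drop = FALSE]
  score_definition(data.frame(snp = kept$snp,
                              effect_allele = kept$effect_allele,
                              other_allele = kept$other_allele,
                              eaf = kept$eaf, weight = kept$beta,
                              pval = kept$pval, source = "direct",
                              stringsAsFactors = FALSE),
                   p_threshold = p_threshold, r2_threshold = r2_threshold,
                   log = log)
}

#' Find a proxy SNP in high LD
#'
#' For a score SNP missing from the cohort genotypes, returns the panel
#' SNP (among those available in the cohort) with maximal r-squared, if it
#' reaches `r2_min`. The returned sign flag records whether the proxy
#' dosage is negatively correlated with the target, in which case the
#' weight's sign must flip.
#'
#' @param snp target SNP id (present in the panel).
#' @param panel a `genotype_matrix`.
#' @param available_snps SNP ids usable as proxies (e.g. the cohort's
#'   genotyped SNPs).
#' @param r2_min minimum r-squared (default 0.8).
#' @return `NULL` when no proxy reaches `r2_min`; otherwise a list with
#'   `proxy`, `r`, `r2` and `sign_flip`.
#' @export
find_proxy <- function(snp, panel, available_snps, r2_min = 0.8) {
  stopifnot(snp %in% panel$map$snp)
  candidates <- setdiff(intersect(available_snps, panel$map$snp), snp)
  if (!length(candidates)) return(NULL)
  r <- drop(stats::cor(panel$dosages[, snp],
                       panel$dosages[, candidates, drop = FALSE]))
  best <- which.max(r^2)
  if (r[best]^2 < r2_min) return(NULL)
  list(proxy = candidates[best], r = unname(r[best]), r2 = unname(r[best]^2),
       sign_flip = r[best] < 0)
}

# Align one GWAS allele pair to a target coding. Returns the weight-sign
# multiplier (+1/-1), or NA when irreconcilable / ambiguous-palindromic.
.align_alleles <- function(ea, oa, target_ea, target_oa, eaf, target_eaf,
                           ambiguity_band = c(0.42, 0.58)) {
  if (.is_palindromic(ea, oa)) {
    if (!is.na(eaf) && eaf >= ambiguity_band[1] && eaf <= ambiguity_band[2]) {
      return(list(mult = NA_real_, reason = "palindromic, ambiguous frequency"))
    }
    # outside the ambiguity band: align by frequency side
    if (is.na(eaf) || is.na(target_eaf)) {
      return(list(mult = NA_real_, reason = "palindromic, frequency missing"))
    }
    same_side <- (eaf < 0.5) == (target_eaf < 0.5)
    return(list(mult = if (same_side) 1 else -1, reason = NULL))
  }
  if (ea == target_ea && oa == target_oa) return(list(mult = 1, reason = NULL))
  if (ea == target_oa && oa == target_ea) return(list(mult = -1, reason = NULL))
  cea <- .complement(ea); coa <- .complement(oa)
  if (cea == target_ea && coa == target_oa) return(list(mult = 1, reason = NULL))
  if (cea == target_oa && coa == target_ea) return(list(mult = -1, reason = NULL))
  list(mult = NA_real_, reason = "alleles irreconcilable")
}

#' Harmonize a score definition to cohort allele coding
#'
#' Aligns each score SNP's weight to the allele counted in the cohort:
#' allele swaps negate the weight, strand flips are resolved by
#' complementing, palindromic SNPs (A/T, C/G) with effect-allele frequency
#' inside `[0.42, 0.58]` are dropped and those outside are aligned by
#' frequency. Irreconcilable or absent SNPs are dropped with a logged
#' reason.
#'
#' @param definition a [score_definition()].
#' @param cohort_map data.frame with columns `snp`, `effect_allele`,
#'   `other_allele`, `freq` (frequency of the cohort's counted allele).
#' @return A harmonized [score_definition()] in the cohort's allele
#'   coding.
#' @export
harmonize_alleles <- function(definition, cohort_map) {
  stopifnot(inherits(definition, "score_definition"))
  log <- attr(definition, "log")
  idx <- match(definition$snp, cohort_map$snp)
  out <- as.data.frame(definition)
  keep <- logical(nrow(out))
  for (i in seq_len(nrow(out))) {
    if (is.na(idx[i])) {
      log <- rbind(log, .log_row(out$snp[i], "absent from cohort genotypes"))
      next
    }
    cm <- cohort_map[idx[i], ]
    al <- .align_alleles(out$effect_allele[i], out$other_allele[i],
                         cm$effect_allele, cm$other_allele,
                         out$eaf[i], cm$freq)
    if (is.na(al$mult)) {
      log <- rbind(log, .log_row(out$snp[i], al$reason))
      next
    }
    keep[i] <- TRUE
    out$weight[i] <- out$weight[i] * al$mult
    if (al$mult < 0) out$eaf[i] <- 1 - out$eaf[i]
    out$effect_allele[i] <- cm$effect_allele
    out$other_allele[i] <- cm$other_allele
  }
  score_definition(out[keep, , drop = FALSE],
                   weighted = attr(definition, "weighted"),
                   p_threshold = attr(definition, "p_threshold"),
                   r2_threshold = attr(definition, "r2_threshold"),
                   log = log)
}

#' Compute a polygenic risk score
#'
#' Raw score per individual: the weighted sum of effect-allele dosages
#' over the definition's SNPs. For unweighted definitions the weight is
#' the sign of the reported beta, so the score counts trait-increasing
#' alleles. Missing dosages contribute the cohort-mean dosage at that SNP
#' (mean imputation); SNPs absent from the genotypes are excluded with the
#' count reported.
#'
#' @param genotypes a `genotype_matrix` (harmonized to the definition's
#'   allele coding).
#' @param definition a [score_definition()].
#' @param na_action `"impute"` (cohort-mean dosage, the default, keeping n
#'   constant) or `"omit"` (drop individuals with any missing dosage).
#' @return A `score_vector` data.frame with columns `iid`, `raw` and
#'   `standardized` (`NA` until [standardize_score()] is applied);
#'   attributes `n_snps` and `n_excluded`.
#' @export
compute_score <- function(genotypes, definition,
                          na_action = c("impute", "omit")) {
  stopifnot(inherits(definition, "score_definition"))
  na_action <- match.arg(na_action)
  present <- definition$snp %in% colnames(genotypes$dosages)
  n_excluded <- sum(!present)
  if (n_excluded) {
    message(n_excluded, " score SNP(s) absent from genotypes, excluded")
  }
  def <- as.data.frame(definition)[present, , drop = FALSE]
  w <- if (attr(definition, "weighted")) def$weight else sign(def$weight)
  G <- genotypes$dosages[, def$snp, drop = FALSE]
  if (anyNA(G)) {
    if (na_action == "impute") {
      for (j in seq_len(ncol(G))) {
        nas <- is.na(G[, j])
        if (any(nas)) G[nas, j] <- mean(G[, j], na.rm = TRUE)
      }
    } else {
      G <- G[stats::complete.cases(G), , drop = FALSE]
    }
  }
  raw <- if (ncol(G)) drop(G %*% w) else rep(0, nrow(G))
  structure(data.frame(iid = rownames(G), raw = raw,
                       standardized = NA_real_, stringsAsFactors = FALSE),
            n_snps = nrow(def), n_excluded = n_excluded,
            class = c("score_vector", "data.frame"))
}

#' Standardize a score to mean 0, SD 1
#'
#' Centers and scales raw scores over the analysis sample, using the
#' sample SD (n - 1 denominator).
#'
#' @param score a `score_vector` (from [compute_score()]) or a bare
#'   numeric vector.
#' @param name label used in error messages.
#' @return The `score_vector` with its `standardized` column filled (or a
#'   standardized numeric vector for numeric input). Errors on zero
#'   variance.
#' @export
standardize_score <- function(score, name = "score") {
  if (is.numeric(score)) return(.standardize(score, name))
  stopifnot(inherits(score, "score_vector"))
  score$standardized <- .standardize(score$raw, name)
  score
}

#' Combine standardized scores
#'
#' Sums standardized component scores over the same individuals and
#' re-standardizes the sum, as when a disease score is pooled with scores
#' for its established risk factors.
#'
#' @param ... `score_vector` objects (standardized) or a single list of
#'   them.
#' @return A standardized `score_vector` for the combined score.
#' @export
combine_scores <- function(...) {
  scores <- list(...)
  if (length(scores) == 1 && is.list(scores[[1]]) &&
      !inherits(scores[[1]], "score_vector")) {
    scores <- scores[[1]]
  }
  stopifnot(length(scores) >= 1)
  ids <- scores[[1]]$iid
  total <- rep(0, length(ids))
  for (s in scores) {
    stopifnot(inherits(s, "score_vector"))
    if (!identical(sort(s$iid), sort(ids))) {
      stop("scores cover different individual sets; cannot combine")
    }
    if (anyNA(s$standardized)) {
      s <- standardize_score(s)
    }
    total <- total + s$standardized[match(ids, s$iid)]
  }
  out <- data.frame(iid = ids, raw = total, standardized = NA_real_,
                    stringsAsFactors = FALSE)
  out <- structure(out, n_snps = NA_integer_, n_excluded = 0L,
                   class = c("score_vector", "data.frame"))
  standardize_score(out, "combined score")
}
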