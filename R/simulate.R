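#' Simulation configuration
#'
#' Bundles the parameters of the two-sample GWAS generative model: additive
#' genotypes in Hardy-Weinberg proportions, an exposure built from causal
#' SNPs and scaled to a target SNP heritability, and an outcome receiving
#' the causal effect of the exposure plus direct (horizontally pleiotropic)
#' SNP effects on a configurable fraction of SNPs.
#'
#' @param n_individuals individuals per GWAS sample (the exposure and
#'   outcome samples are disjoint and each of this size).
#' @param n_snps number of biallelic SNPs.
#' @param maf_range length-2 allele-frequency range in (0, 1) from which
#'   per-SNP frequencies are drawn uniformly.
#' @param causal_effect true causal effect of the exposure on the outcome
#'   (per unit of exposure; the exposure has unit variance).
#' @param n_causal_snps number of SNPs with nonzero exposure effects.
#' @param pleiotropy_fraction proportion of SNPs with direct outcome
#'   effects, violating the exclusion restriction.
#' @param pleiotropy_mean,pleiotropy_sd Normal distribution of the direct
#'   effects: directional pleiotropy when the mean is nonzero, balanced
#'   when zero.
#' @param heritability_exposure proportion of exposure variance explained
#'   by the causal SNPs, in (0, 1).
#' @param seed integer seed, or `NULL` to continue the current RNG stream.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_individuals = 10000, n_snps = 50,
                       maf_range = c(0.05, 0.5), causal_effect = 0,
                       n_causal_snps = n_snps, pleiotropy_fraction = 0,
                       pleiotropy_mean = 0, pleiotropy_sd = 0.05,
                       heritability_exposure = 0.3, seed = NULL) {
  .check_maf_range(maf_range)
  stopifnot(n_individuals >= 10, n_snps >= 1,
            n_causal_snps >= 0, n_causal_snps <= n_snps,
            pleiotropy_fraction >= 0, pleiotropy_fraction <= 1,
            heritability_exposure > 0, heritability_exposure < 1,
            pleiotropy_sd >= 0)
  structure(list(n_individuals = as.integer(n_individuals),
                 n_snps = as.integer(n_snps),
                 maf_range = as.numeric(maf_range),
                 causal_effect = causal_effect,
                 n_causal_snps = as.integer(n_causal_snps),
                 pleiotropy_fraction = pleiotropy_fraction,
                 pleiotropy_mean = pleiotropy_mean,
                 pleiotropy_sd = pleiotropy_sd,
                 heritability_exposure = heritability_exposure,
                 seed = seed),
            class = "sim_config")
}

.check_maf_range <- function(maf_range) {
  if (length(maf_range) != 2 || any(!is.finite(maf_range))) {
    stop("maf_range must be two finite frequencies")
  }
  if (maf_range[1] > maf_range[2]) stop("maf_range must be non-decreasing")
  if (maf_range[1] <= 0 || maf_range[2] >= 1) {
    stop("maf_range must lie strictly inside (0, 1); degenerate ranges at ",
         "0 or 1 produce monomorphic SNPs")
  }
  invisible(TRUE)
}

# SNP metadata shared by every sample drawn from the same generative model:
# id, synthetic position, a random non-identical allele pair, and the
# generating allele frequency.
.make_snp_map <- function(m, maf_range, ld_blocks = NULL) {
  p <- stats::runif(m, maf_range[1], maf_range[2])
  if (!is.null(ld_blocks)) {
    for (blk in ld_blocks) p[blk$snps] <- p[blk$snps[1]]
  }
  ea <- sample(.BASES, m, replace = TRUE)
  oa <- vapply(ea, function(a) sample(setdiff(.BASES, a), 1), character(1))
  data.frame(snp = sprintf("rs%d", seq_len(m)), chr = 1L,
             pos = seq_len(m) * 5000L,
             effect_allele = ea, other_allele = unname(oa), maf = p,
             stringsAsFactors = FALSE)
}

# Dosages in {0,1,2} as the sum of two haplotypes. Within an LD block each
# haplotype allele copies a shared latent haplotype with probability
# s = r2^(1/4) (otherwise an independent Bernoulli(p) draw), giving
# haplotype correlation s^2 and dosage r^2 of s^4 = the requested r2;
# r2 = 1 reduces to exact duplicate columns.
.draw_dosages <- function(n, map, ld_blocks = NULL) {
  m <- nrow(map)
  p <- map$maf
  G <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), nrow = n, ncol = m)
  if (!is.null(ld_blocks)) {
    for (blk in ld_blocks) {
      idx <- blk$snps
      stopifnot(all(idx >= 1), all(idx <= m), blk$r2 >= 0, blk$r2 <= 1)
      s <- blk$r2^(1 / 4)
      pb <- p[idx[1]]
      lat1 <- stats::rbinom(n, 1L, pb)
      lat2 <- stats::rbinom(n, 1L, pb)
      for (j in idx) {
        if (s == 1) {
          G[, j] <- lat1 + lat2
        } else {
          copy1 <- stats::rbinom(n, 1L, s)
          copy2 <- stats::rbinom(n, 1L, s)
          h1 <- ifelse(copy1 == 1L, lat1, stats::rbinom(n, 1L, pb))
          h2 <- ifelse(copy2 == 1L, lat2, stats::rbinom(n, 1L, pb))
          G[, j] <- h1 + h2
        }
      }
    }
  }
  dimnames(G) <- list(sprintf("id%d", seq_len(n)), map$snp)
  G
}

.genotype_matrix <- function(dosages, map) {
  map$freq <- colMeans(dosages) / 2
  structure(list(dosages = dosages, map = map), class = "genotype_matrix")
}

#' Simulate a genotype matrix
#'
#' Draws `n` individuals at `m` biallelic SNPs as additive dosages
#' Binomial(2, p), with per-SNP frequencies p uniform on `maf_range`.
#' Optional LD blocks generate member SNPs from a shared latent haplotype
#' to achieve a requested pairwise dosage r-squared; a target of 1 yields
#' exact duplicate columns.
#'
#' @param n individuals.
#' @param m SNPs.
#' @param maf_range allele-frequency range, strictly inside (0, 1).
#' @param ld_blocks optional list of `list(snps = <indices>, r2 = <target>)`.
#' @param seed integer seed, or `NULL` to continue the RNG stream.
#' @return A `genotype_matrix`: list with `dosages` (individuals x SNPs)
#'   and `map` (snp, chr, pos, alleles, generating and empirical
#'   frequencies). Doubles as the LD reference panel.
#' @export
simulate_genotypes <- function(n, m, maf_range = c(0.05, 0.5),
                               ld_blocks = NULL, seed = NULL) {
  stopifnot(n >= 1, m >= 1)
  .check_maf_range(maf_range)
  if (!is.null(seed)) set.seed(seed)
  map <- .make_snp_map(m, maf_range, ld_blocks)
  .genotype_matrix(.draw_dosages(n, map, ld_blocks), map)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d individuals x %d SNPs\n",
              nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

#' Marginal per-SNP GWAS
#'
#' Runs the simple regression of a trait on each SNP dosage separately and
#' returns the results as [gwas_sumstats()]. This is the summary-statistic
#' generator for all simulated GWAS.
#'
#' @param genotypes a `genotype_matrix`.
#' @param y numeric trait, one value per individual.
#' @param trait,trait_type passed to [gwas_sumstats()].
#' @return A [gwas_sumstats()] object with one row per SNP.
#' @export
marginal_gwas <- function(genotypes, y, trait = "trait",
                          trait_type = "continuous") {
  G <- genotypes$dosages
  n <- nrow(G)
  stopifnot(length(y) == n, n > 2)
  gbar <- colMeans(G)
  ybar <- mean(y)
  ssg <- colSums(G^2) - n * gbar^2
  sxy <- colSums(G * y) - n * gbar * ybar
  ssy <- sum(y^2) - n * ybar^2
  beta <- sxy / ssg
  s2 <- pmax(ssy - beta * sxy, 0) / (n - 2)
  se <- sqrt(s2 / ssg)
  tt <- beta / se
  p <- pmax(2 * stats::pt(-abs(tt), n - 2), 1e-300)
  gwas_sumstats(data.frame(snp = genotypes$map$snp,
                           effect_allele = genotypes$map$effect_allele,
                           other_allele = genotypes$map$other_allele,
                           eaf = gbar / 2, beta = beta, se = se, pval = p,
                           n = n, stringsAsFactors = FALSE),
                trait = trait, trait_type = trait_type)
}

# Per-allele exposure effects for the causal SNPs: every causal SNP
# contributes an equal share h2 / n_causal of the exposure variance
# (b_j^2 2 p_j (1 - p_j) constant), and effects are positive so the
# effect allele is the exposure-increasing allele. Equal contributions
# keep every instrument comfortably above the genome-wide threshold at
# the default sample sizes, so instrument selection introduces no
# winner's-curse attenuation.
.exposure_effects <- function(config, map) {
  m <- config$n_snps
  b <- numeric(m)
  if (config$n_causal_snps == 0) {
    stop("heritability target ", config$heritability_exposure,
         " unreachable: no causal SNPs carry exposure effects")
  }
  idx <- seq_len(config$n_causal_snps)
  share <- config$heritability_exposure / config$n_causal_snps
  b[idx] <- sqrt(share / (2 * map$maf[idx] * (1 - map$maf[idx])))
  b
}

#' Simulate a two-sample GWAS pair with known causal truth
#'
#' Generates two disjoint samples from the same generative model. In the
#' exposure sample, the exposure is `x = G b + e` with the genetic
#' component scaled to `heritability_exposure`. In the outcome sample,
#' `y = beta * x + G alpha + e'` where `alpha` holds direct (pleiotropic)
#' SNP effects, nonzero for a `pleiotropy_fraction` of SNPs drawn
#' Normal(`pleiotropy_mean`, `pleiotropy_sd`^2). Marginal per-SNP GWAS run
#' separately in the two samples give the exposure and outcome summary
#' statistics. Causal SNPs contribute equal variance shares and are coded
#' with the exposure-increasing allele as the effect allele, so
#' directional pleiotropy (nonzero mean) is directional with respect to
#' that orientation.
#'
#' @param config a [sim_config()].
#' @param keep_samples keep the individual-level samples in the result
#'   (needed by the PRS arm of the simulation study).
#' @return A `two_sample_gwas` list: `exposure_stats`, `outcome_stats`
#'   ([gwas_sumstats()]), `truth` (causal `beta`, per-SNP exposure effects
#'   `b`, per-SNP pleiotropic effects `alpha`), `map`, and (optionally)
#'   `samples`.
#' @export
simulate_two_sample_gwas <- function(config, keep_samples = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_individuals
  map <- .make_snp_map(config$n_snps, config$maf_range)
  b <- .exposure_effects(config, map)

  n_pleio <- round(config$pleiotropy_fraction * config$n_snps)
  alpha <- numeric(config$n_snps)
  if (n_pleio > 0) {
    pleio_idx <- sample.int(config$n_snps, n_pleio)
    alpha[pleio_idx] <- stats::rnorm(n_pleio, config$pleiotropy_mean,
                                     config$pleiotropy_sd)
  }

  e_sd <- sqrt(1 - config$heritability_exposure)
  g_exp <- .genotype_matrix(.draw_dosages(n, map), map)
  x_exp <- drop(g_exp$dosages %*% b) + stats::rnorm(n, 0, e_sd)
  g_out <- .genotype_matrix(.draw_dosages(n, map), map)
  x_out <- drop(g_out$dosages %*% b) + stats::rnorm(n, 0, e_sd)
  y_out <- config$causal_effect * x_out + drop(g_out$dosages %*% alpha) +
    stats::rnorm(n)

  structure(list(
    exposure_stats = marginal_gwas(g_exp, x_exp, trait = "exposure"),
    outcome_stats = marginal_gwas(g_out, y_out, trait = "outcome"),
    truth = list(beta = config$causal_effect, b = b, alpha = alpha,
                 pleiotropic = which(alpha != 0)),
    map = map,
    samples = if (keep_samples) {
      list(exposure = list(genotypes = g_exp, x = x_exp),
           outcome = list(genotypes = g_out, y = y_out))
    },
    config = config), class = "two_sample_gwas")
}

#' Trait specification
#'
#' Declares one phenotype of a synthetic cohort (or of a phenome scan):
#' its model family, its generating effects, and any sex restriction.
#'
#' @param name trait name.
#' @param family one of `"continuous"`, `"binary"`, `"ordinal"`,
#'   `"categorical"`.
#' @param causal_snps character vector of SNP ids with genetic effects.
#' @param effects numeric effects per causal SNP (for categorical traits a
#'   matrix with one row per non-reference level).
#' @param covariate_effects named numeric vector over the covariate
#'   columns (`age`, `sex`, `pc1`..`pc10`, `chip`).
#' @param intercept intercept of the linear predictor (for categorical, a
#'   vector per non-reference level).
#' @param noise_sd residual SD (continuous only).
#' @param levels ordered level labels (ordinal, >= 3) or level labels with
#'   the reference first (categorical).
#' @param cutpoints ascending latent-scale cutpoints for ordinal traits
#'   (length `length(levels) - 1`).
#' @param sex_restriction `NA`, `"female"` or `"male"`: restrict analysis
#'   (and generation relevance) to one sex, as for age-at-menarche-type
#'   traits.
#' @return A `trait_spec` list.
#' @export
trait_spec <- function(name, family = c("continuous", "binary", "ordinal",
                                        "categorical"),
                       causal_snps = character(), effects = numeric(),
                       covariate_effects = NULL, intercept = 0,
                       noise_sd = 1, levels = NULL, cutpoints = NULL,
                       sex_restriction = NA_character_) {
  family <- match.arg(family)
  if (family == "ordinal") {
    if (is.null(levels) || length(levels) < 3) {
      stop("ordinal traits need >= 3 ordered levels")
    }
    if (is.null(cutpoints) || length(cutpoints) != length(levels) - 1 ||
        is.unsorted(cutpoints, strictly = TRUE)) {
      stop("ordinal traits need strictly ascending cutpoints, one fewer ",
           "than the number of levels")
    }
  }
  if (family == "categorical") {
    if (is.null(levels) || length(levels) < 2) {
      stop("categorical traits need >= 2 levels (reference first)")
    }
    effects <- rbind(effects)
    if (length(causal_snps) && ncol(effects) != length(causal_snps)) {
      stop("categorical effects must have one column per causal SNP")
    }
  } else if (length(effects) != length(causal_snps)) {
    stop("effects must match causal_snps in length")
  }
  structure(list(name = name, family = family, causal_snps = causal_snps,
                 effects = effects, covariate_effects = covariate_effects,
                 intercept = intercept, noise_sd = noise_sd,
                 levels = levels, cutpoints = cutpoints,
                 sex_restriction = sex_restriction),
            class = "trait_spec")
}

.COVARIATE_NAMES <- c("age", "sex", paste0("pc", 1:10), "chip")

.draw_covariates <- function(n) {
  cov <- data.frame(age = stats::rnorm(n, 57, 8),
                    sex = stats::rbinom(n, 1, 0.51))
  for (k in 1:10) cov[[paste0("pc", k)]] <- stats::rnorm(n)
  cov$chip <- stats::rbinom(n, 1, 0.5)
  rownames(cov) <- sprintf("id%d", seq_len(n))
  cov
}

.linear_predictor <- function(spec, G, cov, intercept, effects) {
  eta <- rep(intercept, nrow(G))
  if (length(spec$causal_snps)) {
    missing_snp <- setdiff(spec$causal_snps, colnames(G))
    if (length(missing_snp)) {
      stop("trait '", spec$name, "' references unknown SNP(s): ",
           paste(missing_snp, collapse = ", "))
    }
    eta <- eta + drop(G[, spec$causal_snps, drop = FALSE] %*% effects)
  }
  if (!is.null(spec$covariate_effects)) {
    bad <- setdiff(names(spec$covariate_effects), .COVARIATE_NAMES)
    if (length(bad)) stop("unknown covariate(s): ", paste(bad, collapse = ", "))
    for (nm in names(spec$covariate_effects)) {
      eta <- eta + spec$covariate_effects[[nm]] * cov[[nm]]
    }
  }
  eta
}

#' Simulate a multi-trait cohort
#'
#' Generates genotypes, covariates (age, sex, ten principal-component
#' surrogates, genotyping-chip indicator) and phenotypes of declared model
#' families with known generating effects: continuous traits are Gaussian
#' around the linear predictor, binary traits use a logistic link, ordinal
#' traits a proportional-odds latent variable with logistic noise, and
#' categorical traits multinomial logits against the reference level.
#'
#' @param config a [sim_config()] (supplies cohort size, SNP count,
#'   frequency range and seed).
#' @param trait_specs list of [trait_spec()] objects.
#' @return A `synthetic_cohort`: list with `genotypes`, `phenotypes`,
#'   `covariates` and `truth` (the trait specs).
#' @export
simulate_cohort <- function(config, trait_specs) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_individuals
  geno <- simulate_genotypes(n, config$n_snps, config$maf_range)
  cov <- .draw_covariates(n)
  G <- geno$dosages
  phen <- data.frame(row.names = rownames(cov))
  for (spec in trait_specs) {
    stopifnot(inherits(spec, "trait_spec"))
    if (spec$family == "categorical") {
      k <- length(spec$levels)
      eta <- matrix(0, n, k)  # reference level fixed at 0
      ints <- rep_len(spec$intercept, k - 1)
      for (l in seq_len(k - 1)) {
        eff_l <- if (length(spec$causal_snps)) spec$effects[l, ] else numeric()
        eta[, l + 1] <- .linear_predictor(spec, G, cov, ints[l], eff_l)
      }
      prob <- exp(eta - apply(eta, 1, max))
      prob <- prob / rowSums(prob)
      draw <- apply(prob, 1, function(p) sample.int(k, 1, prob = p))
      phen[[spec$name]] <- factor(spec$levels[draw], levels = spec$levels)
    } else {
      eta <- .linear_predictor(spec, G, cov, spec$intercept, spec$effects)
      phen[[spec$name]] <- switch(spec$family,
        continuous = eta + stats::rnorm(n, 0, spec$noise_sd),
        binary = stats::rbinom(n, 1, stats::plogis(eta)),
        ordinal = {
          latent <- eta + stats::rlogis(n)
          idx <- findInterval(latent, spec$cutpoints) + 1L
          factor(spec$levels[idx], levels = spec$levels, ordered = TRUE)
        })
    }
  }
  structure(list(genotypes = geno, phenotypes = phen, covariates = cov,
                 truth = trait_specs),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d individuals, %d SNPs, %d trait(s)\n",
              nrow(x$covariates), ncol(x$genotypes$dosages),
              ncol(x$phenotypes)))
  invisible(x)
}

#' Simulate a four-trait mediation chain
#'
#' Generates GWAS summary statistics for a causal chain
#' exposure -> mediator1 -> mediator2 -> outcome with an additional direct
#' exposure -> outcome path. Each of the three upstream traits carries its
#' own private instruments; each of the four GWAS is run in its own
#' disjoint sample over the union of all SNPs. The true proportion
#' mediated, `(b1*b2*b3) / (b1*b2*b3 + direct)`, is recorded in the truth.
#'
#' @param effects named numeric vector with elements `x_m1`, `m1_m2`,
#'   `m2_y` (path effects) and `direct` (direct exposure -> outcome
#'   effect).
#' @param n_per_gwas individuals in each of the four GWAS samples.
#' @param snps_per_trait private instruments per upstream trait.
#' @param h2 variance contributed by each trait's private instruments.
#' @param maf_range allele-frequency range.
#' @param n_panel individuals in the accompanying LD reference panel.
#' @param seed integer seed or `NULL`.
#' @return A `mediation_chain`: list with `gwas` (named list of four
#'   [gwas_sumstats()]), `panel` (a `genotype_matrix`), `truth` (edge
#'   effects, direct, indirect, total, `proportion_mediated`,
#'   per-trait instrument ids), and `map`.
#' @export
simulate_mediation_chain <- function(effects = c(x_m1 = 0.7, m1_m2 = 0.5,
                                                 m2_y = 1.1, direct = 0.115),
                                     n_per_gwas = 20000, snps_per_trait = 10,
                                     h2 = 0.3, maf_range = c(0.1, 0.5),
                                     n_panel = 2000, seed = NULL) {
  stopifnot(all(c("x_m1", "m1_m2", "m2_y", "direct") %in% names(effects)))
  if (!is.null(seed)) set.seed(seed)
  indirect <- unname(effects["x_m1"] * effects["m1_m2"] * effects["m2_y"])
  total <- indirect + unname(effects["direct"])
  if (total == 0 && indirect != 0) {
    warning("total effect is zero with nonzero indirect effect: ",
            "proportion mediated undefined")
    proportion <- NA_real_
  } else {
    proportion <- if (total == 0) NA_real_ else indirect / total
  }

  m <- 3L * snps_per_trait
  map <- .make_snp_map(m, maf_range)
  owner <- rep(c("exposure", "mediator1", "mediator2"), each = snps_per_trait)
  b <- matrix(0, m, 3, dimnames = list(map$snp,
                                       c("exposure", "mediator1", "mediator2")))
  for (k in 1:3) {
    idx <- which(owner == colnames(b)[k])
    share <- h2 / snps_per_trait
    b[idx, k] <- sqrt(share / (2 * map$maf[idx] * (1 - map$maf[idx])))
  }
  e_sd <- sqrt(1 - h2)

  draw_traits <- function(n) {
    G <- .draw_dosages(n, map)
    x <- drop(G %*% b[, 1]) + stats::rnorm(n, 0, e_sd)
    m1 <- effects["x_m1"] * x + drop(G %*% b[, 2]) + stats::rnorm(n, 0, e_sd)
    m2 <- effects["m1_m2"] * m1 + drop(G %*% b[, 3]) + stats::rnorm(n, 0, e_sd)
    y <- effects["m2_y"] * m2 + effects["direct"] * x + stats::rnorm(n)
    list(genotypes = .genotype_matrix(G, map),
         traits = list(exposure = x, mediator1 = m1, mediator2 = m2,
                       outcome = y))
  }

  trait_names <- c("exposure", "mediator1", "mediator2", "outcome")
  gwas <- vector("list", 4)
  names(gwas) <- trait_names
  for (k in 1:4) {
    smp <- draw_traits(n_per_gwas)
    gwas[[k]] <- marginal_gwas(smp$genotypes, smp$traits[[trait_names[k]]],
                               trait = trait_names[k])
  }
  panel <- .genotype_matrix(.draw_dosages(n_panel, map), map)

  structure(list(gwas = gwas, panel = panel, map = map,
                 truth = list(effects = effects, indirect = indirect,
                              total = total,
                              proportion_mediated = proportion,
                              instruments = split(map$snp, owner))),
            class = "mediation_chain")
}
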