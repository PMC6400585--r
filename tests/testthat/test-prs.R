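# A panel with hand-built LD structure: rs1-rs2 correlated, rs3
# independent, rs4 an exact duplicate of rs1.
build_test_panel <- function(n = 2000, seed = 100) {
  set.seed(seed)
  p <- 0.3
  base <- rbinom(n, 2, p)
  noisy <- ifelse(rbinom(n, 1, 0.7) == 1, base, rbinom(n, 2, p))
  G <- cbind(rs1 = base, rs2 = noisy, rs3 = rbinom(n, 2, 0.4), rs4 = base)
  map <- data.frame(snp = colnames(G), chr = 1L, pos = c(1000, 2000, 3000,
                                                         4000),
                    effect_allele = c("A", "C", "G", "A"),
                    other_allele = c("G", "T", "A", "G"),
                    maf = c(p, p, 0.4, p),
                    freq = colMeans(G) / 2, stringsAsFactors = FALSE)
  structure(list(dosages = G, map = map), class = "genotype_matrix")
}

make_stats <- function(snp, pval, beta = 0.1, ea = "A", oa = "G",
                       eaf = 0.3) {
  gwas_sumstats(data.frame(snp = snp, effect_allele = ea, other_allele = oa,
                           eaf = eaf, beta = beta, se = 0.02, pval = pval,
                           n = 50000, stringsAsFactors = FALSE))
}

test_that("greedy clumping keeps the best SNP and its independent peers", {
  panel <- build_test_panel()
  r2_12 <- cor(panel$dosages[, "rs1"], panel$dosages[, "rs2"])^2
  expect_gt(r2_12, 0.3) # fixture sanity: rs1/rs2 genuinely linked
  stats <- make_stats(c("rs1", "rs2", "rs3"), c(1e-10, 1e-6, 1e-7))
  def <- ld_clump(stats, panel, r2_threshold = 0.1)
  expect_setequal(def$snp, c("rs1", "rs3"))
  expect_true("rs2" %in% attr(def, "log")$snp)
  # weights are the GWAS betas
  expect_equal(def$weight, stats$beta[match(def$snp, stats$snp)])
})

test_that("clumping keeps all mutually independent SNPs and dedupes r2 = 1", {
  panel <- build_test_panel()
  stats <- make_stats(c("rs1", "rs3"), c(1e-6, 1e-7))
  def <- ld_clump(stats, panel, r2_threshold = 0.001)
  expect_setequal(def$snp, c("rs1", "rs3"))
  dup <- make_stats(c("rs1", "rs4"), c(1e-10, 1e-8))
  def2 <- ld_clump(dup, panel, r2_threshold = 0.001)
  expect_equal(def2$snp, "rs1")
  expect_warning(ld_clump(make_stats("rs1", 0.5), panel),
                 "no SNP passes")
})

test_that("clumping output is invariant to input row order", {
  panel <- build_test_panel()
  stats <- make_stats(c("rs1", "rs2", "rs3", "rs4"),
                      c(1e-10, 1e-6, 1e-7, 1e-8))
  def_a <- ld_clump(stats, panel, r2_threshold = 0.1)
  shuffled <- gwas_sumstats(as.data.frame(stats)[c(3, 1, 4, 2), ])
  def_b <- ld_clump(shuffled, panel, r2_threshold = 0.1)
  expect_identical(def_a$snp, def_b$snp)
  # every retained pair is below the r2 threshold in the panel
  if (nrow(def_a) > 1) {
    r2 <- cor(panel$dosages[, def_a$snp])^2
    expect_true(all(r2[upper.tri(r2)] < 0.1))
  }
})

test_that("proxy search returns the best panel SNP above the r2 floor", {
  panel <- build_test_panel()
  hit <- find_proxy("rs1", panel, available_snps = c("rs4", "rs3"))
  expect_equal(hit$proxy, "rs4")
  expect_equal(hit$r2, 1)
  expect_false(hit$sign_flip)
  expect_null(find_proxy("rs1", panel, available_snps = "rs3"))
  # negatively correlated proxy flags a sign flip
  neg <- panel
  neg$dosages <- cbind(neg$dosages, rs5 = 2 - neg$dosages[, "rs1"])
  neg$map <- rbind(neg$map, data.frame(snp = "rs5", chr = 1L, pos = 5000,
                                       effect_allele = "C",
                                       other_allele = "T", maf = 0.7,
                                       freq = mean(2 - panel$dosages[, "rs1"]) / 2))
  hit2 <- find_proxy("rs1", neg, available_snps = "rs5")
  expect_equal(hit2$proxy, "rs5")
  expect_true(hit2$sign_flip)
})

test_that("allele harmonization flips, complements and drops correctly", {
  def <- score_definition(data.frame(
    snp = c("s1", "s2", "s3", "s4"),
    effect_allele = c("A", "A", "C", "A"),
    other_allele = c("G", "T", "G", "G"),
    eaf = c(0.3, 0.5, 0.1, 0.3),
    weight = c(0.5, 0.2, 0.4, 0.3), pval = 1e-8, source = "direct",
    stringsAsFactors = FALSE))
  cohort_map <- data.frame(
    snp = c("s1", "s2", "s3", "s4"),
    effect_allele = c("G", "A", "C", "T"),   # s1 swapped, s4 strand-flipped
    other_allele = c("A", "T", "G", "C"),
    freq = c(0.7, 0.5, 0.12, 0.3), stringsAsFactors = FALSE)
  harm <- harmonize_alleles(def, cohort_map)
  # s1: counted allele is the GWAS other allele -> weight negated
  expect_equal(harm$weight[harm$snp == "s1"], -0.5)
  # s2: palindromic A/T with eaf 0.5 -> dropped
  expect_false("s2" %in% harm$snp)
  expect_true(any(grepl("palindromic", attr(harm, "log")$reason)))
  # s3: palindromic C/G with eaf 0.10 vs cohort 0.12 -> retained, same sign
  expect_equal(harm$weight[harm$snp == "s3"], 0.4)
  # s4: A/G stated as T/C -> strand complement, weight unchanged
  expect_equal(harm$weight[harm$snp == "s4"], 0.3)
})

test_that("scoring is the weighted dosage sum with the unweighted sign rule", {
  G <- matrix(c(0, 1, 2), nrow = 1,
              dimnames = list("id1", c("a", "b", "c")))
  geno <- structure(list(dosages = G,
                         map = data.frame(snp = c("a", "b", "c"))),
                    class = "genotype_matrix")
  def <- score_definition(data.frame(
    snp = c("a", "b", "c"), effect_allele = "A", other_allele = "G",
    eaf = 0.3, weight = c(0.1, -0.2, 0.3), pval = 1e-8, source = "direct"))
  expect_equal(compute_score(geno, def)$raw, 0.4)
  zero <- def; zero$weight[] <- 0
  expect_equal(compute_score(geno, zero)$raw, 0)
  # unweighted: signs of betas count trait-increasing alleles
  G2 <- matrix(c(2, 1), nrow = 1, dimnames = list("id1", c("a", "b")))
  geno2 <- structure(list(dosages = G2,
                          map = data.frame(snp = c("a", "b"))),
                     class = "genotype_matrix")
  def2 <- score_definition(data.frame(
    snp = c("a", "b"), effect_allele = "A", other_allele = "G", eaf = 0.3,
    weight = c(-1, 1), pval = 1e-8, source = "direct"), weighted = FALSE)
  expect_equal(compute_score(geno2, def2)$raw, -1)
})

test_that("missing dosages are mean-imputed per SNP", {
  G <- matrix(c(0, 2, NA, 1, 1, 1), nrow = 3,
              dimnames = list(paste0("id", 1:3), c("a", "b")))
  geno <- structure(list(dosages = G,
                         map = data.frame(snp = c("a", "b"))),
                    class = "genotype_matrix")
  def <- score_definition(data.frame(
    snp = c("a", "b"), effect_allele = "A", other_allele = "G", eaf = 0.3,
    weight = c(1, 1), pval = 1e-8, source = "direct"))
  sv <- compute_score(geno, def)
  expect_equal(sv$raw[3], 1 + 1) # imputed mean(0, 2) = 1 plus dosage 1
})

test_that("standardization gives exact mean 0 / SD 1 and errors on constants", {
  expect_equal(standardize_score(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(101)
  x <- rnorm(500)
  z <- standardize_score(x)
  expect_lt(abs(mean(z)), 1e-10)
  expect_lt(abs(sd(z) - 1), 1e-10)
  expect_error(standardize_score(rep(2, 10), name = "flat"), "flat")
})

test_that("scoring is invariant to jointly swapping alleles and dosages", {
  set.seed(102)
  G <- matrix(rbinom(300, 2, 0.4), 100, 3,
              dimnames = list(paste0("id", 1:100), c("a", "b", "c")))
  geno <- structure(list(dosages = G, map = data.frame(snp = c("a", "b", "c"))),
                    class = "genotype_matrix")
  def <- score_definition(data.frame(
    snp = c("a", "b", "c"), effect_allele = "A", other_allele = "G",
    eaf = 0.4, weight = c(0.5, -0.3, 0.2), pval = 1e-8, source = "direct"))
  s_orig <- standardize_score(compute_score(geno, def))$standardized
  # reflect SNP b and negate its weight: standardized score must not change
  geno2 <- geno; geno2$dosages[, "b"] <- 2 - geno2$dosages[, "b"]
  def2 <- def; def2$weight[2] <- -def2$weight[2]
  s_flip <- standardize_score(compute_score(geno2, def2))$standardized
  expect_equal(s_flip, s_orig)
})

test_that("combining scores re-standardizes the standardized sum", {
  set.seed(103)
  mk <- function(x) {
    structure(data.frame(iid = paste0("id", seq_along(x)), raw = x,
                         standardized = NA_real_),
              class = c("score_vector", "data.frame"))
  }
  a <- standardize_score(mk(rnorm(1000)))
  expect_equal(combine_scores(a, a)$standardized, a$standardized)
  b <- a; b$raw <- -a$raw
  expect_error(combine_scores(a, standardize_score(b)), "zero variance")
  # three independent standard-normal scores: raw sum has SD near sqrt(3)
  x <- standardize_score(mk(rnorm(4000)))
  y <- standardize_score(mk(rnorm(4000)))
  z <- standardize_score(mk(rnorm(4000)))
  raw_sum <- x$standardized + y$standardized + z$standardized
  expect_lt(abs(sd(raw_sum) - sqrt(3)), 0.15)
  mismatched <- standardize_score(mk(rnorm(999)))
  expect_error(combine_scores(x, mismatched), "different individual sets")
})

test_that("relaxing the p threshold recovers more of the genetic signal", {
  # many weak true effects: the lenient threshold admits more of them,
  # raising the score's correlation with the true genetic value
  set.seed(104)
  n_disc <- 20000; n_test <- 2000; m <- 60
  p <- runif(m, 0.2, 0.5)
  b <- rnorm(m, 0, 0.03)
  map <- data.frame(snp = sprintf("rs%d", 1:m), chr = 1L, pos = (1:m) * 5000,
                    effect_allele = "A", other_allele = "G", maf = p,
                    stringsAsFactors = FALSE)
  draw <- function(n) matrix(rbinom(n * m, 2, rep(p, each = n)), n, m,
                             dimnames = list(sprintf("id%d", 1:n), map$snp))
  Gd <- draw(n_disc)
  yd <- drop(Gd %*% b) + rnorm(n_disc)
  disc <- structure(list(dosages = Gd, map = map), class = "genotype_matrix")
  stats <- marginal_gwas(disc, yd)
  Gt <- draw(n_test)
  test_geno <- structure(list(dosages = Gt, map = map),
                         class = "genotype_matrix")
  truth <- drop(Gt %*% b)
  cor_at <- function(thr) {
    def <- suppressWarnings(ld_clump(stats, disc, p_threshold = thr))
    if (nrow(def) < 1) return(0)
    cor(compute_score(test_geno, def)$raw, truth)
  }
  expect_gt(cor_at(5e-5), cor_at(5e-8) - 0.05)
})
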