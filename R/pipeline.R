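#' Export a phenome scan as an atlas table
#'
#' Writes the scan in the long format a results browser consumes: one
#' row per executed score-trait test with effect, CI, p, pseudo
#' R-squared, signed -log10(p) and Bonferroni flag, as TSV plus a JSON
#' companion carrying run metadata (thresholds, seed, package version).
#' Numeric columns are written with full precision so a round-trip read
#' reproduces them to 1e-12.
#'
#' @param scan a `scan_result` from [run_scan()].
#' @param path output TSV path (the JSON lands next to it with a `.json`
#'   extension).
#' @param metadata named list merged into the JSON metadata.
#' @return Invisibly, the exported data.frame.
#' @export
export_atlas <- function(scan, path, metadata = list()) {
  stopifnot(inherits(scan, "scan_result"))
  cols <- c("score", "trait", "family", "estimate", "se", "p", "or",
            "ci_lower", "ci_upper", "r2", "n", "signed_log10p",
            "bonferroni_pass", "converged", "note")
  out <- as.data.frame(scan)[, cols]
  fmt <- out
  num <- vapply(fmt, is.numeric, logical(1))
  fmt[num] <- lapply(fmt[num], function(x) sprintf("%.17g", x))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  ok <- tryCatch({
    utils::write.table(fmt, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("failed to write atlas export to ", path)
  meta <- c(list(n_tests = attr(scan, "n_tests"),
                 bonferroni_threshold = attr(scan, "bonferroni"),
                 bonferroni_scope = attr(scan, "bonferroni_scope"),
                 package_version = as.character(utils::packageVersion("prsatlas"))),
            metadata)
  jsonlite::write_json(list(metadata = meta, results = out),
                       sub("\\.tsv$", ".json", path), auto_unbox = TRUE,
                       digits = NA)
  invisible(out)
}

#' Read an atlas export back
#'
#' @param path the TSV written by [export_atlas()].
#' @return data.frame with the exported columns and their original
#'   types.
#' @export
read_atlas <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           na.strings = c("NA", "nan"))
  out$note[is.na(out$note)] <- ""
  out
}

#' Run the full synthetic pipeline
#'
#' End-to-end orchestration on synthetic data: simulate a cohort and a
#' set of discovery GWAS, build clumped/harmonized/standardized scores,
#' run the phenome scan, triage every Bonferroni-passing score-trait
#' pair with two-sample MR (the trait's outcome GWAS is computed in the
#' cohort), and export the atlas table. All randomness flows from
#' `config$seed`; the same config produces byte-identical outputs.
#'
#' @param config list with elements:
#'   \describe{
#'     \item{seed}{integer seed (required).}
#'     \item{out_dir}{output directory (required).}
#'     \item{n_individuals, n_snps}{cohort dimensions (defaults 2000,
#'       30).}
#'     \item{n_gwas}{number of discovery GWAS / scores (default 2).}
#'     \item{gwas_n}{sample size per discovery GWAS (default 20000).}
#'     \item{trait_specs}{list of [trait_spec()]; defaults to one
#'       continuous, one binary and one ordinal trait wired to the first
#'       SNPs.}
#'     \item{p_threshold, r2_threshold}{scoring thresholds (5e-5,
#'       0.001).}
#'     \item{instrument_p}{MR instrument threshold (5e-8).}
#'     \item{alpha}{triage evidence threshold (0.05).}
#'   }
#' @return A list with `scores`, `scan`, `triage` (per flagged pair) and
#'   the export paths; outputs are written under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  for (req in c("seed", "out_dir")) {
    if (is.null(config[[req]])) stop("config$", req, " is required")
  }
  n <- config$n_individuals %||% 2000
  m <- config$n_snps %||% 30
  n_gwas <- config$n_gwas %||% 2
  gwas_n <- config$gwas_n %||% 20000
  p_thr <- config$p_threshold %||% 5e-5
  r2_thr <- config$r2_threshold %||% 0.001
  instr_p <- config$instrument_p %||% 5e-8
  alpha <- config$alpha %||% 0.05
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)

  base <- sim_config(n_individuals = n, n_snps = m, seed = NULL)
  specs <- config$trait_specs %||% list(
    trait_spec("trait_cont", "continuous", causal_snps = c("rs1", "rs2"),
               effects = c(0.3, -0.2)),
    trait_spec("trait_bin", "binary", causal_snps = "rs1", effects = 0.4,
               intercept = -1.5),
    trait_spec("trait_ord", "ordinal", causal_snps = "rs2", effects = 0.3,
               levels = c("low", "mid", "high"), cutpoints = c(-1, 1)))
  cohort <- simulate_cohort(base, specs)
  panel <- cohort$genotypes

  # Discovery GWAS: latent continuous traits sharing the cohort's SNPs.
  map <- panel$map
  scores <- list()
  gwas_list <- list()
  for (g in seq_len(n_gwas)) {
    geno <- .genotype_matrix(.draw_dosages(gwas_n, map), map)
    b <- numeric(m)
    causal <- seq_len(min(5, m))
    b[causal] <- stats::rnorm(length(causal), 0, 0.15)
    y <- drop(geno$dosages %*% b) + stats::rnorm(gwas_n)
    stats <- marginal_gwas(geno, y, trait = sprintf("gwas%d", g))
    gwas_list[[sprintf("gwas%d", g)]] <- stats
    def <- suppressWarnings(ld_clump(stats, panel, p_threshold = p_thr,
                                     r2_threshold = r2_thr))
    if (!nrow(def)) next
    cohort_map <- panel$map
    cohort_map$freq <- panel$map$freq
    def <- harmonize_alleles(def, cohort_map)
    sv <- tryCatch(standardize_score(compute_score(panel, def)),
                   error = function(e) NULL)
    if (!is.null(sv)) scores[[sprintf("gwas%d", g)]] <- sv
  }
  if (!length(scores)) stop("pipeline aborted at scoring: no usable scores")

  scan <- run_scan(scores, cohort)
  export_path <- file.path(config$out_dir, "atlas.tsv")
  export_atlas(scan, export_path, metadata = list(seed = config$seed,
                                                  p_threshold = p_thr,
                                                  instrument_p = instr_p))

  hits <- as.data.frame(scan)[scan$bonferroni_pass, c("score", "trait")]
  triage <- list()
  for (i in seq_len(nrow(hits))) {
    spec <- specs[[which(vapply(specs, `[[`, "", "name") == hits$trait[i])]]
    trait_vals <- cohort$phenotypes[[hits$trait[i]]]
    y <- if (is.factor(trait_vals)) as.numeric(trait_vals) else trait_vals
    outcome_stats <- marginal_gwas(panel, y, trait = hits$trait[i])
    triage[[paste(hits$score[i], hits$trait[i], sep = ":")]] <- tryCatch(
      mr_triage(gwas_list[[hits$score[i]]], outcome_stats, panel,
                alpha = alpha, instrument_p = instr_p, seed = config$seed),
      error = function(e) list(verdict = "NO_INSTRUMENTS",
                               error = conditionMessage(e)))
  }
  verdicts <- vapply(triage, function(t) t$verdict, character(1))
  jsonlite::write_json(list(seed = config$seed,
                            verdicts = as.list(verdicts)),
                       file.path(config$out_dir, "triage.json"),
                       auto_unbox = TRUE)
  list(scores = scores, scan = scan, triage = triage,
       paths = list(atlas = export_path,
                    triage = file.path(config$out_dir, "triage.json")))
}
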