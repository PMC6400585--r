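#' GWAS summary statistics
#'
#' Construct and validate a table of per-SNP association records for one
#' trait: the exposure/outcome inputs for scoring and Mendelian
#' randomization. Rows violating the invariants (non-positive SE, p-values
#' outside (0, 1], non-ACGT or multi-allelic alleles, duplicated SNP ids)
#' are removed with a reason recorded in the `"log"` attribute.
#'
#' @param data data.frame with columns `snp`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#' @param trait trait name.
#' @param trait_type `"continuous"` or `"binary"` (binary effects are
#'   log odds ratios).
#' @param sample_overlap logical; `TRUE` when the GWAS sample overlaps the
#'   analysis cohort, in which case downstream scores should be unweighted.
#' @return A `gwas_sumstats` data.frame with attributes `trait`,
#'   `trait_type`, `sample_overlap` and `log`.
#' @export
gwas_sumstats <- function(data, trait = "trait",
                          trait_type = c("continuous", "binary"),
                          sample_overlap = FALSE) {
  trait_type <- match.arg(trait_type)
  required <- c("snp", "effect_allele", "other_allele", "eaf", "beta",
                "se", "pval", "n")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  data <- as.data.frame(data)[required]
  data$snp <- as.character(data$snp)
  data$effect_allele <- toupper(as.character(data$effect_allele))
  data$other_allele <- toupper(as.character(data$other_allele))
  data$line <- seq_len(nrow(data))

  log <- .empty_log()
  bad_se <- !is.finite(data$se) | data$se <= 0
  bad_p <- !is.finite(data$pval) | data$pval <= 0 | data$pval > 1
  bad_allele <- !.valid_allele(data$effect_allele) |
    !.valid_allele(data$other_allele) |
    data$effect_allele == data$other_allele
  dup <- duplicated(data$snp)
  for (reason in list(list(bad_se, "se <= 0 or missing"),
                      list(bad_p, "pval outside (0, 1]"),
                      list(bad_allele, "alleles not single-base ACGT pair"),
                      list(dup, "duplicated snp id"))) {
    idx <- which(reason[[1]])
    if (length(idx)) {
      log <- rbind(log, data.frame(snp = data$snp[idx],
                                   reason = sprintf("line %d: %s",
                                                    data$line[idx],
                                                    reason[[2]])))
    }
  }
  keep <- !(bad_se | bad_p | bad_allele | dup)
  data <- data[keep, required, drop = FALSE]
  rownames(data) <- NULL
  structure(data,
            trait = trait, trait_type = trait_type,
            sample_overlap = isTRUE(sample_overlap), log = log,
            class = c("gwas_sumstats", "data.frame"))
}

# Header dialects seen across source GWAS files.
.GWAS_SYNONYMS <- list(
  snp = c("snp", "rsid", "markername", "id", "variant_id"),
  effect_allele = c("effect_allele", "ea", "a1", "allele1"),
  other_allele = c("other_allele", "oa", "a2", "allele2", "non_effect_allele"),
  eaf = c("eaf", "effect_allele_freq", "freq", "af", "maf"),
  beta = c("beta", "b", "effect", "beta_hat"),
  se = c("se", "standard_error", "stderr"),
  pval = c("pval", "p", "p_value", "pvalue"),
  n = c("n", "samplesize", "sample_size", "n_total")
)

#' Read GWAS summary statistics from delimited text
#'
#' Reads a tab-separated summary-statistics file, mapping common header
#' dialects (`beta`/`b`, `se`/`standard_error`, `pval`/`p`, ...) onto the
#' canonical columns, then validates rows via [gwas_sumstats()]. Rejected
#' rows are recorded with their line numbers in the `"log"` attribute.
#'
#' @param path file path.
#' @param mapping optional named character vector mapping canonical column
#'   names to the file's column names, overriding the dialect table.
#' @param sep field separator (default tab).
#' @inheritParams gwas_sumstats
#' @return A [gwas_sumstats()] object.
#' @export
read_gwas <- function(path, mapping = NULL, trait = "trait",
                      trait_type = c("continuous", "binary"),
                      sample_overlap = FALSE, sep = "\t") {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  lower <- tolower(names(raw))
  out <- list()
  for (col in names(.GWAS_SYNONYMS)) {
    source_col <- if (!is.null(mapping) && col %in% names(mapping)) {
      mapping[[col]]
    } else {
      hit <- which(lower %in% .GWAS_SYNONYMS[[col]])
      if (length(hit)) names(raw)[hit[1]] else NA_character_
    }
    if (is.na(source_col) || !source_col %in% names(raw)) {
      stop("cannot map mandatory column '", col, "' in ", path)
    }
    out[[col]] <- raw[[source_col]]
  }
  gwas_sumstats(as.data.frame(out, stringsAsFactors = FALSE),
                trait = trait, trait_type = trait_type,
                sample_overlap = sample_overlap)
}

#' Write GWAS summary statistics as tab-separated text
#'
#' @param x a [gwas_sumstats()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gwas <- function(x, path) {
  stopifnot(inherits(x, "gwas_sumstats"))
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.gwas_sumstats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %s (%s), %d SNPs\n",
              attr(x, "trait"), attr(x, "trait_type"), nrow(x)))
  dropped <- attr(x, "log")
  if (!is.null(dropped) && nrow(dropped)) {
    cat(sprintf("  %d row(s) rejected during validation\n", nrow(dropped)))
  }
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}
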