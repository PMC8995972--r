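#' Bootstrap test of regional GWAS signal reliability
#'
#' Resamples individuals with replacement `B` times; for each replicate
#' the kinship matrix is recomputed on the resampled panel, the null mixed
#' model refit, and the region's sites rescanned. The report counts
#' replicates whose minimum region p-value does, and does not, reach
#' `p_threshold`. The decision rule follows the original usage: the
#' regional signal is called *reliable* when more than
#' `decision_fraction` of replicates show **no** significant signal
#' (signal loss attributed to resampling breaking the population's data
#' structure). Both counts are reported so the conventional
#' bootstrap-support reading (many replicates retaining signal) can be
#' applied by the user instead.
#'
#' @param g A [genotype_matrix()] (typically the post-QC panel; kinship is
#'   recomputed from all its sites each replicate).
#' @param pheno Phenotype data frame (`sample_id` + trait columns) aligned
#'   with `g$sample_ids`.
#' @param trait Trait column name to analyse.
#' @param region List or `region_ci` with `chrom`, `start_bp`, `end_bp`.
#' @param p_threshold Significance threshold for the region. When `NULL`,
#'   it is derived from `assoc` as the largest `p_wald` among the region's
#'   records with `q_value < 0.05`.
#' @param assoc Optional `assoc_records` with `q_value`, used to derive
#'   `p_threshold`.
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; the whole report is reproducible from it.
#' @param decision_fraction No-signal fraction above which the rule calls
#'   the region reliable (default 0.95, i.e. 950 of 1,000).
#' @return An object of class `bootstrap_report`.
#' @export
bootstrap_gwas <- function(g, pheno, trait, region, p_threshold = NULL,
                           assoc = NULL, B = 1000L, seed = 1L,
                           decision_fraction = 0.95) {
  stopifnot(inherits(g, "genotype_matrix"), B >= 1)
  B <- as.integer(B)
  chrom <- as.character(region$chrom)
  start_bp <- region$start_bp
  end_bp <- region$end_bp
  ridx <- which(g$sites$chrom == chrom &
    g$sites$pos >= start_bp & g$sites$pos <= end_bp)
  if (length(ridx) == 0L) {
    stop("bootstrap_gwas: region ", chrom, ":", start_bp, "-", end_bp,
      " contains no sites",
      call. = FALSE
    )
  }
  if (is.null(p_threshold)) {
    if (is.null(assoc) || is.null(assoc$q_value)) {
      stop("bootstrap_gwas: supply p_threshold or an assoc table with ",
        "q_value to derive it",
        call. = FALSE
      )
    }
    in_region <- assoc$chrom == chrom & assoc$pos >= start_bp &
      assoc$pos <= end_bp & assoc$q_value < 0.05
    if (!any(in_region)) {
      stop("bootstrap_gwas: no significant records in the region to derive ",
        "a threshold from",
        call. = FALSE
      )
    }
    p_threshold <- max(assoc$p_wald[in_region])
  }
  if (p_threshold <= 0 || p_threshold > 1) {
    stop("bootstrap_gwas: p_threshold must be in (0, 1]", call. = FALSE)
  }
  y_all <- pheno[[trait]]
  if (is.null(y_all)) {
    stop("bootstrap_gwas: trait ", trait, " not in phenotype table",
      call. = FALSE
    )
  }
  if (!identical(as.character(pheno$sample_id), g$sample_ids)) {
    stop("bootstrap_gwas: phenotype rows not aligned with genotype samples",
      call. = FALSE
    )
  }
  n <- length(g$sample_ids)

  set.seed(seed)
  idx_mat <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)

  n_with <- 0L
  n_skipped <- 0L
  distinct <- numeric(B)
  for (b in seq_len(B)) {
    idx <- idx_mat[b, ]
    distinct[b] <- length(unique(idx))
    yb <- y_all[idx]
    keep <- !is.na(yb)
    if (sum(keep) < 3L || stats::sd(yb[keep]) < 1e-12) {
      n_skipped <- n_skipped + 1L
      next
    }
    gb <- subset_genotypes(g, samples = idx[keep])
    kb <- compute_kinship(gb)
    fit <- suppressWarnings(fit_null_lmm(yb[keep], kb))
    reg <- subset_genotypes(gb, sites = ridx)
    scan <- wald_scan(yb[keep], reg, kb, null_fit = fit)
    if (min(scan$p_wald) <= p_threshold) n_with <- n_with + 1L
  }
  n_without <- B - n_with - n_skipped
  cutoff <- decision_fraction * B

  structure(list(
    region = list(chrom = chrom, start_bp = start_bp, end_bp = end_bp),
    n_region_sites = length(ridx),
    trait = trait,
    p_threshold = p_threshold,
    B = B,
    n_without_signal = n_without,
    n_with_signal = n_with,
    n_skipped = n_skipped,
    mean_distinct_fraction = mean(distinct) / n,
    decision_rule_cutoff = cutoff,
    decision = if (n_without > cutoff) "reliable" else "not-reliable",
    seed = seed
  ), class = "bootstrap_report")
}

#' @export
print.bootstrap_report <- function(x, ...) {
  cat(
    "<bootstrap_report>", x$trait, "in",
    paste0(x$region$chrom, ":", x$region$start_bp, "-", x$region$end_bp),
    paste0("(", x$n_region_sites, " sites)\n")
  )
  cat(sprintf(
    "  B = %d, p threshold = %.3g\n", x$B, x$p_threshold
  ))
  cat(sprintf(
    "  without signal: %d, with signal: %d%s\n",
    x$n_without_signal, x$n_with_signal,
    if (x$n_skipped > 0) paste0(", skipped: ", x$n_skipped) else ""
  ))
  cat(sprintf(
    "  rule: reliable when no-signal count > %.0f -> %s\n",
    x$decision_rule_cutoff, x$decision
  ))
  invisible(x)
}

#' @rdname bootstrap_gwas
#' @param report A `bootstrap_report`.
#' @param path Output JSON path.
#' @export
write_bootstrap_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path,
    auto_unbox = TRUE,
    digits = NA, pretty = TRUE
  )
  invisible(path)
}
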