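#' Site-level quality control
#'
#' Applies the study's marker filters: keep biallelic SNPs with minor
#' allele frequency strictly above `maf_min` (computed on non-missing
#' calls), missing-call fraction strictly below `miss_max`, and — when
#' `site_quality` thresholds are supplied and the VCF carried the fields —
#' QUAL/QD/MQ/FS within bounds. Each removed site is tallied under the
#' first filter it violates, in the order non-biallelic, site-quality,
#' missingness, MAF.
#'
#' @param g A [genotype_matrix()].
#' @param maf_min Exclusive lower MAF bound (default 0.05: a site with MAF
#'   exactly 0.05 is removed).
#' @param miss_max Exclusive upper bound on per-site missing fraction
#'   (default 0.1).
#' @param site_quality Optional list with any of `qual_min` (default 30),
#'   `qd_min` (2), `mq_min` (40), `fs_max` (60); pass `TRUE` for all
#'   defaults, `NULL` (default) to skip site-quality filtering.
#' @return A list with `genotypes` (the filtered [genotype_matrix()]) and
#'   `report` (a `qc_report`: per-filter removal counts and sites
#'   retained).
#' @export
#' @examples
#' g <- simulate_genotypes(sim_config(n_individuals = 60, seed = 2))
#' qc <- filter_sites(g)
#' qc$report
filter_sites <- function(g, maf_min = 0.05, miss_max = 0.1,
                         site_quality = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  m <- nrow(g$sites)
  fr <- site_frequencies(g)

  fail_bi <- !g$sites$biallelic
  fail_sq <- rep(FALSE, m)
  if (!is.null(site_quality)) {
    sq <- list(qual_min = 30, qd_min = 2, mq_min = 40, fs_max = 60)
    if (is.list(site_quality)) sq[names(site_quality)] <- site_quality
    chk <- function(x, bad) !is.na(x) & bad
    fail_sq <- chk(g$sites$qual, g$sites$qual < sq$qual_min) |
      chk(g$sites$qd, g$sites$qd < sq$qd_min) |
      chk(g$sites$mq, g$sites$mq < sq$mq_min) |
      chk(g$sites$fs, g$sites$fs > sq$fs_max)
  }
  fail_miss <- fr$missing_rate >= miss_max
  fail_maf <- is.na(fr$maf) | fr$maf <= maf_min

  first_fail <- rep("pass", m)
  first_fail[fail_maf] <- "maf"
  first_fail[fail_miss] <- "missingness"
  first_fail[fail_sq] <- "site_quality"
  first_fail[fail_bi] <- "non_biallelic"

  keep <- first_fail == "pass"
  if (!any(keep)) {
    stop("filter_sites: empty panel - every site removed by QC",
      call. = FALSE
    )
  }
  report <- structure(list(
    input_sites = m,
    removed = c(
      non_biallelic = sum(first_fail == "non_biallelic"),
      site_quality = sum(first_fail == "site_quality"),
      missingness = sum(first_fail == "missingness"),
      maf = sum(first_fail == "maf")
    ),
    retained = sum(keep),
    maf_min = maf_min, miss_max = miss_max
  ), class = "qc_report")
  list(genotypes = subset_genotypes(g, sites = which(keep)), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>", x$input_sites, "sites in,", x$retained, "retained\n")
  rem <- x$removed[x$removed > 0]
  if (length(rem)) {
    cat("  removed:", paste(names(rem), rem, sep = "=", collapse = ", "), "\n")
  }
  cat(
    "  thresholds: MAF >", x$maf_min, "; missing <", x$miss_max, "\n"
  )
  invisible(x)
}

#' @rdname filter_sites
#' @param report A `qc_report`.
#' @param path Output TSV path.
#' @export
write_qc_report <- function(report, path) {
  d <- data.frame(
    filter = c(names(report$removed), "retained", "input"),
    sites = c(report$removed, report$retained, report$input_sites)
  )
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
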