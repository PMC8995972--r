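#' Construct a genotype matrix object
#'
#' The central genotype container: per-sample allele-dosage codes (0/1/2
#' counts of the ALT allele, `NA` for missing) over biallelic SNP sites,
#' with optional phased haplotypes.
#'
#' @param sample_ids Character vector of unique sample identifiers.
#' @param sites Data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`; optionally `biallelic` (logical) and site-quality columns
#'   `qual`, `qd`, `mq`, `fs`.
#' @param dosage Integer matrix, samples x sites.
#' @param phased Logical; are haplotypes available?
#' @param haplotypes When phased, a list of two samples x sites 0/1 allele
#'   matrices (`hap1`, `hap2`) whose sum reproduces `dosage`.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sample_ids, sites, dosage, phased = FALSE,
                            haplotypes = NULL) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) {
    stop("genotype_matrix: duplicated sample ids", call. = FALSE)
  }
  if (!all(c("chrom", "pos", "ref", "alt") %in% names(sites))) {
    stop("genotype_matrix: sites needs chrom/pos/ref/alt", call. = FALSE)
  }
  if (is.null(sites$biallelic)) sites$biallelic <- TRUE
  dosage <- as.matrix(dosage)
  if (nrow(dosage) != length(sample_ids) || ncol(dosage) != nrow(sites)) {
    stop("genotype_matrix: dosage dimensions do not match samples x sites",
      call. = FALSE
    )
  }
  dimnames(dosage) <- list(sample_ids, NULL)
  if (!is.null(haplotypes)) {
    haplotypes <- lapply(haplotypes, function(h) {
      dimnames(h) <- list(sample_ids, NULL)
      h
    })
  }
  # positions strictly increasing within each chromosome
  for (cn in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == cn]
    if (any(diff(p) <= 0)) {
      stop("genotype_matrix: positions not strictly increasing on chromosome ",
        cn,
        call. = FALSE
      )
    }
  }
  if (phased) {
    stopifnot(is.list(haplotypes), length(haplotypes) == 2L)
    hsum <- haplotypes[[1]] + haplotypes[[2]]
    ok <- is.na(dosage) | is.na(hsum) | hsum == dosage
    if (!all(ok)) {
      stop("genotype_matrix: haplotype pair sums disagree with dosage",
        call. = FALSE
      )
    }
  }
  structure(
    list(
      sample_ids = sample_ids, sites = sites, dosage = dosage,
      phased = phased, haplotypes = haplotypes
    ),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(
    "<genotype_matrix>", length(x$sample_ids), "samples x",
    nrow(x$sites), "sites;",
    if (x$phased) "phased" else "unphased", "\n"
  )
  cat(
    "  chromosomes:",
    paste(unique(x$sites$chrom), collapse = ", "), "\n"
  )
  miss <- mean(is.na(x$dosage))
  if (miss > 0) cat("  missing calls:", format(miss, digits = 3), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(length(x$sample_ids), nrow(x$sites))

#' Subset a genotype matrix by samples and/or sites
#'
#' @param g A [genotype_matrix()].
#' @param samples,sites Index vectors (integer/logical) into samples and
#'   site rows; `NULL` keeps everything. Duplicate sample indices are
#'   allowed (used by bootstrap resampling) and get disambiguated ids.
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(g, samples = NULL, sites = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  si <- if (is.null(samples)) seq_along(g$sample_ids) else samples
  vi <- if (is.null(sites)) seq_len(nrow(g$sites)) else sites
  ids <- g$sample_ids[si]
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "#")
  haps <- NULL
  if (g$phased) {
    haps <- list(
      hap1 = g$haplotypes[[1]][si, vi, drop = FALSE],
      hap2 = g$haplotypes[[2]][si, vi, drop = FALSE]
    )
  }
  genotype_matrix(
    sample_ids = ids,
    sites = g$sites[vi, , drop = FALSE],
    dosage = g$dosage[si, vi, drop = FALSE],
    phased = g$phased,
    haplotypes = haps
  )
}

#' Per-site ALT allele frequency and MAF
#'
#' Frequencies are computed on non-missing calls only.
#'
#' @param g A [genotype_matrix()].
#' @return Data frame with columns `af` (ALT frequency), `maf`,
#'   `missing_rate`.
#' @export
site_frequencies <- function(g) {
  af <- colMeans(g$dosage, na.rm = TRUE) / 2
  data.frame(
    af = af,
    maf = pmin(af, 1 - af),
    missing_rate = colMeans(is.na(g$dosage))
  )
}

# Mean-impute missing dosages per site (used by kinship and the scan);
# all-missing sites become the constant 0.
impute_dosage <- function(g) {
  X <- g$dosage
  if (!anyNA(X)) {
    storage.mode(X) <- "double"
    return(X)
  }
  mu <- colMeans(X, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(X), arr.ind = TRUE)
  X[idx] <- mu[idx[, 2]]
  storage.mode(X) <- "double"
  X
}
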