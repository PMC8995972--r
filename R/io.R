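#' Write a genotype matrix to VCF v4.2
#'
#' Phased matrices are written with `|`-separated GT, unphased with `/`;
#' missing calls become `.|.` (or `./.`). Site ids are `chrom_pos`.
#'
#' @param g A [genotype_matrix()].
#' @param path Output file path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  sep <- if (g$phased) "|" else "/"
  n <- length(g$sample_ids)
  m <- nrow(g$sites)
  if (g$phased) {
    a1 <- g$haplotypes[[1]]
    a2 <- g$haplotypes[[2]]
  } else {
    # unphased: emit dosage as an arbitrary-order allele pair
    a1 <- ifelse(g$dosage >= 1L, 1L, 0L)
    a2 <- ifelse(g$dosage == 2L, 1L, 0L)
  }
  gt <- matrix(paste(a1, a2, sep = sep), nrow = n, ncol = m)
  gt[is.na(g$dosage)] <- paste(".", ".", sep = sep)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=duckgwas",
    paste0(
      "##contig=<ID=", unique(g$sites$chrom), ">"
    ),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
      "INFO", "FORMAT", g$sample_ids
    ), collapse = "\t")
  )
  body <- paste(
    g$sites$chrom, g$sites$pos,
    paste0(g$sites$chrom, "_", g$sites$pos),
    g$sites$ref, g$sites$alt, ".", "PASS", ".", "GT",
    apply(gt, 2L, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Parses GT fields via \pkg{vcfR}. Pipe-separated genotypes are kept as
#' phased haplotypes; slash-separated calls drop phase; `./.` becomes a
#' missing dosage. Records with multiple ALT alleles or non-SNP alleles are
#' retained but flagged `biallelic = FALSE` so [filter_sites()] can remove
#' them. Site-quality fields (QUAL and INFO keys QD, MQ, FS) are carried
#' along when present.
#'
#' @param path Path to a VCF v4.2 file (plain or gzipped).
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix # CHROM POS ID REF ALT QUAL FILTER INFO
  gt_raw <- v@gt
  if (is.null(gt_raw) || ncol(gt_raw) < 2L) {
    stop("read_vcf: no genotype columns in ", path, call. = FALSE)
  }
  sample_ids <- colnames(gt_raw)[-1L]
  m <- nrow(fix)
  n <- length(sample_ids)

  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  biallelic <- !grepl(",", alt, fixed = TRUE) &
    nchar(ref) == 1L & nchar(gsub(",.*", "", alt)) == 1L

  # first FORMAT field only
  gt <- sub(":.*", "", gt_raw[, -1L, drop = FALSE]) # m x n
  phased_call <- grepl("|", gt, fixed = TRUE)
  toks <- strsplit(gt, "[|/]")
  bad <- which(lengths(toks) != 2L & gt != "." & !is.na(gt))
  if (length(bad)) {
    rec <- ((bad[1] - 1L) %% m) + 1L
    stop(
      "read_vcf: malformed GT in record ", rec, " (",
      fix[rec, "CHROM"], ":", fix[rec, "POS"], ")",
      call. = FALSE
    )
  }
  tok_mat <- matrix("", nrow = length(toks), ncol = 2L)
  ok2 <- lengths(toks) == 2L
  tok_mat[ok2, ] <- t(vapply(toks[ok2], identity, character(2)))
  a1 <- suppressWarnings(as.integer(tok_mat[, 1]))
  a2 <- suppressWarnings(as.integer(tok_mat[, 2]))
  dim(a1) <- dim(a2) <- dim(gt) # m x n
  dosage <- t((a1 > 0L) + (a2 > 0L)) # n x m, multi-ALT counted as ALT
  phased <- all(phased_call | is.na(a1) | gt == ".")

  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  info <- fix[, "INFO"]
  info_num <- function(key) {
    val <- rep(NA_real_, m)
    hit <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]+"), info))
    has <- grepl(paste0("(^|;)", key, "="), info)
    val[has] <- suppressWarnings(as.numeric(sub(paste0(".*", key, "="), "", hit)))
    val
  }
  sites <- data.frame(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = ref, alt = alt, biallelic = biallelic,
    qual = qual, qd = info_num("QD"), mq = info_num("MQ"),
    fs = info_num("FS"),
    stringsAsFactors = FALSE
  )
  haps <- NULL
  if (phased) {
    haps <- list(
      hap1 = t(ifelse(a1 > 0L, 1L, 0L)),
      hap2 = t(ifelse(a2 > 0L, 1L, 0L))
    )
  }
  genotype_matrix(
    sample_ids = sample_ids, sites = sites, dosage = dosage,
    phased = phased, haplotypes = haps
  )
}

#' Read / write the phenotype table
#'
#' Tab-separated with a header row; first column `sample_id`, remaining
#' columns one per trait (default `AFE`, `EP43w`, `EP66w`). Missing values
#' are allowed and written as `NA`.
#'
#' @param path File path.
#' @return `read_phenotypes()`: a data frame with unique `sample_id` and
#'   numeric trait columns.
#' @export
read_phenotypes <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(d)[1] != "sample_id") {
    stop("read_phenotypes: first column must be sample_id", call. = FALSE)
  }
  if (anyDuplicated(d$sample_id)) {
    stop("read_phenotypes: duplicated sample ids", call. = FALSE)
  }
  for (j in seq_along(d)[-1]) d[[j]] <- as.numeric(d[[j]])
  ok <- vapply(d[-1], function(x) sum(!is.na(x)) >= 2L, logical(1))
  if (!all(ok)) {
    stop("read_phenotypes: trait(s) with fewer than 2 observations: ",
      paste(names(d)[-1][!ok], collapse = ", "),
      call. = FALSE
    )
  }
  d
}

#' @rdname read_phenotypes
#' @param phenotypes Data frame as returned by [simulate_phenotypes()].
#' @export
write_phenotypes <- function(phenotypes, path) {
  stopifnot(names(phenotypes)[1] == "sample_id")
  utils::write.table(phenotypes, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(path)
}
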