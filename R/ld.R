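#' Pairwise linkage disequilibrium r-squared from dosages
#'
#' Genotype-based composite LD: the squared Pearson correlation of the two
#' dosage vectors over pairwise-complete observations (the convention of
#' the usual command-line LD tools when phase is ignored).
#'
#' @param site_a,site_b Equal-length dosage vectors (0/1/2, `NA` allowed).
#' @return r-squared in `[0, 1]`, or `NA` when either site is monomorphic
#'   on the pairwise-complete subset (undefined, deliberately not 0).
#' @export
#' @examples
#' ld_r2(c(0, 0, 1, 1, 2, 2), c(2, 2, 1, 1, 0, 0)) # 1
ld_r2 <- function(site_a, site_b) {
  if (length(site_a) != length(site_b)) {
    stop("ld_r2: sites have different lengths", call. = FALSE)
  }
  ok <- !is.na(site_a) & !is.na(site_b)
  if (sum(ok) < 2L) {
    stop("ld_r2: fewer than 2 pairwise-complete observations",
      call. = FALSE
    )
  }
  a <- site_a[ok]
  b <- site_b[ok]
  if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) {
    return(NA_real_)
  }
  min(stats::cor(a, b)^2, 1)
}

# r^2 of every column of X against the single vector x_top, pairwise
# complete; monomorphic columns come back NA.
ld_r2_vec <- function(X, x_top) {
  vapply(
    seq_len(ncol(X)),
    function(j) ld_r2(X[, j], x_top),
    numeric(1)
  )
}

#' Delineate an LD-based confidence interval around a top SNP
#'
#' Computes r-squared between the top SNP and every site within a window
#' of total width `window_bp` centered on it; sites reaching `r2_min`
#' become interval members and the confidence interval is the span from
#' the first to the last member position (not the window edges).
#'
#' @param top List or one-row data frame with `chrom` and `pos` naming a
#'   site present in `g`.
#' @param g A [genotype_matrix()].
#' @param assoc Optional `assoc_records`; used to attach p-values to
#'   members and the top site.
#' @param window_bp Total window width in bp (default 3 Mb, i.e. +/- 1.5
#'   Mb around the top SNP).
#' @param r2_min Minimum r-squared for membership (default 0.4).
#' @param p_max Optional significance mask: members must additionally have
#'   `p_wald <= p_max` in `assoc`.
#' @return An object of class `region_ci`: `chrom`, `top_pos`, `top_p`,
#'   `window_bp`, `r2_threshold`, `members` (data frame `pos`, `r2`,
#'   `p_wald`), `start_bp`, `end_bp` and `collapsed` (TRUE when the top
#'   SNP is the only member).
#' @export
delineate_ci <- function(top, g, assoc = NULL, window_bp = 3e6,
                         r2_min = 0.4, p_max = NULL) {
  stopifnot(inherits(g, "genotype_matrix"), window_bp > 0)
  chrom <- as.character(top$chrom)
  pos <- as.integer(top$pos)
  ti <- which(g$sites$chrom == chrom & g$sites$pos == pos)
  if (length(ti) != 1L) {
    stop("delineate_ci: top SNP ", chrom, ":", pos, " not found in panel",
      call. = FALSE
    )
  }
  half <- window_bp / 2
  wi <- which(g$sites$chrom == chrom &
    abs(g$sites$pos - pos) <= half)
  X <- g$dosage[, wi, drop = FALSE]
  r2 <- ld_r2_vec(X, g$dosage[, ti])
  r2[wi == ti] <- 1 # the top SNP is always its own perfect proxy

  keep <- !is.na(r2) & r2 >= r2_min
  mem <- data.frame(pos = g$sites$pos[wi][keep], r2 = r2[keep])
  p_of <- function(positions) {
    if (is.null(assoc)) {
      return(rep(NA_real_, length(positions)))
    }
    assoc$p_wald[match(
      paste(chrom, positions),
      paste(assoc$chrom, assoc$pos)
    )]
  }
  mem$p_wald <- p_of(mem$pos)
  if (!is.null(p_max)) {
    keep_sig <- mem$pos == pos | (!is.na(mem$p_wald) & mem$p_wald <= p_max)
    mem <- mem[keep_sig, , drop = FALSE]
  }
  mem <- mem[order(mem$pos), , drop = FALSE]
  rownames(mem) <- NULL
  collapsed <- nrow(mem) <= 1L
  if (collapsed) {
    warning("delineate_ci: no linked neighbors at r2 >= ", r2_min,
      "; interval collapses to the top SNP",
      call. = FALSE
    )
  }
  structure(list(
    chrom = chrom, top_pos = pos, top_p = p_of(pos),
    window_bp = window_bp, r2_threshold = r2_min,
    members = mem,
    start_bp = min(mem$pos), end_bp = max(mem$pos),
    collapsed = collapsed
  ), class = "region_ci")
}

#' @export
print.region_ci <- function(x, ...) {
  cat(
    "<region_ci>", x$chrom, ":", x$start_bp, "-", x$end_bp,
    sprintf(
      "(%.3f Mb, %d members, r2 >= %g)",
      (x$end_bp - x$start_bp) / 1e6, nrow(x$members), x$r2_threshold
    ), "\n"
  )
  cat(
    "  top SNP", paste0(x$chrom, "_", x$top_pos),
    if (!is.na(x$top_p)) paste("p =", format(x$top_p, digits = 3)) else "",
    "\n"
  )
  invisible(x)
}

#' Export a confidence interval
#'
#' `region_to_bed()` converts the 1-based inclusive interval to a 0-based
#' half-open BED line; `write_region_json()` writes the full region
#' description.
#'
#' @param ci A `region_ci`.
#' @return A single BED-format string.
#' @export
region_to_bed <- function(ci) {
  paste(ci$chrom, ci$start_bp - 1L, ci$end_bp, sep = "\t")
}

#' @rdname region_to_bed
#' @param path Output JSON path.
#' @export
write_region_json <- function(ci, path) {
  jsonlite::write_json(unclass(ci), path,
    auto_unbox = TRUE, digits = NA,
    pretty = TRUE, dataframe = "columns"
  )
  invisible(path)
}
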