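#' Bonferroni genome-wide significance threshold
#'
#' @param m Number of markers tested (>= 1).
#' @param alpha Family-wise error rate, in (0, 1).
#' @return The per-marker p-value threshold `alpha / m`.
#' @export
#' @examples
#' bonferroni_threshold(6746746) # 7.41e-09
bonferroni_threshold <- function(m, alpha = 0.05) {
  if (length(m) != 1L || is.na(m) || m < 1) {
    stop("bonferroni_threshold: m must be a positive marker count",
      call. = FALSE
    )
  }
  if (alpha <= 0 || alpha >= 1) {
    stop("bonferroni_threshold: alpha must be in (0, 1)", call. = FALSE)
  }
  alpha / m
}

#' Rank-based empirical false discovery rate (q-values)
#'
#' Computes \eqn{q_i = p_i \, m / \mathrm{rank}(p_i)} with ranks assigned
#' by ascending p, then enforces monotonicity with the step-up clamp
#' (each q becomes the minimum raw q over all markers with p at least as
#' large) and caps at 1. With `m = length(p)` this is exactly the
#' Benjamini-Hochberg adjusted p-value. `m` can be overridden to apply a
#' chromosome-scoped correction with a wider marker count.
#'
#' @param pvals Numeric p-values in (0, 1].
#' @param m Marker count defining the FDR scope; defaults to
#'   `length(pvals)`.
#' @param tie_order Optional numeric key (e.g. genomic position) used to
#'   break rank ties in p deterministically.
#' @return An object of class `fdr_result`: `q_value` (aligned with the
#'   input order), `m_used`, `scope`.
#' @export
#' @examples
#' empirical_fdr(c(0.001, 0.02, 0.9))$q_value # 0.003 0.030 0.900
empirical_fdr <- function(pvals, m = NULL, tie_order = NULL) {
  if (length(pvals) == 0L) {
    stop("empirical_fdr: empty p-value vector", call. = FALSE)
  }
  if (any(is.na(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    stop("empirical_fdr: p-values must lie in (0, 1]", call. = FALSE)
  }
  n <- length(pvals)
  m_used <- if (is.null(m)) n else m
  if (m_used < n) {
    stop("empirical_fdr: scope m cannot be smaller than the number of ",
      "p-values",
      call. = FALSE
    )
  }
  ord <- if (is.null(tie_order)) {
    order(pvals)
  } else {
    order(pvals, tie_order)
  }
  raw <- pvals[ord] * m_used / seq_len(n)
  q_sorted <- pmin(rev(cummin(rev(raw))), 1)
  q <- numeric(n)
  q[ord] <- q_sorted
  structure(
    list(
      q_value = q, m_used = m_used,
      scope = if (is.null(m)) "genome" else "override"
    ),
    class = "fdr_result"
  )
}

#' Attach q-values to an association scan
#'
#' Genome scope corrects over all records at once; chromosome scope
#' reproduces the study's usage of correcting within one chromosome's
#' p-values only.
#'
#' @param assoc An `assoc_records` data frame from [wald_scan()].
#' @param scope `"genome"` or `"chromosome"`.
#' @return `assoc` with a `q_value` column appended.
#' @export
add_qvalues <- function(assoc, scope = c("genome", "chromosome")) {
  scope <- match.arg(scope)
  if (scope == "genome") {
    assoc$q_value <- empirical_fdr(assoc$p_wald, tie_order = assoc$pos)$q_value
  } else {
    assoc$q_value <- NA_real_
    for (cn in unique(assoc$chrom)) {
      i <- assoc$chrom == cn
      assoc$q_value[i] <- empirical_fdr(assoc$p_wald[i],
        tie_order = assoc$pos[i]
      )$q_value
    }
  }
  assoc
}

#' Genomic inflation factor and Q-Q data
#'
#' \eqn{\lambda_{gc}} is the median of the 1-df chi-square quantile
#' transform of the p-values divided by the null median 0.4549364. Q-Q
#' pairs are the sorted observed \eqn{-\log_{10} p} against uniform
#' order-statistic expectations, ready for plotting.
#'
#' @param pvals At least 10 p-values; zeros are clipped to the smallest
#'   positive double with a warning.
#' @return An object of class `inflation_report`: `lambda_gc` and `qq`
#'   (data frame `expected`/`observed`, ascending in `expected`).
#' @export
inflation_qq <- function(pvals) {
  if (length(pvals) < 10L) {
    stop("inflation_qq: need at least 10 p-values", call. = FALSE)
  }
  if (any(pvals == 0)) {
    warning("inflation_qq: zero p-values clipped to the smallest ",
      "positive double",
      call. = FALSE
    )
    pvals[pvals == 0] <- .Machine$double.xmin
  }
  if (any(pvals < 0 | pvals > 1)) {
    stop("inflation_qq: p-values must lie in [0, 1]", call. = FALSE)
  }
  chisq <- stats::qchisq(pvals, df = 1, lower.tail = FALSE)
  lambda_gc <- stats::median(chisq) / stats::qchisq(0.5, df = 1,
    lower.tail = FALSE
  )
  n <- length(pvals)
  qq <- data.frame(
    expected = sort(-log10(stats::ppoints(n))),
    observed = sort(-log10(pvals))
  )
  structure(list(lambda_gc = lambda_gc, qq = qq),
    class = "inflation_report"
  )
}

#' @export
print.inflation_report <- function(x, ...) {
  cat(
    "<inflation_report> lambda_gc =", format(x$lambda_gc, digits = 4),
    "over", nrow(x$qq), "tests\n"
  )
  invisible(x)
}
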