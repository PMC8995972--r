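# Restricted log-likelihood of the variance ratio lambda for the model
# y = W a + u + e,  u ~ N(0, sg2 K), e ~ N(0, se2 I), lambda = sg2/se2,
# evaluated on the eigenbasis of K (d = eigenvalues, inputs pre-rotated).
reml_profile <- function(lambda, yt, Wt, d) {
  n <- length(yt)
  c <- ncol(Wt)
  v <- lambda * d + 1
  sw <- 1 / sqrt(v)
  qrW <- qr(Wt * sw)
  rss <- sum(qr.resid(qrW, yt * sw)^2)
  se2 <- rss / (n - c)
  logdet_wvw <- 2 * sum(log(abs(diag(qr.R(qrW)))))
  ll <- -0.5 * ((n - c) * log(2 * pi * se2) + sum(log(v)) +
    logdet_wvw + (n - c))
  list(ll = ll, se2 = se2, qrW = qrW, v = v)
}

#' Fit the null linear mixed model by REML
#'
#' Estimates the variance ratio \eqn{\lambda = \sigma_g^2/\sigma_e^2} of
#' the model \eqn{y = W\alpha + u + \epsilon}, \eqn{u \sim MVN(0, \lambda
#' \tau^{-1} K)}, \eqn{\epsilon \sim MVN(0, \tau^{-1} I_n)}, by restricted
#' maximum likelihood. The cached eigendecomposition of `K` diagonalizes
#' \eqn{\lambda K + I}, so each candidate \eqn{\lambda} costs O(n);
#' \eqn{\alpha} and \eqn{\tau^{-1}} are profiled out in closed form. The
#' search runs a grid over \eqn{\log_{10}\lambda \in [-5, 5]} followed by
#' local refinement with [stats::optimize()].
#'
#' Eigenvalues are trace-normalized to mean 1 before fitting, so the
#' reported `pve` (proportion of phenotypic variance explained by the
#' polygenic term, i.e. SNP heritability) is simply
#' \eqn{\hat\lambda/(\hat\lambda + 1)}.
#'
#' @param y Numeric trait vector aligned with `k$sample_ids`; must be
#'   finite and non-constant.
#' @param k A [compute_kinship()] result.
#' @param w Covariate matrix including an intercept column of ones;
#'   defaults to intercept only.
#' @return An object of class `null_lmm_fit`: `lambda_hat`, `tau_inv_hat`
#'   (residual variance \eqn{\tau^{-1}}), `alpha_hat`, `loglik_reml`,
#'   `pve`, `boundary` (logical: optimizer at the search edge) and the
#'   rotated data reused by [wald_scan()].
#' @export
fit_null_lmm <- function(y, k, w = NULL) {
  stopifnot(inherits(k, "kinship_matrix"))
  n <- length(k$sample_ids)
  if (length(y) != n || !all(is.finite(y))) {
    stop("fit_null_lmm: y must be finite and aligned with the kinship",
      call. = FALSE
    )
  }
  if (stats::sd(y) < 1e-12) {
    stop("fit_null_lmm: y is constant", call. = FALSE)
  }
  if (is.null(w)) w <- matrix(1, n, 1L)
  w <- as.matrix(w)
  if (!any(apply(w, 2L, function(col) all(col == 1)))) {
    stop("fit_null_lmm: w must include an intercept column of 1s",
      call. = FALSE
    )
  }

  d <- pmax(k$eigen$values, 0)
  tr <- sum(d)
  if (tr < 1e-12) {
    stop("fit_null_lmm: kinship has zero trace", call. = FALSE)
  }
  d <- d * n / tr # mean eigenvalue 1 (trace-normalized convention)
  U <- k$eigen$vectors
  yt <- drop(crossprod(U, y))
  Wt <- crossprod(U, w)

  grid <- seq(-5, 5, by = 0.1)
  ll <- vapply(
    grid, function(lg) reml_profile(10^lg, yt, Wt, d)$ll,
    numeric(1)
  )
  flat <- diff(range(ll)) < 1e-6 # lambda unidentifiable (e.g. K = I)
  if (flat) {
    lg_hat <- grid[1L]
  } else {
    i <- which.max(ll)
    lo <- grid[max(1L, i - 1L)]
    hi <- grid[min(length(grid), i + 1L)]
    opt <- stats::optimize(function(lg) reml_profile(10^lg, yt, Wt, d)$ll,
      lower = lo, upper = hi, maximum = TRUE, tol = 1e-6
    )
    lg_hat <- if (opt$objective > ll[i]) opt$maximum else grid[i]
  }
  boundary <- flat || lg_hat <= -4.5 || lg_hat >= 4.5
  lambda_hat <- 10^lg_hat
  fit <- reml_profile(lambda_hat, yt, Wt, d)
  alpha_hat <- qr.coef(fit$qrW, yt / sqrt(fit$v))
  if (boundary) {
    warning("fit_null_lmm: lambda estimate at the search boundary (",
      format(lambda_hat, digits = 3),
      "); variance ratio weakly identified",
      call. = FALSE
    )
  }
  structure(list(
    lambda_hat = lambda_hat,
    tau_inv_hat = fit$se2,
    alpha_hat = alpha_hat,
    loglik_reml = fit$ll,
    pve = lambda_hat / (lambda_hat + 1),
    boundary = boundary,
    n = n, c = ncol(w),
    eigenvalues = d, rot_y = yt, rot_w = Wt, rot = U
  ), class = "null_lmm_fit")
}

#' @export
print.null_lmm_fit <- function(x, ...) {
  cat("<null_lmm_fit> n =", x$n, "\n")
  cat(
    "  lambda =", format(x$lambda_hat, digits = 4),
    " pve =", format(x$pve, digits = 4),
    " residual var =", format(x$tau_inv_hat, digits = 4), "\n"
  )
  cat("  REML logL =", format(x$loglik_reml, digits = 6))
  if (x$boundary) cat("  [boundary]")
  cat("\n")
  invisible(x)
}

#' Wald association scan under the fitted mixed model
#'
#' For each site, estimates the SNP effect \eqn{\beta} and its standard
#' error by generalized least squares under covariance
#' \eqn{\hat\lambda K + I} and tests \eqn{\beta = 0} with a Wald t test on
#' \eqn{n - c - 1} degrees of freedom (`c` = covariate count including the
#' intercept). By default \eqn{\hat\lambda} comes from the null fit and is
#' held fixed across sites; `per_snp_lambda = TRUE` re-optimizes
#' \eqn{\lambda} under each site's alternative model instead (slower,
#' closer to an exact per-marker REML Wald test).
#'
#' Monomorphic sites are emitted with `p_wald = 1`, `beta = 0` and
#' `monomorphic = TRUE` rather than dropped. With `lambda = 0` the scan
#' reduces exactly to per-site ordinary least-squares t tests.
#'
#' @param y Trait vector aligned with the kinship sample order.
#' @param g A [genotype_matrix()] with the same samples.
#' @param k A [compute_kinship()] result.
#' @param w Covariates including intercept; default intercept only.
#' @param null_fit Optional [fit_null_lmm()] result to reuse.
#' @param lambda Optional fixed variance ratio overriding the null fit
#'   (e.g. `0` for plain linear regression).
#' @param per_snp_lambda Re-estimate lambda per site? Default `FALSE`.
#' @return A data frame of class `assoc_records`, one row per site, sorted
#'   by (chrom, pos): `chrom`, `pos`, `ref`, `alt`, `af`, `beta`, `se`,
#'   `p_wald`, `monomorphic`.
#' @export
wald_scan <- function(y, g, k, w = NULL, null_fit = NULL, lambda = NULL,
                      per_snp_lambda = FALSE) {
  stopifnot(inherits(g, "genotype_matrix"))
  n <- length(g$sample_ids)
  if (is.null(w)) w <- matrix(1, n, 1L)
  w <- as.matrix(w)
  if (is.null(null_fit) && is.null(lambda)) {
    null_fit <- fit_null_lmm(y, k, w)
  }
  if (!is.null(null_fit)) {
    lam <- if (is.null(lambda)) null_fit$lambda_hat else lambda
    d <- null_fit$eigenvalues
    U <- null_fit$rot
    yt <- null_fit$rot_y
    Wt <- null_fit$rot_w
  } else {
    # fixed lambda supplied: no REML needed, just rotate
    lam <- lambda
    d <- pmax(k$eigen$values, 0)
    d <- d * n / sum(d)
    U <- k$eigen$vectors
    yt <- drop(crossprod(U, y))
    Wt <- crossprod(U, w)
  }
  X <- impute_dosage(g)
  Xc <- sweep(X, 2L, colMeans(X))
  mono <- apply(Xc, 2L, function(col) max(abs(col)) < 1e-12)
  Xt <- crossprod(U, Xc)

  c_ <- ncol(w)
  df <- n - c_ - 1L
  if (df < 1L) stop("wald_scan: not enough residual df", call. = FALSE)

  scan_fixed <- function(lam) {
    sw <- 1 / sqrt(lam * d + 1)
    qrW <- qr(Wt * sw)
    yr <- qr.resid(qrW, yt * sw)
    Xr <- qr.resid(qrW, Xt * sw)
    sxx <- colSums(Xr^2)
    sxy <- colSums(Xr * yr)
    beta <- sxy / sxx
    rss <- sum(yr^2) - beta^2 * sxx
    se <- sqrt(pmax(rss, 0) / df / sxx)
    list(beta = beta, se = se)
  }

  if (!per_snp_lambda) {
    est <- scan_fixed(lam)
    beta <- est$beta
    se <- est$se
  } else {
    m <- ncol(Xc)
    beta <- se <- numeric(m)
    for (j in seq_len(m)) {
      if (mono[j]) next
      W2 <- cbind(Wt, Xt[, j])
      opt <- stats::optimize(
        function(lg) reml_profile(10^lg, yt, W2, d)$ll,
        lower = -5, upper = 5, maximum = TRUE, tol = 1e-4
      )
      sw <- 1 / sqrt(10^opt$maximum * d + 1)
      qrW <- qr(Wt * sw)
      yr <- qr.resid(qrW, yt * sw)
      xr <- qr.resid(qrW, Xt[, j] * sw)
      sxx <- sum(xr^2)
      b <- sum(xr * yr) / sxx
      rss <- sum(yr^2) - b^2 * sxx
      beta[j] <- b
      se[j] <- sqrt(max(rss, 0) / df / sxx)
    }
  }

  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), df = df)
  beta[mono] <- 0
  se[mono] <- NA_real_
  p[mono] <- 1
  p <- pmin(pmax(p, .Machine$double.xmin), 1)

  out <- data.frame(
    chrom = g$sites$chrom, pos = g$sites$pos,
    ref = g$sites$ref, alt = g$sites$alt,
    af = colMeans(X) / 2,
    beta = beta, se = se, p_wald = p,
    monomorphic = mono,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("assoc_records", "data.frame")
  out
}

#' @rdname wald_scan
#' @param assoc An `assoc_records` data frame.
#' @param path Output TSV path.
#' @export
write_assoc <- function(assoc, path) {
  utils::write.table(as.data.frame(assoc), path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(path)
}
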