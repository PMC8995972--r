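#' Simulate phased genotypes as founder-haplotype mosaics
#'
#' Each chromosome of each individual is built by copying segments from a
#' small pool of founder haplotypes, switching founders at crossover points
#' drawn at `recomb_rate_per_bp`. This produces block-wise linkage
#' disequilibrium that decays with distance and a long-tailed haplotype
#' frequency spectrum (under skewed founder weights), the two features the
#' downstream confidence-interval and haplotype-sharing stages rely on.
#'
#' Founder allele frequencies are drawn per site from
#' `Beta(maf_beta_params)`. Sites that come out monomorphic in the sample
#' get a single haplotype allele flipped so that every emitted site is
#' segregating. Positions listed in `config$causal_loci` are always
#' included as sites.
#'
#' @param config A [sim_config()].
#' @return A phased [genotype_matrix()]; the founder pool is attached as
#'   attribute `"founders"` (per-chromosome 0/1 matrices).
#' @export
#' @examples
#' g <- simulate_genotypes(sim_config(n_individuals = 20, seed = 7))
#' dim(g)
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_individuals
  K <- config$n_founder_haplotypes
  wts <- switch(config$founder_weights,
    skewed = (1 / seq_len(K)) / sum(1 / seq_len(K)),
    uniform = rep(1 / K, K)
  )
  nh <- 2L * n
  a <- config$maf_beta_params[1]
  b <- config$maf_beta_params[2]

  site_list <- list()
  hap1_list <- list()
  hap2_list <- list()
  founders_out <- list()

  for (ci in seq_len(nrow(config$chromosomes))) {
    cname <- as.character(config$chromosomes$name[ci])
    clen <- config$chromosomes$length_bp[ci]
    m <- config$chromosomes$n_sites[ci]
    causal_pos <- config$causal_loci$pos[config$causal_loci$chrom == cname]

    pos <- sort(unique(c(causal_pos, sample.int(clen, m))))
    if (length(pos) > m) {
      drop_pool <- setdiff(pos, causal_pos)
      pos <- sort(setdiff(pos, sample(drop_pool, length(pos) - m)))
    }
    m <- length(pos)

    # founder pool: marginal allele frequencies p_j ~ Beta(a, b); alleles
    # within a founder are spatially correlated through a latent Gaussian
    # AR(1) process along the chromosome (correlation exp(-d/ld_scale)),
    # so the pool itself carries ancestral LD that decays with distance
    p <- stats::rbeta(m, a, b)
    # planted causal loci get intermediate frequencies: a fixed variance
    # fraction at extreme MAF would imply implausible per-allele effects,
    # and the locus must survive the MAF filter to be discoverable
    if (length(causal_pos)) {
      ci_idx <- match(causal_pos, pos)
      p[ci_idx] <- stats::runif(length(ci_idx), 0.2, 0.8)
    }
    ld_scale <- config$founder_ld_scale_bp
    Z <- matrix(0, K, m)
    Z[, 1] <- stats::rnorm(K)
    if (m > 1L) {
      rho <- if (ld_scale > 0) {
        exp(-diff(pos) / ld_scale)
      } else {
        rep(0, m - 1L)
      }
      for (j in 2:m) {
        Z[, j] <- rho[j - 1L] * Z[, j - 1L] +
          sqrt(1 - rho[j - 1L]^2) * stats::rnorm(K)
      }
    }
    founders <- matrix(0L, K, m)
    founders[Z < matrix(stats::qnorm(p), K, m, byrow = TRUE)] <- 1L
    # keep the pool segregating where possible
    mono <- which(colSums(founders) %in% c(0L, K))
    for (j in mono) {
      founders[sample.int(K, 1L), j] <- 1L - founders[sample.int(K, 1L), j]
    }

    haps <- matrix(0L, nrow = nh, ncol = m)
    exp_cross <- config$recomb_rate_per_bp * clen
    ncross <- stats::rpois(nh, exp_cross)
    for (h in seq_len(nh)) {
      k <- ncross[h]
      seg_founders <- sample.int(K, k + 1L, replace = TRUE, prob = wts)
      if (k == 0L) {
        haps[h, ] <- founders[seg_founders, ]
      } else {
        breaks <- sort(stats::runif(k, 1, clen))
        idx <- seg_founders[findInterval(pos, breaks) + 1L]
        haps[h, ] <- founders[cbind(idx, seq_len(m))]
      }
    }

    # guarantee segregation in the emitted sample
    ac <- colSums(haps)
    for (j in which(ac %in% c(0L, nh))) {
      h <- sample.int(nh, 1L)
      haps[h, j] <- 1L - haps[h, j]
    }

    ref_alt <- replicate(m, sample(c("A", "C", "G", "T"), 2L))
    site_list[[ci]] <- data.frame(
      chrom = cname, pos = pos,
      ref = ref_alt[1, ], alt = ref_alt[2, ],
      biallelic = TRUE, stringsAsFactors = FALSE
    )
    hap1_list[[ci]] <- haps[seq(1L, nh, by = 2L), , drop = FALSE]
    hap2_list[[ci]] <- haps[seq(2L, nh, by = 2L), , drop = FALSE]
    founders_out[[cname]] <- founders
  }

  sites <- do.call(rbind, site_list)
  hap1 <- do.call(cbind, hap1_list)
  hap2 <- do.call(cbind, hap2_list)
  dosage <- hap1 + hap2

  if (config$missing_rate > 0) {
    mask <- matrix(
      stats::runif(length(dosage)) < config$missing_rate,
      nrow = nrow(dosage)
    )
    dosage[mask] <- NA_integer_
    hap1[mask] <- NA_integer_
    hap2[mask] <- NA_integer_
  }

  ids <- sprintf("duck%03d", seq_len(n))
  g <- genotype_matrix(
    sample_ids = ids, sites = sites, dosage = dosage,
    phased = TRUE, haplotypes = list(hap1 = hap1, hap2 = hap2)
  )
  attr(g, "founders") <- founders_out
  g
}

# Residualize the columns of m against the columns of basis (which must
# include an intercept), then rescale/rotate so the empirical covariance of
# the result is exactly `target` (n-1 denominator). Returns a zero matrix
# for a zero target.
recolor_exact <- function(m, basis, target) {
  k <- ncol(m)
  if (all(abs(target) < 1e-300)) {
    return(matrix(0, nrow(m), k))
  }
  r <- qr.resid(qr(basis), m)
  S <- stats::cov(r)
  es <- eigen(S, symmetric = TRUE)
  if (min(es$values) < 1e-12 * max(es$values)) {
    stop("phenotype simulation: raw component matrix is rank deficient; ",
      "increase n_individuals or n_sites",
      call. = FALSE
    )
  }
  whiten <- es$vectors %*% diag(1 / sqrt(es$values), k) %*% t(es$vectors)
  et <- eigen(target, symmetric = TRUE)
  if (min(et$values) < -1e-10) {
    stop("phenotype simulation: target covariance not positive ",
      "semi-definite",
      call. = FALSE
    )
  }
  color <- et$vectors %*% diag(sqrt(pmax(et$values, 0)), k) %*% t(et$vectors)
  r %*% whiten %*% color
}

#' Simulate correlated quantitative traits on top of a genotype panel
#'
#' Each trait is the sum of (i) planted causal-locus effects, (ii) a
#' polygenic component spread over all sites as random per-site effects on
#' centred dosages, and (iii) a residual. The target phenotypic
#' correlation matrix `C` is split into a genetic part
#' `G = D C D` with `D = diag(sqrt(h2))` and a residual part `R = C - G`
#' (both checked for positive semi-definiteness), so heritable traits
#' inherit their cross-trait covariance through the shared polygenic
#' background. Components are constructed with *exact* sample moments
#' (in the spirit of `MASS::mvrnorm(empirical = TRUE)`): each component is
#' residualized against the previous ones and recoloured so that the
#' realized variance decomposition, trait correlations, means and SDs hit
#' their targets exactly in every replicate, while the per-site effects
#' remain random.
#'
#' @param genotypes A [genotype_matrix()] from [simulate_genotypes()].
#' @param config The same [sim_config()] used to generate `genotypes`.
#' @return A list with `phenotypes` (a data frame: `sample_id` plus one
#'   column per trait) and `truth` (a `truth_record`: causal effects on the
#'   phenotype scale, realized per-trait heritability and correlations,
#'   founder pool and seed).
#' @export
simulate_phenotypes <- function(genotypes, config) {
  validate_sim_config(config)
  stopifnot(inherits(genotypes, "genotype_matrix"))
  set.seed(config$seed + 1000003L)
  n <- length(genotypes$sample_ids)
  if (n != config$n_individuals) {
    stop("simulate_phenotypes: genotypes and config disagree on sample size",
      call. = FALSE
    )
  }
  traits <- names(config$h2_targets)
  k <- length(traits)
  h2 <- unname(config$h2_targets)
  C <- unname(config$pheno_corr_targets)

  D <- diag(sqrt(h2), k)
  G <- D %*% C %*% D
  R <- C - G
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-10) {
    stop("simulate_phenotypes: residual covariance (C - G) is not positive ",
      "semi-definite; lower the h2 targets or weaken the correlations",
      call. = FALSE
    )
  }

  X <- impute_dosage(genotypes)
  Xc <- sweep(X, 2L, colMeans(X))

  # causal components, one column per trait
  cl <- config$causal_loci
  causal_cols <- matrix(0, n, k)
  f_tot <- numeric(k)
  causal_truth <- NULL
  if (nrow(cl) > 0) {
    key <- paste(genotypes$sites$chrom, genotypes$sites$pos)
    cl$site <- match(paste(cl$chrom, cl$pos), key)
    if (anyNA(cl$site)) {
      stop("simulate_phenotypes: causal locus not present in genotypes",
        call. = FALSE
      )
    }
    cl$effect <- NA_real_
    for (t in seq_len(k)) {
      rows <- which(cl$trait == traits[t])
      if (!length(rows)) next
      f <- cl$fraction_of_variance[rows]
      z <- scale(Xc[, cl$site[rows], drop = FALSE])
      raw <- drop(z %*% sqrt(f))
      s <- stats::sd(raw)
      if (s < 1e-12) {
        stop("simulate_phenotypes: causal loci for ", traits[t],
          " are degenerate in this sample",
          call. = FALSE
        )
      }
      adj <- sqrt(sum(f)) / s
      causal_cols[, t] <- raw * adj
      # per-ALT-allele effect on the final phenotype scale
      sds <- apply(Xc[, cl$site[rows], drop = FALSE], 2L, stats::sd)
      cl$effect[rows] <- config$trait_sds[t] * sqrt(f) * adj / sds
      f_tot[t] <- sum(f)
    }
    causal_truth <- cl
  }

  # polygenic covariance: same correlation pattern as C, scaled to the
  # heritability left after the (trait-specific) causal share; PSD by
  # construction. The residual absorbs the cross-trait difference so the
  # total phenotypic covariance still hits C exactly.
  Dg <- diag(sqrt(pmax(h2 - f_tot, 0)), k)
  G_poly <- Dg %*% C %*% Dg
  R <- C - diag(f_tot, k) - G_poly
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-10) {
    stop("simulate_phenotypes: residual covariance (C minus genetic parts) ",
      "is not positive semi-definite; reduce causal fractions or h2 targets",
      call. = FALSE
    )
  }

  basis <- cbind(rep(1, n), causal_cols[, f_tot > 0, drop = FALSE])
  need <- ncol(basis) + 2L * k + 1L
  if (n <= need) {
    stop("simulate_phenotypes: need more than ", need,
      " individuals for this architecture",
      call. = FALSE
    )
  }

  U <- recolor_exact(
    Xc %*% matrix(stats::rnorm(ncol(Xc) * k), ncol = k),
    basis, G_poly
  )
  E <- recolor_exact(
    matrix(stats::rnorm(n * k), ncol = k),
    cbind(basis, U), R
  )

  ystd <- causal_cols + U + E # exact mean 0, variance 1 per trait
  Y <- sweep(
    sweep(ystd, 2L, config$trait_sds, "*"), 2L,
    config$trait_means, "+"
  )
  colnames(Y) <- traits
  if (config$round_counts) {
    count_traits <- setdiff(seq_len(k), 1L)
    Y[, count_traits] <- round(Y[, count_traits])
  }

  gen <- causal_cols + U
  realized_h2 <- apply(gen, 2L, stats::var) / apply(ystd, 2L, stats::var)
  names(realized_h2) <- traits

  phenotypes <- data.frame(
    sample_id = genotypes$sample_ids,
    Y, check.names = FALSE, stringsAsFactors = FALSE
  )
  truth <- structure(list(
    truth_schema = 1L,
    causal = causal_truth,
    realized_h2 = realized_h2,
    realized_corr = stats::cor(Y),
    founders = attr(genotypes, "founders"),
    seed = config$seed
  ), class = "truth_record")
  list(phenotypes = phenotypes, truth = truth)
}

#' Write a simulated dataset to disk
#'
#' Emits a phased VCF v4.2, a tab-separated phenotype table and a
#' ground-truth JSON (`truth_schema` 1) that round-trip losslessly through
#' [read_vcf()] / [read_phenotypes()].
#'
#' @param genotypes A phased [genotype_matrix()].
#' @param phenotypes Phenotype data frame (`sample_id` + trait columns).
#' @param truth Optional `truth_record` from [simulate_phenotypes()].
#' @param out_dir Output directory (created if absent).
#' @return Named character vector of file paths (`vcf`, `phenotypes`, and
#'   `truth` when supplied).
#' @export
write_dataset <- function(genotypes, phenotypes, truth = NULL, out_dir) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (length(genotypes$sample_ids) == 0L) {
    stop("write_dataset: no individuals to write", call. = FALSE)
  }
  if (!identical(as.character(phenotypes$sample_id), genotypes$sample_ids)) {
    stop("write_dataset: phenotype and genotype sample ids differ",
      call. = FALSE
    )
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  vcf_path <- file.path(out_dir, "genotypes.vcf")
  phe_path <- file.path(out_dir, "phenotypes.tsv")
  write_vcf(genotypes, vcf_path)
  write_phenotypes(phenotypes, phe_path)
  out <- c(vcf = vcf_path, phenotypes = phe_path)
  if (!is.null(truth)) {
    truth_path <- file.path(out_dir, "truth.json")
    tr <- truth
    tr$realized_corr <- as.data.frame(tr$realized_corr)
    tr$founders <- lapply(tr$founders, function(m) apply(m, 1L, paste,
      collapse = ""
    ))
    jsonlite::write_json(unclass(tr), truth_path,
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    out <- c(out, truth = truth_path)
  }
  out
}
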