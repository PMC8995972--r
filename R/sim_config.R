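#' Default trait architecture for the layer-duck study design
#'
#' Trait names, SNP heritabilities, phenotypic correlations and descriptive
#' location/scale parameters used as generator defaults: heritabilities
#' 0.15 (AFE), 0.20 (EP43w), 0.22 (EP66w); phenotypic correlations
#' AFE--EP43w -0.73, AFE--EP66w -0.34, EP43w--EP66w 0.59; means/SDs
#' 136.95/13.93 days (AFE), 151.27/12.59 eggs (EP43w), 268.96/24.37 eggs
#' (EP66w).
#'
#' @return A list with elements `traits`, `h2`, `corr`, `means`, `sds`.
#' @export
duck_trait_defaults <- function() {
  traits <- c("AFE", "EP43w", "EP66w")
  corr <- matrix(c(
    1.00, -0.73, -0.34,
    -0.73, 1.00, 0.59,
    -0.34, 0.59, 1.00
  ), 3, 3, byrow = TRUE, dimnames = list(traits, traits))
  list(
    traits = traits,
    h2 = c(AFE = 0.15, EP43w = 0.20, EP66w = 0.22),
    corr = corr,
    means = c(AFE = 136.95, EP43w = 151.27, EP66w = 268.96),
    sds = c(AFE = 13.93, EP43w = 12.59, EP66w = 24.37)
  )
}

#' Configuration for the synthetic genotype/phenotype generator
#'
#' Bundles and validates all parameters of the founder-mosaic genotype
#' simulator and the correlated-trait phenotype model.
#'
#' @param n_individuals Number of diploid individuals.
#' @param chromosomes Data frame with columns `name`, `length_bp`,
#'   `n_sites` describing the mock chromosomes.
#' @param n_founder_haplotypes Size of the founder haplotype pool each
#'   chromosome is a mosaic of (>= 2).
#' @param founder_weights Either `"skewed"` (copying probability of founder
#'   k proportional to 1/k, giving a realistic long-tailed haplotype
#'   frequency spectrum) or `"uniform"`.
#' @param recomb_rate_per_bp Crossover rate per base pair used when tiling
#'   founder segments (default 5e-8; avian microchromosomes recombine well
#'   above the ~1 cM/Mb genome average).
#' @param founder_ld_scale_bp Distance scale (bp) of the ancestral LD
#'   carried by the founder pool: allele correlation within a founder
#'   decays as `exp(-d / founder_ld_scale_bp)`. Default 1e6; `0` gives
#'   independent sites.
#' @param maf_beta_params Length-2 shape parameters of the Beta
#'   distribution founder allele frequencies are drawn from.
#' @param causal_loci Data frame with columns `chrom`, `pos`, `trait`,
#'   `fraction_of_variance` (fraction of total phenotypic variance
#'   explained by that locus). May be empty.
#' @param h2_targets Named per-trait SNP heritabilities in `[0, 1]`.
#' @param pheno_corr_targets Target phenotypic correlation matrix
#'   (symmetric, unit diagonal, positive semi-definite).
#' @param trait_means,trait_sds Per-trait location and scale on the
#'   reported phenotype scale (days or eggs).
#' @param missing_rate Per-cell genotype missingness rate (default 0).
#' @param round_counts Round egg-count traits to integers? Default `FALSE`
#'   since the mixed model treats them as continuous.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration.
#'
#' @return An object of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_individuals = 50, seed = 1)
#' cfg$h2_targets
sim_config <- function(n_individuals = 166,
                       chromosomes = data.frame(
                         name = c("25", "29"),
                         length_bp = c(10e6, 10e6),
                         n_sites = c(1000, 1000)
                       ),
                       n_founder_haplotypes = 100,
                       founder_weights = c("skewed", "uniform"),
                       recomb_rate_per_bp = 5e-8,
                       founder_ld_scale_bp = 1e6,
                       maf_beta_params = c(1, 1),
                       causal_loci = NULL,
                       h2_targets = duck_trait_defaults()$h2,
                       pheno_corr_targets = duck_trait_defaults()$corr,
                       trait_means = duck_trait_defaults()$means,
                       trait_sds = duck_trait_defaults()$sds,
                       missing_rate = 0,
                       round_counts = FALSE,
                       seed = 1L) {
  founder_weights <- match.arg(founder_weights)
  if (is.null(causal_loci)) {
    causal_loci <- data.frame(
      chrom = character(), pos = integer(),
      trait = character(), fraction_of_variance = numeric()
    )
  }
  cfg <- structure(list(
    n_individuals = as.integer(n_individuals),
    chromosomes = chromosomes,
    n_founder_haplotypes = as.integer(n_founder_haplotypes),
    founder_weights = founder_weights,
    recomb_rate_per_bp = recomb_rate_per_bp,
    founder_ld_scale_bp = founder_ld_scale_bp,
    maf_beta_params = maf_beta_params,
    causal_loci = causal_loci,
    h2_targets = h2_targets,
    pheno_corr_targets = pheno_corr_targets,
    trait_means = trait_means,
    trait_sds = trait_sds,
    missing_rate = missing_rate,
    round_counts = isTRUE(round_counts),
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param x A `sim_config` object.
#' @export
validate_sim_config <- function(x) {
  stopifnot(inherits(x, "sim_config"))
  if (x$n_individuals < 1L) {
    stop("sim_config: n_individuals must be positive", call. = FALSE)
  }
  ch <- x$chromosomes
  if (!all(c("name", "length_bp", "n_sites") %in% names(ch)) ||
    nrow(ch) < 1L) {
    stop("sim_config: chromosomes needs columns name/length_bp/n_sites",
      call. = FALSE
    )
  }
  if (any(ch$n_sites < 1L) || any(ch$length_bp < ch$n_sites)) {
    stop("sim_config: each chromosome needs >= 1 site and length >= n_sites",
      call. = FALSE
    )
  }
  if (x$n_founder_haplotypes < 2L) {
    stop("sim_config: n_founder_haplotypes must be >= 2", call. = FALSE)
  }
  if (x$recomb_rate_per_bp < 0 || x$founder_ld_scale_bp < 0 ||
    x$missing_rate < 0 || x$missing_rate >= 1) {
    stop("sim_config: rates out of range", call. = FALSE)
  }
  if (length(x$maf_beta_params) != 2L || any(x$maf_beta_params <= 0)) {
    stop("sim_config: maf_beta_params must be two positive shapes",
      call. = FALSE
    )
  }
  traits <- names(x$h2_targets)
  k <- length(traits)
  if (k < 1L || is.null(traits)) {
    stop("sim_config: h2_targets must be a named vector", call. = FALSE)
  }
  if (any(x$h2_targets < 0) || any(x$h2_targets > 1)) {
    stop("sim_config: h2_targets must lie in [0, 1]", call. = FALSE)
  }
  C <- x$pheno_corr_targets
  if (!is.matrix(C) || any(dim(C) != k) ||
    max(abs(C - t(C))) > 1e-8 || max(abs(diag(C) - 1)) > 1e-8) {
    stop("sim_config: pheno_corr_targets must be a symmetric unit-diagonal ",
      k, "x", k, " matrix",
      call. = FALSE
    )
  }
  if (min(eigen(C, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("sim_config: pheno_corr_targets is not positive semi-definite",
      call. = FALSE
    )
  }
  if (length(x$trait_means) != k || length(x$trait_sds) != k ||
    any(x$trait_sds <= 0)) {
    stop("sim_config: trait_means/trait_sds must match traits, SDs > 0",
      call. = FALSE
    )
  }
  cl <- x$causal_loci
  if (nrow(cl) > 0) {
    if (!all(cl$trait %in% traits)) {
      stop("sim_config: causal_loci reference unknown traits", call. = FALSE)
    }
    if (!all(cl$chrom %in% ch$name)) {
      stop("sim_config: causal_loci reference unknown chromosomes",
        call. = FALSE
      )
    }
    if (any(cl$fraction_of_variance <= 0)) {
      stop("sim_config: causal fractions must be positive", call. = FALSE)
    }
    per_trait <- tapply(cl$fraction_of_variance, cl$trait, sum)
    bad <- names(per_trait)[per_trait > x$h2_targets[names(per_trait)] + 1e-12]
    if (length(bad)) {
      stop(
        "sim_config: causal variance fractions exceed h2 target for ",
        paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
  }
  invisible(x)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(
    " ", x$n_individuals, "individuals,",
    sum(x$chromosomes$n_sites), "sites on",
    nrow(x$chromosomes), "chromosome(s)\n"
  )
  cat(
    "  traits:",
    paste0(
      names(x$h2_targets), " (h2=",
      formatC(x$h2_targets, format = "g"), ")",
      collapse = ", "
    ), "\n"
  )
  cat(
    "  founders:", x$n_founder_haplotypes,
    paste0("(", x$founder_weights, " weights)"),
    " recomb:", format(x$recomb_rate_per_bp, scientific = TRUE), "/bp\n"
  )
  if (nrow(x$causal_loci)) {
    cat("  causal loci:", nrow(x$causal_loci), "\n")
  }
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
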