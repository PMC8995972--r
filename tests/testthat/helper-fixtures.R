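# Shared fixtures, built in code and cached per test file.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a small two-chromosome design with one planted EP43w locus
small_causal_config <- function(seed = 1, n = 120) {
  sim_config(
    n_individuals = n,
    chromosomes = data.frame(
      name = c("25", "29"), length_bp = c(5e6, 5e6),
      n_sites = c(400, 400)
    ),
    causal_loci = data.frame(
      chrom = "25", pos = 3219815L, trait = "EP43w",
      fraction_of_variance = 0.15
    ),
    seed = seed
  )
}

small_sim <- function(seed = 1) {
  cached(paste0("small_sim_", seed), {
    cfg <- small_causal_config(seed)
    g <- simulate_genotypes(cfg)
    c(list(config = cfg, genotypes = g), simulate_phenotypes(g, cfg))
  })
}

# hand-built unphased panel: explicit dosages, strictly increasing positions
toy_panel <- function(dosage, chrom = "1", pos = NULL) {
  m <- ncol(dosage)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  genotype_matrix(
    sample_ids = sprintf("s%02d", seq_len(nrow(dosage))),
    sites = data.frame(
      chrom = chrom, pos = pos,
      ref = "A", alt = "C", biallelic = TRUE
    ),
    dosage = dosage
  )
}
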