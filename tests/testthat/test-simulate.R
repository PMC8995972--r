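test_that("config validation rejects degenerate or inconsistent designs", {
  expect_error(sim_config(n_individuals = 0), "positive")
  expect_error(
    sim_config(chromosomes = data.frame(
      name = "1", length_bp = 100, n_sites = 0
    )),
    "site"
  )
  expect_error(sim_config(n_founder_haplotypes = 1), ">= 2")
  expect_error(
    sim_config(h2_targets = c(AFE = 1.2, EP43w = 0.2, EP66w = 0.2)),
    "\\[0, 1\\]"
  )
  bad_corr <- diag(3)
  bad_corr[1, 2] <- 0.5 # asymmetric
  expect_error(sim_config(pheno_corr_targets = bad_corr), "symmetric")
  expect_error(
    sim_config(causal_loci = data.frame(
      chrom = "25", pos = 10L, trait = "EP43w",
      fraction_of_variance = 0.5
    )),
    "exceed"
  )
})

test_that("the generator is deterministic given the config", {
  cfg <- small_causal_config(seed = 42, n = 40)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$dosage, g2$dosage)
  expect_identical(g1$haplotypes, g2$haplotypes)
  expect_identical(g1$sites, g2$sites)
  p1 <- simulate_phenotypes(g1, cfg)
  p2 <- simulate_phenotypes(g2, cfg)
  expect_identical(p1$phenotypes, p2$phenotypes)
})

test_that("without recombination every haplotype is a founder copy and LD is total", {
  cfg <- sim_config(
    n_individuals = 30, n_founder_haplotypes = 2,
    recomb_rate_per_bp = 0,
    chromosomes = data.frame(name = "1", length_bp = 1e6, n_sites = 50),
    seed = 3
  )
  g <- simulate_genotypes(cfg)
  founders <- attr(g, "founders")[["1"]]
  haps <- rbind(g$haplotypes$hap1, g$haplotypes$hap2)
  match_founder <- apply(haps, 1L, function(h) {
    any(apply(founders, 1L, function(f) all(f == h)))
  })
  expect_true(all(match_founder))
  # all pairs of segregating sites perfectly linked
  seg <- which(apply(g$dosage, 2L, sd) > 0)
  pick <- seg[round(seq(1, length(seg), length.out = min(8, length(seg))))]
  for (i in pick) {
    for (j in pick) {
      expect_equal(ld_r2(g$dosage[, i], g$dosage[, j]), 1, tolerance = 1e-12)
    }
  }
})

test_that("LD decays with distance under recombination and ancestral mixing", {
  cfg <- sim_config(
    n_individuals = 200, seed = 11,
    chromosomes = data.frame(name = "1", length_bp = 20e6, n_sites = 2000)
  )
  g <- simulate_genotypes(cfg)
  pos <- g$sites$pos
  idx <- seq(1, 1800, by = 25)
  adjacent <- vapply(
    idx, function(j) ld_r2(g$dosage[, j], g$dosage[, j + 1]),
    numeric(1)
  )
  distant <- vapply(idx, function(j) {
    k <- which(pos > pos[j] + 1e6)[1]
    if (is.na(k)) NA_real_ else ld_r2(g$dosage[, j], g$dosage[, k])
  }, numeric(1))
  expect_gt(mean(adjacent, na.rm = TRUE), mean(distant, na.rm = TRUE))
})

test_that("sample MAFs are positive and controlled by the Beta shapes", {
  g <- simulate_genotypes(small_causal_config(seed = 5, n = 80))
  fr <- site_frequencies(g)
  expect_true(all(fr$maf > 0))
  expect_true(all(fr$maf <= 0.5))
  # more concentrated Beta -> fewer rare alleles
  cfg_mid <- sim_config(
    n_individuals = 80, maf_beta_params = c(8, 8), seed = 5,
    chromosomes = data.frame(name = "1", length_bp = 2e6, n_sites = 400)
  )
  fr_mid <- site_frequencies(simulate_genotypes(cfg_mid))
  expect_lt(mean(fr_mid$maf < 0.1), mean(fr$maf < 0.1))
})

test_that("a null architecture yields phenotypes independent of genotypes", {
  cfg <- sim_config(
    n_individuals = 150,
    h2_targets = c(AFE = 0, EP43w = 0, EP66w = 0),
    chromosomes = data.frame(name = "1", length_bp = 2e6, n_sites = 200),
    seed = 7
  )
  g <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(g, cfg)
  expect_equal(unname(sim$truth$realized_h2), rep(0, 3))
  # single-site regression slopes behave like noise: |t| rarely large
  y <- sim$phenotypes$AFE
  tstats <- apply(g$dosage[, 1:100], 2L, function(x) {
    if (sd(x) == 0) {
      return(0)
    }
    unname(summary(lm(y ~ x))$coefficients[2, 3])
  })
  expect_lt(mean(abs(tstats) > 2.5), 0.08)
})

test_that("phenotype calibration hits the published location/scale and correlations", {
  sim <- small_sim(seed = 2)
  ph <- sim$phenotypes
  expect_equal(mean(ph$AFE), 136.95, tolerance = 1e-10)
  expect_equal(sd(ph$AFE), 13.93, tolerance = 1e-10)
  expect_equal(mean(ph$EP66w), 268.96, tolerance = 1e-10)
  expect_equal(cor(ph$EP43w, ph$EP66w), 0.59, tolerance = 1e-10)
  expect_equal(cor(ph$AFE, ph$EP43w), -0.73, tolerance = 1e-10)
  expect_equal(unname(sim$truth$realized_h2),
    unname(sim$config$h2_targets),
    tolerance = 1e-10
  )
})

test_that("infeasible correlation splits fail loudly naming the matrix", {
  cfg <- small_causal_config()
  cfg$h2_targets[] <- c(0.95, 0.9, 0.9) # leaves no room for residual corr
  expect_error(
    simulate_phenotypes(simulate_genotypes(cfg), cfg),
    "positive semi-definite"
  )
})

test_that("write_dataset round-trips through the readers losslessly", {
  sim <- small_sim(seed = 1)
  out <- withr::local_tempdir()
  paths <- write_dataset(sim$genotypes, sim$phenotypes, sim$truth, out)
  expect_true(all(file.exists(paths)))

  g2 <- read_vcf(paths[["vcf"]])
  expect_identical(unname(g2$dosage), unname(sim$genotypes$dosage))
  expect_identical(
    unname(g2$haplotypes$hap1),
    unname(sim$genotypes$haplotypes$hap1)
  )
  expect_equal(g2$sites$pos, sim$genotypes$sites$pos)
  expect_equal(g2$sites$ref, sim$genotypes$sites$ref)
  expect_identical(g2$sample_ids, sim$genotypes$sample_ids)

  ph2 <- read_phenotypes(paths[["phenotypes"]])
  expect_equal(ph2$EP43w, sim$phenotypes$EP43w, tolerance = 1e-12)

  # truth JSON causal ids all present in the VCF site list
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$truth_schema, 1L)
  key <- paste(g2$sites$chrom, g2$sites$pos)
  expect_true(all(paste(truth$causal$chrom, truth$causal$pos) %in% key))
})

test_that("writing an empty dataset is refused before any file appears", {
  sim <- small_sim(seed = 1)
  g0 <- subset_genotypes(sim$genotypes, samples = integer(0))
  out <- file.path(withr::local_tempdir(), "empty")
  expect_error(
    write_dataset(g0, sim$phenotypes[0, ], NULL, out),
    "no individuals"
  )
  expect_false(file.exists(file.path(out, "genotypes.vcf")))
})
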