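#' Assemble and validate a pipeline configuration
#'
#' A configuration either names input files (`vcf`, `phenotypes`) or
#' carries a `simulate` block (a [sim_config()] or a list of its
#' arguments) - exactly one of the two. All remaining blocks have working
#' defaults.
#'
#' @param x A named list, a path to a YAML file with the same structure,
#'   or `NULL` for all defaults plus a `simulate` block.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(x = NULL) {
  if (is.character(x) && length(x) == 1L) x <- yaml::read_yaml(x)
  if (is.null(x)) x <- list(simulate = sim_config())
  defaults <- list(
    vcf = NULL, phenotypes = NULL, simulate = NULL,
    traits = NULL,
    qc = list(maf_min = 0.05, miss_max = 0.1, site_quality = NULL),
    fdr_scope = "genome",
    ci = list(window_bp = 3e6, r2_min = 0.4),
    hapshare = list(
      share_min_fraction = 0.05, r2_loci_min = 0.8,
      max_loci = 25L
    ),
    bootstrap = list(enabled = TRUE, B = 200L),
    plots = FALSE,
    seed = 1L
  )
  for (nm in names(defaults)) {
    if (is.null(x[[nm]])) {
      x[[nm]] <- defaults[[nm]]
    } else if (is.list(defaults[[nm]]) && is.list(x[[nm]]) &&
      !inherits(x[[nm]], "sim_config")) {
      miss <- setdiff(names(defaults[[nm]]), names(x[[nm]]))
      x[[nm]][miss] <- defaults[[nm]][miss]
    }
  }
  has_files <- !is.null(x$vcf) || !is.null(x$phenotypes)
  has_sim <- !is.null(x$simulate)
  if (has_files == has_sim) {
    stop("pipeline_config: exactly one of {vcf+phenotypes, simulate} ",
      "must be given",
      call. = FALSE
    )
  }
  if (has_files && (is.null(x$vcf) || is.null(x$phenotypes))) {
    stop("pipeline_config: both vcf and phenotypes paths are required",
      call. = FALSE
    )
  }
  if (has_sim && !inherits(x$simulate, "sim_config")) {
    x$simulate <- do.call(sim_config, x$simulate)
  }
  stopifnot(
    x$fdr_scope %in% c("genome", "chromosome"),
    x$qc$maf_min >= 0, x$qc$maf_min < 0.5,
    x$qc$miss_max > 0, x$qc$miss_max <= 1,
    x$ci$window_bp > 0, x$ci$r2_min >= 0, x$ci$r2_min <= 1,
    x$hapshare$share_min_fraction > 0, x$hapshare$share_min_fraction < 1,
    x$bootstrap$B >= 1
  )
  structure(x, class = "pipeline_config")
}

#' Bundled smoke-test configuration
#'
#' A small simulated design (166 individuals, 2,000 sites on two
#' chromosomes, one planted causal region for EP43w, 50 bootstrap
#' replicates) that runs the whole pipeline in seconds.
#'
#' @param seed Simulation seed.
#' @return A `pipeline_config`.
#' @export
smoke_config <- function(seed = 1L) {
  pipeline_config(list(
    simulate = sim_config(
      n_individuals = 166,
      chromosomes = data.frame(
        name = c("25", "29"), length_bp = c(10e6, 10e6),
        n_sites = c(1000, 1000)
      ),
      causal_loci = data.frame(
        chrom = "25", pos = 3219815L, trait = "EP43w",
        fraction_of_variance = 0.15
      ),
      seed = seed
    ),
    bootstrap = list(enabled = TRUE, B = 50L),
    seed = seed
  ))
}

run_stage <- function(name, out_dir, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    writeLines(
      paste0("stage: ", name, "\nerror: ", conditionMessage(e)),
      file.path(out_dir, "FAILED")
    )
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
      call. = FALSE
    )
  })
  message(sprintf(
    "[duckgwas] %-10s %6.2fs", name,
    proc.time()[["elapsed"]] - t0
  ))
  res
}

#' Run the full association pipeline
#'
#' Stages: simulate or read -> site QC -> kinship -> per-trait null REML
#' fit and Wald scan -> Bonferroni/FDR/inflation -> LD confidence interval
#' around each trait's top SNP -> haplotype sharing within the interval ->
#' bootstrap reliability of the interval. Every stage writes its artifact
#' under `out_dir` and the manifest records parameters and file checksums.
#'
#' @param config A [pipeline_config()] (or anything it accepts).
#' @param out_dir Output directory.
#' @return A list of class `result_bundle`: per-trait results plus
#'   `files` (named artifact paths) and `manifest`.
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline(smoke_config(seed = 1), tempfile("duckgwas"))
#' res$traits$EP43w$ci
#' }
run_pipeline <- function(config, out_dir) {
  config <- pipeline_config(if (inherits(config, "pipeline_config")) {
    unclass(config)
  } else {
    config
  })
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(out_dir, "FAILED"))
  files <- character(0)
  add_file <- function(label, path) {
    files[[label]] <<- path
    path
  }

  dat <- run_stage("data", out_dir, {
    if (!is.null(config$simulate)) {
      g <- simulate_genotypes(config$simulate)
      sim <- simulate_phenotypes(g, config$simulate)
      paths <- write_dataset(g, sim$phenotypes, sim$truth,
        out_dir = file.path(out_dir, "dataset")
      )
      for (nm in names(paths)) add_file(paste0("dataset_", nm), paths[[nm]])
      list(g = g, pheno = sim$phenotypes, truth = sim$truth)
    } else {
      list(
        g = read_vcf(config$vcf),
        pheno = read_phenotypes(config$phenotypes), truth = NULL
      )
    }
  })

  qc <- run_stage("qc", out_dir, {
    out <- filter_sites(dat$g,
      maf_min = config$qc$maf_min,
      miss_max = config$qc$miss_max,
      site_quality = config$qc$site_quality
    )
    write_qc_report(out$report, add_file(
      "qc_report",
      file.path(out_dir, "qc_report.tsv")
    ))
    out
  })
  g <- qc$genotypes

  pheno <- dat$pheno[match(g$sample_ids, dat$pheno$sample_id), ,
    drop = FALSE
  ]
  if (anyNA(pheno$sample_id)) {
    stop("run_pipeline: phenotype table lacks some genotyped samples",
      call. = FALSE
    )
  }

  k <- run_stage("kinship", out_dir, {
    kk <- compute_kinship(g)
    write_kinship(kk, add_file("kinship", file.path(out_dir, "kinship.tsv")))
    kk
  })

  traits <- config$traits
  if (is.null(traits)) traits <- setdiff(names(pheno), "sample_id")
  bonf <- bonferroni_threshold(nrow(g$sites))

  trait_res <- list()
  for (tr in traits) {
    y <- pheno[[tr]]
    ok <- !is.na(y)
    gt <- if (all(ok)) g else subset_genotypes(g, samples = which(ok))
    kt <- if (all(ok)) k else compute_kinship(gt)

    fit <- run_stage(paste0("null:", tr), out_dir, {
      suppressWarnings(fit_null_lmm(y[ok], kt))
    })
    assoc <- run_stage(paste0("scan:", tr), out_dir, {
      a <- wald_scan(y[ok], gt, kt, null_fit = fit)
      a <- add_qvalues(a, scope = config$fdr_scope)
      write_assoc(a, add_file(
        paste0("assoc_", tr),
        file.path(out_dir, paste0("assoc_", tr, ".tsv"))
      ))
      a
    })
    infl <- run_stage(paste0("inflation:", tr), out_dir, {
      ir <- inflation_qq(assoc$p_wald)
      jsonlite::write_json(
        list(trait = tr, lambda_gc = ir$lambda_gc, bonferroni = bonf),
        add_file(
          paste0("inflation_", tr),
          file.path(out_dir, paste0("inflation_", tr, ".json"))
        ),
        auto_unbox = TRUE, digits = NA
      )
      utils::write.table(ir$qq,
        add_file(
          paste0("qq_", tr),
          file.path(out_dir, paste0("qq_", tr, ".tsv"))
        ),
        sep = "\t", quote = FALSE, row.names = FALSE
      )
      ir
    })

    top_i <- which.min(assoc$p_wald)
    ci <- run_stage(paste0("ci:", tr), out_dir, {
      r <- suppressWarnings(delineate_ci(
        assoc[top_i, ], gt,
        assoc = assoc,
        window_bp = config$ci$window_bp, r2_min = config$ci$r2_min
      ))
      write_region_json(r, add_file(
        paste0("region_", tr),
        file.path(out_dir, paste0("region_", tr, ".json"))
      ))
      r
    })

    hap <- run_stage(paste0("hapshare:", tr), out_dir, {
      hapshare_stage(gt, y[ok], ci, config$hapshare,
        seed = config$seed,
        path = add_file(
          paste0("hapshare_", tr),
          file.path(out_dir, paste0("hapshare_", tr, ".json"))
        )
      )
    })

    boot <- NULL
    if (isTRUE(config$bootstrap$enabled)) {
      boot <- run_stage(paste0("bootstrap:", tr), out_dir, {
        in_reg <- assoc$chrom == ci$chrom & assoc$pos >= ci$start_bp &
          assoc$pos <= ci$end_bp
        sig <- in_reg & assoc$q_value < 0.05
        thr <- if (any(sig)) {
          max(assoc$p_wald[sig]) # largest p among the significant members
        } else {
          message(
            "[duckgwas] no FDR-significant sites in the ", tr,
            " interval; bootstrapping the region's top p-value instead"
          )
          min(assoc$p_wald[in_reg])
        }
        br <- bootstrap_gwas(gt, pheno[ok, , drop = FALSE], tr,
          region = ci, p_threshold = thr,
          B = config$bootstrap$B, seed = config$seed
        )
        write_bootstrap_report(br, add_file(
          paste0("bootstrap_", tr),
          file.path(out_dir, paste0("bootstrap_", tr, ".json"))
        ))
        br
      })
    }

    if (isTRUE(config$plots) && requireNamespace("ggplot2", quietly = TRUE)) {
      ggplot2::ggsave(
        file.path(out_dir, paste0("manhattan_", tr, ".png")),
        plot_manhattan(assoc, threshold = bonf),
        width = 8, height = 3, dpi = 150
      )
      ggplot2::ggsave(
        file.path(out_dir, paste0("qqplot_", tr, ".png")),
        plot_qq(infl),
        width = 4, height = 4, dpi = 150
      )
    }

    trait_res[[tr]] <- list(
      null_fit = fit, assoc = assoc, inflation = infl,
      ci = ci, hapshare = hap, bootstrap = boot
    )
  }

  manifest <- run_stage("manifest", out_dir, {
    mf <- list(
      package = "duckgwas",
      version = as.character(utils::packageVersion("duckgwas")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = config$seed,
      bonferroni_threshold = bonf,
      parameters = list(
        qc = config$qc, fdr_scope = config$fdr_scope, ci = config$ci,
        hapshare = config$hapshare,
        bootstrap = config$bootstrap[c("enabled", "B")]
      ),
      files = lapply(
        files[order(names(files))],
        function(p) {
          list(path = p, md5 = unname(tools::md5sum(p)))
        }
      )
    )
    path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(mf, path,
      auto_unbox = TRUE, digits = NA,
      pretty = TRUE
    )
    mf
  })
  files[["manifest"]] <- file.path(out_dir, "manifest.json")

  structure(list(
    traits = trait_res, truth = dat$truth, files = files,
    manifest = manifest, out_dir = out_dir
  ), class = "result_bundle")
}

# Haplotype-sharing stage: thin interval members to at most max_loci
# (preferring loci in strong LD with the top SNP), phase, group, and test
# every shared group against the chaotic one (falling back to the pooled
# remainder when the chaotic side is too small).
hapshare_stage <- function(g, y, ci, opts, seed, path) {
  names(y) <- g$sample_ids
  mem <- ci$members
  if (nrow(mem) > opts$max_loci) {
    strong <- mem[mem$r2 > opts$r2_loci_min, , drop = FALSE]
    if (nrow(strong) >= 2L) mem <- strong
    if (nrow(mem) > opts$max_loci) {
      mem <- mem[order(-mem$r2, mem$pos)[seq_len(opts$max_loci)], ,
        drop = FALSE
      ]
    }
  }
  loci <- data.frame(chrom = ci$chrom, pos = sort(mem$pos))
  haps <- phase_window(g, loci, seed = seed)
  grouping <- withCallingHandlers(
    group_haplotypes(haps, y,
      share_min_fraction = opts$share_min_fraction
    ),
    warning = function(w) invokeRestart("muffleWarning")
  )
  shared <- setdiff(grouping$groups$label, "chaotic")
  chaotic_n <- grouping$groups$n[grouping$groups$label == "chaotic"]
  vs_chaotic <- length(chaotic_n) == 1L && chaotic_n >= 2L
  comparisons <- list() # classic comparison: each shared group vs the chaotic pool
  scan <- list() # susceptibility scan: each shared group vs all the rest
  for (lab in shared) {
    if (vs_chaotic) {
      cmp <- tryCatch(compare_groups(grouping, a = lab),
        error = function(e) NULL
      )
      if (!is.null(cmp)) comparisons[[lab]] <- cmp
    }
    sc <- tryCatch(compare_groups(grouping, a = lab, b = "rest"),
      error = function(e) NULL
    )
    if (!is.null(sc)) scan[[lab]] <- sc
  }
  best_p <- if (length(scan)) {
    min(vapply(scan, function(x) x$p_value, numeric(1)))
  } else {
    NA_real_
  }
  out <- list(
    grouping = grouping, comparisons = comparisons, scan = scan,
    best_p = best_p
  )
  jsonlite::write_json(
    list(
      loci = loci, groups = grouping$groups,
      n_excluded = haps$n_excluded,
      vs_chaotic = lapply(comparisons, unclass),
      vs_rest = lapply(scan, unclass),
      best_p = best_p
    ),
    path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "columns"
  )
  out
}

#' @export
print.result_bundle <- function(x, ...) {
  cat("<result_bundle>", length(x$traits), "trait(s) in", x$out_dir, "\n")
  for (tr in names(x$traits)) {
    r <- x$traits[[tr]]
    top <- r$assoc[which.min(r$assoc$p_wald), ]
    cat(sprintf(
      "  %-6s pve=%.3f top=%s_%d p=%.3g lambda_gc=%.3f CI=%d-%d\n",
      tr, r$null_fit$pve, top$chrom, top$pos, top$p_wald,
      r$inflation$lambda_gc, r$ci$start_bp, r$ci$end_bp
    ))
  }
  invisible(x)
}
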