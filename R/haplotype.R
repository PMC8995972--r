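#' Collect or reconstruct haplotypes over a small window of loci
#'
#' For phased input this is a pass-through: each individual contributes
#' its two haplotype allele strings at the requested loci. For unphased
#' input, haplotype frequencies are estimated by an
#' Excoffier--Slatkin-style expectation--maximization over the multinomial
#' haplotype-pair likelihood, and each individual is assigned its
#' maximum-posterior compatible pair. Individuals with a missing genotype
#' at any window locus are excluded and counted.
#'
#' @param g A [genotype_matrix()].
#' @param loci Integer indices into `g$sites`, or a data frame with
#'   `chrom`/`pos`. At most 25 loci (EM feasibility cap; thin wide windows
#'   by LD first, see [delineate_ci()]).
#' @param seed Seed for the EM random restarts.
#' @param em_restarts Number of random restarts added to the deterministic
#'   uniform initialization (default 3).
#' @return An object of class `haplotype_set`: `strings` (allele strings,
#'   two per retained individual), `owner` (sample id per string), `loci`
#'   (site table), `n_excluded`, `excluded_ids`, `method` and, for EM,
#'   `frequencies`.
#' @export
phase_window <- function(g, loci, seed = 1L, em_restarts = 3L) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.data.frame(loci)) {
    idx <- match(
      paste(loci$chrom, loci$pos),
      paste(g$sites$chrom, g$sites$pos)
    )
    if (anyNA(idx)) {
      stop("phase_window: some loci not present in the panel", call. = FALSE)
    }
  } else {
    idx <- as.integer(loci)
  }
  L <- length(idx)
  if (L < 1L) stop("phase_window: no loci", call. = FALSE)
  if (L > 25L) {
    stop("phase_window: ", L, " loci exceed the 25-locus EM cap; thin the ",
      "window by LD to the top SNP first",
      call. = FALSE
    )
  }
  D <- g$dosage[, idx, drop = FALSE]
  complete <- rowSums(is.na(D)) == 0L
  excluded <- g$sample_ids[!complete]

  if (g$phased) {
    h1 <- g$haplotypes[[1]][complete, idx, drop = FALSE]
    h2 <- g$haplotypes[[2]][complete, idx, drop = FALSE]
    strings <- as.vector(rbind(
      apply(h1, 1L, paste, collapse = ""),
      apply(h2, 1L, paste, collapse = "")
    ))
    owner <- rep(g$sample_ids[complete], each = 2L)
    return(structure(list(
      strings = strings, owner = owner,
      loci = g$sites[idx, , drop = FALSE],
      n_excluded = sum(!complete), excluded_ids = excluded,
      method = "passthrough"
    ), class = "haplotype_set"))
  }

  D <- D[complete, , drop = FALSE]
  n <- nrow(D)
  if (n < 1L) stop("phase_window: no complete individuals", call. = FALSE)
  het_counts <- rowSums(D == 1L)
  if (max(het_counts) > 16L) {
    stop("phase_window: an individual is heterozygous at ",
      max(het_counts), " loci; enumeration infeasible - thin loci by LD",
      call. = FALSE
    )
  }

  bits <- 2L^(seq_len(L) - 1L)
  code_of <- function(alleles) sum(alleles * bits)
  string_of <- function(code) {
    paste(as.integer(bitwAnd(code, bits) > 0), collapse = "")
  }

  # enumerate compatible ordered-canonical haplotype pairs per individual
  pairs <- vector("list", n)
  for (i in seq_len(n)) {
    geno <- D[i, ]
    het <- which(geno == 1L)
    base <- ifelse(geno == 2L, 1L, 0L)
    if (length(het) == 0L) {
      cd <- code_of(base)
      pairs[[i]] <- cbind(a = cd, b = cd)
    } else {
      # fix the first het locus on haplotype a to halve the enumeration
      rest <- het[-1L]
      nassign <- 2L^length(rest)
      a <- matrix(base, nassign, L, byrow = TRUE)
      if (length(rest)) {
        grid <- as.matrix(expand.grid(rep(list(0:1), length(rest))))
        a[, rest] <- grid
      }
      a[, het[1L]] <- 1L
      b <- matrix(rep(geno, nassign), nassign, L, byrow = TRUE) - a
      pairs[[i]] <- cbind(
        a = as.vector(a %*% bits),
        b = as.vector(b %*% bits)
      )
    }
  }

  cand <- sort(unique(unlist(lapply(pairs, as.vector))))
  H <- length(cand)
  pa <- lapply(pairs, function(p) match(p[, 1], cand))
  pb <- lapply(pairs, function(p) match(p[, 2], cand))

  em_run <- function(f) {
    loglik <- -Inf
    for (it in seq_len(500L)) {
      counts <- numeric(H)
      ll <- 0
      for (i in seq_len(n)) {
        ia <- pa[[i]]
        ib <- pb[[i]]
        w <- f[ia] * f[ib] * ifelse(ia == ib, 1, 2)
        tot <- sum(w)
        if (tot <= 0) {
          w <- rep(1 / length(w), length(w))
          tot <- 1
        } else {
          ll <- ll + log(tot)
          w <- w / tot
        }
        counts[ia] <- counts[ia] + w
        counts[ib] <- counts[ib] + w
      }
      f <- counts / (2 * n)
      if (is.finite(loglik) && abs(ll - loglik) < 1e-8) {
        loglik <- ll
        break
      }
      loglik <- ll
    }
    list(f = f, loglik = loglik)
  }

  set.seed(seed)
  best <- em_run(rep(1 / H, H))
  for (r in seq_len(max(0L, em_restarts))) {
    init <- stats::rgamma(H, 1)
    fit <- em_run(init / sum(init))
    if (fit$loglik > best$loglik) best <- fit
  }
  f <- best$f

  strings <- character(2L * n)
  for (i in seq_len(n)) {
    ia <- pa[[i]]
    ib <- pb[[i]]
    w <- f[ia] * f[ib] * ifelse(ia == ib, 1, 2)
    j <- which.max(w)
    strings[2L * i - 1L] <- string_of(cand[ia[j]])
    strings[2L * i] <- string_of(cand[ib[j]])
  }
  freq <- f
  names(freq) <- vapply(cand, string_of, character(1))

  structure(list(
    strings = strings,
    owner = rep(g$sample_ids[complete], each = 2L),
    loci = g$sites[idx, , drop = FALSE],
    n_excluded = sum(!complete), excluded_ids = excluded,
    method = "em", frequencies = freq,
    loglik = best$loglik
  ), class = "haplotype_set")
}

#' Partition haplotype sequences into shared and chaotic groups
#'
#' Identical allele strings are collapsed; strings carried by at least
#' `share_min_fraction` of all sequences become named shared groups
#' (`haplotype 1`, `haplotype 2`, ... in decreasing frequency), everything
#' rarer is pooled into one `chaotic` group. Each sequence carries its
#' owner's phenotype, so an individual homozygous for a shared haplotype
#' contributes its phenotype twice to that group's mean.
#'
#' @param haps A [phase_window()] result (>= 4 sequences).
#' @param phenotype Named numeric vector of trait values, names = sample
#'   ids; sequences whose owner has a missing phenotype are dropped from
#'   the grouping.
#' @param share_min_fraction Minimum frequency for a haplotype to count as
#'   shared (default 0.05).
#' @return An object of class `haplotype_grouping`: `groups` (data frame
#'   `label`, `string`, `n`, `pheno_mean`), `assignment` (label per
#'   sequence), `strings`, `owner`, `pheno` and bookkeeping fields.
#' @export
group_haplotypes <- function(haps, phenotype, share_min_fraction = 0.05) {
  stopifnot(inherits(haps, "haplotype_set"))
  pheno <- phenotype[haps$owner]
  ok <- !is.na(pheno)
  strings <- haps$strings[ok]
  owner <- haps$owner[ok]
  pheno <- as.numeric(pheno[ok])
  total <- length(strings)
  if (total < 4L) {
    stop("group_haplotypes: need at least 4 sequences", call. = FALSE)
  }

  tab <- table(strings)
  tab <- tab[order(-tab, names(tab))] # count desc, string for ties
  shared <- names(tab)[as.vector(tab) >= share_min_fraction * total]
  if (length(shared) == 0L) {
    warning("group_haplotypes: no haplotype reaches the sharing threshold; ",
      "everything is chaotic and no group test is possible",
      call. = FALSE
    )
  }

  assignment <- rep("chaotic", total)
  labels <- character(0)
  rows <- list()
  for (i in seq_along(shared)) {
    lab <- paste("haplotype", i)
    labels <- c(labels, lab)
    hit <- strings == shared[i]
    assignment[hit] <- lab
    rows[[lab]] <- data.frame(
      label = lab, string = shared[i], n = sum(hit),
      pheno_mean = mean(pheno[hit]), stringsAsFactors = FALSE
    )
  }
  n_chaotic <- sum(assignment == "chaotic")
  if (n_chaotic > 0L) {
    rows[["chaotic"]] <- data.frame(
      label = "chaotic", string = NA_character_, n = n_chaotic,
      pheno_mean = mean(pheno[assignment == "chaotic"]),
      stringsAsFactors = FALSE
    )
  }
  groups <- do.call(rbind, rows)
  rownames(groups) <- NULL

  structure(list(
    groups = groups, assignment = assignment,
    strings = strings, owner = owner, pheno = pheno,
    share_min_fraction = share_min_fraction,
    n_sequences = total,
    loci = haps$loci
  ), class = "haplotype_grouping")
}

#' @export
print.haplotype_grouping <- function(x, ...) {
  cat(
    "<haplotype_grouping>", x$n_sequences, "sequences over",
    nrow(x$loci), "loci\n"
  )
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Test a phenotype difference between haplotype groups
#'
#' Two-sample t test of owner phenotypes between group A (one shared
#' haplotype, or several merged) and group B (default the chaotic group).
#' Welch's unequal-variance test is the default; `pooled = TRUE` gives the
#' classical equal-variance variant.
#'
#' @param grouping A [group_haplotypes()] result.
#' @param a Character vector of group labels forming side A; default the
#'   most frequent shared haplotype.
#' @param b Label(s) for side B (default `"chaotic"`), or `"rest"` for
#'   every sequence not on side A.
#' @param pooled Use the pooled-variance t test? Default `FALSE` (Welch).
#' @return An object of class `group_comparison`: labels, per-side n and
#'   means, `t`, `df`, `p_value`, `variant`.
#' @export
compare_groups <- function(grouping, a = NULL, b = "chaotic",
                           pooled = FALSE) {
  stopifnot(inherits(grouping, "haplotype_grouping"))
  labs <- grouping$groups$label
  if (is.null(a)) a <- labs[labs != "chaotic"][1]
  rest <- identical(b, "rest")
  check <- if (rest) a else c(a, b)
  if (any(!check %in% labs)) {
    stop("compare_groups: unknown group label(s): ",
      paste(setdiff(check, labs), collapse = ", "),
      call. = FALSE
    )
  }
  xa <- grouping$pheno[grouping$assignment %in% a]
  xb <- if (rest) {
    grouping$pheno[!grouping$assignment %in% a]
  } else {
    grouping$pheno[grouping$assignment %in% b]
  }
  if (length(xa) < 2L || length(xb) < 2L) {
    stop("compare_groups: both sides need at least 2 sequences",
      call. = FALSE
    )
  }
  if (stats::sd(xa) < 1e-12 && stats::sd(xb) < 1e-12) {
    stop("compare_groups: zero variance on both sides; t test undefined",
      call. = FALSE
    )
  }
  ht <- stats::t.test(xa, xb, var.equal = pooled)
  structure(list(
    a = a, b = b,
    n_a = length(xa), n_b = length(xb),
    mean_a = mean(xa), mean_b = mean(xb),
    t = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value,
    variant = if (pooled) "pooled" else "welch"
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(
    "<group_comparison>", paste(x$a, collapse = "+"), "vs", x$b,
    sprintf("(%s t test)\n", x$variant)
  )
  cat(sprintf(
    "  n = %d vs %d; means %.4g vs %.4g\n",
    x$n_a, x$n_b, x$mean_a, x$mean_b
  ))
  cat(sprintf(
    "  t = %.4g on %.4g df, p = %.4g\n", x$t, x$df, x$p_value
  ))
  invisible(x)
}

#' @rdname group_haplotypes
#' @param grouping A `haplotype_grouping`.
#' @param path Output TSV path.
#' @export
write_grouping <- function(grouping, path) {
  utils::write.table(grouping$groups, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(path)
}
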