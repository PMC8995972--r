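make_hapset <- function(strings, owner, loci = NULL) {
  structure(list(
    strings = strings, owner = owner,
    loci = if (is.null(loci)) {
      data.frame(chrom = "1", pos = 1000L, ref = "A", alt = "C")
    } else {
      loci
    },
    n_excluded = 0L, excluded_ids = character(0), method = "passthrough"
  ), class = "haplotype_set")
}

test_that("phased input passes through unchanged", {
  sim <- small_sim(seed = 1)
  g <- sim$genotypes
  loci <- 1:5
  hs <- phase_window(g, loci)
  expect_equal(hs$method, "passthrough")
  expect_equal(length(hs$strings), 2L * length(g$sample_ids))
  h1 <- apply(g$haplotypes$hap1[, loci], 1L, paste, collapse = "")
  expect_equal(hs$strings[seq(1, length(hs$strings), 2)], unname(h1))
})

test_that("a fully homozygous individual phases uniquely", {
  d <- rbind(
    c(0L, 2L, 0L, 2L),
    c(1L, 1L, 0L, 2L),
    c(0L, 2L, 0L, 2L),
    c(2L, 0L, 2L, 0L)
  )
  g <- toy_panel(d)
  hs <- phase_window(g, 1:4)
  expect_equal(hs$method, "em")
  expect_equal(hs$strings[1], "0101") # deterministic: no het locus
  expect_equal(hs$strings[2], "0101")
  expect_equal(hs$strings[7], "1010")
})

test_that("EM recovers truth-known haplotype frequencies and phases double hets", {
  set.seed(77)
  n <- 40
  pool <- c("11", "00")
  draw <- matrix(sample(pool, 2 * n, replace = TRUE, prob = c(0.7, 0.3)), n, 2)
  h1 <- t(sapply(strsplit(draw[, 1], ""), as.integer))
  h2 <- t(sapply(strsplit(draw[, 2], ""), as.integer))
  g <- toy_panel(h1 + h2)
  hs <- phase_window(g, 1:2, seed = 5)
  truth_freq <- c(mean(draw == "11"), mean(draw == "00"))
  expect_lt(abs(hs$frequencies["11"] - truth_freq[1]), 0.05)
  expect_lt(abs(hs$frequencies["00"] - truth_freq[2]), 0.05)
  # double heterozygotes resolved as 11|00, never 10|01
  dh <- which(h1[, 1] + h2[, 1] == 1 & h1[, 2] + h2[, 2] == 1)
  for (i in dh) {
    pair <- sort(hs$strings[c(2 * i - 1, 2 * i)])
    expect_equal(pair, c("00", "11"))
  }
})

test_that("individuals with missing window genotypes are excluded and counted", {
  sim <- small_sim(seed = 2)
  g <- sim$genotypes
  g$dosage[3, 2] <- NA
  g$haplotypes$hap1[3, 2] <- NA
  g$haplotypes$hap2[3, 2] <- NA
  hs <- phase_window(g, 1:4)
  expect_equal(hs$n_excluded, 1L)
  expect_equal(hs$excluded_ids, g$sample_ids[3])
  expect_equal(length(hs$strings), 2L * (length(g$sample_ids) - 1L))
})

test_that("windows beyond the locus cap are refused with thinning advice", {
  sim <- small_sim(seed = 2)
  expect_error(phase_window(sim$genotypes, 1:26), "25-locus")
})

test_that("grouping partitions sequences and recovers truth-known means", {
  set.seed(15)
  shared_ph <- rnorm(60, 100, 3)
  single_ph <- rnorm(40, 110, 3)
  strings <- c(rep("1100", 60), sprintf("%04d", 1:40)) # 40 distinct rares
  owner <- sprintf("o%03d", 1:100)
  pheno <- c(shared_ph, single_ph)
  names(pheno) <- owner
  gr <- group_haplotypes(make_hapset(strings, owner), pheno)
  expect_equal(sum(gr$groups$n), 100L) # partition
  h1 <- gr$groups[gr$groups$label == "haplotype 1", ]
  ch <- gr$groups[gr$groups$label == "chaotic", ]
  expect_equal(h1$n, 60L)
  expect_equal(ch$n, 40L)
  expect_equal(h1$pheno_mean, mean(shared_ph))
  expect_equal(ch$pheno_mean, mean(single_ph))
  expect_lt(abs(h1$pheno_mean - 100), 2)
  expect_lt(abs(ch$pheno_mean - 110), 2)
})

test_that("identical sequences give one shared group and no chaotic row", {
  pheno <- setNames(rnorm(10, 50), sprintf("o%d", 1:10))
  gr <- group_haplotypes(
    make_hapset(rep("101", 20), rep(sprintf("o%d", 1:10), each = 2)),
    pheno
  )
  expect_equal(nrow(gr$groups), 1L)
  expect_equal(gr$groups$n, 20L)
  expect_false("chaotic" %in% gr$groups$label)
})

test_that("all-unique sequences collapse to one chaotic group with a warning", {
  pheno <- setNames(rnorm(8), sprintf("o%d", 1:8))
  expect_warning(
    gr <- group_haplotypes(
      make_hapset(sprintf("%03d", 1:8), sprintf("o%d", 1:8)),
      pheno, share_min_fraction = 0.3
    ),
    "chaotic"
  )
  expect_equal(gr$groups$label, "chaotic")
  expect_equal(gr$groups$n, 8L)
})

test_that("lowering the sharing threshold never loses shared groups", {
  set.seed(8)
  strings <- sample(c("00", "01", "10", "11"), 200,
    replace = TRUE,
    prob = c(0.5, 0.3, 0.15, 0.05)
  )
  owner <- sprintf("o%03d", 1:200)
  pheno <- setNames(rnorm(200), owner)
  hapset <- make_hapset(strings, owner)
  counts <- vapply(c(0.4, 0.2, 0.1, 0.04), function(f) {
    gr <- suppressWarnings(group_haplotypes(hapset, pheno,
      share_min_fraction = f
    ))
    sum(gr$groups$label != "chaotic")
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("the Welch comparison matches the closed form and is symmetric", {
  strings <- c(rep("11", 3), rep("00", 3))
  owner <- sprintf("o%d", 1:6)
  pheno <- setNames(c(10, 11, 12, 20, 21, 22), owner)
  gr <- suppressWarnings(
    group_haplotypes(make_hapset(strings, owner), pheno,
      share_min_fraction = 0.4
    )
  )
  lab_lo <- gr$groups$label[gr$groups$string == "11"]
  lab_hi <- gr$groups$label[gr$groups$string == "00"]
  cmp <- compare_groups(gr, a = lab_lo, b = lab_hi)
  # closed-form Welch on (10,11,12) vs (20,21,22)
  se <- sqrt(1 / 3 + 1 / 3)
  t_hand <- (11 - 21) / se
  df_hand <- (1 / 3 + 1 / 3)^2 / ((1 / 3)^2 / 2 + (1 / 3)^2 / 2)
  p_hand <- 2 * pt(-abs(t_hand), df_hand)
  expect_equal(cmp$t, t_hand, tolerance = 1e-10)
  expect_equal(cmp$df, df_hand, tolerance = 1e-10)
  expect_equal(cmp$p_value, p_hand, tolerance = 1e-10)
  rev <- compare_groups(gr, a = lab_hi, b = lab_lo)
  expect_equal(rev$p_value, cmp$p_value, tolerance = 1e-12)
  expect_equal(rev$t, -cmp$t, tolerance = 1e-12)
})

test_that("merged groups pool their sequences for the test", {
  strings <- c(rep("11", 10), rep("10", 10), rep("00", 10))
  owner <- sprintf("o%02d", 1:30)
  set.seed(44)
  pheno <- setNames(c(rnorm(20, 5), rnorm(10, 9)), owner)
  gr <- group_haplotypes(make_hapset(strings, owner), pheno,
    share_min_fraction = 0.2
  )
  lab_of <- function(str) gr$groups$label[gr$groups$string == str]
  merged <- compare_groups(gr,
    a = c(lab_of("11"), lab_of("10")),
    b = lab_of("00")
  )
  expect_equal(merged$n_a, 20L)
  oracle <- t.test(pheno[1:20], pheno[21:30])
  expect_equal(merged$p_value, oracle$p.value, tolerance = 1e-12)
})

test_that("degenerate comparisons are refused", {
  strings <- c(rep("11", 4), rep("00", 4))
  owner <- sprintf("o%d", 1:8)
  pheno <- setNames(rep(5, 8), owner)
  gr <- group_haplotypes(make_hapset(strings, owner), pheno,
    share_min_fraction = 0.3
  )
  expect_error(
    compare_groups(gr, a = "haplotype 1", b = "rest"),
    "zero variance"
  )
  expect_error(compare_groups(gr, a = "nope"), "unknown")
})
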