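test_that("window tiling follows the 50-kb/25-kb sliding rule", {
  cfg <- scan_config()
  w <- make_windows(c(chr1 = 100000), cfg)
  expect_equal(w$start, c(0L, 25000L, 50000L, 75000L))
  expect_equal(w$end, c(50000L, 75000L, 100000L, 100000L))  # terminal truncated
  w2 <- make_windows(c(chr1 = 50000), cfg)
  expect_equal(nrow(w2), 2)
  expect_equal(w2$start, c(0L, 25000L))
  # chromosome shorter than the step -> one window covering it all
  w3 <- make_windows(c(chr1 = 10000), cfg)
  expect_equal(nrow(w3), 1)
  expect_equal(c(w3$start, w3$end), c(0L, 10000L))
  # deterministic (chrom, start) ordering
  w4 <- make_windows(c(chr2 = 60000, chr1 = 60000), cfg)
  expect_equal(w4$chrom, rep(c("chr1", "chr2"), each = 3))
})

test_that("site-to-window assignment respects half-open boundaries", {
  g <- genotype_matrix(
    data.frame(chrom = "chr1", pos = c(25000L, 25001L), ref = "A", alt = "C"),
    c("s1", "s2"), matrix(0L, 2, 2))
  w <- make_windows(c(chr1 = 100000), scan_config())
  a <- assign_sites(g, w)
  # 1-based 25,000 (0-based 24,999) -> window [0, 50k) only
  expect_equal(a$window[a$site == 1], 1)
  # 1-based 25,001 (0-based 25,000) -> windows [0, 50k) and [25k, 75k)
  expect_equal(sort(a$window[a$site == 2]), c(1, 2))
  g2 <- genotype_matrix(
    data.frame(chrom = "chrX", pos = 5L, ref = "A", alt = "C"),
    c("s1"), matrix(0L, 1, 1))
  expect_error(assign_sites(g2, w), "chrX")
})

test_that("assignment counts match a brute-force interval-membership oracle", {
  g <- make_test_matrix(n_sites = 200, n_samples = 4, seed = 13,
                        chrom_len = 2e5)
  w <- make_windows(c(chr1 = 2e5, chr2 = 2e5), scan_config())
  a <- assign_sites(g, w)
  for (i in seq_len(nrow(g$variants))) {
    p0 <- g$variants$pos[i] - 1L
    expected <- which(w$chrom == g$variants$chrom[i] &
                        w$start <= p0 & p0 < w$end)
    expect_equal(sort(a$window[a$site == i]), expected)
  }
  # with step = span/2, interior sites fall in exactly two windows
  interior <- g$variants$pos - 1L >= 25000
  counts <- table(factor(a$site, levels = seq_len(nrow(g$variants))))
  expect_true(all(counts[interior] == 2))
})

test_that("top-quantile rule keeps ties and uses the type-7 cutoff", {
  cut <- quantile_threshold(1:100, 0.05)
  expect_equal(cut, 95.05)
  expect_equal(which(1:100 >= cut), 96:100)
  # degenerate all-equal values: everything ties at the cutoff and is kept
  vals <- rep(3.2, 40)
  expect_equal(sum(vals >= quantile_threshold(vals, 0.05)), 40)
  expect_error(quantile_threshold(numeric(), 0.05), "no values")
  expect_error(quantile_threshold(c(1, NA), 0.05), "non-finite")
  # continuous values: flagged fraction within 1/N of the nominal q
  set.seed(8)
  v <- rnorm(1000)
  fr <- mean(v >= quantile_threshold(v, 0.05))
  expect_gte(fr, 0.05 - 1 / 1000)
  expect_lte(fr, 0.05 + 1 / 1000)
})

test_that("candidates are the intersection of the two outlier tails", {
  set.seed(9)
  n <- 200
  w <- data.frame(chrom = "chr1", start = (seq_len(n) - 1) * 25000,
                  end = (seq_len(n) - 1) * 25000 + 50000,
                  n_sites = 10L, fst = rnorm(n),
                  diversity_score = rnorm(n), pi_target = runif(n))
  # force one window into the top F_ST tail but keep its score at the median
  w$fst[1] <- max(w$fst) + 10
  w$diversity_score[1] <- stats::median(w$diversity_score)
  f <- flag_candidates(w, scan_config())
  expect_true(f$fst_outlier[1])
  expect_false(f$candidate[1])
  expect_true(all(f$candidate == (f$fst_outlier & f$pi_outlier)))
  expect_lte(mean(f$candidate), mean(f$fst_outlier))
  expect_lte(mean(f$candidate), mean(f$pi_outlier))
  # sparse windows are excluded from the distributions and never flagged
  w$n_sites[2] <- 1L
  f2 <- flag_candidates(w, scan_config())
  expect_false(f2$usable[2])
  expect_false(f2$fst_outlier[2] || f2$pi_outlier[2])
})

test_that("overlapping and book-ended candidate windows merge into maximal regions", {
  w <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                  start = c(0L, 25000L, 0L), end = c(50000L, 75000L, 50000L),
                  n_sites = 10L, fst = c(0.5, 0.6, 0.4),
                  diversity_score = 5, pi_target = c(1e-5, 2e-5, 3e-5),
                  usable = TRUE, fst_outlier = TRUE, pi_outlier = TRUE,
                  candidate = TRUE)
  r <- merge_regions(w)
  expect_equal(nrow(r), 2)           # different chromosomes never merge
  expect_equal(r$start[r$chrom == "chr1"], 0L)
  expect_equal(r$end[r$chrom == "chr1"], 75000L)
  expect_equal(r$max_fst[r$chrom == "chr1"], 0.6)
  expect_equal(r$min_pi_target[r$chrom == "chr1"], 1e-5)
  expect_equal(r$n_windows, c(2L, 1L))
  # no candidates -> zero-row table
  w$candidate <- FALSE
  expect_equal(nrow(merge_regions(w)), 0)
})

test_that("region merging equals a union-of-intervals oracle on random flags", {
  set.seed(14)
  for (rep_i in 1:5) {
    n <- 80
    w <- data.frame(chrom = "chr1", start = (seq_len(n) - 1) * 25000,
                    end = (seq_len(n) - 1) * 25000 + 50000,
                    n_sites = 5L, fst = 0.1, diversity_score = 1,
                    pi_target = 1e-4, usable = TRUE,
                    fst_outlier = TRUE, pi_outlier = TRUE,
                    candidate = runif(n) < 0.15)
    if (!any(w$candidate)) next
    r <- merge_regions(w)
    o <- union_intervals_oracle(w$start[w$candidate], w$end[w$candidate])
    expect_equal(r$start, o$start)
    expect_equal(r$end, o$end)
  }
})

test_that("the scan is deterministic for identical input and config", {
  sim <- simulate_dataset(sim_config(seed = 17, n_snps = 800,
                                     chrom_lengths = c(chr1 = 1e6),
                                     sweeps = default_sweeps()[1:2, ]))
  s1 <- scan_selection(sim$genotypes, sim$sample_map, "NJ",
                       sim$config$chrom_lengths)
  s2 <- scan_selection(sim$genotypes, sim$sample_map, "NJ",
                       sim$config$chrom_lengths)
  expect_identical(s1$windows, s2$windows)
  expect_identical(s1$regions, s2$regions)
  # candidate windows satisfy the structural invariant
  expect_true(all(!s1$windows$candidate |
                    (s1$windows$fst_outlier & s1$windows$pi_outlier)))
})
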