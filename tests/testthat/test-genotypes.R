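test_that("read_vcf drops multi-allelic records and honours missing-call conventions", {
  vcf <- write_toy_vcf(withr::local_tempfile(fileext = ".vcf"))
  expect_warning(
    expect_message(g <- read_vcf(vcf), "multi-allelic"),
    "half-call")
  expect_equal(nrow(g$variants), 2)           # tri-allelic site dropped
  expect_equal(g$variants$pos, c(100L, 300L))
  expect_equal(unname(g$gt[1, ]), c(0L, 1L, 2L))
  # "./." missing, "0/." half-call -> NA, phased "1|1" -> 2
  expect_equal(unname(g$gt[2, ]), c(NA_integer_, NA_integer_, 2L))
})

test_that("read_vcf validates inputs", {
  vcf <- write_toy_vcf(withr::local_tempfile(fileext = ".vcf"))
  expect_error(read_vcf("no/such/file.vcf"), "not found")
  expect_error(suppressWarnings(suppressMessages(
    read_vcf(vcf, keep_samples = c("S1", "SX")))), "SX")
  only_indel <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
               "chr1\t5\t.\tAT\tA\t.\t.\t.\tGT\t0/1"), only_indel)
  expect_error(suppressMessages(read_vcf(only_indel)), "no biallelic")
})

test_that("VCF round-trip preserves variants and every dosage cell", {
  g <- make_test_matrix(n_sites = 1000, n_samples = 12, seed = 7,
                        chrom_len = 5e5)
  path <- withr::local_tempfile(fileext = ".vcf.gz")
  write_vcf(g, path, chrom_lengths = c(chr1 = 5e5, chr2 = 5e5))
  g2 <- read_vcf(path)
  expect_equal(g2$variants, g$variants)
  expect_equal(g2$samples, g$samples)
  expect_identical(g2$gt, g$gt)
})

test_that("the seven-population sample map fixture matches the sampling design", {
  map <- read_sample_map(system.file("extdata", "camel_sample_map.tsv",
                                     package = "sweepscan"))
  expect_s3_class(map, "sample_map")
  expect_equal(nrow(map), 47)
  counts <- table(map$population)
  expect_equal(length(counts), 7)
  expect_equal(as.integer(counts[c("NJ", "BJ", "DJ", "HX", "QH", "ALS", "SNT")]),
               c(7L, 7L, 7L, 5L, 7L, 7L, 7L))
})

test_that("sample map validation catches duplicates and undersized populations", {
  expect_error(sample_map(c("a", "a", "b"), c("P", "P", "P")), "duplicate")
  expect_error(sample_map(c("a", "b", "c"), c("P", "P", "Q")), "fewer than 2")
  # single population is fine; the reference pool is built later
  expect_s3_class(sample_map(c("a", "b"), c("P", "P")), "sample_map")
})

test_that("allele_stats counts alleles, MAF and missingness by hand-checkable rules", {
  gt <- rbind(c(0L, 1L, 1L, 2L),
              c(NA, NA, NA, NA),
              c(0L, 0L, 0L, 0L),
              c(2L, NA, 1L, 0L))
  g <- genotype_matrix(
    data.frame(chrom = "chr1", pos = c(10L, 20L, 30L, 40L),
               ref = "A", alt = "C"),
    c("s1", "s2", "s3", "s4"), gt)
  st <- allele_stats(g)
  expect_equal(st$n, c(8L, 0L, 8L, 6L))
  expect_equal(st$p[1], 0.5)
  expect_equal(st$maf[1], 0.5)
  expect_equal(st$missing_fraction, c(0, 1, 0, 0.25))
  expect_equal(st$maf[2], 0)   # all missing -> maf reported as 0
  expect_equal(st$maf[3], 0)   # monomorphic
  expect_error(allele_stats(g, character()), "empty")
  expect_error(allele_stats(g, "nope"), "nope")
  # invariants: maf <= 0.5 and missing in [0, 1] on a random matrix
  st2 <- allele_stats(make_test_matrix(200, 10, seed = 3))
  expect_true(all(st2$maf <= 0.5 + 1e-12))
  expect_true(all(st2$missing_fraction >= 0 & st2$missing_fraction <= 1))
})

test_that("variant filter applies strict boundaries on MAF and missingness", {
  # 20 samples fully called, alt_count 2 -> p = 2/40 = 0.05 exactly
  gt <- matrix(0L, nrow = 2, ncol = 20)
  gt[1, 1] <- 2L                      # maf exactly 0.05 -> dropped
  gt[2, 1:8] <- 1L                    # maf 0.2, missing 0 -> kept
  g <- genotype_matrix(
    data.frame(chrom = "chr1", pos = c(1L, 2L), ref = "A", alt = "C"),
    sprintf("s%02d", 1:20), gt)
  gf <- suppressMessages(filter_variants(g))
  expect_equal(gf$variants$pos, 2L)

  # 4 samples, 1 missing -> missing_fraction exactly 0.25 -> dropped
  gt2 <- rbind(c(NA, 1L, 1L, 0L),   # missing 0.25
               c(1L, 1L, 0L, 0L))   # kept
  g2 <- genotype_matrix(
    data.frame(chrom = "chr1", pos = c(1L, 2L), ref = "A", alt = "C"),
    c("a", "b", "c", "d"), gt2)
  gf2 <- suppressMessages(filter_variants(g2))
  expect_equal(gf2$variants$pos, 2L)
})

test_that("variant filter matches a per-site predicate oracle and is idempotent", {
  g <- make_test_matrix(n_sites = 300, n_samples = 20, seed = 11,
                        missing_rate = 0.2)
  cfg <- filter_config()
  gf <- suppressMessages(filter_variants(g, cfg))
  # independent re-evaluation of both predicates, site by site
  keep <- logical(nrow(g$variants))
  for (i in seq_len(nrow(g$variants))) {
    d <- g$gt[i, ]
    called <- sum(!is.na(d))
    p <- if (called > 0) sum(d, na.rm = TRUE) / (2 * called) else 0
    maf <- min(p, 1 - p)
    miss <- mean(is.na(d))
    keep[i] <- (maf > cfg$maf_min) && (miss < cfg$missing_max)
  }
  expect_equal(gf$variants, g$variants[keep, , drop = FALSE],
               ignore_attr = TRUE)
  gff <- suppressMessages(filter_variants(gf, cfg))
  expect_identical(gff$gt, gf$gt)
  expect_identical(gff$variants, gf$variants)
})

test_that("pool_reference partitions the cohort into target and remaining pool", {
  map <- read_sample_map(system.file("extdata", "camel_sample_map.tsv",
                                     package = "sweepscan"))
  p <- pool_reference(map, "NJ")
  expect_length(p$target, 7)
  expect_length(p$reference, 40)
  expect_length(intersect(p$target, p$reference), 0)
  expect_setequal(c(p$target, p$reference), map$sample_id)

  two <- sample_map(c("a", "b", "c", "d"), c("A", "A", "B", "B"))
  expect_equal(pool_reference(two, "A")$reference, c("c", "d"))
  expect_error(pool_reference(map, "XX"), "NJ")   # error lists known codes
  one <- sample_map(c("a", "b"), c("A", "A"))
  expect_error(pool_reference(one, "A"), "non-target")
})
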