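# Independent oracles, deliberately coded differently from the package:
# scalar loops and direct textbook transcriptions, never calls into the
# code paths they check.

# Mean pairwise difference among a vector of 0/1 alleles, by exhaustive
# enumeration of all unordered pairs.
pi_pair_oracle <- function(alleles) {
  n <- length(alleles)
  if (n < 2) return(0)
  diff_pairs <- 0L
  total <- 0L
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      total <- total + 1L
      if (alleles[i] != alleles[j]) diff_pairs <- diff_pairs + 1L
    }
  }
  diff_pairs / total
}

# Weir & Cockerham (1984) variance components for one biallelic site and
# two samples of diploid dosages; scalar transcription of the published
# formulas with r = 2.
wc_site_oracle <- function(dos1, dos2) {
  pops <- list(dos1[!is.na(dos1)], dos2[!is.na(dos2)])
  n <- vapply(pops, length, 0L)
  if (any(n < 1)) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  p <- vapply(pops, function(d) sum(d) / (2 * length(d)), 0)
  h <- vapply(pops, function(d) mean(d == 1L), 0)
  r <- 2
  nbar <- mean(n)
  if (nbar <= 1) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  CV2 <- sum((n - nbar)^2) / ((r - 1) * nbar^2)  # squared CV of sample sizes
  nc <- nbar * (1 - CV2 / r)
  pbar <- sum(n * p) / sum(n)
  ssq <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / sum(n)
  a <- (nbar / nc) * (ssq - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * ssq - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * ssq -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cv <- hbar / 2
  c(a = a, b = b, c = cv)
}

# Union of half-open integer intervals by sweep over sorted endpoints,
# merging overlapping or book-ended pieces.
union_intervals_oracle <- function(starts, ends) {
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  out_s <- starts[1]; out_e <- ends[1]
  res_s <- c(); res_e <- c()
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= out_e) {        # overlap or book-ended
      out_e <- max(out_e, ends[i])
    } else {
      res_s <- c(res_s, out_s); res_e <- c(res_e, out_e)
      out_s <- starts[i]; out_e <- ends[i]
    }
  }
  data.frame(start = c(res_s, out_s), end = c(res_e, out_e))
}

# Small random genotype matrix for structural tests.
make_test_matrix <- function(n_sites = 50, n_samples = 8, seed = 99,
                             chroms = c("chr1", "chr2"),
                             chrom_len = 1e5, missing_rate = 0.1) {
  set.seed(seed)
  chrom <- sort(sample(chroms, n_sites, replace = TRUE))
  pos <- unlist(lapply(unique(chrom), function(ch)
    sort(sample.int(chrom_len, sum(chrom == ch)))))
  gt <- matrix(rbinom(n_sites * n_samples, 2, runif(n_sites, 0.05, 0.95)),
               nrow = n_sites)
  gt[runif(length(gt)) < missing_rate] <- NA
  genotype_matrix(
    data.frame(chrom = chrom, pos = pos, ref = "A", alt = "G",
               stringsAsFactors = FALSE),
    sprintf("s%02d", seq_len(n_samples)), gt)
}

# A tiny hand-written VCF exercising multi-allelic, missing and half-call
# records.
write_toy_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "chr1\t100\t.\tA\tG\t.\t.\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t200\t.\tC\tG,T\t.\t.\t.\tGT\t0/0\t0/1\t0/2",
    "chr1\t300\t.\tT\tA\t.\t.\t.\tGT\t./.\t0/.\t1|1"),
    path)
  path
}
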