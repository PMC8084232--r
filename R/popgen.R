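#' Per-site Nei's nucleotide diversity
#'
#' Unbiased pairwise-difference estimator at a biallelic site:
#' `pi = 2 k (n - k) / (n (n - 1))` where `k` is the alt-allele count among
#' `n` called alleles — the fraction of the `n(n-1)/2` allele pairs that
#' differ. Returns 0 for monomorphic sites and for sites with fewer than two
#' called alleles. Vectorised over sites.
#'
#' @param alt_count alt-allele count(s), `0 <= alt_count <= n`.
#' @param n called allele count(s) (2 x called diploid genotypes).
#' @return numeric vector of per-site diversity values.
#' @export
site_pi <- function(alt_count, n) {
  if (any(alt_count < 0) || any(alt_count > n))
    stop("alt_count must lie in [0, n]")
  len <- max(length(alt_count), length(n))
  k <- rep_len(alt_count, len)
  nn <- rep_len(n, len)
  out <- numeric(len)
  ok <- nn >= 2
  out[ok] <- 2 * k[ok] * (nn[ok] - k[ok]) / (nn[ok] * (nn[ok] - 1))
  out
}

#' Window nucleotide diversity per base pair
#'
#' Sums per-site diversity over the sites falling in a window and divides by
#' the window span in bp, so unobserved and monomorphic positions contribute
#' zero — the convention of VCFtools' windowed-pi output.
#'
#' @param pi_sites per-site diversity values of the sites in the window.
#' @param window_span window width in bp (> 0); for a truncated terminal
#'   window pass its actual width.
#' @return per-bp diversity (0 for an empty window).
#' @export
window_pi <- function(pi_sites, window_span) {
  stopifnot(window_span > 0)
  sum(pi_sites) / window_span
}

# Per-population summaries from a dosage matrix (sites x individuals):
# called sample count, alt frequency, observed heterozygote proportion.
.pop_site_stats <- function(m) {
  m <- as.matrix(m)
  n <- rowSums(!is.na(m))
  list(n = n,
       p = ifelse(n > 0, rowSums(m, na.rm = TRUE) / (2 * n), NA_real_),
       h = ifelse(n > 0, rowSums(m == 1L, na.rm = TRUE) / n, NA_real_))
}

#' Weir & Cockerham (1984) per-site variance components
#'
#' Two-population variance components `a` (among populations), `b` (between
#' individuals within populations) and `c` (within individuals), computed
#' from sample sizes, allele frequencies and observed heterozygosities with
#' missing dosages excluded. Sites where either population has no called
#' genotype — or where both have a single one, so the within-population
#' degrees of freedom vanish — are returned as `NA` rows and reported via
#' `message()`; they contribute nothing to a window's ratio of sums.
#'
#' @param target,reference dosage matrices (sites x individuals, values 0/1/2
#'   or `NA`) for the two sample sets; vectors are treated as one site.
#' @return data.frame with numeric columns `a`, `b`, `c`, one row per site.
#' @export
wc_fst_components <- function(target, reference) {
  if (is.null(dim(target))) target <- matrix(target, nrow = 1)
  if (is.null(dim(reference))) reference <- matrix(reference, nrow = 1)
  stopifnot(nrow(target) == nrow(reference))
  s1 <- .pop_site_stats(target)
  s2 <- .pop_site_stats(reference)
  r <- 2
  n1 <- s1$n; n2 <- s2$n
  nbar <- (n1 + n2) / r
  usable <- n1 >= 1 & n2 >= 1 & nbar > 1
  n_skip <- sum(!usable)
  if (n_skip > 0)
    message(n_skip, " site(s) skipped in F_ST components ",
            "(a population had no called genotype)")
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * s1$p + n2 * s2$p) / (r * nbar)
  s2v <- (n1 * (s1$p - pbar)^2 + n2 * (s2$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * s1$h + n2 * s2$h) / (r * nbar)
  a <- (nbar / nc) *
    (s2v - (pbar * (1 - pbar) - (r - 1) / r * s2v - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2v - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a[!usable] <- NA_real_
  b[!usable] <- NA_real_
  cc[!usable] <- NA_real_
  data.frame(a = a, b = b, c = cc)
}

#' Window F_ST as a ratio of sums
#'
#' Weir & Cockerham's ratio-of-averages estimator over the usable sites of a
#' window: `sum(a) / sum(a + b + c)`. Negative estimates are retained as
#' computed (they populate the lower tail and never reach a top-quantile
#' cut). When the window is empty or its denominator is zero the estimate is
#' undefined and `NA` is returned, never 0.
#'
#' @param comp data.frame of per-site components from
#'   [wc_fst_components()] (`NA` rows are ignored).
#' @return a single F_ST estimate, or `NA_real_` when undefined.
#' @export
window_fst <- function(comp) {
  ok <- stats::complete.cases(comp)
  if (!any(ok)) return(NA_real_)
  den <- sum(comp$a[ok] + comp$b[ok] + comp$c[ok])
  if (den == 0) return(NA_real_)
  sum(comp$a[ok]) / den
}

#' Hudson-style per-site F_ST components
#'
#' Alternative estimator for sensitivity checks: per-site numerator
#' `(p1 - p2)^2 - p1(1-p1)/(n1'-1) - p2(1-p2)/(n2'-1)` and denominator
#' `p1(1-p2) + p2(1-p1)`, with `ni'` the called allele counts; windowed as a
#' ratio of sums by [window_fst()] (the `b`/`c` split is folded into a single
#' remainder column so the same aggregation applies).
#'
#' @inheritParams wc_fst_components
#' @return data.frame with columns `a` (numerator) and `b`, `c` such that
#'   `a + b + c` is the denominator.
#' @export
hudson_fst_components <- function(target, reference) {
  if (is.null(dim(target))) target <- matrix(target, nrow = 1)
  if (is.null(dim(reference))) reference <- matrix(reference, nrow = 1)
  s1 <- .pop_site_stats(target)
  s2 <- .pop_site_stats(reference)
  m1 <- 2 * s1$n  # called alleles
  m2 <- 2 * s2$n
  usable <- m1 >= 2 & m2 >= 2
  num <- (s1$p - s2$p)^2 -
    s1$p * (1 - s1$p) / (m1 - 1) - s2$p * (1 - s2$p) / (m2 - 1)
  den <- s1$p * (1 - s2$p) + s2$p * (1 - s1$p)
  num[!usable] <- NA_real_
  den[!usable] <- NA_real_
  data.frame(a = num, b = den - num, c = 0)
}

#' Low-diversity score of a window
#'
#' `-log10(pi + epsilon)` of the target population's per-bp window diversity:
#' monotone decreasing in pi, so a *high* score marks a *low*-diversity
#' window and the top tail of the score distribution is the lower end of the
#' diversity distribution. `epsilon` (default 1e-8) keeps zero-diversity
#' windows finite while sitting far below any attainable per-bp diversity at
#' realistic sample sizes, so the ordering of nonzero windows is untouched.
#'
#' @param pi_target per-bp window diversity (>= 0); vectorised.
#' @param epsilon small positive guard added before the log.
#' @return numeric score(s).
#' @export
diversity_score <- function(pi_target, epsilon = 1e-8) {
  if (any(pi_target < 0)) stop("pi_target must be >= 0")
  -log10(pi_target + epsilon)
}
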