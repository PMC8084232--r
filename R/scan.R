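#' Scan configuration
#'
#' Parameters of the sliding-window selection scan: 50-kb windows advanced in
#' 25-kb steps, with the top 5% of each statistic's distribution flagged as
#' outliers. Windows carrying fewer than `min_sites_per_window` SNPs are
#' excluded from both outlier distributions (sparse windows would otherwise
#' flood the low-diversity tail artifactually); set it to 1 to mimic a naive
#' script.
#'
#' @param window_span window width in bp (default 50000).
#' @param step window step in bp (default 25000; `0 < step <= window_span`).
#' @param outlier_quantile upper-tail mass defining outliers (default 0.05).
#' @param min_sites_per_window minimum SNPs for a window to enter the
#'   distributions (default 3).
#' @param epsilon guard constant for [diversity_score()].
#' @param fst_estimator `"wc"` (Weir-Cockerham, default) or `"hudson"`.
#' @export
scan_config <- function(window_span = 50000L, step = 25000L,
                        outlier_quantile = 0.05, min_sites_per_window = 3L,
                        epsilon = 1e-8, fst_estimator = c("wc", "hudson")) {
  stopifnot(window_span > 0, step > 0, step <= window_span,
            outlier_quantile > 0, outlier_quantile < 1,
            min_sites_per_window >= 1, epsilon > 0)
  structure(list(window_span = as.integer(window_span),
                 step = as.integer(step),
                 outlier_quantile = outlier_quantile,
                 min_sites_per_window = as.integer(min_sites_per_window),
                 epsilon = epsilon,
                 fst_estimator = match.arg(fst_estimator)),
            class = "scan_config")
}

#' Tile sliding windows over chromosomes
#'
#' Windows start at 0, `step`, `2*step`, ... (0-based half-open coordinates);
#' a window is emitted iff its start lies before the chromosome end, and the
#' terminal window is truncated at the chromosome length. Ordering is
#' deterministic by `(chrom, start)`.
#'
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param cfg a [scan_config()].
#' @return data.frame with columns `chrom`, `start` (0-based inclusive),
#'   `end` (exclusive).
#' @export
make_windows <- function(chrom_lengths, cfg = scan_config()) {
  stopifnot(length(chrom_lengths) > 0, all(chrom_lengths >= 1),
            !is.null(names(chrom_lengths)))
  chroms <- sort(names(chrom_lengths))
  out <- lapply(chroms, function(ch) {
    len <- as.integer(chrom_lengths[[ch]])
    starts <- seq.int(0L, len - 1L, by = cfg$step)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + cfg$window_span, len),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Assign SNPs to windows
#'
#' A site at 1-based position `p` belongs to the window `[start, end)` iff
#' its 0-based coordinate `p - 1` lies in the interval; with `step` equal to
#' half the span, every interior site falls in exactly two windows.
#'
#' @param g a [genotype_matrix()].
#' @param windows window table from [make_windows()].
#' @return data.frame with columns `window` (row index into `windows`) and
#'   `site` (row index into `g$variants`).
#' @export
assign_sites <- function(g, windows) {
  stopifnot(inherits(g, "genotype_matrix"))
  extra <- setdiff(unique(g$variants$chrom), unique(windows$chrom))
  if (length(extra))
    stop("chromosome(s) in genotypes but not in chrom_lengths: ",
         paste(extra, collapse = ", "))
  win_gr <- GenomicRanges::GRanges(
    windows$chrom, IRanges::IRanges(start = windows$start + 1L,
                                    end = windows$end))
  site_gr <- GenomicRanges::GRanges(
    g$variants$chrom, IRanges::IRanges(start = g$variants$pos, width = 1L))
  hits <- GenomicRanges::findOverlaps(win_gr, site_gr)
  data.frame(window = S4Vectors::queryHits(hits),
             site = S4Vectors::subjectHits(hits))
}

#' Empirical top-quantile cutoff
#'
#' Linear-interpolation (type-7) empirical `(1 - q)` quantile. A value is an
#' outlier iff it is greater than or equal to the cutoff, so ties sitting
#' exactly on the threshold are always retained.
#'
#' @param values numeric vector (non-finite values are an error; filter
#'   undefined windows out beforehand).
#' @param q upper-tail mass (e.g. 0.05 for the top 5%).
#' @return the cutoff value.
#' @export
quantile_threshold <- function(values, q) {
  if (length(values) == 0) stop("no values to take a quantile of")
  if (any(!is.finite(values))) stop("non-finite values in quantile input")
  stopifnot(q > 0, q < 1)
  stats::quantile(values, probs = 1 - q, type = 7, names = FALSE)
}

#' Flag outlier and candidate windows
#'
#' Marks each usable window (at least `min_sites_per_window` SNPs and a
#' defined F_ST) as an F_ST outlier and/or a low-diversity outlier by the
#' top-`q` rule of [quantile_threshold()], and as a *candidate* iff it is
#' both — the joint-outlier intersection. Unusable windows are excluded from
#' the distributions and can never be flagged.
#'
#' @param windows window table holding `n_sites`, `fst` and
#'   `diversity_score` columns.
#' @param cfg a [scan_config()].
#' @return `windows` with logical columns `usable`, `fst_outlier`,
#'   `pi_outlier`, `candidate` added, plus attributes `fst_cutoff` and
#'   `score_cutoff`.
#' @export
flag_candidates <- function(windows, cfg = scan_config()) {
  usable <- windows$n_sites >= cfg$min_sites_per_window &
    is.finite(windows$fst) & is.finite(windows$diversity_score)
  if (!any(usable)) stop("no usable windows to rank")
  fst_cut <- quantile_threshold(windows$fst[usable], cfg$outlier_quantile)
  score_cut <- quantile_threshold(windows$diversity_score[usable],
                                  cfg$outlier_quantile)
  windows$usable <- usable
  windows$fst_outlier <- usable & windows$fst >= fst_cut
  windows$pi_outlier <- usable & windows$diversity_score >= score_cut
  windows$candidate <- windows$fst_outlier & windows$pi_outlier
  attr(windows, "fst_cutoff") <- fst_cut
  attr(windows, "score_cutoff") <- score_cut
  windows
}

#' Merge candidate windows into candidate regions
#'
#' Overlapping or book-ended candidate windows on one chromosome are merged
#' into maximal regions (half-open interval union); regions on different
#' chromosomes are never joined. Summary statistics are aggregated over the
#' member windows.
#'
#' @param windows flagged window table from [flag_candidates()].
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `n_windows`, `window_ids` (comma-separated row indices),
#'   `max_fst`, `min_pi_target`; zero rows when there is no candidate.
#' @export
merge_regions <- function(windows) {
  cand <- which(windows$candidate)
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      n_windows = integer(), window_ids = character(),
                      max_fst = numeric(), min_pi_target = numeric(),
                      stringsAsFactors = FALSE)
  if (length(cand) == 0) return(empty)
  cw <- windows[cand, , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    cw$chrom, IRanges::IRanges(start = cw$start + 1L, end = cw$end))
  red <- GenomicRanges::reduce(gr)  # adjacent (book-ended) intervals merge
  hits <- GenomicRanges::findOverlaps(red, gr)
  member <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red),
    n_windows = lengths(member),
    window_ids = vapply(member, function(i) paste(cand[i], collapse = ","), ""),
    max_fst = vapply(member, function(i) max(cw$fst[i]), 0),
    min_pi_target = vapply(member, function(i) min(cw$pi_target[i]), 0),
    stringsAsFactors = FALSE)
}

#' Windowed selection-signature scan of one target population
#'
#' The core contrast of the pipeline: computes, for every sliding window,
#' the target population's Nei's diversity (per bp), the pooled-reference
#' diversity, the low-diversity score and the Weir-Cockerham F_ST between
#' target and reference, then flags joint top-quantile outliers and merges
#' them into candidate regions.
#'
#' @param g a filtered [genotype_matrix()].
#' @param map a [sample_map()] covering the samples of `g`.
#' @param target population code to contrast against the pool of all
#'   remaining populations.
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param cfg a [scan_config()].
#' @return list of class `selection_scan` with elements `target`,
#'   `windows` (one row per window: coordinates, `n_sites`, `pi_target`,
#'   `pi_ref`, `pi_ratio`, `diversity_score`, `fst`, flags), `regions`
#'   (merged [merge_regions()] output), `fst_cutoff`, `score_cutoff`,
#'   `n_target`, `n_reference`.
#' @export
scan_selection <- function(g, map, target, chrom_lengths, cfg = scan_config()) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(map, "sample_map"))
  pools <- pool_reference(map, target)
  absent <- setdiff(c(pools$target, pools$reference), g$samples)
  if (length(absent))
    stop("sample(s) in map but not in genotypes: ",
         paste(absent, collapse = ", "))

  st_t <- allele_stats(g, pools$target)
  st_r <- allele_stats(g, pools$reference)
  pi_t <- site_pi(st_t$alt_count, st_t$n)
  pi_r <- site_pi(st_r$alt_count, st_r$n)
  comp_fun <- if (cfg$fst_estimator == "wc") wc_fst_components else
    hudson_fst_components
  comp <- suppressMessages(
    comp_fun(g$gt[, pools$target, drop = FALSE],
             g$gt[, pools$reference, drop = FALSE]))
  abc <- comp$a + comp$b + comp$c

  windows <- make_windows(chrom_lengths, cfg)
  asg <- assign_sites(g, windows)
  nw <- nrow(windows)
  agg <- function(x) {
    v <- rowsum(x[asg$site], asg$window, na.rm = TRUE)
    out <- numeric(nw)
    out[as.integer(rownames(v))] <- v
    out
  }
  counts <- tabulate(asg$window, nbins = nw)
  span <- windows$end - windows$start
  windows$n_sites <- counts
  windows$pi_target <- agg(pi_t) / span
  windows$pi_ref <- agg(pi_r) / span
  windows$pi_ratio <- windows$pi_ref / windows$pi_target
  windows$diversity_score <- diversity_score(windows$pi_target, cfg$epsilon)
  sum_a <- agg(comp$a)
  sum_abc <- agg(abc)
  windows$fst <- ifelse(sum_abc != 0, sum_a / sum_abc, NA_real_)
  windows$fst[counts == 0] <- NA_real_

  windows <- flag_candidates(windows, cfg)
  structure(list(target = target,
                 windows = windows,
                 regions = merge_regions(windows),
                 fst_cutoff = attr(windows, "fst_cutoff"),
                 score_cutoff = attr(windows, "score_cutoff"),
                 n_target = length(pools$target),
                 n_reference = length(pools$reference)),
            class = "selection_scan")
}

#' @export
print.selection_scan <- function(x, ...) {
  cat(sprintf(
    "selection_scan: target %s (%d samples) vs pooled reference (%d samples)\n",
    x$target, x$n_target, x$n_reference))
  cat(sprintf("  %d windows (%d usable), F_ST cutoff %.4g, score cutoff %.4g\n",
              nrow(x$windows), sum(x$windows$usable),
              x$fst_cutoff, x$score_cutoff))
  cat(sprintf("  %d candidate windows in %d merged region(s)\n",
              sum(x$windows$candidate), nrow(x$regions)))
  invisible(x)
}

#' Write windows or regions as BED and TSV
#'
#' BED output keeps the internal 0-based half-open coordinates; the
#' human-readable TSV reports 1-based inclusive `start`/`end` alongside all
#' statistics columns.
#'
#' @param x a window or region data.frame with `chrom`, `start`, `end`.
#' @param path output file path.
#' @param name_col optional column used for the BED name field.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, name_col = NULL) {
  nm <- if (!is.null(name_col)) x[[name_col]] else
    sprintf("%s:%d-%d", x$chrom, x$start, x$end)
  d <- data.frame(x$chrom, x$start, x$end, nm)
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
write_tsv_1based <- function(x, path) {
  y <- x
  y$start <- y$start + 1L  # 1-based inclusive for human-readable output
  utils::write.table(y, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
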