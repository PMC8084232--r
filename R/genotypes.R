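#' Construct a genotype matrix
#'
#' The central data container of the package: a set of biallelic SNPs with a
#' diploid alt-allele dosage (0, 1, 2 or `NA` for a missing call) for every
#' sample. Rows are kept sorted by `(chrom, pos)`; all downstream statistics
#' (allele frequencies, nucleotide diversity, F_ST) are computed from this
#' object.
#'
#' @param variants data.frame with columns `chrom` (character), `pos`
#'   (1-based integer bp), `ref`, `alt` (single bases, `ref != alt`).
#' @param samples character vector of unique sample identifiers.
#' @param gt integer matrix, `nrow(variants)` x `length(samples)`, values in
#'   `{0, 1, 2, NA}`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `variants`, `samples` and `gt` (dimnames of `gt` carry the sample ids).
#' @export
genotype_matrix <- function(variants, samples, gt) {
  stopifnot(is.data.frame(variants),
            all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("duplicate sample ids")
  gt <- as.matrix(gt)
  if (nrow(gt) != nrow(variants) || ncol(gt) != length(samples))
    stop("gt dimensions do not match variants/samples")
  if (any(variants$pos < 1)) stop("positions must be >= 1")
  if (any(variants$ref == variants$alt)) stop("ref and alt alleles must differ")
  bad <- gt[!is.na(gt)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("dosages must be 0, 1, 2 or NA")
  storage.mode(gt) <- "integer"
  ord <- order(variants$chrom, variants$pos)
  variants <- variants[ord, , drop = FALSE]
  rownames(variants) <- NULL
  gt <- gt[ord, , drop = FALSE]
  dimnames(gt) <- list(NULL, samples)
  structure(list(variants = variants, samples = samples, gt = gt),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d biallelic SNPs x %d samples (%d chromosome%s)\n",
              nrow(x$variants), length(x$samples),
              length(unique(x$variants$chrom)),
              if (length(unique(x$variants$chrom)) == 1) "" else "s"))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$gt)

# GT-string -> dosage lookup; anything not listed is treated as missing.
.gt_codes <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)

#' Read a VCF into a genotype matrix
#'
#' Reads a VCF 4.x file (plain or gzipped) and returns the diploid alt-allele
#' dosages of its biallelic SNPs. Multi-allelic records and non-SNP records
#' (indels, symbolic alleles) are dropped with a message reporting the count.
#' Missing calls (`./.`), half-calls (e.g. `0/.`) and non-diploid genotypes
#' are all stored as `NA`; half-calls and non-diploid calls additionally raise
#' a warning, since silently counting their called allele would bias allele
#' frequencies.
#'
#' @param path path to a VCF file with a GT FORMAT field.
#' @param keep_samples optional character vector restricting the matrix to a
#'   subset of the samples in the header; an unknown sample id is an error.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, keep_samples = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))  # single-record VCFs drop to a named vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (is.null(fix) || nrow(fix) == 0) stop("no records in VCF: ", path)
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  bases <- c("A", "C", "G", "T")
  keep <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
    ref %in% bases & alt %in% bases
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message(n_drop, " multi-allelic or non-SNP record(s) dropped")
  if (!any(keep)) stop("no biallelic SNPs in VCF: ", path)

  gt_str <- vcfR::extract.gt(v, element = "GT")
  gt_str <- gt_str[keep, , drop = FALSE]
  samples <- colnames(gt_str)
  if (!is.null(keep_samples)) {
    missing_s <- setdiff(keep_samples, samples)
    if (length(missing_s))
      stop("sample(s) not in VCF header: ", paste(missing_s, collapse = ", "))
    gt_str <- gt_str[, keep_samples, drop = FALSE]
    samples <- keep_samples
  }
  x <- gsub("|", "/", gt_str, fixed = TRUE)
  dos <- .gt_codes[x]
  unknown <- !is.na(x) & !(x %in% names(.gt_codes)) & x != "./." & x != "."
  if (any(unknown))
    warning(sum(unknown), " half-call or non-diploid genotype(s) set to missing")
  gt <- matrix(dos, nrow = nrow(gt_str), ncol = ncol(gt_str))

  variants <- data.frame(chrom = fix[keep, "CHROM"],
                         pos = as.integer(fix[keep, "POS"]),
                         ref = ref[keep], alt = alt[keep],
                         stringsAsFactors = FALSE)
  genotype_matrix(variants, samples, gt)
}

#' Write a genotype matrix as VCF 4.2
#'
#' Emits one GT-only record per SNP (`0/0`, `0/1`, `1/1`, `./.`). Output is
#' gzip-compressed when `path` ends in `.gz`. Round-trips through
#' [read_vcf()] without loss of chromosome, position, alleles or dosage.
#'
#' @param g a [genotype_matrix()].
#' @param path output path (`.vcf` or `.vcf.gz`).
#' @param chrom_lengths optional named vector of chromosome lengths, written
#'   as `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path, chrom_lengths = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  header <- c("##fileformat=VCFv4.2",
              "##source=sweepscan",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (!is.null(chrom_lengths))
    header <- c(header, sprintf("##contig=<ID=%s,length=%d>",
                                names(chrom_lengths),
                                as.integer(chrom_lengths)))
  header <- c(header, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                              "FILTER", "INFO", "FORMAT", g$samples),
                            collapse = "\t"))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[g$gt + 1L],
                   nrow = nrow(g$gt), ncol = ncol(g$gt))
  gt_str[is.na(g$gt)] <- "./."
  body <- paste(g$variants$chrom, g$variants$pos, ".", g$variants$ref,
                g$variants$alt, ".", ".", ".", "GT",
                apply(gt_str, 1L, paste, collapse = "\t"), sep = "\t")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read a sample-to-population map
#'
#' Expects a two-column TSV `sample_id<TAB>population_code`; `#` comment lines
#' are ignored and a header row (first field `sample_id` or `sample`) is
#' optional. Sample ids must be unique and every population must contain at
#' least two samples (a single diploid gives only two chromosomes, too few
#' for a stable F_ST contrast).
#'
#' @param path path to the TSV file.
#' @return A data.frame of class `sample_map` with columns `sample_id` and
#'   `population`.
#' @export
read_sample_map <- function(path) {
  if (!file.exists(path)) stop("sample map not found: ", path)
  d <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(d) < 2) stop("sample map must have two tab-separated columns")
  if (tolower(d[1, 1]) %in% c("sample_id", "sample", "id"))
    d <- d[-1, , drop = FALSE]
  sample_map(d[[1]], d[[2]])
}

#' @rdname read_sample_map
#' @param sample_id,population character vectors of equal length.
#' @export
sample_map <- function(sample_id, population) {
  sample_id <- as.character(sample_id)
  population <- as.character(population)
  stopifnot(length(sample_id) == length(population))
  if (anyDuplicated(sample_id))
    stop("duplicate sample id(s): ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  if (any(!nzchar(population))) stop("empty population code")
  sizes <- table(population)
  if (any(sizes < 2))
    stop("population(s) with fewer than 2 samples: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  structure(data.frame(sample_id = sample_id, population = population,
                       stringsAsFactors = FALSE),
            class = c("sample_map", "data.frame"))
}

#' Per-variant allele statistics over a sample subset
#'
#' For each SNP, counts called alleles among the chosen samples and derives
#' the alt-allele frequency, minor allele frequency and per-site missingness.
#'
#' @param g a [genotype_matrix()].
#' @param samples character vector of sample ids (default: all samples).
#' @return data.frame with one row per variant: `chrom`, `pos`, `n` (called
#'   allele count, 2 x non-missing diploid calls), `alt_count`, `p` (alt
#'   frequency), `maf` (`min(p, 1 - p)`, 0 when no call), `missing_fraction`
#'   (missing calls / subset size).
#' @export
allele_stats <- function(g, samples = g$samples) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (length(samples) == 0) stop("empty sample subset")
  missing_s <- setdiff(samples, g$samples)
  if (length(missing_s))
    stop("sample(s) not in matrix: ", paste(missing_s, collapse = ", "))
  sub <- g$gt[, samples, drop = FALSE]
  called <- rowSums(!is.na(sub))
  n <- 2L * called
  alt_count <- as.integer(rowSums(sub, na.rm = TRUE))
  p <- ifelse(n > 0, alt_count / n, 0)
  data.frame(chrom = g$variants$chrom, pos = g$variants$pos,
             n = n, alt_count = alt_count, p = p,
             maf = pmin(p, 1 - p),
             missing_fraction = 1 - called / length(samples),
             stringsAsFactors = FALSE)
}

#' Variant filter configuration
#'
#' Cohort-wide post-calling filter: a SNP is retained iff its minor allele
#' frequency is strictly greater than `maf_min` and its missing-genotype
#' fraction is strictly below `missing_max`. Both inequalities are strict, so
#' sites sitting exactly on a boundary are dropped.
#'
#' @param maf_min minor-allele-frequency cutoff (default 0.05, exclusive).
#' @param missing_max missing-fraction cutoff (default 0.25, exclusive).
#' @export
filter_config <- function(maf_min = 0.05, missing_max = 0.25) {
  stopifnot(maf_min >= 0, maf_min < 0.5, missing_max > 0, missing_max <= 1)
  structure(list(maf_min = maf_min, missing_max = missing_max),
            class = "filter_config")
}

#' Filter variants on MAF and missingness
#'
#' Statistics are computed across *all* samples in the matrix (a single
#' cohort-wide pass, as a post-calling VCFtools-style filter applies it),
#' never per population. Variant order is preserved and the operation is
#' idempotent.
#'
#' @param g a [genotype_matrix()].
#' @param cfg a [filter_config()].
#' @return The filtered [genotype_matrix()]; retained/dropped counts are
#'   reported via `message()`.
#' @export
filter_variants <- function(g, cfg = filter_config()) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(cfg, "filter_config"))
  st <- allele_stats(g)
  keep <- st$maf > cfg$maf_min & st$missing_fraction < cfg$missing_max
  message(sum(keep), " of ", length(keep), " variants retained (",
          sum(!keep), " dropped: MAF <= ", cfg$maf_min,
          " or missing >= ", cfg$missing_max, ")")
  genotype_matrix(g$variants[keep, , drop = FALSE], g$samples,
                  g$gt[keep, , drop = FALSE])
}

#' Split samples into a target population and the pooled reference
#'
#' The reference is the pool of all remaining populations: every sample not
#' belonging to the target. The two sets partition the cohort.
#'
#' @param map a [sample_map()].
#' @param target a population code present in `map`.
#' @return list with character vectors `target` and `reference`.
#' @export
pool_reference <- function(map, target) {
  stopifnot(inherits(map, "sample_map"))
  codes <- unique(map$population)
  if (!target %in% codes)
    stop("unknown target population '", target, "'; known codes: ",
         paste(codes, collapse = ", "))
  if (length(codes) < 2)
    stop("need at least one non-target population to pool as reference")
  list(target = map$sample_id[map$population == target],
       reference = map$sample_id[map$population != target])
}
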