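#' Default population design of the simulator
#'
#' Seven diploid populations of 7/7/7/5/7/7/7 individuals (47 in total),
#' mirroring a realistic multi-site livestock sampling design.
#'
#' @return data.frame with columns `code` and `n`.
#' @export
default_populations <- function() {
  data.frame(code = c("NJ", "BJ", "DJ", "HX", "QH", "ALS", "SNT"),
             n = c(7L, 7L, 7L, 5L, 7L, 7L, 7L),
             stringsAsFactors = FALSE)
}

#' Default sweep layout
#'
#' Ten 250-kb sweeps aligned to the 50-kb window grid, five per chromosome,
#' separated by 150-kb background gaps; target populations are assigned
#' round-robin so the first three populations carry two sweeps each. Each
#' sweep lifts the target population's differentiation to F_ST 0.4 (over a
#' 0.05 background) and depresses its heterozygosity to 10% of the draw.
#'
#' @param populations population design data.frame (see
#'   [default_populations()]).
#' @return data.frame of class `sweep_spec` with columns `chrom`, `start`,
#'   `end` (0-based half-open), `target`, `sweep_fst`, `pi_scale`.
#' @export
default_sweeps <- function(populations = default_populations()) {
  starts <- c(50e3, 450e3, 850e3, 1250e3, 1650e3)
  d <- data.frame(chrom = rep(c("chr1", "chr2"), each = length(starts)),
                  start = as.integer(rep(starts, 2)),
                  end = as.integer(rep(starts + 250e3, 2)),
                  stringsAsFactors = FALSE)
  d$target <- rep_len(populations$code, nrow(d))
  d$sweep_fst <- 0.4
  d$pi_scale <- 0.1
  class(d) <- c("sweep_spec", "data.frame")
  d
}

#' Simulation configuration
#'
#' Balding-Nichols multi-population SNP simulation with embedded sweeps.
#' Ancestral allele frequencies are drawn from a Beta distribution rescaled
#' to `ancestral_range`; each population's frequency is then drawn from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` with `F = background_fst` (or the sweep's
#' `sweep_fst` for the sweep target at in-sweep sites). Within a sweep the
#' target frequency is additionally pushed toward the nearer allele-frequency
#' boundary so its heterozygosity is scaled by `pi_scale` exactly (see
#' [simulate_frequencies()]). Missing genotype calls are injected i.i.d.
#'
#' @param seed RNG seed; every random choice of the simulation flows from it.
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param n_snps total SNP count, split evenly across chromosomes.
#' @param populations data.frame with columns `code`, `n`.
#' @param background_fst genome-wide differentiation level (0 < F < 1).
#' @param sweeps sweep table (see [default_sweeps()]); may have zero rows.
#' @param missing_rate per-call missingness probability in `[0, 1)`.
#' @param ancestral_beta `c(shape1, shape2)` of the ancestral frequency Beta.
#' @param ancestral_range interval the ancestral frequency is rescaled into;
#'   the default spans the 0.05 MAF filter boundary.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chr1 = 2e6, chr2 = 2e6),
                       n_snps = 5000L,
                       populations = default_populations(),
                       background_fst = 0.05,
                       sweeps = default_sweeps(populations),
                       missing_rate = 0.10,
                       ancestral_beta = c(0.8, 0.8),
                       ancestral_range = c(0.01, 0.99)) {
  stopifnot(background_fst > 0, background_fst < 1,
            missing_rate >= 0, missing_rate < 1,
            all(populations$n >= 2), n_snps >= 1,
            all(ancestral_beta > 0),
            ancestral_range[1] > 0, ancestral_range[2] < 1,
            ancestral_range[1] < ancestral_range[2])
  if (nrow(sweeps)) {
    stopifnot(all(sweeps$target %in% populations$code),
              all(sweeps$sweep_fst >= background_fst),
              all(sweeps$pi_scale > 0), all(sweeps$pi_scale <= 1),
              all(sweeps$chrom %in% names(chrom_lengths)),
              all(sweeps$start >= 0),
              all(sweeps$end <= chrom_lengths[sweeps$chrom]),
              all(sweeps$start < sweeps$end))
  }
  structure(list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
                 n_snps = as.integer(n_snps), populations = populations,
                 background_fst = background_fst, sweeps = sweeps,
                 missing_rate = missing_rate,
                 ancestral_beta = ancestral_beta,
                 ancestral_range = ancestral_range),
            class = "sim_config")
}

#' Matched null configuration
#'
#' Returns the same configuration with the sweep *effects* removed
#' (`sweep_fst` set to the background level, `pi_scale` to 1) while keeping
#' the sweep intervals, so fixtures built from it have an identical gene and
#' term layout — including the planted term — but no selection signal.
#'
#' @param cfg a [sim_config()].
#' @export
remove_sweeps <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (nrow(cfg$sweeps)) {
    cfg$sweeps$sweep_fst <- cfg$background_fst
    cfg$sweeps$pi_scale <- 1
  }
  cfg
}

# Exact heterozygosity scaling: move q to the root of q'(1-q') =
# pi_scale * q(1-q) lying on the side of q's nearer boundary.
.scale_het <- function(q, pi_scale) {
  t <- pi_scale * q * (1 - q)
  disc <- sqrt(pmax(0, 1 - 4 * t))
  ifelse(q <= 0.5, (1 - disc) / 2, (1 + disc) / 2)
}

#' Draw per-population allele frequencies
#'
#' Balding-Nichols construction (see [sim_config()]). Consumes RNG state;
#' callers wanting reproducibility seed beforehand ([simulate_dataset()]
#' does).
#'
#' @param cfg a [sim_config()].
#' @param variants data.frame with `chrom`, `pos` (1-based) for the sites.
#' @return list with `p_anc` (ancestral frequencies) and `freq` (sites x
#'   populations matrix of population allele frequencies, columns named by
#'   population code).
#' @export
simulate_frequencies <- function(cfg, variants) {
  S <- nrow(variants)
  r <- stats::rbeta(S, cfg$ancestral_beta[1], cfg$ancestral_beta[2])
  lo <- cfg$ancestral_range[1]
  p_anc <- lo + (cfg$ancestral_range[2] - lo) * r
  bn_draw <- function(p, F) {
    stats::rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
  }
  freq <- vapply(cfg$populations$code,
                 function(code) bn_draw(p_anc, cfg$background_fst),
                 numeric(S))
  colnames(freq) <- cfg$populations$code
  if (nrow(cfg$sweeps)) {
    for (i in seq_len(nrow(cfg$sweeps))) {
      sw <- cfg$sweeps[i, ]
      # site at 1-based pos p is inside [start, end) iff p - 1 is
      idx <- which(variants$chrom == sw$chrom &
                     variants$pos - 1L >= sw$start &
                     variants$pos - 1L < sw$end)
      if (!length(idx)) next
      q <- bn_draw(p_anc[idx], sw$sweep_fst)
      freq[idx, sw$target] <- .scale_het(q, sw$pi_scale)
    }
  }
  list(p_anc = p_anc, freq = freq)
}

#' Sample diploid genotypes from population frequencies
#'
#' Hardy-Weinberg sampling: each individual's dosage is Binomial(2, p) at
#' its population's frequency; missing calls are injected i.i.d. at
#' `missing_rate`. Consumes RNG state.
#'
#' @param freq sites x populations allele-frequency matrix.
#' @param cfg a [sim_config()].
#' @return integer dosage matrix (sites x individuals) with `NA` for missing
#'   calls; column names are sample ids `<code>01`, `<code>02`, ...
#' @export
sample_genotypes <- function(freq, cfg) {
  S <- nrow(freq)
  cols <- lapply(seq_len(nrow(cfg$populations)), function(i) {
    code <- cfg$populations$code[i]
    n <- cfg$populations$n[i]
    m <- matrix(stats::rbinom(S * n, 2L, rep(freq[, code], n)), nrow = S)
    colnames(m) <- sprintf("%s%02d", code, seq_len(n))
    m
  })
  gt <- do.call(cbind, cols)
  if (cfg$missing_rate > 0)
    gt[stats::runif(length(gt)) < cfg$missing_rate] <- NA_integer_
  gt
}

#' Simulate a multi-population sweep dataset
#'
#' Runs the full construction under `cfg$seed`: SNP positions uniform
#' without replacement per chromosome (sorted), Balding-Nichols frequencies
#' with sweep adjustment, Hardy-Weinberg genotypes with missingness, random
#' ref/alt allele pairs, a tiled gene annotation, a term map with one term
#' planted on the genes inside the sweeps, and a ground-truth table with the
#' realized in-sweep statistics. Fully deterministic given the seed.
#'
#' @param cfg a [sim_config()].
#' @return list of class `sweep_sim` with elements `genotypes`
#'   ([genotype_matrix()]), `sample_map`, `freq` (population frequencies),
#'   `genes`, `terms`, `truth` (per-sweep `chrom`, `start`, `end`, `target`,
#'   `n_sites`, `realized_fst`, `realized_het`), and `config`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  chroms <- names(cfg$chrom_lengths)
  per <- rep(cfg$n_snps %/% length(chroms), length(chroms))
  per[seq_len(cfg$n_snps %% length(chroms))] <-
    per[seq_len(cfg$n_snps %% length(chroms))] + 1L
  variants <- do.call(rbind, lapply(seq_along(chroms), function(i) {
    data.frame(chrom = chroms[i],
               pos = sort(sample.int(as.integer(cfg$chrom_lengths[i]), per[i])),
               stringsAsFactors = FALSE)
  }))
  bases <- c("A", "C", "G", "T")
  variants$ref <- sample(bases, nrow(variants), replace = TRUE)
  shift <- sample.int(3L, nrow(variants), replace = TRUE)
  variants$alt <- bases[(match(variants$ref, bases) - 1L + shift) %% 4L + 1L]

  fr <- simulate_frequencies(cfg, variants)
  gt <- sample_genotypes(fr$freq, cfg)
  map <- sample_map(colnames(gt),
                    rep(cfg$populations$code, cfg$populations$n))
  g <- genotype_matrix(variants, colnames(gt), gt)

  genes <- make_gene_models(cfg$chrom_lengths)
  terms <- make_term_map(genes, cfg$sweeps)

  truth <- cfg$sweeps[, c("chrom", "start", "end", "target"), drop = FALSE]
  if (nrow(truth)) {
    truth$n_sites <- NA_integer_
    truth$realized_fst <- NA_real_
    truth$realized_het <- NA_real_
    for (i in seq_len(nrow(truth))) {
      sw <- truth[i, ]
      idx <- which(g$variants$chrom == sw$chrom &
                     g$variants$pos - 1L >= sw$start &
                     g$variants$pos - 1L < sw$end)
      truth$n_sites[i] <- length(idx)
      if (!length(idx)) next
      pools <- pool_reference(map, sw$target)
      comp <- suppressMessages(
        wc_fst_components(g$gt[idx, pools$target, drop = FALSE],
                          g$gt[idx, pools$reference, drop = FALSE]))
      truth$realized_fst[i] <- window_fst(comp)
      qf <- fr$freq[idx, sw$target]
      truth$realized_het[i] <- mean(2 * qf * (1 - qf))
    }
  }
  structure(list(genotypes = g, sample_map = map, freq = fr$freq,
                 genes = genes, terms = terms, truth = truth, config = cfg),
            class = "sweep_sim")
}

#' @export
print.sweep_sim <- function(x, ...) {
  cat(sprintf("sweep_sim: %d SNPs x %d samples, %d populations, %d sweep(s)\n",
              nrow(x$genotypes$variants), length(x$genotypes$samples),
              length(unique(x$sample_map$population)), nrow(x$truth)))
  invisible(x)
}

#' Tile synthetic gene models over the genome
#'
#' Deterministic layout: a 20-kb gene every 40 kb starting at 10 kb, strands
#' alternating, ids `g_<chrom>_<index>` — dense enough that every sweep
#' overlaps several genes.
#'
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param spacing,gene_length,offset layout parameters in bp.
#' @return gene table in the shape returned by [read_gff_genes()].
#' @export
make_gene_models <- function(chrom_lengths, spacing = 40e3,
                             gene_length = 20e3, offset = 10e3) {
  out <- lapply(sort(names(chrom_lengths)), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(offset, len - gene_length, by = spacing)
    data.frame(gene_id = sprintf("g_%s_%03d", ch, seq_along(starts)),
               chrom = ch,
               start = as.integer(starts),
               end = as.integer(starts + gene_length),
               strand = rep_len(c("+", "-"), length(starts)),
               name = sprintf("g_%s_%03d", ch, seq_along(starts)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Build a term map with one planted sweep term
#'
#' The planted term (`PLANTED_SWEEP`) is exactly the set of genes whose body
#' overlaps any sweep interval; `n_random` further terms draw gene sets of
#' size 5-30 uniformly from the whole annotation. Consumes RNG state (called
#' inside [simulate_dataset()] under its seed).
#'
#' @param genes gene table (see [make_gene_models()]).
#' @param sweeps sweep table (intervals only are used).
#' @param n_random number of random background terms.
#' @return term map data.frame (`gene_id`, `term_id`, `term_name`,
#'   `category`).
#' @export
make_term_map <- function(genes, sweeps, n_random = 20L) {
  planted <- if (nrow(sweeps)) {
    genes_in_regions(sweeps[, c("chrom", "start", "end")], genes)
  } else character()
  rows <- list()
  if (length(planted))
    rows[[1]] <- data.frame(gene_id = planted, term_id = "PLANTED_SWEEP",
                            term_name = "planted sweep response",
                            category = "pathway", stringsAsFactors = FALSE)
  sizes <- pmin(sample(5:30, n_random, replace = TRUE), nrow(genes))
  for (j in seq_len(n_random)) {
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = sample(genes$gene_id, sizes[j]),
      term_id = sprintf("TERM%04d", j),
      term_name = sprintf("random term %d", j),
      category = c("BP", "CC", "MF", "pathway")[(j - 1L) %% 4L + 1L],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a simulated dataset as a plain-text fixture bundle
#'
#' Emits VCF 4.2 genotypes, the sample map, a GFF3 gene annotation, the term
#' map, the sweep ground truth and the chromosome lengths — all of which
#' parse back through the package's readers with zero loss. Byte-identical
#' across runs for the same simulated object.
#'
#' @param sim a `sweep_sim` from [simulate_dataset()].
#' @param out_dir output directory (created if needed).
#' @return named character vector of the file paths, invisibly.
#' @export
write_fixture <- function(sim, out_dir) {
  stopifnot(inherits(sim, "sweep_sim"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(vcf = file.path(out_dir, "genotypes.vcf"),
             sample_map = file.path(out_dir, "sample_map.tsv"),
             gff = file.path(out_dir, "genes.gff3"),
             terms = file.path(out_dir, "terms.tsv"),
             truth = file.path(out_dir, "sweep_truth.tsv"),
             chrom_lengths = file.path(out_dir, "chrom_lengths.tsv"))
  write_vcf(sim$genotypes, paths["vcf"],
            chrom_lengths = sim$config$chrom_lengths)
  utils::write.table(sim$sample_map, paths["sample_map"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  gr <- GenomicRanges::GRanges(
    sim$genes$chrom,
    IRanges::IRanges(start = sim$genes$start + 1L, end = sim$genes$end),
    strand = sim$genes$strand,
    type = "gene", ID = sim$genes$gene_id, Name = sim$genes$name,
    source = "sweepscan")
  rtracklayer::export(gr, paths["gff"], format = "gff3")
  utils::write.table(sim$terms, paths["terms"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(chrom = names(sim$config$chrom_lengths),
               length = as.integer(sim$config$chrom_lengths)),
    paths["chrom_lengths"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
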