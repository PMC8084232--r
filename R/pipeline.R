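#' Scan every requested target against its pooled reference
#'
#' In-memory pipeline core: cohort-wide variant filtering followed by one
#' [scan_selection()] contrast per target (the pooled reference is
#' recomputed for each target — the pool of all remaining populations
#' differs per contrast), then gene extraction and per-target term
#' enrichment, plus one study-level enrichment over the union of all
#' targets' selected genes. Seed-free and deterministic.
#'
#' @param g a [genotype_matrix()] (unfiltered).
#' @param map a [sample_map()].
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param genes gene table from [read_gff_genes()], or `NULL` to skip
#'   annotation.
#' @param terms term map data.frame, or `NULL` to skip enrichment.
#' @param targets population codes to scan (default: all populations).
#' @param filter_cfg a [filter_config()].
#' @param scan_cfg a [scan_config()].
#' @param alpha enrichment FDR threshold (default 0.05).
#' @return list of class `scan_report`: `filtered` (genotype matrix),
#'   `n_input`/`n_retained` variant counts, `per_target` (named list with
#'   `scan`, `genes`, `enrichment` per target), `pooled_genes`,
#'   `pooled_enrichment`, and the configs.
#' @export
scan_all_targets <- function(g, map, chrom_lengths, genes = NULL,
                             terms = NULL, targets = NULL,
                             filter_cfg = filter_config(),
                             scan_cfg = scan_config(), alpha = 0.05) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(map, "sample_map"))
  if (is.null(targets)) targets <- unique(map$population)
  unknown <- setdiff(targets, unique(map$population))
  if (length(unknown))
    stop("target(s) not in sample map: ", paste(unknown, collapse = ", "))
  n_input <- nrow(g$variants)
  gf <- filter_variants(g, filter_cfg)
  per_target <- lapply(targets, function(tg) {
    scan <- scan_selection(gf, map, tg, chrom_lengths, scan_cfg)
    sel <- if (!is.null(genes)) {
      if (nrow(scan$regions) > 0) genes_in_regions(scan$regions, genes)
      else character()
    } else NULL
    enr <- if (!is.null(genes) && !is.null(terms)) {
      suppressWarnings(hypergeom_enrich(sel, terms, genes$gene_id, alpha))
    } else NULL
    list(scan = scan, genes = sel, enrichment = enr)
  })
  names(per_target) <- targets
  pooled_genes <- if (!is.null(genes))
    sort(unique(unlist(lapply(per_target, `[[`, "genes")))) else NULL
  pooled_enrichment <- if (!is.null(genes) && !is.null(terms))
    suppressWarnings(hypergeom_enrich(pooled_genes, terms,
                                      genes$gene_id, alpha)) else NULL
  structure(list(filtered = gf, n_input = n_input,
                 n_retained = nrow(gf$variants),
                 per_target = per_target,
                 pooled_genes = pooled_genes,
                 pooled_enrichment = pooled_enrichment,
                 filter_cfg = filter_cfg, scan_cfg = scan_cfg,
                 alpha = alpha, chrom_lengths = chrom_lengths),
            class = "scan_report")
}

#' @export
print.scan_report <- function(x, ...) {
  cat(sprintf("scan_report: %d/%d variants retained; %d target contrast(s)\n",
              x$n_retained, x$n_input, length(x$per_target)))
  for (tg in names(x$per_target)) {
    pt <- x$per_target[[tg]]
    cat(sprintf("  %s: %d candidate window(s), %d region(s), %s gene(s)\n",
                tg, sum(pt$scan$windows$candidate), nrow(pt$scan$regions),
                if (is.null(pt$genes)) "-" else length(pt$genes)))
  }
  invisible(x)
}

# md5 of an object's canonical JSON serialisation, via a temp file.
.config_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tf))
}

#' Run the full pipeline and write one output bundle per target
#'
#' File-level wrapper around [scan_all_targets()]: reads the inputs when
#' given as paths, runs filter / scan / annotate / enrich for every target,
#' and writes under `out_dir` one sub-directory per target (window TSV,
#' candidate-region BED + TSV, gene list, enrichment TSV), a `pooled/`
#' study-level enrichment, and a `manifest.json` recording the package
#' version, the configuration and its hash, and the md5 checksums of any
#' file inputs. Reruns on identical inputs produce identical outputs.
#'
#' @param vcf path to a VCF file, or a [genotype_matrix()].
#' @param sample_map path to a sample-map TSV, or a [sample_map()].
#' @param chrom_lengths named vector, or path to a two-column
#'   `chrom<TAB>length` TSV.
#' @param gff path to a GFF3 file, a gene table, or `NULL`.
#' @param terms path to a term-map TSV, a term data.frame, or `NULL`.
#' @param out_dir output directory.
#' @param make_plots also render per-chromosome scan plots (see
#'   [render_report()]).
#' @inheritParams scan_all_targets
#' @return the `scan_report`, invisibly.
#' @export
run_pipeline <- function(vcf, sample_map, chrom_lengths, gff = NULL,
                         terms = NULL, targets = NULL,
                         filter_cfg = filter_config(),
                         scan_cfg = scan_config(), alpha = 0.05,
                         out_dir, make_plots = FALSE) {
  inputs <- list()
  if (is.character(vcf)) { inputs$vcf <- vcf; vcf <- read_vcf(vcf) }
  if (is.character(sample_map)) {
    inputs$sample_map <- sample_map
    sample_map <- read_sample_map(sample_map)
  }
  if (is.character(chrom_lengths)) {
    inputs$chrom_lengths <- chrom_lengths
    cl <- utils::read.table(chrom_lengths, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    chrom_lengths <- stats::setNames(cl[[2]], cl[[1]])
  }
  if (is.character(gff)) { inputs$gff <- gff; gff <- read_gff_genes(gff) }
  if (is.character(terms)) { inputs$terms <- terms; terms <- read_term_map(terms) }

  rep <- scan_all_targets(vcf, sample_map, chrom_lengths, genes = gff,
                          terms = terms, targets = targets,
                          filter_cfg = filter_cfg, scan_cfg = scan_cfg,
                          alpha = alpha)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (tg in names(rep$per_target)) {
    pt <- rep$per_target[[tg]]
    td <- file.path(out_dir, tg)
    dir.create(td, showWarnings = FALSE)
    w <- pt$scan$windows
    write_tsv_1based(w, file.path(td, "windows.tsv"))
    write_bed(pt$scan$regions, file.path(td, "candidates.bed"))
    write_tsv_1based(pt$scan$regions, file.path(td, "candidate_regions.tsv"))
    if (!is.null(pt$genes)) {
      writeLines(pt$genes, file.path(td, "genes.txt"))
      if (length(pt$genes) == 0)
        warning("no candidate genes for target ", tg)
    }
    if (!is.null(pt$enrichment))
      utils::write.table(pt$enrichment, file.path(td, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(rep$pooled_enrichment)) {
    pd <- file.path(out_dir, "pooled")
    dir.create(pd, showWarnings = FALSE)
    writeLines(rep$pooled_genes, file.path(pd, "genes.txt"))
    utils::write.table(rep$pooled_enrichment, file.path(pd, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  cfg <- list(filter = unclass(filter_cfg), scan = unclass(scan_cfg),
              alpha = alpha, targets = names(rep$per_target),
              chrom_lengths = as.list(chrom_lengths))
  manifest <- list(
    tool = "sweepscan",
    version = as.character(utils::packageVersion("sweepscan")),
    config = cfg,
    config_md5 = .config_hash(cfg),
    input_md5 = as.list(vapply(inputs, function(p) unname(tools::md5sum(p)), "")),
    counts = list(
      variants_in = rep$n_input, variants_retained = rep$n_retained,
      per_target = lapply(rep$per_target, function(pt) list(
        windows = nrow(pt$scan$windows),
        usable_windows = sum(pt$scan$windows$usable),
        fst_outliers = sum(pt$scan$windows$fst_outlier),
        pi_outliers = sum(pt$scan$windows$pi_outlier),
        candidate_windows = sum(pt$scan$windows$candidate),
        candidate_regions = nrow(pt$scan$regions),
        genes = if (is.null(pt$genes)) NA else length(pt$genes),
        significant_terms = if (is.null(pt$enrichment)) NA else
          sum(pt$enrichment$significant)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (make_plots) render_report(rep, out_dir)
  invisible(rep)
}

#' Score candidate regions against simulated sweep truth
#'
#' Two detection summaries for a `scan_report` run on simulated data:
#' *recovery*, the fraction of truth sweeps overlapped by at least one
#' candidate region of their own target's contrast; and *precision*, the
#' fraction of all candidate-region bases (pooled over targets) lying
#' inside the truth intervals of the matching target.
#'
#' @param rep a `scan_report` from [scan_all_targets()].
#' @param truth truth table with columns `chrom`, `start`, `end`, `target`.
#' @return list with `recovery`, `precision`, `n_sweeps`, `n_recovered`,
#'   `candidate_bases`, `bases_in_truth`.
#' @export
evaluate_against_truth <- function(rep, truth) {
  stopifnot(inherits(rep, "scan_report"))
  recovered <- logical(nrow(truth))
  total_bases <- 0
  in_bases <- 0
  for (tg in names(rep$per_target)) {
    regions <- rep$per_target[[tg]]$scan$regions
    tr <- truth[truth$target == tg, , drop = FALSE]
    if (nrow(regions) == 0) next
    rg <- GenomicRanges::GRanges(
      regions$chrom, IRanges::IRanges(regions$start + 1L, regions$end))
    total_bases <- total_bases + sum(GenomicRanges::width(rg))
    if (nrow(tr) == 0) next
    tg_gr <- GenomicRanges::GRanges(
      tr$chrom, IRanges::IRanges(tr$start + 1L, tr$end))
    hit <- GenomicRanges::countOverlaps(tg_gr, rg) > 0
    recovered[which(truth$target == tg)] <- hit
    ov <- GenomicRanges::intersect(rg, tg_gr)
    in_bases <- in_bases + sum(GenomicRanges::width(ov))
  }
  list(recovery = if (nrow(truth)) mean(recovered) else NA_real_,
       precision = if (total_bases > 0) in_bases / total_bases else NA_real_,
       n_sweeps = nrow(truth), n_recovered = sum(recovered),
       candidate_bases = total_bases, bases_in_truth = in_bases)
}
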