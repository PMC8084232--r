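#' Read gene models from a GFF3 annotation
#'
#' Keeps `gene`-type features only; the gene identifier is taken from the
#' `ID` attribute, falling back to `gene_id` and then `Name`. Coordinates are
#' converted to the package's internal 0-based half-open convention.
#'
#' @param path path to a GFF3 file.
#' @return data.frame with columns `gene_id`, `chrom`, `start` (0-based),
#'   `end` (exclusive), `strand`, `name`, sorted by `(chrom, start)`.
#' @export
read_gff_genes <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & gr$type == "gene"]
  if (length(gr) == 0) stop("no gene features in GFF3: ", path)
  mc <- S4Vectors::mcols(gr)
  id <- if ("ID" %in% names(mc)) as.character(mc$ID) else NA_character_
  if (all(is.na(id)) && "gene_id" %in% names(mc))
    id <- as.character(mc$gene_id)
  if (all(is.na(id)) && "Name" %in% names(mc)) id <- as.character(mc$Name)
  if (anyNA(id)) stop("gene feature(s) without an ID attribute")
  if (anyDuplicated(id)) stop("duplicate gene ids in GFF3")
  nm <- if ("Name" %in% names(mc)) as.character(mc$Name) else id
  g <- data.frame(gene_id = id,
                  chrom = as.character(GenomicRanges::seqnames(gr)),
                  start = GenomicRanges::start(gr) - 1L,
                  end = GenomicRanges::end(gr),
                  strand = as.character(GenomicRanges::strand(gr)),
                  name = nm, stringsAsFactors = FALSE)
  g <- g[order(g$chrom, g$start), , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Read a gene-to-term map
#'
#' Generic functional-annotation table (GO/KEGG exports fit this shape):
#' a TSV with columns `gene_id`, `term_id`, `term_name`, `category`; `#`
#' comments allowed, header optional.
#'
#' @param path path to the TSV file.
#' @return data.frame with those four character columns.
#' @export
read_term_map <- function(path) {
  if (!file.exists(path)) stop("term map not found: ", path)
  d <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE, colClasses = "character",
                         quote = "")
  if (ncol(d) < 4) stop("term map must have 4 tab-separated columns")
  if (tolower(d[1, 1]) %in% c("gene_id", "gene")) d <- d[-1, , drop = FALSE]
  names(d)[1:4] <- c("gene_id", "term_id", "term_name", "category")
  rownames(d) <- NULL
  d[, 1:4]
}

#' Genes overlapping candidate regions
#'
#' A gene is selected iff its body overlaps any region by at least one base
#' pair (strand ignored; half-open intervals, so a gene abutting a region
#' end does not overlap). The result is deduplicated and ordered by
#' `(chrom, start)`.
#'
#' @param regions region data.frame (`chrom`, `start`, `end`, 0-based
#'   half-open), e.g. from [merge_regions()].
#' @param genes gene table from [read_gff_genes()].
#' @return character vector of selected gene ids.
#' @export
genes_in_regions <- function(regions, genes) {
  if (nrow(regions) == 0) return(character())
  if (nrow(genes) == 0) stop("empty gene table")
  if (!any(unique(regions$chrom) %in% unique(genes$chrom)))
    stop("no chromosome names shared between regions and annotation; ",
         "check for a naming mismatch (e.g. 'chr1' vs '1')")
  rg <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(start = regions$start + 1L,
                                    end = regions$end))
  gg <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(start = genes$start + 1L, end = genes$end))
  hits <- GenomicRanges::findOverlaps(gg, rg, minoverlap = 1L)
  sel <- sort(unique(S4Vectors::queryHits(hits)))
  genes$gene_id[sel]  # genes table is (chrom, start)-ordered already
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH adjustment with monotonicity enforcement, delegated to
#' `stats::p.adjust(method = "BH")` after validating the inputs; adjusted
#' values follow their p-values under any permutation of the input.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return vector of FDR-adjusted values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric())
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric term enrichment of a gene set
#'
#' For each term, tests over-representation of the selected genes with the
#' upper-tail hypergeometric probability `P(X >= k)` where `k` selected genes
#' carry the term, `K` universe genes carry it, `n` genes are selected and
#' `N` is the universe size (a one-sided Fisher exact test). P-values are
#' BH-adjusted across all tested terms and a term is significant iff its FDR
#' is at or below `alpha`. Terms absent from the universe (`K = 0`) are
#' skipped; term genes outside the universe are ignored.
#'
#' @param selected character vector of selected gene ids (must be a subset
#'   of `universe`).
#' @param terms term map data.frame (see [read_term_map()]).
#' @param universe character vector of background gene ids — by default the
#'   full annotation, not just genes with a term; this choice changes `N`
#'   and every p-value, so it is exposed rather than implied.
#' @param alpha FDR significance threshold (default 0.05).
#' @return data.frame ordered by p-value with columns `term_id`,
#'   `term_name`, `category`, `k`, `K`, `n`, `N`, `p_value`, `fdr`,
#'   `significant`.
#' @export
hypergeom_enrich <- function(selected, terms, universe, alpha = 0.05) {
  universe <- unique(as.character(universe))
  selected <- unique(as.character(selected))
  if (length(setdiff(selected, universe)))
    stop("selected gene(s) outside the universe: ",
         paste(utils::head(setdiff(selected, universe), 5), collapse = ", "))
  empty <- data.frame(term_id = character(), term_name = character(),
                      category = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p_value = numeric(),
                      fdr = numeric(), significant = logical(),
                      stringsAsFactors = FALSE)
  if (length(selected) == 0) {
    warning("empty selected gene set; no enrichment computed")
    return(empty)
  }
  terms <- terms[terms$gene_id %in% universe, , drop = FALSE]
  if (nrow(terms) == 0) return(empty)
  sets <- split(terms$gene_id, terms$term_id)
  sets <- lapply(sets, unique)
  info <- terms[!duplicated(terms$term_id), c("term_id", "term_name", "category")]
  rownames(info) <- info$term_id
  N <- length(universe)
  n <- length(selected)
  K <- lengths(sets)
  k <- vapply(sets, function(gs) sum(selected %in% gs), 0L)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  fdr <- bh_fdr(p)
  out <- data.frame(term_id = names(sets),
                    term_name = info[names(sets), "term_name"],
                    category = info[names(sets), "category"],
                    k = as.integer(k), K = as.integer(K),
                    n = n, N = N, p_value = p, fdr = fdr,
                    significant = fdr <= alpha,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count terms per category
#'
#' Simple per-category tally of the distinct terms hit by a gene set — the
#' flat classification-bar-chart view of a functional annotation (no
#' ontology graph is used or bundled).
#'
#' @param selected character vector of gene ids.
#' @param terms term map data.frame.
#' @return data.frame with columns `category`, `n_terms`, `n_genes`.
#' @export
category_counts <- function(selected, terms) {
  t2 <- terms[terms$gene_id %in% selected, , drop = FALSE]
  if (nrow(t2) == 0)
    return(data.frame(category = character(), n_terms = integer(),
                      n_genes = integer(), stringsAsFactors = FALSE))
  sp <- split(t2, t2$category)
  data.frame(category = names(sp),
             n_terms = vapply(sp, function(d) length(unique(d$term_id)), 0L),
             n_genes = vapply(sp, function(d) length(unique(d$gene_id)), 0L),
             row.names = NULL, stringsAsFactors = FALSE)
}
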