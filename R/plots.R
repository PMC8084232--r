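#' Manhattan-style plot of one scan statistic
#'
#' Per-window scatter of F_ST or the low-diversity score along a
#' chromosome, with the outlier cutoff as a dashed line and candidate
#' windows highlighted.
#'
#' @param scan a `selection_scan` from [scan_selection()].
#' @param statistic `"fst"` or `"diversity_score"`.
#' @param chrom optional single chromosome to restrict to.
#' @return a ggplot object.
#' @export
plot_scan <- function(scan, statistic = c("fst", "diversity_score"),
                      chrom = NULL) {
  statistic <- match.arg(statistic)
  w <- scan$windows[scan$windows$usable, , drop = FALSE]
  if (!is.null(chrom)) w <- w[w$chrom == chrom, , drop = FALSE]
  w$mid <- (w$start + w$end) / 2
  cutoff <- if (statistic == "fst") scan$fst_cutoff else scan$score_cutoff
  ylab <- if (statistic == "fst") expression(F[ST]) else
    expression(-log[10] * "(" * pi * ")")
  w$value <- w[[statistic]]
  ggplot2::ggplot(w, ggplot2::aes(x = mid / 1e6, y = value,
                                  colour = candidate)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = ylab,
                  title = sprintf("%s vs pooled reference", scan$target)) +
    ggplot2::theme_minimal()
}

#' Render plots and a markdown summary for a pipeline run
#'
#' Writes, per target and chromosome, a pair of PNG scan plots (F_ST and
#' low-diversity score) plus a `summary.md` with per-target counts. A
#' plotting failure (e.g. no usable graphics device) is downgraded to a
#' warning so a headless run never dies on cosmetics.
#'
#' @param rep a `scan_report` from [scan_all_targets()].
#' @param out_dir output directory (per-target sub-directories are used).
#' @return character vector of files written, invisibly.
#' @export
render_report <- function(rep, out_dir) {
  stopifnot(inherits(rep, "scan_report"))
  written <- character()
  lines <- c("# Selection scan summary", "",
             sprintf("Variants retained: %d of %d", rep$n_retained,
                     rep$n_input), "")
  for (tg in names(rep$per_target)) {
    pt <- rep$per_target[[tg]]
    td <- file.path(out_dir, tg)
    dir.create(td, recursive = TRUE, showWarnings = FALSE)
    for (ch in unique(pt$scan$windows$chrom)) {
      for (stat in c("fst", "diversity_score")) {
        f <- file.path(td, sprintf("%s_%s.png", ch, stat))
        ok <- tryCatch({
          grDevices::png(f, width = 1200, height = 500, res = 120)
          print(plot_scan(pt$scan, stat, chrom = ch))
          grDevices::dev.off()
          TRUE
        }, error = function(e) {
          try(grDevices::dev.off(), silent = TRUE)
          warning("plot failed for ", tg, "/", ch, ": ",
                  conditionMessage(e))
          FALSE
        })
        if (ok) written <- c(written, f)
      }
    }
    n_genes <- if (is.null(pt$genes)) NA_integer_ else length(pt$genes)
    n_sig <- if (is.null(pt$enrichment)) NA_integer_ else
      sum(pt$enrichment$significant)
    lines <- c(lines, sprintf(
      "- **%s**: %d candidate window(s), %d region(s), %s gene(s), %s significant term(s)",
      tg, sum(pt$scan$windows$candidate), nrow(pt$scan$regions),
      n_genes, n_sig))
  }
  if (!is.null(rep$pooled_enrichment))
    lines <- c(lines, "", sprintf(
      "Pooled across targets: %d gene(s), %d significant term(s)",
      length(rep$pooled_genes), sum(rep$pooled_enrichment$significant)))
  md <- file.path(out_dir, "summary.md")
  writeLines(lines, md)
  invisible(c(written, md))
}
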