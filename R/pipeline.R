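# End-to-end orchestration: catalog -> quantification -> distribution
# statistics -> TSS neighborhood, with a machine-readable report.

#' Run the full expression-analysis pipeline
#'
#' Executes the stages in analysis order on a catalog (with `biotype`
#' distinguishing coding from lncRNA genes) and a two-sample count matrix:
#' RPKM quantification, the RPKM > `min_rpkm` expression filter, fold-change
#' calls per class, distribution statistics (skewness, D'Agostino K-squared,
#' two-sample KS, Student's t, chi-squared on the lncRNA up-vs-down
#' proportions), and the TSS-neighborhood analysis of upregulated lncRNAs
#' (nearest expressed coding TSS, window enrichment, fold-change
#' correlation, length/expression independence). Rerunning with the same
#' inputs produces an identical report.
#'
#' @param catalog a [gene_catalog] containing both coding (`biotype ==
#'   "coding"`) and lncRNA (`biotype == "lncRNA"`) genes.
#' @param counts genes x samples count matrix covering the catalog's genes.
#' @param control_sample,depleted_sample column names in `counts`.
#' @param library_sizes optional named vector; defaults to column sums.
#' @param min_rpkm expression floor (default 1.0, strict).
#' @param fc_threshold fold-change call threshold (default 2.0, strict).
#' @param window_nt TSS window for the enrichment test (default 5000).
#' @param pseudocount pseudocount for the distribution-statistics fold
#'   changes, keeping log2 FCs finite (default 0.1); direction calls use
#'   pseudocount 0.
#' @param out_dir if non-NULL, per-stage TSVs and a JSON report are written
#'   here.
#' @return List of class `analysis_report`; see Details in the vignette.
#' @export
run_pipeline <- function(catalog, counts, control_sample = "control",
                         depleted_sample = "depleted", library_sizes = NULL,
                         min_rpkm = 1.0, fc_threshold = 2.0,
                         window_nt = 5000L, pseudocount = 0.1,
                         out_dir = NULL) {
  stopifnot(min_rpkm > 0, fc_threshold > 0, window_nt > 0)
  lens <- setNames(catalog$genes$exonic_length, catalog$genes$gene_id)
  expr <- expression_table(counts, lens, library_sizes)
  expressed <- expression_filter(expr, min_rpkm = min_rpkm)
  biotype <- setNames(catalog$genes$biotype, catalog$genes$gene_id)
  cls <- list(coding = expressed[biotype[expressed] == "coding"],
              lncRNA = expressed[biotype[expressed] == "lncRNA"])

  per_class <- lapply(names(cls), function(cl) {
    ids <- cls[[cl]]
    if (length(ids) == 0) return(NULL)
    fc <- fold_changes(expr, control_sample, depleted_sample,
                       fc_threshold = fc_threshold, pseudocount = 0,
                       genes = ids)
    fc_s <- fold_changes(expr, control_sample, depleted_sample,
                         fc_threshold = fc_threshold,
                         pseudocount = pseudocount, genes = ids)
    lfc <- fc_s$log2fc[is.finite(fc_s$log2fc)]
    n_up <- sum(fc$direction == "up")
    n_down <- sum(fc$direction == "down")
    list(class = cl, fc = fc, fc_smoothed = fc_s, log2fc = lfc,
         n_expressed = length(ids), n_up = n_up, n_down = n_down,
         pct_up = 100 * n_up / length(ids),
         pct_down = 100 * n_down / length(ids),
         skewness = if (length(lfc) >= 3) sample_skewness(lfc) else NA_real_,
         dagostino = if (length(lfc) >= 20) dagostino_k2(lfc) else NULL)
  })
  names(per_class) <- names(cls)

  tests <- list()
  if (!is.null(per_class$coding) && !is.null(per_class$lncRNA)) {
    tests$ks <- ks_two_sample(per_class$coding$log2fc, per_class$lncRNA$log2fc)
    tests$t <- student_t_two_sample(per_class$lncRNA$log2fc,
                                    per_class$coding$log2fc)
  }
  if (!is.null(per_class$lncRNA)) {
    lc <- per_class$lncRNA
    tests$chi2_up_down <- chi2_two_proportions(lc$n_up, lc$n_expressed,
                                               lc$n_down, lc$n_expressed)
  }

  neighborhood <- NULL
  if (!is.null(per_class$lncRNA) && !is.null(per_class$coding)) {
    lnc_up_ids <- per_class$lncRNA$fc$gene_id[per_class$lncRNA$fc$direction == "up"]
    coding_expressed <- subset_catalog(catalog, cls$coding)
    lnc_all <- subset_catalog(catalog, cls$lncRNA)
    links_all <- nearest_expressed_tss(lnc_all, coding_expressed)
    links_up <- links_all[links_all$lnc_gene_id %in% lnc_up_ids, , drop = FALSE]
    enr <- if (nrow(links_up) > 0) window_enrichment(links_up, window_nt)
           else NULL
    fc_cor <- if (nrow(links_up) >= 3)
      tryCatch(neighbor_fc_correlation(links_up, per_class$lncRNA$fc_smoothed,
                                       per_class$coding$fc_smoothed),
               error = function(e) NULL) else NULL
    lnc_fc_s <- per_class$lncRNA$fc_smoothed
    lnc_len <- lens[lnc_fc_s$gene_id]
    indep <- tryCatch(
      independence_diagnostics(lnc_fc_s$log2fc, unname(lnc_len),
                               lnc_fc_s$rpkm_control),
      error = function(e) NULL)
    neighborhood <- list(links = links_all, links_upregulated = links_up,
                         window_enrichment = enr,
                         neighbor_fc_correlation = fc_cor,
                         independence = indep)
  }

  report <- structure(list(
    thresholds = list(min_rpkm = min_rpkm, fc_threshold = fc_threshold,
                      window_nt = window_nt, pseudocount = pseudocount),
    samples = list(control = control_sample, depleted = depleted_sample),
    expression = expr, expressed_gene_ids = expressed,
    classes = per_class, tests = tests, neighborhood = neighborhood
  ), class = "analysis_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  for (cl in names(x$classes)) {
    pc <- x$classes[[cl]]
    if (is.null(pc)) next
    cat(sprintf("%s: %d expressed; %d up (%.1f%%), %d down (%.1f%%); skewness %.3f\n",
                cl, pc$n_expressed, pc$n_up, pc$pct_up, pc$n_down,
                pc$pct_down, pc$skewness))
  }
  if (!is.null(x$tests$chi2_up_down)) {
    cat(sprintf("lncRNA up vs down: chi-squared p = %.3g\n",
                x$tests$chi2_up_down$p_value))
  }
  if (!is.null(x$neighborhood$window_enrichment)) {
    e <- x$neighborhood$window_enrichment
    cat(sprintf("within %d nt of a coding TSS: %d upstream vs %d downstream (of %d; Fisher p = %.3g)\n",
                e$window_nt, e$n_up_in_window, e$n_down_in_window, e$n_total,
                e$fisher_result$p_value))
  }
  invisible(x)
}

#' Serialize an analysis report
#'
#' Writes the expression table, per-class fold-change tables and the
#' neighbor-link table as TSVs, plus a JSON summary (counts, percentages
#' and test results; no timestamps, so identical runs serialize
#' identically).
#'
#' @param report an `analysis_report` from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return Invisible character vector of the files written.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  w <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, path)
  }
  w(report$expression, "expression.tsv")
  for (cl in names(report$classes)) {
    if (!is.null(report$classes[[cl]])) {
      w(report$classes[[cl]]$fc, paste0("fold_changes_", cl, ".tsv"))
    }
  }
  if (!is.null(report$neighborhood)) {
    w(report$neighborhood$links, "neighbor_links.tsv")
  }
  summ <- report_summary(report)
  json_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(summ, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(c(files, json_path))
}

# plain-list summary of an analysis_report (JSON-serializable, no tables)
report_summary <- function(report) {
  cls <- lapply(report$classes, function(pc) {
    if (is.null(pc)) return(NULL)
    list(n_expressed = pc$n_expressed, n_up = pc$n_up, n_down = pc$n_down,
         pct_up = pc$pct_up, pct_down = pc$pct_down, skewness = pc$skewness,
         dagostino_p = if (!is.null(pc$dagostino)) pc$dagostino$p_value
                       else NULL)
  })
  tst <- lapply(report$tests, function(t) {
    list(statistic = t$statistic, p_value = t$p_value, method = t$method)
  })
  nb <- NULL
  if (!is.null(report$neighborhood$window_enrichment)) {
    e <- report$neighborhood$window_enrichment
    nb <- list(window_nt = e$window_nt, n_up_in_window = e$n_up_in_window,
               n_down_in_window = e$n_down_in_window, n_total = e$n_total,
               fisher_p = e$fisher_result$p_value)
  }
  list(thresholds = report$thresholds, samples = report$samples,
       classes = cls, tests = tst, window_enrichment = nb)
}
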