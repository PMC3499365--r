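# TSS-neighborhood analysis: for each lncRNA, the nearest expressed
# protein-coding transcription start site, with signed distance,
# upstream/downstream side in the coding gene's frame, and sense/antisense
# orientation.

#' Transcription start site of a gene
#'
#' 0-based position of the first transcribed base: `start` of the span on
#' the + strand, `end - 1` on the - strand.
#'
#' @param start,end gene span, 0-based half-open.
#' @param strand `"+"` or `"-"` (vectorized).
#' @return Integer TSS coordinate(s).
#' @export
tss_of <- function(start, end, strand) {
  ifelse(strand == "+", start, end - 1L)
}

#' Nearest expressed coding TSS for each lncRNA
#'
#' For every lncRNA gene, finds the protein-coding gene (restricted to an
#' expressed set) whose TSS minimizes the gap to the lncRNA span:
#' `distance_nt = 0` when the TSS falls inside the span, otherwise the
#' distance from the TSS to the nearest span edge. `side` is assigned in
#' the coding gene's frame: `upstream` when the lncRNA lies on the promoter
#' side of the TSS, `downstream` when it lies within/beyond the gene body
#' side, `overlapping` when the TSS is inside the lncRNA span. `orientation`
#' is `sense` when the two genes share a strand, `antisense` otherwise.
#' Equidistant coding genes tie-break on the smaller `gene_id`.
#'
#' @param lnc [gene_catalog] of lncRNA genes.
#' @param coding_expressed [gene_catalog] of expressed coding genes.
#' @return data.frame (one row per lncRNA): `lnc_gene_id`, `coding_gene_id`
#'   (NA when no coding gene shares the chromosome), `distance_nt`, `side`,
#'   `orientation`.
#' @export
nearest_expressed_tss <- function(lnc, coding_expressed) {
  cg <- coding_expressed$genes
  cg$tss <- tss_of(cg$start, cg$end, cg$strand)
  lg <- lnc$genes
  out <- vector("list", nrow(lg))
  for (i in seq_len(nrow(lg))) {
    cand <- cg[cg$chrom == lg$chrom[[i]], , drop = FALSE]
    if (nrow(cand) == 0) {
      out[[i]] <- data.frame(lnc_gene_id = lg$gene_id[[i]],
                             coding_gene_id = NA_character_,
                             distance_nt = NA_integer_, side = NA_character_,
                             orientation = NA_character_,
                             stringsAsFactors = FALSE)
      next
    }
    d <- span_point_gap(lg$start[[i]], lg$end[[i]], cand$tss)
    best <- which(d == min(d))
    best <- best[order(cand$gene_id[best])][1]
    out[[i]] <- data.frame(
      lnc_gene_id = lg$gene_id[[i]],
      coding_gene_id = cand$gene_id[[best]],
      distance_nt = d[[best]],
      side = tss_side(lg$start[[i]], lg$end[[i]], cand$tss[[best]],
                      cand$strand[[best]]),
      orientation = if (lg$strand[[i]] == cand$strand[[best]]) "sense"
                    else "antisense",
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# gap between span [s,e) and point p: distance to the nearer span boundary,
# 0 when the point lies inside (or at) the span
span_point_gap <- function(s, e, p) {
  ifelse(p < s, s - p, ifelse(p > e, p - e, 0L))
}

# which side of the coding TSS the lncRNA lies on, in the coding gene's frame
tss_side <- function(s, e, tss, coding_strand) {
  if (tss >= s && tss <= e) return("overlapping")
  before <- e <= tss  # lncRNA entirely at coordinates below the TSS
  if (coding_strand == "+") {
    if (before) "upstream" else "downstream"
  } else {
    if (before) "downstream" else "upstream"
  }
}

#' Upstream/downstream enrichment within a window of the TSS
#'
#' Counts neighbor links whose gap satisfies `0 < distance_nt <= window_nt`,
#' split by side, and tests the asymmetry with Fisher's exact test on
#' `[[n_up_in_window, n_total - n_up_in_window], [n_down_in_window,
#' n_total - n_down_in_window]]`. Overlapping links (distance 0) belong to
#' neither window.
#'
#' @param links data.frame from [nearest_expressed_tss()] (typically
#'   restricted to upregulated lncRNAs).
#' @param window_nt window size in nt (default 5000, inclusive).
#' @return List of class `window_enrichment`: `window_nt`,
#'   `n_up_in_window`, `n_down_in_window`, `n_total`, `fisher_result`.
#' @export
window_enrichment <- function(links, window_nt = 5000L) {
  links <- links[!is.na(links$coding_gene_id), , drop = FALSE]
  if (nrow(links) == 0) stop("empty link set")
  inw <- links$distance_nt > 0 & links$distance_nt <= window_nt
  n_up <- sum(inw & links$side == "upstream")
  n_down <- sum(inw & links$side == "downstream")
  n <- nrow(links)
  fr <- fisher_exact(matrix(c(n_up, n - n_up, n_down, n - n_down),
                            nrow = 2, byrow = TRUE))
  structure(list(window_nt = window_nt, n_up_in_window = n_up,
                 n_down_in_window = n_down, n_total = n,
                 fisher_result = fr),
            class = "window_enrichment")
}

#' Correlation between lncRNA and neighboring-gene fold changes
#'
#' Pearson correlation, with two-sided p-value, of the paired log2 fold
#' changes of each lncRNA and its nearest coding neighbor — a specificity
#' check: absence of correlation argues the lncRNA response is not a
#' neighborhood transcription effect.
#'
#' @param links data.frame from [nearest_expressed_tss()].
#' @param lnc_fc,coding_fc fold-change data.frames from [fold_changes()]
#'   covering the linked genes.
#' @return `test_result` with `statistic` (r), `p_value` and `n`.
#' @export
neighbor_fc_correlation <- function(links, lnc_fc, coding_fc) {
  links <- links[!is.na(links$coding_gene_id), , drop = FALSE]
  a <- setNames(lnc_fc$log2fc, lnc_fc$gene_id)[links$lnc_gene_id]
  b <- setNames(coding_fc$log2fc, coding_fc$gene_id)[links$coding_gene_id]
  if (any(is.na(a)) || any(is.na(b))) stop("link gene lacks a fold-change record")
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3) stop("need >= 3 finite pairs")
  ct <- cor.test(a[ok], b[ok], method = "pearson")
  test_result(unname(ct$estimate), ct$p.value,
              "Pearson correlation of paired log2 fold changes",
              n = sum(ok))
}

#' Histogram of signed distances to the nearest coding TSS
#'
#' Upstream distances are negative, downstream positive; distance-0
#' (overlapping) links fall in the central bin. Bins are half-open on the
#' left, `(lo, hi]`, at multiples of `bin_nt`.
#'
#' @param links data.frame from [nearest_expressed_tss()], non-empty.
#' @param bin_nt bin width in nt (default 10000).
#' @return data.frame `bin_lo`, `bin_hi`, `count`; counts sum to the number
#'   of links.
#' @export
distance_histogram <- function(links, bin_nt = 10000L) {
  links <- links[!is.na(links$coding_gene_id), , drop = FALSE]
  if (nrow(links) == 0) stop("no links")
  signed <- ifelse(links$side == "upstream", -links$distance_nt,
                   links$distance_nt)
  # (lo, hi] bins: value v belongs to bin index ceiling(v / bin_nt)
  idx <- ceiling(signed / bin_nt)
  rng <- range(idx)
  all_idx <- seq(rng[1], rng[2])
  counts <- vapply(all_idx, function(k) sum(idx == k), integer(1))
  data.frame(bin_lo = (all_idx - 1L) * bin_nt, bin_hi = all_idx * bin_nt,
             count = counts)
}

#' Independence of lncRNA response from transcript length and expression
#'
#' Pearson correlations of log2 fold change against log10 transcript length
#' and against log10 expression level.
#'
#' @param lnc_fc numeric vector of log2 fold changes.
#' @param lengths transcript lengths in nt, aligned with `lnc_fc`.
#' @param expression expression levels (e.g. control RPKM), aligned.
#' @return List with `length_cor` and `expression_cor`, both `test_result`s.
#' @export
independence_diagnostics <- function(lnc_fc, lengths, expression) {
  if (length(lnc_fc) != length(lengths) ||
      length(lnc_fc) != length(expression)) {
    stop("input vectors must have equal length")
  }
  if (var(lnc_fc[is.finite(lnc_fc)]) == 0) stop("zero variance in fold changes")
  run <- function(y, what) {
    ok <- is.finite(lnc_fc) & is.finite(y) & y > 0
    ct <- cor.test(lnc_fc[ok], log10(y[ok]), method = "pearson")
    test_result(unname(ct$estimate), ct$p.value,
                paste("Pearson correlation of log2 FC vs", what),
                n = sum(ok))
  }
  list(length_cor = run(lengths, "log10 length"),
       expression_cor = run(expression, "log10 expression"))
}
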