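# Independent brute-force oracles, kept deliberately naive and separate
# from the implementation paths they check.

# per-nucleotide boolean-array union of exon intervals (0-based half-open)
oracle_union <- function(starts, ends) {
  lo <- min(starts)
  hi <- max(ends)
  covered <- logical(hi - lo)
  for (i in seq_along(starts)) {
    covered[(starts[i] - lo + 1):(ends[i] - lo)] <- TRUE
  }
  r <- rle(covered)
  pos <- lo + cumsum(c(0, r$lengths))
  keep <- which(r$values)
  data.frame(start = pos[keep], end = pos[keep + 1])
}

# exhaustive O(n^2) containment scan; returns ids that should be removed
# under the deduplication rule (contained in a retained gene)
oracle_contained_pairs <- function(genes) {
  bad <- logical(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    for (j in seq_len(nrow(genes))) {
      if (i == j || genes$chrom[i] != genes$chrom[j]) next
      same_span <- genes$start[i] == genes$start[j] &&
        genes$end[i] == genes$end[j]
      inside <- genes$start[i] >= genes$start[j] &&
        genes$end[i] <= genes$end[j]
      if (inside && (!same_span || genes$gene_id[i] > genes$gene_id[j])) {
        bad[i] <- TRUE
      }
    }
  }
  genes$gene_id[bad]
}

# per-fragment brute-force exonic counting
oracle_count <- function(fragments, locus) {
  ids <- unique(fragments$fragment_id[fragments$chrom == locus$chrom])
  n <- 0L
  for (id in ids) {
    bl <- fragments[fragments$fragment_id == id &
                      fragments$chrom == locus$chrom, , drop = FALSE]
    if (min(bl$start) < locus$span[["start"]] ||
        max(bl$end) > locus$span[["end"]]) next
    hit <- FALSE
    for (b in seq_len(nrow(bl))) {
      for (u in seq_len(nrow(locus$exonic_union))) {
        ov <- min(bl$end[b], locus$exonic_union$end[u]) -
          max(bl$start[b], locus$exonic_union$start[u])
        if (ov >= 1) hit <- TRUE
      }
    }
    if (hit) n <- n + 1L
  }
  n
}

# full hypergeometric enumeration for a 2x2 Fisher two-sided p
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  p_obs <- dhyper(tab[1, 1], r1, r2, c1)
  p <- 0
  for (a in max(0, c1 - r2):min(r1, c1)) {
    pa <- dhyper(a, r1, r2, c1)
    if (pa <= p_obs * (1 + 1e-7)) p <- p + pa
  }
  p
}

# exhaustive nearest-TSS scan over all (lnc, coding) pairs
oracle_nearest <- function(lnc_genes, coding_genes) {
  out <- vector("list", nrow(lnc_genes))
  for (i in seq_len(nrow(lnc_genes))) {
    s <- lnc_genes$start[i]; e <- lnc_genes$end[i]
    best_d <- Inf; best_id <- NA_character_
    for (j in seq_len(nrow(coding_genes))) {
      if (coding_genes$chrom[j] != lnc_genes$chrom[i]) next
      tss <- if (coding_genes$strand[j] == "+") coding_genes$start[j]
             else coding_genes$end[j] - 1L
      d <- if (tss < s) s - tss else if (tss > e) tss - e else 0L
      if (d < best_d || (d == best_d && !is.na(best_id) &&
                         coding_genes$gene_id[j] < best_id)) {
        best_d <- d; best_id <- coding_genes$gene_id[j]
      }
    }
    out[[i]] <- data.frame(lnc_gene_id = lnc_genes$gene_id[i],
                           coding_gene_id = best_id,
                           distance_nt = if (is.finite(best_d)) best_d
                                         else NA_integer_)
  }
  do.call(rbind, out)
}

# quick builder for a catalog from a span table (single-exon genes unless
# an exon table is supplied)
make_catalog <- function(genes, exons = NULL) {
  defaults <- list(source = "t", biotype = "other", has_protein_id = FALSE)
  for (nm in names(defaults)) {
    if (is.null(genes[[nm]])) genes[[nm]] <- defaults[[nm]]
  }
  if (is.null(exons)) {
    exons <- data.frame(gene_id = genes$gene_id, isoform = genes$gene_id,
                        start = genes$start, end = genes$end)
  }
  gene_catalog(genes, exons)
}

random_span_genes <- function(n, chrom_len = 10000, chroms = "c1",
                              prefix = "G") {
  start <- sample.int(chrom_len - 100, n, replace = TRUE)
  width <- sample.int(500, n, replace = TRUE)
  data.frame(gene_id = sprintf("%s%03d", prefix, seq_len(n)),
             chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + width,
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}
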