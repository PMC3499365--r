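# Fragment-level quantification: read filtering, exonic counting within
# maximal loci, RPKM, expression filtering and fold-change calls.

#' Filter and trim sequencing reads
#'
#' Applies the pre-alignment filters used for 100-bp paired-end libraries:
#' reads containing an adapter match strictly longer than
#' `max_adapter_match_nt` are removed; terminal bases with quality below
#' `quality_floor` are trimmed from both ends; reads shorter than
#' `min_len_nt` after trimming are discarded. Input order is preserved.
#'
#' An adapter match is the longest exact match, anywhere in the read,
#' between the read and a prefix of the adapter (truncated at the read end,
#' as for read-through at the 3' end).
#'
#' @param reads data.frame with columns `read_id`, `sequence`, `qualities`
#'   (list column of integer Phred scores, or a single string of
#'   Phred+33 characters per read).
#' @param adapter adapter sequence (non-empty).
#' @param max_adapter_match_nt longest tolerated adapter match (default 11;
#'   matches of 12 nt or more cause removal).
#' @param quality_floor minimum terminal base quality (default 20).
#' @param min_len_nt minimum read length after trimming (default 32; reads
#'   of 31 nt or less are discarded).
#'
#' @return The filtered `reads` data.frame (trimmed sequences/qualities).
#' @export
filter_reads <- function(reads, adapter, max_adapter_match_nt = 11L,
                         quality_floor = 20L, min_len_nt = 32L) {
  if (!nzchar(adapter)) stop("adapter must be non-empty")
  if (nrow(reads) == 0) return(reads)
  quals <- decode_quals(reads$qualities)
  keep <- logical(nrow(reads))
  seq_out <- character(nrow(reads))
  qual_out <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    s <- reads$sequence[[i]]
    if (longest_adapter_match(s, adapter) > max_adapter_match_nt) next
    q <- quals[[i]]
    lo <- 1L; hi <- length(q)
    while (lo <= hi && q[lo] < quality_floor) lo <- lo + 1L
    while (hi >= lo && q[hi] < quality_floor) hi <- hi - 1L
    if (hi - lo + 1L < min_len_nt) next
    keep[i] <- TRUE
    seq_out[i] <- substr(s, lo, hi)
    qual_out[[i]] <- q[lo:hi]
  }
  out <- reads[keep, , drop = FALSE]
  out$sequence <- seq_out[keep]
  out$qualities <- qual_out[keep]
  rownames(out) <- NULL
  out
}

decode_quals <- function(q) {
  if (is.list(q)) return(q)
  lapply(q, function(s) as.integer(charToRaw(s)) - 33L)
}

longest_adapter_match <- function(read, adapter) {
  n <- nchar(read); m <- nchar(adapter)
  best <- 0L
  rch <- strsplit(read, "", fixed = TRUE)[[1]]
  ach <- strsplit(adapter, "", fixed = TRUE)[[1]]
  for (start in seq_len(n)) {
    len <- 0L
    while (start + len <= n && len < m && rch[start + len] == ach[len + 1L]) {
      len <- len + 1L
    }
    if (len > best) best <- len
    if (best == m) break
  }
  best
}

#' Count exonic fragments within a maximal locus
#'
#' A fragment is counted for a gene when its outer span lies entirely within
#' the gene's maximal locus span and at least one of its aligned blocks
#' overlaps the locus's exonic union by >= 1 nt ("exonic reads mapping
#' within the maximal genomic locus"). Each fragment counts at most once per
#' gene.
#'
#' @param fragments data.frame of aligned blocks with columns `fragment_id`,
#'   `chrom`, `start`, `end` (0-based half-open; one row per block, several
#'   rows per spliced fragment).
#' @param locus a `maximal_locus` from [build_maximal_locus()].
#' @return Integer fragment count.
#' @export
count_exonic_fragments <- function(fragments, locus) {
  fr <- fragments[fragments$chrom == locus$chrom, , drop = FALSE]
  if (nrow(fr) == 0) return(0L)
  outer_start <- tapply(fr$start, fr$fragment_id, min)
  outer_end <- tapply(fr$end, fr$fragment_id, max)
  inside <- names(outer_start)[outer_start >= locus$span[["start"]] &
                               outer_end <= locus$span[["end"]]]
  if (length(inside) == 0) return(0L)
  fr <- fr[fr$fragment_id %in% inside, , drop = FALSE]
  bl <- IRanges::IRanges(fr$start + 1L, fr$end)
  un <- IRanges::IRanges(locus$exonic_union$start + 1L, locus$exonic_union$end)
  hit <- IRanges::overlapsAny(bl, un, minoverlap = 1L)
  length(unique(fr$fragment_id[hit]))
}

#' Reads per kilobase of transcript per million mapped reads
#'
#' `count / (exonic_length_nt/1000) / (library_size/1e6)`: expression
#' normalized by the length of the counting territory and sequencing depth.
#'
#' @param count non-negative fragment count (vectorized).
#' @param exonic_length_nt exonic-union length in nucleotides (> 0).
#' @param library_size total counted fragments in the sample (> 0).
#' @return RPKM value(s).
#' @export
compute_rpkm <- function(count, exonic_length_nt, library_size) {
  if (any(exonic_length_nt <= 0)) stop("exonic_length_nt must be > 0")
  if (any(library_size <= 0)) stop("library_size must be > 0")
  count / (exonic_length_nt / 1000) / (library_size / 1e6)
}

#' Build a per-gene, per-sample expression table
#'
#' @param counts matrix or data.frame of counts, genes in rows (rownames =
#'   gene ids), samples in columns.
#' @param exonic_length_nt named vector of exonic lengths covering every gene.
#' @param library_sizes optional named vector per sample; defaults to column
#'   sums of `counts`.
#' @return Long-format data.frame: `gene_id`, `sample_id`, `count`,
#'   `exonic_length_nt`, `library_size`, `rpkm`.
#' @export
expression_table <- function(counts, exonic_length_nt, library_sizes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(library_sizes)) library_sizes <- colSums(counts)
  missing_len <- setdiff(rownames(counts), names(exonic_length_nt))
  if (length(missing_len) > 0) {
    stop("no exonic length for gene(s): ", paste(head(missing_len, 3), collapse = ", "))
  }
  len <- exonic_length_nt[rownames(counts)]
  out <- do.call(rbind, lapply(colnames(counts), function(s) {
    data.frame(gene_id = rownames(counts), sample_id = s,
               count = counts[, s], exonic_length_nt = unname(len),
               library_size = unname(library_sizes[[s]]),
               stringsAsFactors = FALSE)
  }))
  out$rpkm <- compute_rpkm(out$count, out$exonic_length_nt, out$library_size)
  rownames(out) <- NULL
  out
}

#' Genes expressed above a minimum level
#'
#' A gene is retained iff its RPKM is strictly greater than `min_rpkm` in at
#' least one sample (the RPKM > 1 cutoff).
#'
#' @param table expression table from [expression_table()]; every gene must
#'   have a record in every sample.
#' @param min_rpkm expression floor (default 1.0, strict).
#' @return Character vector of expressed gene ids.
#' @export
expression_filter <- function(table, min_rpkm = 1.0) {
  n_samples <- length(unique(table$sample_id))
  per_gene <- table(table$gene_id)
  bad <- names(per_gene)[per_gene != n_samples]
  if (length(bad) > 0) {
    stop("gene(s) missing a sample record: ", paste(head(bad, 3), collapse = ", "))
  }
  mx <- tapply(table$rpkm, table$gene_id, max)
  sort(names(mx)[mx > min_rpkm])
}

#' Fold changes between depleted and control samples
#'
#' For each gene, `fc = (rpkm_depleted + pseudocount) / (rpkm_control +
#' pseudocount)`. Direction is `up` when `fc > fc_threshold`, `down` when
#' `fc < 1/fc_threshold`, else `unchanged` ("more than a 2-fold change" is
#' strict). Genes are expected to be pre-filtered with [expression_filter()];
#' with `pseudocount = 0` a gene at zero in one sample yields an infinite or
#' zero fold change, which is kept (and excluded from moment statistics
#' downstream).
#'
#' @param table expression table from [expression_table()].
#' @param control_sample,depleted_sample sample ids present in `table`.
#' @param fc_threshold fold-change call threshold (default 2.0, strict).
#' @param pseudocount added to both RPKMs before the ratio (default 0;
#'   use e.g. 0.1 to keep log2 fold changes finite for distribution plots).
#' @param genes optional gene subset (e.g. the output of
#'   [expression_filter()]); default all genes in `table`.
#' @return data.frame: `gene_id`, `rpkm_control`, `rpkm_depleted`, `fc`,
#'   `log2fc`, `direction`.
#' @export
fold_changes <- function(table, control_sample, depleted_sample,
                         fc_threshold = 2.0, pseudocount = 0,
                         genes = NULL) {
  ctl <- table[table$sample_id == control_sample, , drop = FALSE]
  dep <- table[table$sample_id == depleted_sample, , drop = FALSE]
  if (nrow(ctl) == 0 || nrow(dep) == 0) stop("sample id not found in table")
  if (is.null(genes)) genes <- sort(unique(table$gene_id))
  ctl <- setNames(ctl$rpkm, ctl$gene_id)[genes]
  dep <- setNames(dep$rpkm, dep$gene_id)[genes]
  if (any(is.na(ctl)) || any(is.na(dep))) stop("gene missing from a sample")
  if (any(ctl < 0) || any(dep < 0)) stop("negative RPKM")
  fc <- (dep + pseudocount) / (ctl + pseudocount)
  direction <- ifelse(fc > fc_threshold, "up",
                      ifelse(fc < 1 / fc_threshold, "down", "unchanged"))
  data.frame(gene_id = genes, rpkm_control = unname(ctl),
             rpkm_depleted = unname(dep), fc = unname(fc),
             log2fc = log2(unname(fc)), direction = unname(direction),
             stringsAsFactors = FALSE)
}

#' Count fragments for every gene of a catalog
#'
#' Vectorized wrapper around [count_exonic_fragments()]: builds each gene's
#' maximal locus and counts the fragments of each sample within it.
#'
#' @param catalog a [gene_catalog].
#' @param fragments_by_sample named list of fragment block data.frames, one
#'   per sample (see [count_exonic_fragments()]).
#' @return Count matrix, genes x samples.
#' @export
count_matrix <- function(catalog, fragments_by_sample) {
  ids <- catalog$genes$gene_id
  m <- matrix(0L, nrow = length(ids), ncol = length(fragments_by_sample),
              dimnames = list(ids, names(fragments_by_sample)))
  loci <- lapply(ids, function(id) build_maximal_locus(catalog, id))
  for (s in names(fragments_by_sample)) {
    fr <- fragments_by_sample[[s]]
    for (j in seq_along(loci)) {
      m[j, s] <- count_exonic_fragments(fr, loci[[j]])
    }
  }
  m
}
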