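# Internal coordinate convention: 0-based, half-open [start, end).
# GTF input (1-based, closed) is converted at the I/O boundary; BED is native.

#' Construct a gene catalog
#'
#' A `gene_catalog` is the container used throughout the pipeline for a set
#' of annotated genes. It holds one row per gene (span, strand, biotype
#' evidence, spliced exonic length) plus an exon table with one row per exon
#' per isoform. All coordinates are 0-based half-open.
#'
#' @param genes data.frame with columns `gene_id`, `source`, `chrom`,
#'   `start`, `end`, `strand`, `biotype`, `has_protein_id`. Column
#'   `exonic_length` is recomputed from `exons`.
#' @param exons data.frame with columns `gene_id`, `isoform`, `start`, `end`.
#'   Every `gene_id` must appear in `genes`; exon intervals must satisfy
#'   `start < end`.
#' @param provenance character vector of source file paths (bookkeeping).
#'
#' @return An object of class `gene_catalog`.
#' @export
gene_catalog <- function(genes, exons, provenance = character()) {
  req <- c("gene_id", "source", "chrom", "start", "end", "strand",
           "biotype", "has_protein_id")
  missing_cols <- setdiff(req, names(genes))
  if (length(missing_cols) > 0) {
    stop("gene table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(genes$gene_id)) {
    dup <- genes$gene_id[duplicated(genes$gene_id)][1]
    stop("duplicate gene_id in catalog: ", dup)
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    bad <- setdiff(unique(genes$strand), c("+", "-"))
    stop("unknown strand symbol: ", paste(bad, collapse = ", "))
  }
  if (any(genes$start >= genes$end)) stop("gene span must satisfy start < end")
  if (nrow(exons) > 0) {
    if (!all(exons$gene_id %in% genes$gene_id)) {
      stop("exon table references unknown gene_id")
    }
    if (any(exons$start >= exons$end)) stop("exon must satisfy start < end")
  }
  genes <- genes[order(genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  genes$exonic_length <- exonic_lengths(exons, genes$gene_id)
  structure(list(genes = genes, exons = exons,
                 provenance = as.character(provenance)),
            class = "gene_catalog")
}

#' @export
print.gene_catalog <- function(x, ...) {
  cat(sprintf("gene_catalog: %d genes (%d coding, %d lncRNA) from %d source(s)\n",
              nrow(x$genes), sum(x$genes$biotype == "coding"),
              sum(x$genes$biotype == "lncRNA"),
              length(unique(x$genes$source))))
  invisible(x)
}

#' @export
length.gene_catalog <- function(x) nrow(x$genes)

# exonic-union length per gene_id, in gene_id order
exonic_lengths <- function(exons, gene_ids) {
  out <- setNames(integer(length(gene_ids)), gene_ids)
  if (nrow(exons) == 0) return(unname(out))
  by_gene <- split(IRanges::IRanges(exons$start + 1L, exons$end),
                   factor(exons$gene_id, levels = gene_ids))
  red <- IRanges::reduce(IRanges::IRangesList(by_gene))
  unname(vapply(red, function(ir) sum(IRanges::width(ir)), integer(1)))
}

# spans as a GRanges (1-based internally to GRanges only)
catalog_spans <- function(catalog, ignore_strand = FALSE) {
  g <- catalog$genes
  GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges::IRanges(g$start + 1L, g$end),
    strand = if (ignore_strand) "*" else g$strand,
    gene_id = g$gene_id
  )
}

#' Load gene annotations from GTF and BED files
#'
#' Reads one or more annotation files into a single [gene_catalog], tagging
#' each record with its source. GTF coordinates (1-based, closed) are
#' converted to the internal 0-based half-open convention; BED is already
#' native. Gene identifiers are prefixed with their source tag
#' (`"source:gene_id"`) so the same id arriving from two databases never
#' collides.
#'
#' @param files character vector of file paths.
#' @param sources character vector of source tags, one per file.
#' @param dialects character vector, one per file: `"gtf"`, `"bed6"` or
#'   `"bed12"`.
#' @param biotype biotype assigned to all records of each file: `"coding"`,
#'   `"lncRNA"` or `"other"` (recycled to the number of files).
#' @param has_protein_id logical, recycled: whether records of each file
#'   carry protein-ID evidence.
#'
#' @return A [gene_catalog]. Malformed lines raise an error naming the file
#'   and line number.
#' @export
load_annotations <- function(files, sources, dialects,
                             biotype = "other", has_protein_id = FALSE) {
  stopifnot(length(files) == length(sources), length(files) == length(dialects))
  biotype <- rep_len(biotype, length(files))
  has_protein_id <- rep_len(has_protein_id, length(files))
  genes_l <- list(); exons_l <- list()
  for (i in seq_along(files)) {
    parsed <- switch(dialects[[i]],
      gtf = read_gtf_genes(files[[i]]),
      bed6 = read_bed_genes(files[[i]], blocks = FALSE),
      bed12 = read_bed_genes(files[[i]], blocks = TRUE),
      stop("unknown dialect: ", dialects[[i]])
    )
    pre <- paste0(sources[[i]], ":")
    parsed$genes$gene_id <- paste0(pre, parsed$genes$gene_id)
    parsed$exons$gene_id <- paste0(pre, parsed$exons$gene_id)
    parsed$genes$source <- sources[[i]]
    parsed$genes$biotype <- biotype[[i]]
    parsed$genes$has_protein_id <- has_protein_id[[i]]
    genes_l[[i]] <- parsed$genes
    exons_l[[i]] <- parsed$exons
  }
  gene_catalog(do.call(rbind, genes_l), do.call(rbind, exons_l),
               provenance = files)
}

# Validates field shape line-by-line (for error locality), then delegates
# coordinate semantics to rtracklayer.
validate_lines <- function(file, min_fields, strand_field) {
  lines <- readLines(file)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  for (i in which(keep)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < min_fields) {
      stop(sprintf("malformed line in %s at line %d: expected >=%d fields, got %d",
                   file, i, min_fields, length(f)))
    }
    if (!is.na(strand_field) && !(f[[strand_field]] %in% c("+", "-"))) {
      stop(sprintf("unknown strand symbol '%s' in %s at line %d",
                   f[[strand_field]], file, i))
    }
  }
  invisible(TRUE)
}

read_gtf_genes <- function(file) {
  validate_lines(file, min_fields = 9L, strand_field = 7L)
  gr <- rtracklayer::import(file, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0) stop("no exon records in ", file)
  # rtracklayer yields 1-based closed GRanges; shift to 0-based half-open
  ex <- data.frame(
    gene_id = as.character(gr$gene_id),
    isoform = as.character(gr$transcript_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  genes <- do.call(rbind, lapply(split(ex, ex$gene_id), function(d) {
    data.frame(gene_id = d$gene_id[[1]], chrom = d$chrom[[1]],
               start = min(d$start), end = max(d$end),
               strand = d$strand[[1]], stringsAsFactors = FALSE)
  }))
  rownames(genes) <- NULL
  list(genes = genes, exons = ex[c("gene_id", "isoform", "start", "end")])
}

read_bed_genes <- function(file, blocks = FALSE) {
  validate_lines(file, min_fields = if (blocks) 12L else 6L, strand_field = 6L)
  gr <- rtracklayer::import(file, format = "bed")
  nm <- as.character(gr$name)
  if (anyDuplicated(nm)) stop("duplicate gene names within ", file)
  genes <- data.frame(
    gene_id = nm,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  if (blocks && !is.null(gr$blocks)) {
    bl <- gr$blocks # IRangesList, 1-based relative to chromStart
    n <- S4Vectors::elementNROWS(bl)
    flat <- unlist(bl, use.names = FALSE)
    off <- rep(genes$start, n)
    exons <- data.frame(
      gene_id = rep(nm, n),
      isoform = rep(nm, n),
      start = off + IRanges::start(flat) - 1L,
      end = off + IRanges::end(flat),
      stringsAsFactors = FALSE
    )
  } else {
    exons <- data.frame(gene_id = nm, isoform = nm,
                        start = genes$start, end = genes$end,
                        stringsAsFactors = FALSE)
  }
  list(genes = genes, exons = exons)
}

#' Maximal genomic locus of one gene
#'
#' The maximal locus is the counting territory for expression
#' quantification: the span covering all of a gene's known isoforms,
#' together with the disjoint union of their exons and the spliced
#' (exonic-union) length in nucleotides.
#'
#' @param catalog a [gene_catalog].
#' @param gene_id gene identifier present in `catalog`.
#'
#' @return A list of class `maximal_locus` with elements `gene_id`, `chrom`,
#'   `strand`, `span` (length-2 integer, 0-based half-open), `exonic_union`
#'   (data.frame `start`/`end`, disjoint and sorted) and `exonic_length_nt`.
#' @export
build_maximal_locus <- function(catalog, gene_id) {
  g <- catalog$genes[catalog$genes$gene_id == gene_id, , drop = FALSE]
  if (nrow(g) == 0) stop("unknown gene_id: ", gene_id)
  ex <- catalog$exons[catalog$exons$gene_id == gene_id, , drop = FALSE]
  if (nrow(ex) == 0) stop("gene ", gene_id, " has no isoforms/exons")
  ir <- IRanges::reduce(IRanges::IRanges(ex$start + 1L, ex$end))
  union <- data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  structure(list(
    gene_id = gene_id, chrom = g$chrom, strand = g$strand,
    span = c(start = min(union$start), end = max(union$end)),
    exonic_union = union,
    exonic_length_nt = sum(union$end - union$start)
  ), class = "maximal_locus")
}

#' Remove genes completely contained within another gene
#'
#' Redundancy removal for compiled catalogs: a gene is dropped when its span
#' is completely contained within the span of another retained gene on the
#' same chromosome. Containment is strand-agnostic and span-based. Two genes
#' with identical spans tie-break deterministically: the lexicographically
#' larger `gene_id` is removed. Idempotent.
#'
#' @param catalog a [gene_catalog].
#' @return The deduplicated [gene_catalog].
#' @export
deduplicate <- function(catalog) {
  g <- catalog$genes
  if (nrow(g) <= 1) return(catalog)
  # widest first; ties by gene_id so the lexicographically smaller survives
  ord <- order(-(g$end - g$start), g$gene_id)
  g <- g[ord, , drop = FALSE]
  spans <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start + 1L, g$end))
  keep <- logical(nrow(g))
  kept_idx <- integer(0)
  for (i in seq_len(nrow(g))) {
    contained <- FALSE
    if (length(kept_idx) > 0) {
      hits <- GenomicRanges::findOverlaps(spans[i], spans[kept_idx],
                                          type = "within", ignore.strand = TRUE)
      contained <- length(hits) > 0
    }
    if (!contained) {
      keep[i] <- TRUE
      kept_idx <- c(kept_idx, i)
    }
  }
  ids <- g$gene_id[keep]
  subset_catalog(catalog, ids)
}

subset_catalog <- function(catalog, gene_ids) {
  genes <- catalog$genes[catalog$genes$gene_id %in% gene_ids, , drop = FALSE]
  exons <- catalog$exons[catalog$exons$gene_id %in% gene_ids, , drop = FALSE]
  gene_catalog(genes, exons, provenance = catalog$provenance)
}

#' Compile the lncRNA gene set from multiple annotation sources
#'
#' Unions several source catalogs (ids already source-prefixed by
#' [load_annotations]), eliminates redundancies with the containment rule of
#' [deduplicate], and keeps only genes whose spliced (exonic-union) length
#' exceeds `min_len_nt` — the conventional >200 nt definition of a lncRNA.
#'
#' @param catalogs list of [gene_catalog] objects.
#' @param min_len_nt minimum spliced length, strict inequality (default 200).
#' @return A [gene_catalog] of lncRNA genes (`biotype` forced to `"lncRNA"`).
#' @export
build_lncrna_set <- function(catalogs, min_len_nt = 200L) {
  stopifnot(length(catalogs) >= 1)
  genes <- do.call(rbind, lapply(catalogs, function(x) x$genes))
  exons <- do.call(rbind, lapply(catalogs, function(x) x$exons))
  # identical records contributed by several sources collapse to one copy
  key <- paste(sub("^[^:]*:", "", genes$gene_id), genes$chrom,
               genes$start, genes$end, genes$strand)
  first <- !duplicated(key)
  genes <- genes[first, , drop = FALSE]
  exons <- exons[exons$gene_id %in% genes$gene_id, , drop = FALSE]
  genes$biotype <- "lncRNA"
  merged <- gene_catalog(genes, exons,
                         provenance = unlist(lapply(catalogs, `[[`, "provenance")))
  merged <- deduplicate(merged)
  keep <- merged$genes$gene_id[merged$genes$exonic_length > min_len_nt]
  subset_catalog(merged, keep)
}

#' Partition a catalog into coding and lncRNA-nonoverlapping coding sets
#'
#' `coding` is every record carrying protein-ID evidence; `coding_nonoverlapping`
#' additionally excludes coding genes whose span overlaps any lncRNA span by
#' at least one nucleotide, i.e. loci that also harbor an annotated ncRNA.
#'
#' @param catalog a [gene_catalog] (the candidate coding set).
#' @param lnc a [gene_catalog] of lncRNA genes.
#' @return List with elements `coding` and `coding_nonoverlapping`, both
#'   [gene_catalog]s.
#' @export
partition_coding_noncoding <- function(catalog, lnc) {
  coding_ids <- catalog$genes$gene_id[catalog$genes$has_protein_id]
  coding <- subset_catalog(catalog, coding_ids)
  if (length(coding) == 0 || length(lnc) == 0) {
    return(list(coding = coding, coding_nonoverlapping = coding))
  }
  # suppress the seqlevel-mismatch warning: disjoint chromosome sets
  # between the two catalogs simply mean no overlap is possible there
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(catalog_spans(coding), catalog_spans(lnc),
                                minoverlap = 1L, ignore.strand = TRUE))
  overl <- coding$genes$gene_id[unique(S4Vectors::queryHits(hits))]
  list(coding = coding,
       coding_nonoverlapping = subset_catalog(coding,
                                              setdiff(coding_ids, overl)))
}

#' Write a catalog as BED12 (blocks = exonic union) and read it back
#'
#' One BED12 line per gene; blocks are the gene's exonic union, so a
#' round-trip through [read_catalog_bed12()] reconstructs spans, strands and
#' exonic unions exactly.
#'
#' @param catalog a [gene_catalog].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_catalog_bed12 <- function(catalog, file) {
  g <- catalog$genes
  rows <- character(nrow(g))
  for (i in seq_len(nrow(g))) {
    loc <- build_maximal_locus(catalog, g$gene_id[[i]])
    u <- loc$exonic_union
    rows[[i]] <- paste(
      g$chrom[[i]], loc$span[["start"]], loc$span[["end"]], g$gene_id[[i]],
      0, g$strand[[i]], loc$span[["start"]], loc$span[["start"]], "0",
      nrow(u),
      paste0(paste(u$end - u$start, collapse = ","), ","),
      paste0(paste(u$start - loc$span[["start"]], collapse = ","), ","),
      sep = "\t")
  }
  writeLines(rows, file)
  invisible(file)
}

#' @rdname write_catalog_bed12
#' @param source source tag for reloaded records (default `"bed"`); set to
#'   `NA` to keep ids unprefixed.
#' @param biotype,has_protein_id record metadata, as in [load_annotations].
#' @export
read_catalog_bed12 <- function(file, source = NA, biotype = "other",
                               has_protein_id = FALSE) {
  parsed <- read_bed_genes(file, blocks = TRUE)
  if (!is.na(source)) {
    parsed$genes$gene_id <- paste0(source, ":", parsed$genes$gene_id)
    parsed$exons$gene_id <- paste0(source, ":", parsed$exons$gene_id)
    parsed$genes$source <- source
  } else {
    parsed$genes$source <- "bed"
  }
  parsed$genes$biotype <- biotype
  parsed$genes$has_protein_id <- has_protein_id
  gene_catalog(parsed$genes, parsed$exons, provenance = file)
}

#' Write the catalog manifest as TSV
#'
#' @param catalog a [gene_catalog].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_catalog_tsv <- function(catalog, file) {
  g <- catalog$genes[, c("gene_id", "source", "chrom", "start", "end",
                         "strand", "exonic_length", "biotype")]
  utils::write.table(g, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
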