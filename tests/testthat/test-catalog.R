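# Catalog construction: dialect conversion, maximal loci, redundancy
# removal, lncRNA set compilation and the coding/noncoding partition.

test_that("BED and GTF loaders agree on the internal coordinate convention", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("c1\t100\t200\tgA\t0\t+", "c1\t500\t900\tgB\t0\t-"), bed)
  cat_bed <- load_annotations(bed, sources = "s", dialects = "bed6")
  expect_equal(length(cat_bed), 2L)
  expect_equal(cat_bed$genes$start, c(100L, 500L))
  expect_equal(cat_bed$genes$end, c(200L, 900L))

  gtf <- tempfile(fileext = ".gtf")
  writeLines(paste("c1", "src", "exon", "101", "200", ".", "+", ".",
                   'gene_id "gA"; transcript_id "gA.1";', sep = "\t"), gtf)
  cat_gtf <- load_annotations(gtf, sources = "s", dialects = "gtf")
  # 1-based closed [101, 200] becomes 0-based half-open [100, 200)
  expect_equal(cat_gtf$genes$start, 100L)
  expect_equal(cat_gtf$genes$end, 200L)
  expect_equal(cat_gtf$genes$exonic_length, 100L)
})

test_that("same gene_id from two sources is disambiguated by prefixing", {
  f1 <- tempfile(fileext = ".bed"); f2 <- tempfile(fileext = ".bed")
  writeLines("c1\t0\t100\tG1\t0\t+", f1)
  writeLines("c2\t0\t100\tG1\t0\t+", f2)
  cat2 <- load_annotations(c(f1, f2), sources = c("srcA", "srcB"),
                           dialects = c("bed6", "bed6"))
  expect_setequal(cat2$genes$gene_id, c("srcA:G1", "srcB:G1"))
})

test_that("malformed lines are reported with file and line number", {
  bad <- tempfile(fileext = ".bed")
  writeLines(c("c1\t0\t100\tgA\t0\t+", "c1\t200"), bad)
  expect_error(load_annotations(bad, "s", "bed6"), "line 2")
  badstrand <- tempfile(fileext = ".bed")
  writeLines("c1\t0\t100\tgA\t0\t?", badstrand)
  expect_error(load_annotations(badstrand, "s", "bed6"), "strand")
})

test_that("maximal locus merges isoform exons into a minimal union", {
  ct <- make_catalog(
    data.frame(gene_id = "g", chrom = "c1", start = 0L, end = 150L,
               strand = "+"),
    exons = data.frame(gene_id = "g", isoform = c("i1", "i2"),
                       start = c(0L, 50L), end = c(100L, 150L)))
  loc <- build_maximal_locus(ct, "g")
  expect_equal(loc$exonic_union, data.frame(start = 0L, end = 150L))
  expect_equal(loc$exonic_length_nt, 150L)

  ct2 <- make_catalog(
    data.frame(gene_id = "g", chrom = "c1", start = 0L, end = 150L,
               strand = "+"),
    exons = data.frame(gene_id = "g", isoform = "i1",
                       start = c(0L, 100L), end = c(50L, 150L)))
  loc2 <- build_maximal_locus(ct2, "g")
  expect_equal(nrow(loc2$exonic_union), 2L)
  expect_equal(loc2$exonic_length_nt, 100L)
})

test_that("exonic union equals the per-nucleotide boolean-array oracle", {
  set.seed(11)
  for (rep in 1:20) {
    n_iso <- sample(1:5, 1)
    starts <- integer(0); ends <- integer(0); iso <- character(0)
    for (k in seq_len(n_iso)) {
      n_ex <- sample(1:4, 1)
      s <- sort(sample.int(2000, n_ex))
      e <- s + sample.int(300, n_ex, replace = TRUE)
      starts <- c(starts, s); ends <- c(ends, e)
      iso <- c(iso, rep(paste0("i", k), n_ex))
    }
    ct <- make_catalog(
      data.frame(gene_id = "g", chrom = "c1", start = min(starts),
                 end = max(ends), strand = "+"),
      exons = data.frame(gene_id = "g", isoform = iso,
                         start = starts, end = ends))
    loc <- build_maximal_locus(ct, "g")
    orc <- oracle_union(starts, ends)
    expect_equal(loc$exonic_union$start, orc$start)
    expect_equal(loc$exonic_union$end, orc$end)
    expect_equal(loc$exonic_length_nt, sum(orc$end - orc$start))
  }
})

test_that("deduplication removes contained genes, tie-breaks equal spans, and is idempotent", {
  ct <- make_catalog(data.frame(
    gene_id = c("A", "B", "C", "D", "E"),
    chrom = c("c1", "c1", "c1", "c2", "c1"),
    start = c(0L, 10L, 200L, 10L, 0L),
    end = c(100L, 20L, 300L, 20L, 100L),
    strand = c("+", "-", "+", "+", "-")))
  dd <- deduplicate(ct)
  # B is inside A (strand-agnostic); D shares B's coords on another chrom;
  # E's span equals A's, so the lexicographically larger id (E) is removed
  expect_setequal(dd$genes$gene_id, c("A", "C", "D"))
  expect_identical(deduplicate(dd)$genes, dd$genes)
})

test_that("after deduplication an exhaustive containment scan finds nothing", {
  set.seed(23)
  for (rep in 1:5) {
    ct <- make_catalog(random_span_genes(120, chroms = c("c1", "c2")))
    dd <- deduplicate(ct)
    expect_length(oracle_contained_pairs(dd$genes), 0)
    # every removed gene really is contained in some retained gene
    removed <- setdiff(ct$genes$gene_id, dd$genes$gene_id)
    for (id in removed) {
      g <- ct$genes[ct$genes$gene_id == id, ]
      host <- dd$genes[dd$genes$chrom == g$chrom &
                         dd$genes$start <= g$start & dd$genes$end >= g$end, ]
      expect_gt(nrow(host), 0)
    }
  }
})

test_that("lncRNA set enforces strict spliced-length cutoff and union semantics", {
  mk <- function(src, ids, starts, lens) {
    make_catalog(data.frame(gene_id = paste0(src, ":", ids), chrom = "c1",
                            start = starts, end = starts + lens,
                            strand = "+", source = src))
  }
  c1 <- mk("a", c("n1", "n2", "shared"), c(0L, 10000L, 20000L),
           c(150L, 201L, 500L))
  c2 <- mk("b", c("n3", "shared"), c(40000L, 20000L), c(200L, 500L))
  lset <- build_lncrna_set(list(c1, c2), min_len_nt = 200L)
  ids <- sub("^[ab]:", "", lset$genes$gene_id)
  expect_false("n1" %in% ids)       # 150 nt: too short
  expect_false("n3" %in% ids)       # exactly 200 nt: strict inequality
  expect_true("n2" %in% ids)        # 201 nt: retained
  expect_equal(sum(ids == "shared"), 1L)  # one copy across sources
  expect_true(all(lset$genes$exonic_length > 200L))
  expect_true(all(lset$genes$biotype == "lncRNA"))
})

test_that("coding partition excludes 1-nt overlaps but keeps 1-nt gaps", {
  coding <- make_catalog(data.frame(
    gene_id = c("p1", "p2", "p3"), chrom = "c1",
    start = c(0L, 2000L, 4000L), end = c(1000L, 3000L, 5000L),
    strand = "+", has_protein_id = TRUE))
  lnc <- make_catalog(data.frame(
    gene_id = c("l1", "l2"), chrom = "c1",
    start = c(999L, 3001L), end = c(1500L, 3500L), strand = "-",
    biotype = "lncRNA"))
  # l1 overlaps p1 by exactly 1 nt; l2 starts 1 nt after p2 ends
  part <- partition_coding_noncoding(coding, lnc)
  expect_setequal(part$coding$genes$gene_id, c("p1", "p2", "p3"))
  expect_setequal(part$coding_nonoverlapping$genes$gene_id, c("p2", "p3"))
  # with no overlapping lncRNAs the two sets coincide
  far <- make_catalog(data.frame(gene_id = "lx", chrom = "c9", start = 0L,
                                 end = 300L, strand = "+",
                                 biotype = "lncRNA"))
  part2 <- partition_coding_noncoding(coding, far)
  expect_identical(part2$coding_nonoverlapping$genes, part2$coding$genes)
})

test_that("catalog round-trips through BED12 with exonic unions intact", {
  set.seed(31)
  genes <- random_span_genes(25, chrom_len = 50000)
  exons <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    n_ex <- sample(1:3, 1)
    w <- genes$end[i] - genes$start[i]
    cuts <- sort(sample.int(w - 1, 2 * n_ex - 2)) # interior cut points
    bounds <- c(0, cuts, w)
    data.frame(gene_id = genes$gene_id[i], isoform = genes$gene_id[i],
               start = genes$start[i] + bounds[seq(1, 2 * n_ex, by = 2)],
               end = genes$start[i] + bounds[seq(2, 2 * n_ex, by = 2)])
  }))
  exons <- exons[exons$end > exons$start, ]
  keep <- unique(exons$gene_id)
  ct <- make_catalog(genes[genes$gene_id %in% keep, ], exons = exons)
  bed <- tempfile(fileext = ".bed")
  write_catalog_bed12(ct, bed)
  back <- read_catalog_bed12(bed)
  expect_equal(back$genes$gene_id, ct$genes$gene_id)
  expect_equal(back$genes$strand, ct$genes$strand)
  expect_equal(back$genes$exonic_length, ct$genes$exonic_length)
  for (id in ct$genes$gene_id) {
    expect_equal(build_maximal_locus(back, id)$exonic_union,
                 build_maximal_locus(ct, id)$exonic_union,
                 ignore_attr = TRUE)
  }
})
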