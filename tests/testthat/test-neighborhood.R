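# Strand-aware nearest-TSS links, window enrichment, fold-change
# correlations and distance histograms.

test_that("TSS coordinates follow the strand convention", {
  expect_equal(tss_of(100L, 200L, "+"), 100L)
  expect_equal(tss_of(100L, 200L, "-"), 199L)
  expect_equal(tss_of(5L, 6L, "+"), 5L)
  expect_equal(tss_of(5L, 6L, "-"), 5L)
})

test_that("nearest-TSS links carry the expected geometry", {
  lnc <- make_catalog(data.frame(
    gene_id = c("l_up_anti", "l_overlap", "l_lonely"),
    chrom = c("c1", "c1", "cX"),
    start = c(0L, 2500L, 0L), end = c(1000L, 3500L, 500L),
    strand = c("-", "+", "+"), biotype = "lncRNA"))
  coding <- make_catalog(data.frame(
    gene_id = "pc1", chrom = "c1", start = 3000L, end = 9000L,
    strand = "+", has_protein_id = TRUE))
  links <- nearest_expressed_tss(lnc, coding)
  up <- links[links$lnc_gene_id == "l_up_anti", ]
  expect_equal(up$distance_nt, 2000L)
  expect_equal(up$side, "upstream")
  expect_equal(up$orientation, "antisense")
  ov <- links[links$lnc_gene_id == "l_overlap", ]
  expect_equal(ov$distance_nt, 0L)
  expect_equal(ov$side, "overlapping")
  # no coding gene on cX: link flagged absent
  expect_true(is.na(links$coding_gene_id[links$lnc_gene_id == "l_lonely"]))
})

test_that("nearest-TSS search matches the exhaustive pairwise oracle", {
  set.seed(55)
  lnc <- random_span_genes(200, chrom_len = 500000,
                           chroms = c("c1", "c2"), prefix = "L")
  coding <- random_span_genes(100, chrom_len = 500000,
                              chroms = c("c1", "c2"), prefix = "P")
  links <- nearest_expressed_tss(make_catalog(lnc), make_catalog(coding))
  orc <- oracle_nearest(lnc, coding)
  expect_equal(links$coding_gene_id, orc$coding_gene_id)
  expect_equal(links$distance_nt, orc$distance_nt)
})

test_that("mirroring the genome preserves distances and the upstream side", {
  set.seed(61)
  L <- 1000000L
  lnc <- random_span_genes(40, chrom_len = L - 600, prefix = "L")
  coding <- random_span_genes(25, chrom_len = L - 600, prefix = "P")
  links <- nearest_expressed_tss(make_catalog(lnc), make_catalog(coding))
  mirror <- function(g) {
    data.frame(gene_id = g$gene_id, chrom = g$chrom,
               start = L - g$end, end = L - g$start,
               strand = chartr("+-", "-+", g$strand),
               stringsAsFactors = FALSE)
  }
  m_links <- nearest_expressed_tss(make_catalog(mirror(lnc)),
                                   make_catalog(mirror(coding)))
  m_links <- m_links[match(links$lnc_gene_id, m_links$lnc_gene_id), ]
  # half-open reflection shifts strand-dependent TSS bases by one, so the
  # gap is preserved to within a single nucleotide; labels are exact
  expect_true(all(abs(m_links$distance_nt - links$distance_nt) <= 1))
  expect_equal(m_links$side, links$side)
  expect_equal(m_links$orientation, links$orientation)
})

test_that("window enrichment reproduces the 24-vs-1 asymmetry call", {
  mk_links <- function(n_up, n_down, n_far) {
    data.frame(
      lnc_gene_id = sprintf("l%02d", seq_len(n_up + n_down + n_far)),
      coding_gene_id = "pc",
      distance_nt = c(rep(3000L, n_up + n_down), rep(50000L, n_far)),
      side = c(rep("upstream", n_up), rep("downstream", n_down),
               rep("upstream", n_far)),
      orientation = "antisense", stringsAsFactors = FALSE)
  }
  enr <- window_enrichment(mk_links(24, 1, 35), window_nt = 5000L)
  expect_equal(enr$n_up_in_window, 24L)
  expect_equal(enr$n_down_in_window, 1L)
  expect_lt(enr$fisher_result$p_value, 0.001)
  sym <- window_enrichment(mk_links(10, 10, 40), window_nt = 5000L)
  expect_equal(sym$fisher_result$p_value, 1)
  empty <- data.frame(lnc_gene_id = character(0),
                      coding_gene_id = character(0),
                      distance_nt = integer(0), side = character(0),
                      orientation = character(0))
  expect_error(window_enrichment(empty), "empty")
})

test_that("window membership is 0 < d <= window, excluding overlaps", {
  links <- data.frame(
    lnc_gene_id = c("a", "b", "c", "d"), coding_gene_id = "pc",
    distance_nt = c(0L, 1L, 5000L, 5001L),
    side = c("overlapping", "upstream", "upstream", "upstream"),
    orientation = "sense", stringsAsFactors = FALSE)
  enr <- window_enrichment(links, window_nt = 5000L)
  expect_equal(enr$n_up_in_window, 2L)  # d = 1 and d = 5000; not 0 or 5001
})

test_that("simulated upstream placement bias is detected by the Fisher test", {
  set.seed(71)
  reps <- 200
  hits <- 0L
  for (r in seq_len(reps)) {
    side <- ifelse(runif(60) < 0.9, "upstream", "downstream")
    links <- data.frame(lnc_gene_id = sprintf("l%02d", 1:60),
                        coding_gene_id = "pc",
                        distance_nt = sample.int(5000, 60, replace = TRUE),
                        side = side, orientation = "antisense",
                        stringsAsFactors = FALSE)
    if (window_enrichment(links)$fisher_result$p_value < 0.01) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits / reps, 0.95)
})

test_that("neighbor fold-change correlation behaves at its extremes and under the null", {
  mk_fc <- function(ids, lfc) {
    data.frame(gene_id = ids, rpkm_control = 1, rpkm_depleted = 2^lfc,
               fc = 2^lfc, log2fc = lfc, direction = "unchanged",
               stringsAsFactors = FALSE)
  }
  links <- data.frame(lnc_gene_id = sprintf("l%02d", 1:60),
                      coding_gene_id = sprintf("p%02d", 1:60),
                      distance_nt = 1000L, side = "upstream",
                      orientation = "antisense", stringsAsFactors = FALSE)
  set.seed(81)
  v <- rnorm(60)
  ident <- neighbor_fc_correlation(links, mk_fc(links$lnc_gene_id, v),
                                   mk_fc(links$coding_gene_id, v))
  expect_equal(ident$statistic, 1)
  anti <- neighbor_fc_correlation(links, mk_fc(links$lnc_gene_id, v),
                                  mk_fc(links$coding_gene_id, -v))
  expect_equal(anti$statistic, -1)
  indep <- neighbor_fc_correlation(links, mk_fc(links$lnc_gene_id, v),
                                   mk_fc(links$coding_gene_id, rnorm(60)))
  expect_lt(abs(indep$statistic), 0.3)
})

test_that("distance histogram bins signed distances and conserves counts", {
  links <- data.frame(
    lnc_gene_id = c("a", "b", "c"), coding_gene_id = "pc",
    distance_nt = c(15000L, 5000L, 5000L),
    side = c("upstream", "upstream", "downstream"),
    orientation = "sense", stringsAsFactors = FALSE)
  h <- distance_histogram(links, bin_nt = 10000L)
  expect_equal(sum(h$count), 3L)
  expect_equal(h$count[h$bin_lo == -20000], 1L)  # -15 kb
  expect_equal(h$count[h$bin_lo == -10000], 1L)  # -5 kb
  expect_equal(h$count[h$bin_lo == 0], 1L)       # +5 kb
  zero <- links; zero$distance_nt <- 0L; zero$side <- "overlapping"
  h0 <- distance_histogram(zero)
  expect_equal(nrow(h0), 1L)
  expect_equal(h0$count, 3L)
  set.seed(91)
  rnd <- links[sample(1:3, 50, replace = TRUE), ]
  rnd$distance_nt <- sample.int(100000, 50, replace = TRUE)
  expect_equal(sum(distance_histogram(rnd)$count), 50L)
})

test_that("independence diagnostics separate null from deterministic coupling", {
  set.seed(95)
  n <- 469
  lfc <- rnorm(n, 0, 1)
  lengths <- exp(runif(n, log(300), log(10000)))
  expr <- exp(rnorm(n, 2, 1))
  d <- independence_diagnostics(lfc, lengths, expr)
  expect_lt(abs(d$length_cor$statistic), 0.3)
  expect_lt(abs(d$expression_cor$statistic), 0.3)
  coupled <- independence_diagnostics(log10(lengths), lengths, expr)
  expect_equal(coupled$length_cor$statistic, 1, tolerance = 1e-9)
  expect_error(independence_diagnostics(rep(0, n), lengths, expr),
               "variance")
  expect_error(independence_diagnostics(lfc, lengths[-1], expr), "length")
})
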