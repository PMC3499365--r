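# Seeded synthetic-data generators. They emulate the structure the analysis
# assumes: a two-condition RNA-seq experiment with coding genes mostly
# unchanged and a minority of lncRNAs upregulated, lncRNAs placed with an
# upstream-antisense bias around coding TSSs, condition-dependent
# proximal/distal 3'UTR usage, and transcription-shutoff decay curves with
# known half-lives. Every generator returns a ground-truth manifest.

#' Simulation configuration
#'
#' Defaults are desk-scale study conditions: one chromosome, one library per
#' condition, 13% of lncRNAs truly upregulated with mean log2 effect 2
#' (i.e. >2-fold), an 80% upstream placement bias and an 83% antisense bias
#' around coding TSSs.
#'
#' @param seed integer RNG seed; the same config and seed reproduce the
#'   simulated data exactly.
#' @param n_coding,n_lnc numbers of coding and lncRNA genes.
#' @param chrom_size length of the simulated chromosome (nt). Must leave
#'   enough room that neighboring coding loci cannot capture each other's
#'   paired lncRNAs.
#' @param frac_lnc_up fraction of lncRNAs truly upregulated.
#' @param effect_size_log2 mean true log2 fold change of upregulated
#'   lncRNAs (sd `effect_sd_log2`); all other genes have true log2 FC 0.
#' @param effect_sd_log2 sd of the true effect (default 0.25).
#' @param dispersion negative-binomial dispersion (0 gives Poisson counts).
#' @param baseline_mean mean of the per-gene lognormal baseline expression.
#' @param upstream_bias probability a lncRNA is placed on the upstream
#'   (promoter) side of its paired coding TSS.
#' @param antisense_bias probability a lncRNA takes the strand opposite its
#'   paired coding gene.
#' @param placement_window_nt maximum gap between a lncRNA and its paired
#'   coding TSS.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_coding = 500L, n_lnc = 80L,
                       chrom_size = 5e7, frac_lnc_up = 0.13,
                       effect_size_log2 = 2.0, effect_sd_log2 = 0.25,
                       dispersion = 0.05, baseline_mean = 200,
                       upstream_bias = 0.8, antisense_bias = 20 / 24,
                       placement_window_nt = 10000L) {
  cfg <- list(seed = seed, n_coding = n_coding, n_lnc = n_lnc,
              chrom_size = chrom_size, frac_lnc_up = frac_lnc_up,
              effect_size_log2 = effect_size_log2,
              effect_sd_log2 = effect_sd_log2, dispersion = dispersion,
              baseline_mean = baseline_mean, upstream_bias = upstream_bias,
              antisense_bias = antisense_bias,
              placement_window_nt = placement_window_nt)
  fracs <- c(frac_lnc_up, upstream_bias, antisense_bias)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (n_coding < 1 || n_lnc < 1) stop("gene counts must be positive")
  structure(cfg, class = "sim_config")
}

.coding_max_len <- 20000L
.lnc_max_len <- 3000L

#' Simulate a gene annotation with placement and orientation ground truth
#'
#' Coding genes are laid out along the chromosome on a jittered grid (so
#' each lncRNA's paired TSS is unambiguously its nearest). Each lncRNA is
#' paired with a coding gene and placed within `placement_window_nt` of its
#' TSS: on the upstream side with probability `upstream_bias`, on the
#' opposite strand with probability `antisense_bias`. lncRNA spliced
#' lengths are all > 200 nt. True log2 fold changes are assigned here:
#' a `frac_lnc_up` fraction of lncRNAs get effects drawn around
#' `effect_size_log2`; every other gene gets 0.
#'
#' @param config a [sim_config].
#' @return List with `catalog` (a [gene_catalog] of coding + lncRNA genes)
#'   and `truth` (data.frame: `gene_id`, `biotype`, `true_log2fc`,
#'   `paired_coding`, `true_side`, `true_orientation`).
#' @export
simulate_annotation <- function(config) {
  spacing <- floor(config$chrom_size / config$n_coding)
  need <- 2L * (config$placement_window_nt + .lnc_max_len) + .coding_max_len
  if (spacing < need) {
    stop("chromosome too small for requested gene count: spacing ", spacing,
         " < required ", need)
  }
  withr::with_seed(config$seed, {
    n_c <- config$n_coding
    jitter <- floor(runif(n_c, 0, spacing / 10))
    c_start <- (seq_len(n_c) - 1L) * spacing +
      config$placement_window_nt + .lnc_max_len + jitter
    c_len <- floor(runif(n_c, 2000, .coding_max_len))
    c_strand <- sample(c("+", "-"), n_c, replace = TRUE)
    c_id <- sprintf("sim:PC%04d", seq_len(n_c))
    coding_genes <- data.frame(
      gene_id = c_id, source = "sim", chrom = "chrS1",
      start = c_start, end = c_start + c_len, strand = c_strand,
      biotype = "coding", has_protein_id = TRUE, stringsAsFactors = FALSE)
    # two exons per coding gene: first and last 30% of the locus
    exon_frac <- 0.3
    e1_len <- pmax(100L, floor(c_len * exon_frac))
    coding_exons <- rbind(
      data.frame(gene_id = c_id, isoform = paste0(c_id, ".1"),
                 start = c_start, end = c_start + e1_len),
      data.frame(gene_id = c_id, isoform = paste0(c_id, ".1"),
                 start = c_start + c_len - e1_len, end = c_start + c_len))

    n_l <- config$n_lnc
    pair <- if (n_l <= n_c) sample.int(n_c, n_l)
            else sample.int(n_c, n_l, replace = TRUE)
    l_len <- floor(runif(n_l, 300, .lnc_max_len))
    gap <- floor(runif(n_l, 200, config$placement_window_nt - .lnc_max_len))
    side <- ifelse(runif(n_l) < config$upstream_bias, "upstream", "downstream")
    orient <- ifelse(runif(n_l) < config$antisense_bias, "antisense", "sense")
    tss <- tss_of(c_start[pair], c_start[pair] + c_len[pair], c_strand[pair])
    l_start <- integer(n_l)
    for (i in seq_len(n_l)) {
      up <- side[[i]] == "upstream"
      plus <- c_strand[[pair[[i]]]] == "+"
      l_start[[i]] <- if (plus == up) tss[[i]] - gap[[i]] - l_len[[i]]
                      else tss[[i]] + gap[[i]]
    }
    l_strand <- ifelse(orient == "antisense",
                       chartr("+-", "-+", c_strand[pair]), c_strand[pair])
    l_id <- sprintf("sim:LNC%04d", seq_len(n_l))
    lnc_genes <- data.frame(
      gene_id = l_id, source = "sim", chrom = "chrS1",
      start = l_start, end = l_start + l_len, strand = l_strand,
      biotype = "lncRNA", has_protein_id = FALSE, stringsAsFactors = FALSE)
    lnc_exons <- data.frame(gene_id = l_id, isoform = paste0(l_id, ".1"),
                            start = l_start, end = l_start + l_len)

    up_lnc <- runif(n_l) < config$frac_lnc_up
    lfc <- numeric(n_c + n_l)
    lfc[n_c + which(up_lnc)] <- rnorm(sum(up_lnc), config$effect_size_log2,
                                      config$effect_sd_log2)
    truth <- data.frame(
      gene_id = c(c_id, l_id),
      biotype = c(rep("coding", n_c), rep("lncRNA", n_l)),
      true_log2fc = lfc,
      paired_coding = c(rep(NA_character_, n_c), c_id[pair]),
      true_side = c(rep(NA_character_, n_c), side),
      true_orientation = c(rep(NA_character_, n_c), orient),
      stringsAsFactors = FALSE)
    list(catalog = gene_catalog(rbind(coding_genes, lnc_genes),
                                rbind(coding_exons, lnc_exons),
                                provenance = "simulate_annotation"),
         truth = truth)
  })
}

#' Simulate two-condition counts with known fold changes
#'
#' Control counts are negative binomial around per-gene lognormal baselines;
#' depleted counts scale the baseline by `2^true_log2fc`. With
#' `dispersion = 0` counts are Poisson.
#'
#' @param catalog a [gene_catalog] from [simulate_annotation()].
#' @param truth its truth manifest.
#' @param config the same [sim_config].
#' @return List with `counts` (genes x `c("control", "depleted")` matrix),
#'   `library_sizes`, and `truth` (with the per-gene `baseline` appended).
#' @export
simulate_counts <- function(catalog, truth, config) {
  stopifnot(identical(sort(truth$gene_id), catalog$genes$gene_id))
  withr::with_seed(config$seed + 1L, {
    truth <- truth[match(catalog$genes$gene_id, truth$gene_id), , drop = FALSE]
    n <- nrow(truth)
    baseline <- rlnorm(n, meanlog = log(config$baseline_mean), sdlog = 0.8)
    mu_ctl <- baseline
    mu_dep <- baseline * 2^truth$true_log2fc
    draw <- function(mu) {
      if (config$dispersion <= 0) stats::rpois(n, mu)
      else rnbinom(n, mu = mu, size = 1 / config$dispersion)
    }
    counts <- cbind(control = draw(mu_ctl), depleted = draw(mu_dep))
    rownames(counts) <- truth$gene_id
    truth$baseline <- baseline
    list(counts = counts, library_sizes = colSums(counts), truth = truth)
  })
}

#' Place single-block fragments realizing a count matrix
#'
#' For each gene and sample, places `counts[gene, sample]` fragments of
#' length `frag_len` uniformly within the gene's exons (each fragment fully
#' inside one exon, so every fragment is exonic and within the maximal
#' locus).
#'
#' @param catalog a [gene_catalog].
#' @param counts genes x samples count matrix (rownames = gene ids).
#' @param frag_len fragment length (default 100; clipped to short exons).
#' @param seed RNG seed.
#' @return Named list of per-sample fragment data.frames (`fragment_id`,
#'   `chrom`, `start`, `end`).
#' @export
simulate_fragments <- function(catalog, counts, frag_len = 100L, seed = 1L) {
  withr::with_seed(seed, {
    ex <- catalog$exons
    chrom <- setNames(catalog$genes$chrom, catalog$genes$gene_id)
    out <- list()
    for (s in colnames(counts)) {
      rows <- vector("list", nrow(counts))
      for (g in seq_len(nrow(counts))) {
        n <- counts[g, s]
        if (n == 0) next
        gid <- rownames(counts)[[g]]
        gx <- ex[ex$gene_id == gid, , drop = FALSE]
        w <- gx$end - gx$start
        pick <- sample.int(nrow(gx), n, replace = TRUE, prob = w)
        len <- pmin(frag_len, w[pick])
        start <- gx$start[pick] +
          floor(runif(n, 0, w[pick] - len + 1))
        rows[[g]] <- data.frame(
          fragment_id = sprintf("%s:%s:%d", s, gid, seq_len(n)),
          chrom = chrom[[gid]], start = start, end = start + len,
          stringsAsFactors = FALSE)
      }
      out[[s]] <- do.call(rbind, rows)
    }
    out
  })
}

#' Simulate transcription-shutoff decay time courses
#'
#' `abundance(t) = 2^(-t / half_life) * exp(noise)` with lognormal
#' multiplicative noise; the t = 0 point is included.
#'
#' @param true_half_lives named numeric vector of half-lives (minutes, > 0).
#' @param timepoints minutes, starting at 0.
#' @param noise_sd sd of the lognormal noise (0 = noiseless).
#' @param seed RNG seed.
#' @return data.frame: `gene_id`, `time_min`, `abundance`,
#'   `true_half_life`.
#' @export
simulate_decay <- function(true_half_lives, timepoints, noise_sd = 0,
                           seed = 1L) {
  if (any(true_half_lives <= 0)) stop("half-lives must be > 0")
  if (timepoints[[1]] != 0) stop("timepoints must start at 0")
  withr::with_seed(seed, {
    out <- lapply(names(true_half_lives), function(g) {
      t12 <- true_half_lives[[g]]
      ab <- 2^(-timepoints / t12) *
        exp(rnorm(length(timepoints), 0, noise_sd))
      data.frame(gene_id = g, time_min = timepoints, abundance = ab,
                 true_half_life = t12, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Simulate 3'UTR fragments with a condition-dependent proximal usage shift
#'
#' Each fragment is assigned to the proximal segment with the per-sample
#' usage probability and positioned uniformly within its segment (its
#' 3'-most base inside the segment).
#'
#' @param partition a `utr_partition` from [partition_utr()].
#' @param usage_control,usage_depleted proximal-usage probabilities in (0,1).
#' @param n_fragments fragments per sample.
#' @param seed RNG seed.
#' @param frag_len fragment length (default 50, clipped to the segment).
#' @return Named list (`control`, `depleted`) of fragment data.frames.
#' @export
simulate_apa <- function(partition, usage_control, usage_depleted,
                         n_fragments, seed = 1L, frag_len = 50L) {
  if (usage_control <= 0 || usage_control >= 1 ||
      usage_depleted <= 0 || usage_depleted >= 1) {
    stop("usage fractions must lie in (0, 1)")
  }
  withr::with_seed(seed, {
    gen <- function(usage, tag) {
      prox <- runif(n_fragments) < usage
      seg <- ifelse(prox, "proximal", "distal")
      lo <- ifelse(prox, partition$proximal_segment[["start"]],
                   partition$distal_segment[["start"]])
      hi <- ifelse(prox, partition$proximal_segment[["end"]],
                   partition$distal_segment[["end"]])
      p3 <- floor(runif(n_fragments, lo, hi))  # 3'-most base, in-segment
      if (partition$strand == "+") {
        start <- pmax(lo, p3 - frag_len + 1L)
        end <- p3 + 1L
      } else {
        start <- p3
        end <- pmin(hi, p3 + frag_len)
      }
      data.frame(fragment_id = sprintf("%s:%d", tag, seq_len(n_fragments)),
                 start = start, end = end, segment = seg,
                 stringsAsFactors = FALSE)
    }
    list(control = gen(usage_control, "ctl"),
         depleted = gen(usage_depleted, "dep"))
  })
}

#' Simulate qPCR Ct tables with known fold changes
#'
#' Case target Cts are lowered by `log2(true FC)` cycles relative to the
#' control; reference Cts are constant up to noise.
#'
#' @param true_fold_changes named vector of true fold changes (> 0).
#' @param ct_baseline baseline target Ct (default 22).
#' @param ct_reference reference-gene Ct (default 18).
#' @param noise_sd sd of Gaussian Ct noise (cycles).
#' @param seed RNG seed.
#' @return data.frame: `gene_id`, `ct_target_case`, `ct_ref_case`,
#'   `ct_target_control`, `ct_ref_control`, `true_fc`.
#' @export
simulate_qpcr <- function(true_fold_changes, ct_baseline = 22,
                          ct_reference = 18, noise_sd = 0, seed = 1L) {
  if (any(true_fold_changes <= 0)) stop("fold changes must be > 0")
  withr::with_seed(seed, {
    n <- length(true_fold_changes)
    noise <- function() rnorm(n, 0, noise_sd)
    data.frame(
      gene_id = names(true_fold_changes),
      ct_target_case = ct_baseline - log2(true_fold_changes) + noise(),
      ct_ref_case = ct_reference + noise(),
      ct_target_control = ct_baseline + noise(),
      ct_ref_control = ct_reference + noise(),
      true_fc = unname(true_fold_changes),
      stringsAsFactors = FALSE)
  })
}
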