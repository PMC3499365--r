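# Alternative polyadenylation: proximal/distal 3'UTR partitioning, segment
# RPKMs and usage-ratio fold changes, plus poly(A)-signal hexamer scanning.

#' Partition a 3'UTR into proximal and distal segments
#'
#' The proximal 3'UTR runs from just downstream of the stop codon to the
#' most proximal poly(A) site; the distal 3'UTR from just downstream of the
#' proximal poly(A) site to the most distal poly(A) site. Coordinates are
#' given in genomic space; on the - strand transcription order is reversed,
#' so the genomic intervals mirror accordingly.
#'
#' @param stop_codon_end genomic coordinate of the 3' end of the stop codon
#'   (0-based; on + strand the first UTR base, on - strand one past it).
#' @param proximal_pa,distal_pa genomic coordinates of the proximal and
#'   distal poly(A) sites.
#' @param strand `"+"` or `"-"`. Coordinates must be in strict
#'   transcription order: `stop < proximal < distal` on +, reversed on -.
#' @return List of class `utr_partition`: `strand`, `stop_codon_end`,
#'   `proximal_pa`, `distal_pa`, `proximal_segment` and `distal_segment`
#'   (each `c(start, end)`, 0-based half-open genomic intervals).
#' @export
partition_utr <- function(stop_codon_end, proximal_pa, distal_pa, strand) {
  if (!(strand %in% c("+", "-"))) stop("unknown strand symbol: ", strand)
  if (strand == "+") {
    if (!(stop_codon_end < proximal_pa && proximal_pa < distal_pa)) {
      stop("coordinates must be in strict transcription order")
    }
    prox <- c(start = stop_codon_end, end = proximal_pa)
    dist <- c(start = proximal_pa, end = distal_pa)
  } else {
    if (!(stop_codon_end > proximal_pa && proximal_pa > distal_pa)) {
      stop("coordinates must be in strict transcription order")
    }
    prox <- c(start = proximal_pa, end = stop_codon_end)
    dist <- c(start = distal_pa, end = proximal_pa)
  }
  structure(list(strand = strand, stop_codon_end = stop_codon_end,
                 proximal_pa = proximal_pa, distal_pa = distal_pa,
                 proximal_segment = prox, distal_segment = dist),
            class = "utr_partition")
}

# 3'-most aligned genomic base of each fragment (0-based)
fragment_3prime <- function(fragments, strand) {
  if (strand == "+") {
    tapply(fragments$end, fragments$fragment_id, max) - 1L
  } else {
    tapply(fragments$start, fragments$fragment_id, min)
  }
}

#' Proximal/distal poly(A)-site usage from segment coverage
#'
#' Fragments are assigned to the UTR segment containing their 3'-most
#' aligned base; segment RPKMs are computed per sample with
#' [compute_rpkm()]; the per-sample usage ratio is
#' `rpkm_proximal / rpkm_distal` and `ratio_fold_change` is the depleted
#' ratio over the control ratio. A `ratio_fold_change > 1` reports
#' increased usage of the proximal site in the depleted condition.
#'
#' @param fragments_by_sample named list with elements `control` and
#'   `depleted`, each a data.frame of fragment blocks (`fragment_id`,
#'   `chrom` optional, `start`, `end`).
#' @param partition a `utr_partition` from [partition_utr()].
#' @param library_sizes named numeric vector (`control`, `depleted`), > 0.
#' @return List of class `apa_result`: per-sample `rpkm_proximal`,
#'   `rpkm_distal`, `ratio`, plus `ratio_fold_change` and `flagged`
#'   (TRUE when a sample had zero distal coverage, leaving its ratio
#'   undefined).
#' @export
apa_usage <- function(fragments_by_sample, partition, library_sizes) {
  stopifnot(all(c("control", "depleted") %in% names(fragments_by_sample)),
            all(c("control", "depleted") %in% names(library_sizes)))
  if (any(library_sizes <= 0)) stop("library sizes must be > 0")
  prox <- partition$proximal_segment
  dist <- partition$distal_segment
  per_sample <- lapply(c(control = "control", depleted = "depleted"), function(s) {
    fr <- fragments_by_sample[[s]]
    p3 <- fragment_3prime(fr, partition$strand)
    n_prox <- sum(p3 >= prox[["start"]] & p3 < prox[["end"]])
    n_dist <- sum(p3 >= dist[["start"]] & p3 < dist[["end"]])
    rp <- compute_rpkm(n_prox, prox[["end"]] - prox[["start"]],
                       library_sizes[[s]])
    rd <- compute_rpkm(n_dist, dist[["end"]] - dist[["start"]],
                       library_sizes[[s]])
    list(rpkm_proximal = rp, rpkm_distal = rd,
         ratio = if (rd > 0) rp / rd else NA_real_)
  })
  ratios <- vapply(per_sample, `[[`, numeric(1), "ratio")
  flagged <- any(is.na(ratios))
  structure(list(
    control = per_sample$control, depleted = per_sample$depleted,
    ratio_fold_change = if (flagged) NA_real_ else
      ratios[["depleted"]] / ratios[["control"]],
    flagged = flagged
  ), class = "apa_result")
}

#' Scan for poly(A)-signal hexamers upstream of a cleavage site
#'
#' Finds all occurrences of the canonical AAUAAA hexamer (and any configured
#' variants) whose 3' end lies within `window_nt` upstream of the cleavage
#' position. RNA and DNA alphabets are treated identically (U == T). Hits
#' are returned ordered by increasing offset (closest to the cleavage site
#' first).
#'
#' @param sequence nucleotide string (DNA or RNA alphabet), sense strand.
#' @param cleavage_index 0-based position of the cleavage site within
#'   `sequence` (`0 <= cleavage_index <= nchar(sequence)`).
#' @param window_nt scan window upstream of the cleavage site (default 50,
#'   must be >= 6).
#' @param hexamers character vector of 6-mers (default canonical
#'   `"AAUAAA"`).
#' @return data.frame with columns `hexamer`, `position` (0-based start of
#'   the match) and `offset_nt` (distance from hexamer end to the cleavage
#'   site).
#' @export
scan_polya_signal <- function(sequence, cleavage_index, window_nt = 50L,
                              hexamers = "AAUAAA") {
  seq_dna <- chartr("Uu", "Tt", toupper(sequence))
  n <- nchar(seq_dna)
  if (cleavage_index < 0 || cleavage_index > n) {
    stop("cleavage_index out of range")
  }
  if (window_nt < 6) stop("window_nt must be >= 6")
  if (any(nchar(hexamers) != 6)) stop("hexamers must be 6-mers")
  hex_dna <- chartr("Uu", "Tt", toupper(hexamers))
  subj <- Biostrings::DNAString(seq_dna)
  hits <- list()
  for (k in seq_along(hex_dna)) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(hex_dna[[k]]), subj)
    if (length(m) == 0) next
    pos0 <- Biostrings::start(m) - 1L           # 0-based match start
    offset <- cleavage_index - (pos0 + 6L)      # end-to-cleavage distance
    ok <- offset >= 0 & offset <= window_nt
    if (any(ok)) {
      hits[[length(hits) + 1L]] <- data.frame(
        hexamer = hexamers[[k]], position = pos0[ok],
        offset_nt = offset[ok], stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0) {
    return(data.frame(hexamer = character(0), position = integer(0),
                      offset_nt = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$offset_nt, out$hexamer), , drop = FALSE]
  rownames(out) <- NULL
  out
}
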