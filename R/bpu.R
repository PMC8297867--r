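## Bounded edit-distance scanning for short mobile elements (Bpu-like).
##
## The dominant Cycas consensus is a 36-bp element with AAGG terminal
## direct repeats and a Bpu10I endonuclease recognition site around
## positions 15-21. Occurrences are accepted when the full consensus aligns
## to a genomic window with at most max_edits unit-cost edits
## (substitutions, insertions and deletions all cost 1), which also admits
## exact but truncated copies down to 36 - max_edits bp.

BPU_DOMINANT <- "AAGGTTATCCCTTTCCTGAGCGTAGCGAAGGGAAGG"

#' Bpu-like consensus description
#'
#' @param sequence consensus DNA string (default: the dominant 36-bp
#'   Cycas element).
#' @param max_edits maximum unit-cost edit distance (mismatches including
#'   gaps) for an accepted hit.
#' @param terminal_repeat the conserved terminal direct repeat motif.
#' @param endonuclease_site integer c(start, end) of the endonuclease
#'   recognition site within the consensus.
#' @return object of class `bpu_consensus`.
#' @export
bpu_consensus <- function(sequence = BPU_DOMINANT, max_edits = 7L,
                          terminal_repeat = "AAGG",
                          endonuclease_site = c(15L, 21L)) {
  sequence <- check_dna(sequence, "consensus")
  if (max_edits < 0L || max_edits >= nchar(sequence))
    stop("max_edits must be in [0, consensus length)")
  structure(list(sequence = sequence, max_edits = as.integer(max_edits),
                 terminal_repeat = terminal_repeat,
                 endonuclease_site = endonuclease_site),
            class = "bpu_consensus")
}

## semi-global DP, vectorized over text positions: returns for each end
## position i the minimal edit distance of the full pattern against any
## substring of `text` ending at i (free start, free end position).
semi_global_end_dists <- function(pattern, text) {
  p <- chars(pattern); tb <- chars(text)
  m <- length(p); nt <- length(tb)
  prev <- rep(0, nt + 1L)              # row j = 0: D[0, i] = 0
  for (j in seq_len(m)) {
    sub_cost <- prev[1L:nt] + (tb != p[j])      # diagonal
    del_cost <- prev[2L:(nt + 1L)] + 1          # pattern char deleted
    e <- pmin(sub_cost, del_cost)
    ## horizontal (text char inserted): D[j,i] = min_k<=i (E[k] + i - k),
    ## with E[0] = D[j,0] = j, as a prefix scan
    prev <- c(j, cummin_seed(e, j))
  }
  prev[-1L]
}

## helper kept out of the hot loop for clarity: the horizontal recurrence
## D[j,i] = min(E[i], D[j,i-1] + 1) as a prefix scan
cummin_seed <- function(e, first) {
  n <- length(e)
  idx <- seq_len(n)
  cummin(c(first, e - idx))[-1L] + idx
}

#' Scan a genome for consensus matches within a bounded edit distance
#'
#' Both strands are scanned with a semi-global alignment (full consensus
#' vs. any genomic window, unit costs). For circular genomes the first
#' `nchar(consensus) + max_edits - 1` bases are appended so
#' origin-spanning copies are seen. Candidate matches are resolved
#' greedily by ascending edit distance, then ascending start, then `+`
#' strand first; a candidate overlapping an accepted hit is discarded.
#'
#' @param genome an [mt_genome()] or DNA string.
#' @param consensus a [bpu_consensus()].
#' @return data.frame of hits: start, end, strand, edit_distance,
#'   matched_length, sequence (element sequence in consensus orientation).
#'   `end > length(genome)` marks an origin-wrapping hit.
#' @export
scan_motif <- function(genome, consensus = bpu_consensus()) {
  seq <- if (inherits(genome, "mt_genome")) genome$sequence else check_dna(genome)
  circular <- if (inherits(genome, "mt_genome")) genome$circular else TRUE
  n <- nchar(seq)
  pat <- consensus$sequence
  m <- nchar(pat)
  if (n < m) stop("genome shorter than the consensus")
  maxe <- consensus$max_edits
  n_amb <- sum(chars(seq) == "N")
  if (n_amb / n > 0.05)
    warning("genome has >5% ambiguous bases; treated as mismatches", call. = FALSE)
  wrap <- if (circular) min(m + maxe - 1L, n) else 0L
  text <- if (wrap > 0L) paste0(seq, substr(seq, 1L, wrap)) else seq
  nt <- nchar(text)

  cands <- list()
  for (strand in c("+", "-")) {
    t2 <- if (strand == "+") text else rev_comp(text)
    d <- semi_global_end_dists(pat, t2)
    ends <- which(d <= maxe)
    for (e in ends) {
      fit <- semi_global_traceback(pat, t2, e, maxe)
      if (strand == "+") { gs <- fit$start; ge <- e }
      else { gs <- nt - e + 1L; ge <- nt - fit$start + 1L }
      cands[[length(cands) + 1L]] <- data.frame(
        start = gs, end = ge, strand = strand, edit_distance = d[e])
    }
  }
  if (length(cands) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), edit_distance = integer(0),
                      matched_length = integer(0), sequence = character(0)))
  cand <- do.call(rbind, cands)
  ## circular normalization: shift hits living entirely in the appended copy
  shift <- cand$start > n
  cand$start[shift] <- cand$start[shift] - n
  cand$end[shift] <- cand$end[shift] - n
  cand <- cand[!duplicated(cand[, c("start", "end", "strand")]), , drop = FALSE]
  hits <- greedy_select_hits(cand, n, circular)
  hits$matched_length <- hits$end - hits$start + 1L
  hits$sequence <- vapply(seq_len(nrow(hits)), function(i) {
    s <- circular_substr(text, seq, hits$start[i], hits$end[i], n)
    if (hits$strand[i] == "-") rev_comp(s) else s
  }, "")
  rownames(hits) <- NULL
  hits
}

circular_substr <- function(text, seq, start, end, n) {
  if (end <= nchar(text)) substr(text, start, end)
  else paste0(substr(seq, start, n), substr(seq, 1L, end - n))
}

## minimal-distance start for an alignment of `pat` ending at text position
## `e`: reverse DP over the candidate window; among minimal-distance starts
## the tightest (shortest) window is reported, so exact truncated cores are
## not padded with cost-neutral flank columns.
semi_global_traceback <- function(pat, text, e, maxe) {
  m <- nchar(pat)
  w0 <- max(1L, e - m - maxe + 1L)
  win <- substr(text, w0, e)
  rp <- paste(rev(chars(pat)), collapse = "")
  rw <- paste(rev(chars(win)), collapse = "")
  ## distance of pat vs text[k..e] = semi-global dist of reversed pat
  ## against reversed window ending at position (e - k + 1)
  d <- semi_global_end_dists(rp, rw)
  best <- min(d)
  len <- min(which(d == best))          # shortest window
  list(start = e - len + 1L, distance = best)
}

## greedy overlap resolution shared by scanner (documented tie-break:
## ascending edit distance, then start, then '+' strand first)
greedy_select_hits <- function(cand, n, circular) {
  ord <- order(cand$edit_distance, cand$start, cand$strand)
  cand <- cand[ord, , drop = FALSE]
  acc <- integer(0)
  covered_s <- integer(0); covered_e <- integer(0)
  overlaps <- function(s, e) {
    if (length(covered_s) == 0L) return(FALSE)
    direct <- any(covered_s <= e & covered_e >= s)
    if (direct || !circular) return(direct)
    ## compare against origin-shifted copies as well
    any(covered_s <= e - n & covered_e >= s - n) ||
      any(covered_s <= e + n & covered_e >= s + n)
  }
  for (i in seq_len(nrow(cand))) {
    if (!overlaps(cand$start[i], cand$end[i])) {
      acc <- c(acc, i)
      covered_s <- c(covered_s, cand$start[i])
      covered_e <- c(covered_e, cand$end[i])
    }
  }
  cand[acc, , drop = FALSE]
}

#' Classify scanned hits against the dominant consensus
#'
#' A hit is `dominant_exact` when its sequence equals the full consensus,
#' `truncated_exact` when it is identical to a contiguous consensus
#' substring of 29-35 bp (more generally `length(consensus) - max_edits`
#' to `length(consensus) - 1`), and `variant` otherwise.
#'
#' @param hits data.frame from [scan_motif()].
#' @param consensus the [bpu_consensus()] used for the scan.
#' @return list with `hits` (the data.frame plus an `identity_class`
#'   column) and `summary` (counts per class and total).
#' @export
classify_hits <- function(hits, consensus = bpu_consensus()) {
  pat <- consensus$sequence
  m <- nchar(pat)
  lo <- m - consensus$max_edits
  cls <- vapply(seq_len(nrow(hits)), function(i) {
    s <- hits$sequence[i]
    if (s == pat) return("dominant_exact")
    if (nchar(s) >= lo && nchar(s) < m && grepl(s, pat, fixed = TRUE))
      return("truncated_exact")
    "variant"
  }, "")
  if (nrow(hits) == 0L) cls <- character(0)
  hits$identity_class <- cls
  list(hits = hits,
       summary = list(total = nrow(hits),
                      dominant_exact = sum(cls == "dominant_exact"),
                      truncated_exact = sum(cls == "truncated_exact"),
                      variant = sum(cls == "variant")))
}

#' Pair element insertion sites of two genomes by flank orthology
#'
#' Two hits are orthologous when their flanking sequences (`flank` bases on
#' each side, element excluded, read in element orientation) are reciprocal
#' best matches at >= `min_identity` identity (edit-distance identity).
#'
#' @param hits_a,hits_b classified hit data.frames.
#' @param genome_a,genome_b the corresponding [mt_genome()]s.
#' @param flank flank length in bases.
#' @param min_identity minimum flank identity for a pairing.
#' @return list with `pairs` (data.frame of indices and identities),
#'   `n_paired`, `n_unpaired_a`, `n_unpaired_b`.
#' @export
compare_genomes <- function(hits_a, hits_b, genome_a, genome_b,
                            flank = 50L, min_identity = 0.9) {
  key <- function(hits, g) {
    vapply(seq_len(nrow(hits)), function(i) {
      s <- hits$start[i]; e <- hits$end[i]; n <- g$length
      lf_s <- s - flank; lf_e <- s - 1L
      rf_s <- e + 1L; rf_e <- e + flank
      grab <- function(a, b) {
        if (g$circular) {
          a <- wrap_coord(a, n)
          b2 <- a + (b - a)
          genome_subseq(g, a, b2)
        } else {
          a2 <- max(1L, a); b2 <- min(n, b)
          if (a2 > b2) "" else substr(g$sequence, a2, b2)
        }
      }
      if (!g$circular && (lf_s < 1L || rf_e > n))
        warning("flank truncated at a linear genome end", call. = FALSE)
      lf <- grab(lf_s, lf_e); rf <- grab(rf_s, rf_e)
      if (hits$strand[i] == "-") paste0(rev_comp(rf), rev_comp(lf))
      else paste0(lf, rf)
    }, "")
  }
  if (nrow(hits_a) == 0L || nrow(hits_b) == 0L)
    return(list(pairs = data.frame(a = integer(0), b = integer(0),
                                   identity = numeric(0)),
                n_paired = 0L, n_unpaired_a = nrow(hits_a),
                n_unpaired_b = nrow(hits_b)))
  ka <- key(hits_a, genome_a); kb <- key(hits_b, genome_b)
  dm <- adist(ka, kb)
  len <- outer(nchar(ka), nchar(kb), pmax)
  idm <- 1 - dm / pmax(len, 1L)
  best_a <- apply(idm, 1L, which.max)
  best_b <- apply(idm, 2L, which.max)
  pairs <- data.frame(a = integer(0), b = integer(0), identity = numeric(0))
  for (i in seq_along(best_a)) {
    j <- best_a[i]
    if (best_b[j] == i && idm[i, j] >= min_identity)
      pairs <- rbind(pairs, data.frame(a = i, b = j, identity = idm[i, j]))
  }
  list(pairs = pairs, n_paired = nrow(pairs),
       n_unpaired_a = nrow(hits_a) - nrow(pairs),
       n_unpaired_b = nrow(hits_b) - nrow(pairs))
}
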