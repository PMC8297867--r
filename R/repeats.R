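## Dispersed exact-repeat detection.
##
## The unit reported is the maximal exact repeat: a sequence of length >=
## min_length occurring at two or more genomic loci (counting the reverse
## complement when inverted copies are included) whose occurrence set is
## both left- and right-diverse, i.e. the sequence cannot be extended on
## either flank without losing an occurrence. Discovery is by
## min_length-mer seeding followed by flank extension of left-maximal seed
## pairs; each maximal pair is discovered from its leftmost seed exactly
## once.

#' Find dispersed exact repeats of a genome
#'
#' Detects every maximal exact repeated sequence of at least `min_length`
#' bases, groups occurrences into unique-sequence families, excludes
#' tandem-adjacent copies (occurrences abutting within one period) from
#' dispersed families, and removes families nested inside a longer family
#' at every occurrence. Circularly wrapping occurrences are found by
#' scanning the sequence concatenated with its first `min_length - 1`
#' bases; a wrapped occurrence is reported with `end > length(genome)`.
#'
#' @param genome an [mt_genome()] or a plain DNA string.
#' @param min_length minimum repeat length in bases (>= 2; the mitogenome
#'   convention is 50).
#' @param include_inverted also count reverse-complement (inverted) copies.
#' @return an object of class `repeat_families`: a list of families, each
#'   with `family_id`, `sequence` (canonical orientation), `length`,
#'   `copy_number` and an `occurrences` data.frame (start, end,
#'   orientation).
#' @export
find_exact_repeats <- function(genome, min_length = 50L, include_inverted = TRUE) {
  if (min_length < 2L) stop("min_length must be >= 2")
  seq <- if (inherits(genome, "mt_genome")) genome$sequence else check_dna(genome)
  circular <- if (inherits(genome, "mt_genome")) genome$circular else TRUE
  n <- nchar(seq)
  k <- as.integer(min_length)
  text <- if (circular && n > k) paste0(seq, substr(seq, 1L, k - 1L)) else seq
  nt <- nchar(text)
  if (nt < k) return(empty_repeat_set())
  tb <- chars(text)                       # per-base vector for extension
  nw <- nt - k + 1L
  km_f <- substring(text, 1L:nw, k:nt)
  ents_pos <- 1L:nw
  ents_strand <- rep("+", nw)
  ents_kmer <- km_f
  if (include_inverted) {
    rt <- rev_comp(text)
    km_rt <- substring(rt, 1L:nw, k:nt)
    ## rc of the forward window starting at p is the rt window at nt-p-k+2
    km_r <- km_rt[nt - (1L:nw) - k + 2L]
    ents_pos <- c(ents_pos, 1L:nw)
    ents_strand <- c(ents_strand, rep("-", nw))
    ents_kmer <- c(ents_kmer, km_r)
  }

  grp <- split(seq_along(ents_kmer), ents_kmer)
  grp <- grp[lengths(grp) >= 2L]
  cand <- new.env(parent = emptyenv())    # candidate maximal strings (set)

  left_char <- function(p) if (p >= 1L) tb[p] else "^"
  right_char <- function(p) if (p <= nt) tb[p] else "$"

  for (g in grp) {
    pos <- ents_pos[g]; str <- ents_strand[g]
    fw <- which(str == "+"); rv <- which(str == "-")
    ## direct pairs among forward entries
    if (length(fw) >= 2L) {
      fp <- sort(pos[fw])
      for (a in seq_len(length(fp) - 1L)) for (b in (a + 1L):length(fp)) {
        p <- fp[a]; q <- fp[b]
        if (left_char(p - 1L) == left_char(q - 1L) && p - 1L >= 1L && q - 1L >= 1L) next
        l <- k
        while (p + l <= nt && q + l <= nt && tb[p + l] == tb[q + l]) l <- l + 1L
        assign(substr(text, p, p + l - 1L), TRUE, envir = cand)
      }
    }
    ## inverted pairs: forward entry p vs reverse entry q
    ## (window at p equals the reverse complement of the window at q)
    if (length(fw) >= 1L && length(rv) >= 1L) {
      for (a in fw) for (b in rv) {
        p <- pos[a]; q <- pos[b]
        if (p == q) next                 # palindromic self-match
        ## leftmost-seed condition: no left extension of the repeat
        if (q + k <= nt && p - 1L >= 1L &&
            left_char(p - 1L) == comp_base(tb[q + k])) next
        l <- k
        while (p + l <= nt && q - (l - k) - 1L >= 1L &&
               tb[p + l] == comp_base(tb[q - (l - k) - 1L])) l <- l + 1L
        assign(substr(text, p, p + l - 1L), TRUE, envir = cand)
      }
    }
  }

  strings <- ls(cand)
  strings <- strings[nchar(strings) >= k]
  if (length(strings) == 0L) return(empty_repeat_set())
  canon <- vapply(strings, function(s) {
    if (!include_inverted) return(s)
    r <- rev_comp(s); if (r < s) r else s
  }, "")
  canon <- unique(canon)

  fams <- list()
  for (C in canon) {
    L <- nchar(C)
    occ_s <- as.integer(Biostrings::start(
      Biostrings::matchPattern(C, text)))
    occ <- data.frame(start = occ_s, end = occ_s + L - 1L,
                      orientation = rep("direct", length(occ_s)))
    if (include_inverted) {
      R <- rev_comp(C)
      if (R != C) {
        occ_r <- as.integer(Biostrings::start(Biostrings::matchPattern(R, text)))
        if (length(occ_r))
          occ <- rbind(occ, data.frame(start = occ_r, end = occ_r + L - 1L,
                                       orientation = "inverted"))
      }
    }
    occ <- occ[occ$start <= n, , drop = FALSE]  # genomic loci only
    occ <- occ[order(occ$start), , drop = FALSE]
    if (nrow(occ) < 2L) next
    ## tandem exclusion: drop occurrences abutting within one period
    if (nrow(occ) >= 2L) {
      tand <- rep(FALSE, nrow(occ))
      for (i in seq_len(nrow(occ) - 1L))
        if (occ$start[i + 1L] <= occ$start[i] + L) tand[c(i, i + 1L)] <- TRUE
      occ <- occ[!tand, , drop = FALSE]
    }
    if (nrow(occ) < 2L) next
    fams[[length(fams) + 1L]] <- list(sequence = C, length = L,
                                      occurrences = occ)
  }
  if (length(fams) == 0L) return(empty_repeat_set())

  ## nested-family resolution: keep a shorter family only if it has an
  ## occurrence outside every longer family's occurrences
  lens <- vapply(fams, `[[`, 1L, "length")
  ord <- order(-lens, vapply(fams, `[[`, "", "sequence"))
  fams <- fams[ord]; lens <- lens[ord]
  keep <- rep(TRUE, length(fams))
  for (i in seq_along(fams)) {
    if (i == 1L) next
    oc <- fams[[i]]$occurrences
    contained <- vapply(seq_len(nrow(oc)), function(r) {
      for (j in seq_len(i - 1L)) {
        if (!keep[j] || lens[j] <= lens[i]) next
        oj <- fams[[j]]$occurrences
        if (any(oj$start <= oc$start[r] & oj$end >= oc$end[r])) return(TRUE)
      }
      FALSE
    }, TRUE)
    if (all(contained)) keep[i] <- FALSE
  }
  fams <- fams[keep]
  for (i in seq_along(fams)) {
    fams[[i]]$family_id <- i
    fams[[i]]$copy_number <- nrow(fams[[i]]$occurrences)
  }
  structure(list(families = fams, genome_length = n, min_length = k,
                 include_inverted = include_inverted),
            class = "repeat_families")
}

empty_repeat_set <- function() {
  structure(list(families = list(), genome_length = NA_integer_,
                 min_length = NA_integer_, include_inverted = TRUE),
            class = "repeat_families")
}

#' @export
print.repeat_families <- function(x, ...) {
  cat(sprintf("<repeat_families> %d families (min length %s)\n",
              length(x$families), x$min_length))
  invisible(x)
}

#' Summarize repeat families
#'
#' Totals follow unique-sequence reporting: each family's length is counted
#' once regardless of copy number. The size histogram uses the
#' short/intermediate/large classes (<100, 100-900, >1000 bp; lengths in
#' 901-1000 are counted with the intermediate class).
#'
#' @param families a `repeat_families` object (or its `families` list).
#' @param genome_length genome size in bases.
#' @return list with `family_count`, `total_unique_length`,
#'   `genome_fraction` and `size_histogram`.
#' @export
summarize_repeats <- function(families, genome_length) {
  if (genome_length <= 0) stop("genome_length must be positive")
  fams <- if (inherits(families, "repeat_families")) families$families else families
  lens <- vapply(fams, `[[`, 1L, "length")
  total <- sum(lens)
  hist <- c("<100" = sum(lens < 100L),
            "100-900" = sum(lens >= 100L & lens <= 1000L),
            ">1000" = sum(lens > 1000L))
  list(family_count = length(fams),
       total_unique_length = as.integer(total),
       genome_fraction = total / genome_length,
       size_histogram = hist)
}

#' Repeat occurrences as a flat table
#'
#' One row per occurrence: family_id, length, copy_number, orientation,
#' start, end.
#'
#' @param families a `repeat_families` object.
#' @return data.frame.
#' @export
repeat_table <- function(families) {
  rows <- lapply(families$families, function(f)
    data.frame(family_id = f$family_id, length = f$length,
               copy_number = f$copy_number,
               orientation = f$occurrences$orientation,
               start = f$occurrences$start, end = f$occurrences$end))
  if (length(rows) == 0L)
    return(data.frame(family_id = integer(0), length = integer(0),
                      copy_number = integer(0), orientation = character(0),
                      start = integer(0), end = integer(0)))
  do.call(rbind, rows)
}

#' Write repeat families to TSV (one row per occurrence) and FASTA
#' @param families a `repeat_families` object.
#' @param tsv,fasta output paths (either may be NULL to skip).
#' @return invisibly, a list of the written paths.
#' @export
write_repeat_tables <- function(families, tsv = NULL, fasta = NULL) {
  if (!is.null(tsv)) write_tsv(repeat_table(families), tsv)
  if (!is.null(fasta) && length(families$families) > 0L) {
    s <- Biostrings::DNAStringSet(vapply(families$families, `[[`, "", "sequence"))
    names(s) <- sprintf("repeat_%d_len%d_x%d",
                        vapply(families$families, `[[`, 1L, "family_id"),
                        vapply(families$families, `[[`, 1L, "length"),
                        vapply(families$families, `[[`, 1L, "copy_number"))
    Biostrings::writeXStringSet(s, fasta)
  }
  invisible(list(tsv = tsv, fasta = fasta))
}
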