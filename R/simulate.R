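## Synthetic genomes with machine-readable ground truth. Every generator
## is deterministic under (specification, seed) and returns a manifest
## sufficient to compute the expected output of the consuming analysis
## without re-running generation. Background sequence is i.i.d. over
## {A,C,G,T} with a GC knob (plant mitogenomes run ~47-53% GC).

#' Random DNA string
#' @param n length in bases.
#' @param gc GC fraction.
#' @return character scalar.
#' @export
random_dna <- function(n, gc = 0.47) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Random DNA with no repeated k-mers
#'
#' Rejection sampler: windows whose canonical k-mer (the lexicographic
#' minimum of the k-mer and its reverse complement) occurs twice are
#' resampled until none remain, so the sequence carries no exact repeat of
#' length k or more on either strand. Used as the clean background for
#' planted-repeat fixtures.
#'
#' @param n sequence length in bases.
#' @param k repeat-freedom scale in bases.
#' @param gc GC fraction.
#' @param max_rounds resampling rounds before giving up.
#' @return character scalar.
#' @export
repeat_free_dna <- function(n, k, gc = 0.47, max_rounds = 60L) {
  s <- chars(random_dna(n, gc))
  for (round in seq_len(max_rounds)) {
    txt <- paste(s, collapse = "")
    nw <- n - k + 1L
    km <- substring(txt, 1L:nw, k:n)
    rt <- rev_comp(txt)
    kmr <- substring(rt, 1L:nw, k:n)[n - (1L:nw) - k + 2L]
    canon <- pmin(km, kmr)
    dup <- duplicated(canon) | duplicated(canon, fromLast = TRUE)
    ## palindromic self-hits are fine to break as well
    dup <- dup | (km == kmr)
    if (!any(dup)) return(txt)
    hit <- which(dup)
    touch <- unique(unlist(lapply(hit, function(p) p:(p + k - 1L))))
    s[touch] <- sample(c("A", "C", "G", "T"), length(touch), replace = TRUE)
  }
  stop("could not build a repeat-free sequence (n too large for k?)")
}

## sample m non-overlapping [start, start+width-1] intervals inside 1..n
## (linear placement with a pad; errors when overcrowded)
place_intervals <- function(n, widths, pad = 2L, occupied = NULL,
                            max_tries = 400L) {
  occ_s <- occupied$start %||% integer(0)
  occ_e <- occupied$end %||% integer(0)
  out <- data.frame(start = integer(0), end = integer(0))
  for (w in widths) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      s <- sample.int(n - w + 1L, 1L)
      e <- s + w - 1L
      if (!any(occ_s <= e + pad & occ_e >= s - pad)) {
        occ_s <- c(occ_s, s); occ_e <- c(occ_e, e)
        out <- rbind(out, data.frame(start = s, end = e))
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("infeasible placement: no room for a ", w,
                      "-bp element in ", n, " bp")
  }
  out
}

#' Simulate an annotated circular genome
#'
#' Places non-overlapping genes (optionally with cis introns and
#' trans-split genes) on a random circular sequence and returns both the
#' genome and a truth manifest.
#'
#' @param length genome size in bases.
#' @param gene_plan list of gene descriptions, each a list with `name`,
#'   `category` ("PCG"/"tRNA"/"rRNA"), `strand`, `exon_lengths`,
#'   `intron_lengths` (length exons - 1; use 0-length `intron_lengths`
#'   for single-exon genes), and optional `trans` (logical: each exon
#'   group separated at `trans_after` becomes a disjoint locus), `pseudo`,
#'   `foreign`. NULL builds a default plan of `n_genes` single-exon genes.
#' @param n_genes number of genes for the default plan.
#' @param seed RNG seed.
#' @param gc background GC fraction.
#' @param repeat_free_k if non-NULL, the background is made repeat-free at
#'   this k-mer size before genes are written.
#' @return list with `genome` ([mt_genome()]) and `manifest`.
#' @export
simulate_genome <- function(length, gene_plan = NULL, n_genes = 20L,
                            seed = 1L, gc = 0.47, repeat_free_k = NULL) {
  set.seed(seed)
  if (is.null(gene_plan)) {
    cats <- rep(c("PCG", "tRNA", "rRNA"), times = c(
      ceiling(n_genes * 0.6), ceiling(n_genes * 0.3), n_genes))[seq_len(n_genes)]
    gene_plan <- lapply(seq_len(n_genes), function(i) list(
      name = sprintf("%s%02d", tolower(cats[i]), i), category = cats[i],
      strand = sample(c("+", "-"), 1L),
      exon_lengths = if (cats[i] == "PCG") sample(300:1200, 1L) else
        sample(70:120, 1L),
      intron_lengths = integer(0)))
  }
  span_of <- function(g) sum(g$exon_lengths) + sum(g$intron_lengths %||% 0L)
  spans <- vapply(gene_plan, span_of, 1)
  if (sum(spans) * 1.2 > length)
    stop("infeasible plan: genes occupy ", sum(spans), " of ", length, " bp")
  background <- if (!is.null(repeat_free_k))
    repeat_free_dna(length, repeat_free_k, gc) else random_dna(length, gc)

  ## each trans gene contributes one placement block per exon group
  blocks <- list()
  for (gi in seq_along(gene_plan)) {
    g <- gene_plan[[gi]]
    nex <- length(g$exon_lengths)
    il <- g$intron_lengths %||% integer(0)
    if (length(il) != max(nex - 1L, 0L))
      stop("gene '", g$name, "': need ", nex - 1L, " intron lengths")
    if (isTRUE(g$trans)) {
      cut <- g$trans_after %||% (nex %/% 2L)
      groups <- list(seq_len(cut), (cut + 1L):nex)
    } else groups <- list(seq_len(nex))
    for (k in seq_along(groups)) {
      idx <- groups[[k]]
      w <- sum(g$exon_lengths[idx])
      if (length(idx) > 1L) w <- w + sum(il[idx[-length(idx)]])
      blocks[[length(blocks) + 1L]] <- list(gene = gi, group = k,
                                            exons = idx, width = w)
    }
  }
  loci <- place_intervals(length, vapply(blocks, `[[`, 1, "width"))

  features <- list(); manifest_genes <- list()
  for (gi in seq_along(gene_plan)) {
    g <- gene_plan[[gi]]
    il <- g$intron_lengths %||% integer(0)
    bix <- which(vapply(blocks, `[[`, 1L, "gene") == gi)
    exon_rows <- list(); intron_truth <- list()
    for (k in seq_along(bix)) {
      b <- blocks[[bix[k]]]
      s <- loci$start[bix[k]]
      pos <- s
      for (j in seq_along(b$exons)) {
        e_idx <- b$exons[j]
        w <- g$exon_lengths[e_idx]
        exon_rows[[length(exon_rows) + 1L]] <-
          data.frame(start = pos, end = pos + w - 1L, strand = g$strand,
                     segment = k)
        if (j < length(b$exons)) {
          iw <- il[e_idx]
          intron_truth[[length(intron_truth) + 1L]] <-
            data.frame(gene = g$name, length = iw,
                       donor = pos + w - 1L, acceptor = pos + w + iw)
          pos <- pos + w + iw
        } else pos <- pos + w
      }
    }
    ex <- do.call(rbind, exon_rows)
    if (g$strand == "-" && !isTRUE(g$trans))
      ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]  # transcript order
    features[[length(features) + 1L]] <- gene_feature(
      name = g$name, category = g$category, strand = g$strand, exons = ex,
      pseudo = isTRUE(g$pseudo), foreign = isTRUE(g$foreign),
      trans_splicing = isTRUE(g$trans))
    manifest_genes[[length(manifest_genes) + 1L]] <- list(
      name = g$name, category = g$category, strand = g$strand,
      trans = isTRUE(g$trans),
      exons = ex,
      introns = if (length(intron_truth)) do.call(rbind, intron_truth) else NULL)
  }
  features <- assign_copy_indices(features)
  genome <- mt_genome(paste0("sim", seed), background, circular = TRUE,
                      features = features)
  cis_lengths <- unlist(lapply(manifest_genes, function(m)
    if (is.null(m$introns)) NULL else m$introns$length))
  list(genome = genome,
       manifest = list(seed = seed, length = length,
                       genes = manifest_genes,
                       n_cis_introns = length(cis_lengths),
                       cis_intron_total = sum(cis_lengths)))
}

#' Apply random DCJ operations to a circular gene order
#'
#' Each operation is a segment inversion (the DCJ on two adjacencies that
#' keeps a single circular chromosome). An operation identical to the
#' immediately preceding one (which would revert it) is rejected and
#' redrawn.
#'
#' @param order a [gene_order()].
#' @param k number of operations.
#' @param seed RNG seed.
#' @return list with `order` (the rearranged [gene_order()]) and `ops`
#'   (data.frame log of cut positions).
#' @export
apply_dcj_ops <- function(order, k, seed = 1L) {
  set.seed(seed)
  n <- length(order$markers)
  if (k > 0L && n < 2L) stop("order too small for a DCJ operation")
  m <- order$markers
  ops <- data.frame(cut1 = integer(0), cut2 = integer(0))
  last <- c(NA_integer_, NA_integer_)
  for (i in seq_len(k)) {
    repeat {
      cuts <- sort(sample.int(n, 2L))
      if (cuts[2L] - cuts[1L] == 0L) next
      if (identical(cuts, last)) next     # would revert the previous op
      break
    }
    seg <- (cuts[1L] + 1L):cuts[2L]
    flipped <- vapply(rev(m[seg]), function(x)
      paste0(if (marker_sign(x) == "+") "-" else "+", marker_symbol(x)), "")
    m[seg] <- flipped
    ops <- rbind(ops, data.frame(cut1 = cuts[1L], cut2 = cuts[2L]))
    last <- cuts
  }
  list(order = gene_order(order$genome_id, m, circular = order$circular),
       ops = ops)
}

## inject a string into a genome sequence, replacing bases in place
inject <- function(sequence, at, what) {
  stopifnot(at + nchar(what) - 1L <= nchar(sequence))
  paste0(substr(sequence, 1L, at - 1L), what,
         substr(sequence, at + nchar(what), nchar(sequence)))
}

#' Plant dispersed repeats into a genome
#'
#' Each specification plants one family: a fresh random unit copied to
#' `copies` non-overlapping loci (direct or inverted per copy). Distinct
#' flanking bases are forced at every copy so the planted boundaries are
#' the maximal-repeat boundaries.
#'
#' @param genome an [mt_genome()] (ideally with a repeat-free background).
#' @param spec list of lists with `length`, `copies` (default 2), and
#'   optional `orientations` character vector per copy.
#' @param seed RNG seed.
#' @return list with `genome` and `manifest` (per family: sequence, loci,
#'   orientations).
#' @export
plant_repeats <- function(genome, spec, seed = 1L) {
  set.seed(seed)
  seqn <- genome$sequence
  n <- genome$length
  occupied <- data.frame(start = integer(0), end = integer(0))
  fams <- list()
  flank_letters <- c("A", "C", "G", "T")
  for (fs in spec) {
    copies <- fs$copies %||% 2L
    orient <- fs$orientations %||% rep("direct", copies)
    unit <- random_dna(fs$length, gc = 0.5)
    loci <- place_intervals(n, rep(fs$length + 2L, copies), pad = 4L,
                            occupied = occupied)
    occupied <- rbind(occupied, loci)
    ## distinct flank letters per copy break flank extension
    lf <- sample(flank_letters, copies, replace = copies > 4L)
    rf <- sample(flank_letters, copies, replace = copies > 4L)
    starts <- integer(copies)
    for (ci in seq_len(copies)) {
      body <- if (orient[ci] == "inverted") rev_comp(unit) else unit
      seqn <- inject(seqn, loci$start[ci], paste0(lf[ci], body, rf[ci]))
      starts[ci] <- loci$start[ci] + 1L
    }
    fams[[length(fams) + 1L]] <- list(sequence = unit, length = fs$length,
                                      starts = starts,
                                      ends = starts + fs$length - 1L,
                                      orientations = orient)
  }
  g2 <- genome; g2$sequence <- seqn
  list(genome = g2, manifest = list(seed = seed, families = fams))
}

## mutate a string to an exact target edit distance (unit-cost ops),
## verified with utils::adist; retries until the realized distance matches
mutate_to_distance <- function(s, d, max_tries = 200L) {
  if (d == 0L) return(s)
  for (t in seq_len(max_tries)) {
    x <- chars(s)
    for (i in seq_len(d)) {
      op <- sample(c("sub", "ins", "del"), 1L, prob = c(0.7, 0.15, 0.15))
      p <- sample.int(length(x), 1L)
      if (op == "sub") x[p] <- sample(setdiff(c("A", "C", "G", "T"), x[p]), 1L)
      else if (op == "ins") x <- append(x, sample(c("A", "C", "G", "T"), 1L), p)
      else if (length(x) > 1L) x <- x[-p]
    }
    out <- paste(x, collapse = "")
    if (adist(s, out) == d) return(out)
  }
  stop("could not realize edit distance ", d)
}

#' Plant consensus-motif copies at controlled edit distances
#'
#' @param genome an [mt_genome()].
#' @param consensus a [bpu_consensus()] (its sequence is the unit).
#' @param edits integer vector: one planted copy per entry, at that exact
#'   edit distance from the consensus.
#' @param strands optional "+"/"-" per copy (default random).
#' @param seed RNG seed.
#' @return list with `genome` and `manifest` (loci, distances, strands,
#'   planted sequences).
#' @export
plant_motifs <- function(genome, consensus = bpu_consensus(), edits,
                         strands = NULL, seed = 1L) {
  set.seed(seed)
  strands <- strands %||% sample(c("+", "-"), length(edits), replace = TRUE)
  seqn <- genome$sequence
  variants <- vapply(edits, function(d)
    mutate_to_distance(consensus$sequence, d), "")
  loci <- place_intervals(genome$length, nchar(variants) + 2L,
                          pad = nchar(consensus$sequence) + consensus$max_edits)
  rows <- list()
  for (i in seq_along(edits)) {
    body <- if (strands[i] == "-") rev_comp(variants[i]) else variants[i]
    seqn <- inject(seqn, loci$start[i] + 1L, body)
    rows[[length(rows) + 1L]] <- data.frame(
      start = loci$start[i] + 1L, end = loci$start[i] + nchar(body),
      strand = strands[i], edit_distance = edits[i], sequence = variants[i])
  }
  g2 <- genome; g2$sequence <- seqn
  list(genome = g2,
       manifest = list(seed = seed, planted = do.call(rbind, rows)))
}

#' Simulate a mitochondrial + plastid genome pair with planted transfers
#'
#' Copies segments of the plastid sequence into the mitochondrial sequence
#' at a controlled per-base identity (substitutions only).
#'
#' @param mt_length,cp_length genome sizes.
#' @param segments list of lists with `length`, `identity` (0-1) and
#'   optional `strand`.
#' @param seed RNG seed.
#' @param gc background GC fraction.
#' @return list with `mt`, `cp` ([mt_genome()]s) and `manifest`.
#' @export
simulate_plastid_pair <- function(mt_length, cp_length, segments, seed = 1L,
                                  gc = 0.47) {
  set.seed(seed)
  mt_seq <- random_dna(mt_length, gc)
  cp_seq <- random_dna(cp_length, gc)
  widths <- vapply(segments, `[[`, 1, "length")
  cp_loci <- place_intervals(cp_length, widths, pad = 50L)
  mt_loci <- place_intervals(mt_length, widths, pad = 50L)
  rows <- list()
  for (i in seq_along(segments)) {
    sg <- segments[[i]]
    src <- substr(cp_seq, cp_loci$start[i], cp_loci$end[i])
    x <- chars(src)
    nmut <- round((1 - sg$identity) * length(x))
    if (nmut > 0L) {
      at <- sample.int(length(x), nmut)
      x[at] <- vapply(x[at], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
    }
    strand <- sg$strand %||% "+"
    body <- paste(x, collapse = "")
    if (strand == "-") body <- rev_comp(body)
    mt_seq <- inject(mt_seq, mt_loci$start[i], body)
    rows[[length(rows) + 1L]] <- data.frame(
      mt_start = mt_loci$start[i], mt_end = mt_loci$end[i],
      cp_start = cp_loci$start[i], cp_end = cp_loci$end[i],
      strand = strand, length = sg$length,
      identity = 1 - nmut / sg$length)
  }
  list(mt = mt_genome(paste0("mt_sim", seed), mt_seq, circular = TRUE),
       cp = mt_genome(paste0("cp_sim", seed), cp_seq, circular = TRUE),
       manifest = list(seed = seed, segments = do.call(rbind, rows)))
}

#' Simulate an RNA-editing evidence dataset
#'
#' Builds random CDS references, plants C-to-U edits at controlled
#' fractions, plants genomic C->T SNP confounders (present in both DNA and
#' RNA reads), draws per-site read counts binomially, and emits a
#' prediction list with a configurable overlap against the planted
#' non-silent truth.
#'
#' @param n_cds number of CDS references.
#' @param cds_length length of each CDS (multiple of 3).
#' @param n_edits planted editing sites (across all CDS).
#' @param n_snps planted genomic SNP confounders.
#' @param edit_fraction_range range of per-site edited-read fractions.
#' @param depth_range RNA and DNA read-depth range.
#' @param prediction_recall fraction of planted non-silent edits included
#'   in the prediction list.
#' @param n_false_predictions extra predicted sites that are not edited.
#' @param error_rate per-base sequencing error rate (default 0).
#' @param seed RNG seed.
#' @return list with `evidence` (site table), `cds_sequences`,
#'   `predictions` (data.frame) and `manifest`.
#' @export
simulate_editing_dataset <- function(n_cds = 10L, cds_length = 900L,
                                     n_edits = 200L, n_snps = 20L,
                                     edit_fraction_range = c(0.3, 1.0),
                                     depth_range = c(30L, 100L),
                                     prediction_recall = 0.9,
                                     n_false_predictions = 50L,
                                     error_rate = 0, seed = 1L) {
  set.seed(seed)
  stopifnot(cds_length %% 3L == 0L)
  cds <- setNames(vapply(seq_len(n_cds), function(i)
    random_dna(cds_length, gc = 0.47), ""),
    sprintf("cds%02d", seq_len(n_cds)))
  ## all C positions, coding strand
  cpos <- do.call(rbind, lapply(names(cds), function(id) {
    p <- which(chars(cds[[id]]) == "C")
    data.frame(cds_id = id, position = p)
  }))
  if (nrow(cpos) < n_edits + n_snps)
    stop("not enough C positions for the requested edits and SNPs")
  pick <- sample.int(nrow(cpos), n_edits + n_snps)
  edit_rows <- cpos[pick[seq_len(n_edits)], , drop = FALSE]
  snp_rows <- cpos[pick[n_edits + seq_len(n_snps)], , drop = FALSE]
  edit_rows$fraction <- runif(n_edits, edit_fraction_range[1L],
                              edit_fraction_range[2L])

  per_cds <- lapply(names(cds), function(id) {
    bases <- chars(cds[[id]])
    L <- length(bases)
    rd <- depth_range[1L] + sample.int(depth_range[2L] - depth_range[1L] + 1L,
                                       L, replace = TRUE) - 1L
    dd <- depth_range[1L] + sample.int(depth_range[2L] - depth_range[1L] + 1L,
                                       L, replace = TRUE) - 1L
    base_idx <- match(bases, c("A", "C", "G", "T"))
    rna <- matrix(0L, L, 4L, dimnames = list(NULL, c("A", "C", "G", "T")))
    dna <- rna
    rna[cbind(seq_len(L), base_idx)] <- rd        # reads match the reference
    dna[cbind(seq_len(L), base_idx)] <- dd
    ep <- edit_rows$position[edit_rows$cds_id == id]
    efr <- edit_rows$fraction[edit_rows$cds_id == id]
    if (length(ep)) {
      t_n <- rbinom(length(ep), rd[ep], efr)      # edited RNA reads
      rna[ep, "C"] <- rd[ep] - t_n
      rna[ep, "T"] <- t_n
    }
    sp <- snp_rows$position[snp_rows$cds_id == id]
    if (length(sp)) {                             # genome truly carries T
      rna[sp, ] <- 0L; rna[cbind(sp, 4L)] <- rd[sp]
      dna[sp, ] <- 0L; dna[cbind(sp, 4L)] <- dd[sp]
    }
    if (error_rate > 0) {                         # scattered miscalls
      err <- rbinom(L, rd, error_rate)
      hit <- which(err > 0L)
      for (p in hit) {
        from <- which.max(rna[p, ])
        to <- sample(setdiff(1:4, from), 1L)
        k <- min(err[p], rna[p, from])
        rna[p, from] <- rna[p, from] - k
        rna[p, to] <- rna[p, to] + k
      }
    }
    data.frame(cds_id = id, position = seq_len(L), ref = bases,
               rna_depth = rd, rna_A = rna[, 1L], rna_C = rna[, 2L],
               rna_G = rna[, 3L], rna_T = rna[, 4L],
               dna_depth = dd, dna_A = dna[, 1L], dna_C = dna[, 2L],
               dna_G = dna[, 3L], dna_T = dna[, 4L])
  })
  evidence <- do.call(rbind, per_cds)

  ## predictions: a sample of the planted non-silent edits + false extras
  cls <- classify_sites(edit_rows[, c("cds_id", "position")], cds)
  nonsil <- cls[!cls$silent & cls$conversion != "indeterminate", , drop = FALSE]
  n_take <- round(prediction_recall * nrow(nonsil))
  pred <- nonsil[sample.int(nrow(nonsil), n_take), c("cds_id", "position")]
  unedited <- cpos[-pick, , drop = FALSE]
  if (n_false_predictions > 0L)
    pred <- rbind(pred, unedited[sample.int(nrow(unedited),
                                            n_false_predictions),
                                 c("cds_id", "position")])
  rownames(pred) <- NULL
  list(evidence = evidence, cds_sequences = cds, predictions = pred,
       manifest = list(seed = seed, edits = edit_rows, snps = snp_rows,
                       n_nonsilent_planted = nrow(nonsil)))
}

#' Write a truth manifest as JSON
#' @param manifest a manifest list from any simulator.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
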