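## Empirical C-to-U RNA-editing detection on coding sequences.
##
## Evidence is a per-site pileup over each CDS (coding strand): RNA read
## depth and per-base counts, and optionally the same from genomic DNA
## reads used to remove genomic SNPs masquerading as editing. Plant
## mitochondrial editing is overwhelmingly C-to-U, observed as C->T
## mismatches between RNA reads and the genomic reference; only that event
## type is ever called.

#' Read / write a site-evidence pileup table
#'
#' Columns: cds_id, position (1-based within the CDS), ref, rna_depth,
#' rna_A, rna_C, rna_G, rna_T, dna_depth, dna_A, dna_C, dna_G, dna_T.
#' DNA columns may be NA when no genomic evidence exists at a site.
#'
#' @param path TSV path.
#' @return data.frame of site evidence.
#' @export
read_pileup <- function(path) {
  ev <- read_tsv(path)
  need <- c("cds_id", "position", "ref", "rna_depth",
            "rna_A", "rna_C", "rna_G", "rna_T")
  if (!all(need %in% names(ev)))
    stop("pileup lacks required columns: ",
         paste(setdiff(need, names(ev)), collapse = ", "))
  ev
}

#' @rdname read_pileup
#' @param evidence pileup data.frame.
#' @export
write_pileup <- function(evidence, path) write_tsv(evidence, path)

#' Build a pileup from SAM alignments
#'
#' Adapter from read alignments to the native per-site evidence format:
#' the SAM file (reads mapped against the CDS reference, coding-strand
#' oriented) is converted to BAM and piled up with Rsamtools.
#'
#' @param sam_path SAM file of reads mapped to CDS references.
#' @param cds_sequences named character vector of the CDS reference
#'   sequences (for the ref column).
#' @return data.frame with cds_id, position, ref, depth and per-base
#'   counts, suitable for the `rna_*` or `dna_*` half of the evidence
#'   table (see [combine_evidence()]).
#' @export
pileup_from_sam <- function(sam_path, cds_sequences) {
  bam <- Rsamtools::asBam(sam_path, destination = tempfile("aln"),
                          overwrite = TRUE, indexDestination = TRUE)
  pp <- Rsamtools::PileupParam(max_depth = 100000L, min_base_quality = 0L,
                               min_mapq = 0L, distinguish_strands = FALSE,
                               distinguish_nucleotides = TRUE,
                               include_deletions = FALSE,
                               include_insertions = FALSE)
  p <- Rsamtools::pileup(bam, pileupParam = pp)
  if (nrow(p) == 0L)
    return(data.frame(cds_id = character(0), position = integer(0),
                      ref = character(0), depth = integer(0), A = integer(0),
                      C = integer(0), G = integer(0), T = integer(0)))
  wide <- stats::reshape(p[, c("seqnames", "pos", "nucleotide", "count")],
                         idvar = c("seqnames", "pos"),
                         timevar = "nucleotide", direction = "wide")
  names(wide) <- sub("^count\\.", "", names(wide))
  for (b in c("A", "C", "G", "T"))
    if (is.null(wide[[b]])) wide[[b]] <- 0L else
      wide[[b]][is.na(wide[[b]])] <- 0L
  out <- data.frame(cds_id = as.character(wide$seqnames),
                    position = wide$pos,
                    depth = wide$A + wide$C + wide$G + wide$T,
                    A = wide$A, C = wide$C, G = wide$G, T = wide$T)
  out$ref <- toupper(substring(cds_sequences[out$cds_id], out$position,
                               out$position))
  out[order(out$cds_id, out$position),
      c("cds_id", "position", "ref", "depth", "A", "C", "G", "T")]
}

#' Combine RNA and DNA pileups into one evidence table
#' @param rna,dna data.frames from [pileup_from_sam()] (dna may be NULL).
#' @return site-evidence data.frame as in [read_pileup()].
#' @export
combine_evidence <- function(rna, dna = NULL) {
  ev <- data.frame(cds_id = rna$cds_id, position = rna$position, ref = rna$ref,
                   rna_depth = rna$depth, rna_A = rna$A, rna_C = rna$C,
                   rna_G = rna$G, rna_T = rna$T,
                   dna_depth = NA_integer_, dna_A = NA_integer_,
                   dna_C = NA_integer_, dna_G = NA_integer_,
                   dna_T = NA_integer_)
  if (!is.null(dna) && nrow(dna) > 0L) {
    key <- paste(ev$cds_id, ev$position)
    dkey <- paste(dna$cds_id, dna$position)
    m <- match(key, dkey)
    ok <- !is.na(m)
    ev$dna_depth[ok] <- dna$depth[m[ok]]
    ev$dna_A[ok] <- dna$A[m[ok]]; ev$dna_C[ok] <- dna$C[m[ok]]
    ev$dna_G[ok] <- dna$G[m[ok]]; ev$dna_T[ok] <- dna$T[m[ok]]
  }
  ev
}

#' Call candidate C-to-U editing sites from RNA evidence
#'
#' A site is called when the reference base is C (coding strand), RNA
#' depth is at least `min_depth`, and the T fraction among RNA reads is at
#' least `min_fraction`. No other substitution type is ever called.
#'
#' @param evidence site-evidence data.frame.
#' @param min_depth minimum RNA read depth.
#' @param min_fraction minimum edited (T) read fraction.
#' @return data.frame of candidate sites: cds_id, position, ref,
#'   edit_fraction, rna_depth, support = "empirical".
#' @export
call_candidate_sites <- function(evidence, min_depth = 10L, min_fraction = 0.1) {
  bad <- !evidence$ref %in% c("A", "C", "G", "T")
  if (any(bad)) {
    warning(sum(bad), " site(s) with ambiguous reference base skipped",
            call. = FALSE)
    evidence <- evidence[!bad, , drop = FALSE]
  }
  frac <- ifelse(evidence$rna_depth > 0L, evidence$rna_T / evidence$rna_depth, 0)
  sel <- evidence$ref == "C" & evidence$rna_depth >= min_depth &
    frac >= min_fraction
  out <- data.frame(cds_id = evidence$cds_id[sel],
                    position = evidence$position[sel],
                    ref = evidence$ref[sel],
                    edit_fraction = frac[sel],
                    rna_depth = evidence$rna_depth[sel],
                    support = if (any(sel)) "empirical" else character(0))
  rownames(out) <- NULL
  out
}

#' Remove candidates explained by genomic SNPs
#'
#' A candidate is removed when genomic DNA reads support a non-reference
#' base at the same position at a fraction of at least `snp_fraction` with
#' depth at least `min_dna_depth`. Candidates without DNA evidence are
#' kept and flagged `unverified`.
#'
#' @param sites candidate data.frame from [call_candidate_sites()].
#' @param evidence the full site-evidence table.
#' @param snp_fraction minimum non-reference DNA fraction for removal.
#' @param min_dna_depth minimum DNA depth for a verdict.
#' @return list with `sites` (kept candidates, plus a `verified` logical)
#'   and `removed` (the genomic-SNP candidates).
#' @export
filter_genomic_snps <- function(sites, evidence, snp_fraction = 0.2,
                                min_dna_depth = 10L) {
  key <- paste(sites$cds_id, sites$position)
  ekey <- paste(evidence$cds_id, evidence$position)
  m <- match(key, ekey)
  refcol <- paste0("dna_", sites$ref)
  nonref <- vapply(seq_len(nrow(sites)), function(i) {
    if (is.na(m[i])) return(NA_real_)
    dd <- evidence$dna_depth[m[i]]
    if (is.na(dd) || dd < min_dna_depth) return(NA_real_)
    (dd - evidence[[refcol[i]]][m[i]]) / dd
  }, 1)
  is_snp <- !is.na(nonref) & nonref >= snp_fraction
  kept <- sites[!is_snp, , drop = FALSE]
  kept$verified <- !is.na(nonref[!is_snp])
  rownames(kept) <- NULL
  list(sites = kept, removed = sites[is_snp, , drop = FALSE])
}

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", `*` = "Stop")

## default hydropathy partition, chosen so the canonical plant editing
## conversions (e.g. Pro->Leu, Ser->Leu, Ser->Phe) read hydrophilic ->
## hydrophobic; Gly, Pro and Tyr count as hydrophilic here.
HYDROPHOBIC_AA <- c("A", "V", "L", "I", "F", "M", "W", "C")

#' Classify editing sites by codon context
#'
#' Adds codon position, the amino acids before and after the edit
#' (standard genetic code), the silent flag, a conversion label
#' ("Pro->Leu") and the hydropathy transition class.
#'
#' @param sites data.frame with cds_id and position.
#' @param cds_sequences named character vector of CDS sequences
#'   (coding strand).
#' @param hydrophobic amino-acid single-letter set treated as hydrophobic.
#' @return the input with columns codon_position, codon_before,
#'   codon_after, aa_before, aa_after, silent, conversion, hydropathy
#'   appended; codons containing N are classified "indeterminate".
#' @export
classify_sites <- function(sites, cds_sequences,
                           hydrophobic = HYDROPHOBIC_AA) {
  code <- Biostrings::GENETIC_CODE
  hyd <- function(aa) {
    if (aa == "*") "stop" else if (aa %in% hydrophobic) "phob" else "phil"
  }
  n <- nrow(sites)
  out <- sites
  out$codon_position <- ((sites$position - 1L) %% 3L) + 1L
  cb <- ca <- ab <- aa <- conv <- hyc <- character(n)
  sil <- logical(n)
  for (i in seq_len(n)) {
    s <- cds_sequences[[sites$cds_id[i]]]
    if (is.null(s) || is.na(s)) stop("unknown cds_id: ", sites$cds_id[i])
    if (nchar(s) %% 3L != 0L && sites$position[i] > 3L * (nchar(s) %/% 3L)) {
      cb[i] <- ca[i] <- ab[i] <- aa[i] <- conv[i] <- hyc[i] <- "indeterminate"
      next
    }
    cstart <- sites$position[i] - out$codon_position[i] + 1L
    codon <- toupper(substr(s, cstart, cstart + 2L))
    edited <- codon
    substr(edited, out$codon_position[i], out$codon_position[i]) <- "T"
    if (grepl("N", codon, fixed = TRUE)) {
      cb[i] <- ca[i] <- ab[i] <- aa[i] <- conv[i] <- hyc[i] <- "indeterminate"
      next
    }
    a1 <- code[[codon]]; a2 <- code[[edited]]
    cb[i] <- codon; ca[i] <- edited
    ab[i] <- a1; aa[i] <- a2
    sil[i] <- a1 == a2
    conv[i] <- paste0(AA3[[a1]], "->", AA3[[a2]])
    hyc[i] <- paste0(hyd(a1), "->", hyd(a2))
  }
  out$codon_before <- cb; out$codon_after <- ca
  out$aa_before <- ab; out$aa_after <- aa
  out$silent <- sil; out$conversion <- conv; out$hydropathy <- hyc
  out
}

#' Compare empirical editing sites with a prediction list
#'
#' Predictions (e.g. from an in-silico editing predictor) cover non-silent
#' sites only, so silent empirical sites are reported separately and the
#' confirmed total is shared non-silent sites plus empirical silent sites.
#'
#' @param empirical classified empirical sites ([classify_sites()]).
#' @param predicted data.frame with cds_id and position columns (or a TSV
#'   path to one).
#' @return list of counts and the partitioned site tables.
#' @export
compare_with_predictions <- function(empirical, predicted) {
  if (is.character(predicted)) predicted <- read_tsv(predicted)
  known <- unique(empirical$cds_id)
  unk <- !predicted$cds_id %in% known
  if (any(unk)) {
    warning(sum(unk), " prediction(s) for unknown cds_id skipped", call. = FALSE)
    predicted <- predicted[!unk, , drop = FALSE]
  }
  ekey <- paste(empirical$cds_id, empirical$position)
  pkey <- unique(paste(predicted$cds_id, predicted$position))
  emp_nonsilent <- empirical[!empirical$silent, , drop = FALSE]
  emp_silent <- empirical[empirical$silent, , drop = FALSE]
  nskey <- paste(emp_nonsilent$cds_id, emp_nonsilent$position)
  shared <- emp_nonsilent[nskey %in% pkey, , drop = FALSE]
  emp_only <- emp_nonsilent[!nskey %in% pkey, , drop = FALSE]
  pred_only <- setdiff(pkey, ekey)
  list(n_predicted = length(pkey),
       n_empirical = nrow(empirical),
       n_shared = nrow(shared),
       n_empirical_silent = nrow(emp_silent),
       n_confirmed = nrow(shared) + nrow(emp_silent),
       n_predicted_only = length(pred_only),
       n_empirical_only_nonsilent = nrow(emp_only),
       shared = shared, empirical_only = emp_only, silent = emp_silent)
}

#' Per-gene editing frequency
#'
#' The editing-frequency statistic: 100 times the number of edited sites
#' divided by the gene length in bases.
#'
#' @param site_count number of edited sites (A).
#' @param gene_length gene length in bases (B).
#' @return percentage, 100 * A / B.
#' @export
editing_frequency <- function(site_count, gene_length) {
  if (any(gene_length <= 0)) stop("gene_length must be positive")
  100 * site_count / gene_length
}

#' Summarize classified editing sites
#'
#' @param sites classified site data.frame.
#' @param cds_lengths optional named vector of CDS lengths for per-gene
#'   frequencies.
#' @return list with totals, codon-position counts and percentages,
#'   amino-acid conversion counts (descending), hydropathy proportions
#'   over non-silent conversion events, and per-gene editing frequencies.
#' @export
summarize_editing <- function(sites, cds_lengths = NULL) {
  total <- nrow(sites)
  cp <- table(factor(sites$codon_position, levels = 1:3))
  conv <- sort(table(sites$conversion[!sites$silent &
                                        sites$conversion != "indeterminate"]),
               decreasing = TRUE)
  hy <- sites$hydropathy[!sites$silent & !sites$hydropathy %in%
                           c("indeterminate") & !grepl("stop", sites$hydropathy)]
  hyp <- if (length(hy)) table(hy) / length(hy) else table(character(0))
  freq <- NULL
  if (!is.null(cds_lengths)) {
    cnt <- table(sites$cds_id)
    genes <- names(cds_lengths)
    freq <- data.frame(gene = genes,
                       n_sites = as.integer(ifelse(is.na(cnt[genes]), 0L,
                                                   cnt[genes])),
                       length = as.integer(cds_lengths))
    freq$frequency <- editing_frequency(freq$n_sites, freq$length)
  }
  list(total_sites = total,
       codon_position_counts = as.integer(cp),
       codon_position_pct = if (total > 0L) 100 * as.integer(cp) / total
                            else rep(0, 3L),
       conversion_counts = conv,
       hydropathy_proportions = hyp,
       per_gene_frequency = freq,
       n_silent = sum(sites$silent))
}
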