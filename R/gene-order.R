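#' Construct a signed gene order
#'
#' @param genome_id genome label.
#' @param markers character vector of signed marker symbols, each of the
#'   form `+name` or `-name`.
#' @param circular logical.
#' @return object of class `gene_order`.
#' @export
gene_order <- function(genome_id, markers, circular = TRUE) {
  if (length(markers) == 0L) stop("gene order for '", genome_id, "' is empty")
  if (!all(grepl("^[+-].", markers)))
    stop("markers must be signed, e.g. '+nad5'; got: ",
         paste(head(markers[!grepl("^[+-].", markers)], 3L), collapse = ", "))
  structure(list(genome_id = genome_id, markers = markers,
                 circular = isTRUE(circular)),
            class = "gene_order")
}

#' @export
print.gene_order <- function(x, ...) {
  cat(sprintf("<gene_order> %s (%s, %d markers): %s\n", x$genome_id,
              if (x$circular) "circular" else "linear", length(x$markers),
              paste(head(x$markers, 8L), collapse = " "),
              if (length(x$markers) > 8L) "..." else ""))
  invisible(x)
}

marker_sign <- function(m) substr(m, 1L, 1L)
marker_symbol <- function(m) substr(m, 2L, nchar(m))
## base symbol = symbol with a per-genome duplicate suffix "#k" removed
marker_base <- function(sym) sub("#[0-9]+$", "", sym)

## split a trans-spliced feature's exons (transcript order) into its
## disjoint loci: by the explicit `segment` column when the annotation
## carries one, otherwise into contiguous same-strand,
## coordinate-monotonic groups
split_trans_segments <- function(f) {
  ex <- f$exons
  k <- nrow(ex)
  if (k == 1L) return(list(ex))
  if (!is.null(ex$segment) && !anyNA(ex$segment)) {
    grp <- cumsum(c(0L, diff(as.integer(factor(ex$segment,
                                               levels = unique(ex$segment)))) != 0L))
    return(lapply(split(seq_len(k), grp), function(idx) ex[idx, , drop = FALSE]))
  }
  brk <- logical(k - 1L)
  for (i in seq_len(k - 1L)) {
    same_strand <- ex$strand[i + 1L] == ex$strand[i]
    mono <- if (ex$strand[i] == "+") ex$start[i + 1L] > ex$end[i]
            else ex$end[i + 1L] < ex$start[i]
    brk[i] <- !(same_strand && mono)
  }
  grp <- cumsum(c(0L, brk))
  lapply(split(seq_len(k), grp), function(idx) ex[idx, , drop = FALSE])
}

#' Extract the signed gene order of an annotated genome
#'
#' Markers are the genes of the included categories, sorted by the genomic
#' coordinate of each feature's (or trans-segment's) first exon; the sign is
#' the coding strand. Each contiguous exon group of a trans-spliced gene
#' becomes an independent marker `gene_segK` (K in genome-coordinate order),
#' and duplicated genes get distinct suffixes `#1`, `#2`, ... in coordinate
#' order. Pseudogenes and foreign (plastid-/nuclear-derived) copies are
#' removed when the corresponding flag is set.
#'
#' @param genome an [mt_genome()].
#' @param include character vector of categories to keep.
#' @param drop_pseudo,drop_foreign logicals.
#' @return a [gene_order()].
#' @export
extract_gene_order <- function(genome, include = c("PCG", "tRNA", "rRNA"),
                               drop_pseudo = TRUE, drop_foreign = TRUE) {
  feats <- Filter(function(f) {
    f$category %in% include &&
      !(drop_pseudo && f$pseudo) && !(drop_foreign && f$foreign)
  }, genome$features)
  if (length(feats) == 0L)
    stop("no features left after filtering (include = ",
         paste(include, collapse = "/"), ", drop_pseudo = ", drop_pseudo,
         ", drop_foreign = ", drop_foreign, ") in genome '", genome$id, "'")

  ## expand into marker candidates: (symbol, sign, first coordinate)
  cand <- list()
  for (f in feats) {
    if (f$trans_splicing) {
      segs <- split_trans_segments(f)
      ## ordinal by genome coordinate of the segments
      seg_first <- vapply(segs, function(e) min(e$start), 1)
      ord <- order(seg_first)
      for (k in seq_along(ord)) {
        e <- segs[[ord[k]]]
        cand[[length(cand) + 1L]] <- list(
          symbol = paste0(f$name, "_seg", k),
          sign = if (e$strand[1L] == "-") "-" else "+",
          ## position by the segment's first exon in transcript order
          first = e$start[1L])
      }
    } else {
      cand[[length(cand) + 1L]] <- list(symbol = f$name, sign = f$strand,
                                        first = feature_first_coord(f))
    }
  }
  syms <- vapply(cand, `[[`, "", "symbol")
  firsts <- vapply(cand, `[[`, 1, "first")
  signs <- vapply(cand, `[[`, "", "sign")

  ## duplicate suffixes in coordinate order
  for (nm in unique(syms[duplicated(syms)])) {
    idx <- which(syms == nm)
    ord <- idx[order(firsts[idx])]
    for (k in seq_along(ord)) syms[ord[k]] <- paste0(nm, "#", k)
  }
  ord <- order(firsts)
  gene_order(genome$id, paste0(signs[ord], syms[ord]), circular = genome$circular)
}

#' Write gene orders to a TSV table
#'
#' One genome per row: the genome id followed by its tab-separated signed
#' markers (the shape of a gene-order supplementary matrix). Round-trips
#' losslessly through [read_gene_order_table()].
#'
#' @param orders list of [gene_order()] objects.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_gene_order_table <- function(orders, path) {
  ids <- vapply(orders, function(o) o$genome_id, "")
  if (anyDuplicated(ids)) stop("duplicate genome_id: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  lines <- vapply(orders, function(o)
    paste(c(o$genome_id, o$markers), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-order TSV table
#' @param path file written by [write_gene_order_table()] (or of the same
#'   shape: id then signed markers, tab-separated, no header).
#' @param circular logical applied to every order.
#' @return list of [gene_order()] objects.
#' @export
read_gene_order_table <- function(path, circular = TRUE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    gene_order(parts[1L], parts[-1L], circular = circular)
  })
}
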