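## Minimal GenBank flat-file reader.
##
## Parses LOCUS (length/topology), the FEATURES table (CDS/tRNA/rRNA keys,
## join/order/complement locations, qualifiers) and ORIGIN. This is a small
## purpose-built parser: it covers the subset of the format produced by the
## common organellar annotation tools, not the full INSDC grammar.

parse_gb_location <- function(loc, line = NA_integer_) {
  loc <- gsub("[<>]", "", gsub("[[:space:]]", "", loc))
  parse1 <- function(s, strand) {
    if (grepl("^complement\\(", s)) {
      inner <- substr(s, 12L, nchar(s) - 1L)
      ## complement reverses both strand and part order (transcript order)
      parts <- parse1(inner, if (strand == "+") "-" else "+")
      return(parts[rev(seq_len(nrow(parts))), , drop = FALSE])
    }
    if (grepl("^(join|order)\\(", s)) {
      inner <- sub("^(join|order)\\(", "", s)
      inner <- substr(inner, 1L, nchar(inner) - 1L)
      ## split on top-level commas
      depth <- 0L; cuts <- integer(0)
      cs <- chars(inner)
      for (i in seq_along(cs)) {
        if (cs[i] == "(") depth <- depth + 1L
        else if (cs[i] == ")") depth <- depth - 1L
        else if (cs[i] == "," && depth == 0L) cuts <- c(cuts, i)
      }
      starts <- c(1L, cuts + 1L); ends <- c(cuts - 1L, nchar(inner))
      parts <- lapply(seq_along(starts), function(i)
        parse1(substr(inner, starts[i], ends[i]), strand))
      return(do.call(rbind, parts))
    }
    m <- regmatches(s, regexec("^([0-9]+)\\.\\.([0-9]+)$", s))[[1L]]
    if (length(m) == 3L)
      return(data.frame(start = as.integer(m[2L]), end = as.integer(m[3L]),
                        strand = strand))
    if (grepl("^[0-9]+$", s))
      return(data.frame(start = as.integer(s), end = as.integer(s), strand = strand))
    stop("cannot parse GenBank location '", loc, "'",
         if (!is.na(line)) paste0(" (line ", line, ")") else "", call. = FALSE)
  }
  parts <- parse1(loc, "+")
  rownames(parts) <- NULL
  parts
}

gb_qualifiers <- function(qlines) {
  ## qualifier lines already joined; returns named character vector
  out <- character(0)
  for (q in qlines) {
    m <- regmatches(q, regexec('^/([A-Za-z_0-9]+)(=(.*))?$', q))[[1L]]
    if (length(m) == 0L) next
    val <- if (is.na(m[4L]) || m[4L] == "") "TRUE" else gsub('^"|"$', "", m[4L])
    out[m[2L]] <- val
  }
  out
}

read_genbank <- function(path, circular = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty GenBank file: ", path)

  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0L) stop("malformed GenBank file (no LOCUS line): ", path)
  toks <- strsplit(trimws(locus[1L]), "[[:space:]]+")[[1L]]
  gid <- toks[2L]
  circ <- if (!is.null(circular)) circular else any(grepl("circular", locus[1L]))

  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  if (length(ostart) == 0L) stop("malformed GenBank file (no ORIGIN): ", path)

  ## --- sequence ---
  seq_lines <- lines[(ostart[1L] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) == 0L) stop("zero-length sequence in ", path)
  n <- nchar(sequence)

  ## --- features ---
  features <- list(); ignored <- character(0)
  if (length(fstart) > 0L) {
    flines <- lines[(fstart[1L] + 1L):(ostart[1L] - 1L)]
    ## group raw feature blocks
    key_idx <- grep("^ {5}\\S", flines)
    for (bi in seq_along(key_idx)) {
      i0 <- key_idx[bi]
      i1 <- if (bi < length(key_idx)) key_idx[bi + 1L] - 1L else length(flines)
      block <- flines[i0:i1]
      key <- sub("^ {5}(\\S+).*$", "\\1", block[1L])
      body <- trimws(c(sub("^ {5}\\S+\\s*", "", block[1L]), block[-1L]))
      ## location = leading lines up to the first qualifier
      qstart <- grep("^/", body)
      loc_str <- paste(body[seq_len(if (length(qstart)) qstart[1L] - 1L else length(body))],
                       collapse = "")
      quals <- character(0)
      if (length(qstart)) {
        ## re-join qualifier continuation lines
        qlines <- body[qstart[1L]:length(body)]
        joined <- character(0)
        for (q in qlines) {
          if (grepl("^/", q) || length(joined) == 0L) joined <- c(joined, q)
          else joined[length(joined)] <- paste(joined[length(joined)], q)
        }
        quals <- gb_qualifiers(joined)
      }
      if (key %in% c("source", "gene", "exon", "intron", "misc_feature")) next
      if (!key %in% c("CDS", "tRNA", "rRNA")) { ignored <- c(ignored, key); next }

      exons <- parse_gb_location(loc_str, line = fstart[1L] + i0)
      qget <- function(k) if (k %in% names(quals)) quals[[k]] else NULL
      name <- qget("gene") %||% qget("locus_tag") %||% paste0(key, "_", bi)
      note <- tolower(qget("note") %||% "")
      trans <- !is.null(qget("trans_splicing")) ||
        identical(tolower(qget("exception") %||% ""), "trans-splicing")
      wrap <- !trans && any(exons$end == n) && any(exons$start == 1L) &&
        nrow(exons) > 1L
      strand <- names(sort(table(exons$strand), decreasing = TRUE))[1L]
      iid <- qget("intron_ids")
      features[[length(features) + 1L]] <- gene_feature(
        name = name,
        category = c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA")[[key]],
        strand = strand, exons = exons,
        pseudo = !is.null(qget("pseudo")),
        foreign = grepl("plastid|chloroplast|nuclear", note) || grepl("-cp$", name),
        trans_splicing = trans, origin_spanning = wrap,
        intron_ids = if (!is.null(iid)) strsplit(iid, ",", fixed = TRUE)[[1L]] else NULL)
    }
  }
  if (length(ignored) > 0L)
    warning("ignored unknown feature kinds: ", paste(unique(ignored), collapse = ", "),
            call. = FALSE)
  g <- mt_genome(gid, sequence, circular = circ, features = features)
  g$features <- assign_copy_indices(g$features)
  g
}

## per-genome duplicate numbering: copy_index = coordinate rank among
## same-named features (1 for unique genes)
assign_copy_indices <- function(features) {
  if (length(features) == 0L) return(features)
  nms <- vapply(features, function(f) f$name, "")
  firsts <- vapply(features, feature_first_coord, 1L)
  for (nm in unique(nms)) {
    idx <- which(nms == nm)
    ord <- idx[order(firsts[idx])]
    for (k in seq_along(ord)) features[[ord[k]]]$copy_index <- k
  }
  features
}
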