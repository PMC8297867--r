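# Independent oracles used to validate the fast implementations. These are
# deliberately written from the definitions (full enumeration, base-R
# adist DP, breadth-first search) and share no code with the package paths
# they check.

# ---- maximal exact repeats: per-length full enumeration -----------------

# enumerate every maximal repeat family (left- and right-diverse occurrence
# set) of length >= min_length by scanning all substring lengths upward
# until no length has a duplicated substring
oracle_maximal_repeats <- function(seq, min_length, include_inverted = TRUE,
                                   circular = FALSE) {
  n <- nchar(seq)
  text <- if (circular && n > min_length)
    paste0(seq, substr(seq, 1, min_length - 1)) else seq
  nt <- nchar(text)
  comp1 <- function(b) chartr("ACGTN", "TGCAN", b)
  rc <- function(x) mitostruct::rev_comp(x)
  res <- list()
  l <- min_length
  repeat {
    if (l > nt) break
    nw <- nt - l + 1
    subs <- substring(text, 1:nw, l:nt)
    rcs <- if (include_inverted) vapply(subs, rc, "", USE.NAMES = FALSE) else subs
    canon <- pmin(subs, rcs)
    groups <- split(seq_len(nw), canon)
    groups <- groups[lengths(groups) >= 2]
    for (Cn in names(groups)) {
      pos <- groups[[Cn]]
      ori <- ifelse(subs[pos] == Cn | subs[pos] == rcs[pos], "direct", "inverted")
      lefts <- rights <- character(length(pos))
      for (i in seq_along(pos)) {
        p <- pos[i]
        if (ori[i] == "direct") {
          lefts[i] <- if (p > 1) substr(text, p - 1, p - 1) else paste0("^", i)
          rights[i] <- if (p + l <= nt) substr(text, p + l, p + l) else paste0("$", i)
        } else {
          lefts[i] <- if (p + l <= nt) comp1(substr(text, p + l, p + l)) else paste0("^", i)
          rights[i] <- if (p > 1) comp1(substr(text, p - 1, p - 1)) else paste0("$", i)
        }
      }
      if (length(unique(lefts)) > 1 && length(unique(rights)) > 1) {
        occ <- data.frame(start = pos, end = pos + l - 1, orientation = ori)
        occ <- occ[occ$start <= n, , drop = FALSE]
        occ <- occ[order(occ$start), , drop = FALSE]
        if (nrow(occ) >= 2)
          res[[length(res) + 1]] <- list(sequence = Cn, length = l,
                                         occurrences = occ)
      }
    }
    if (length(groups) == 0) break
    l <- l + 1
  }
  oracle_repeat_filters(res)
}

# the documented tandem / nested post-filters, applied from their
# definitions
oracle_repeat_filters <- function(fams) {
  out <- list()
  for (f in fams) {
    occ <- f$occurrences
    L <- f$length
    drop <- rep(FALSE, nrow(occ))
    if (nrow(occ) >= 2)
      for (i in seq_len(nrow(occ) - 1))
        if (occ$start[i + 1] <= occ$start[i] + L) drop[c(i, i + 1)] <- TRUE
    occ <- occ[!drop, , drop = FALSE]
    if (nrow(occ) >= 2) {
      f$occurrences <- occ
      out[[length(out) + 1]] <- f
    }
  }
  if (length(out) == 0) return(out)
  lens <- vapply(out, `[[`, 1, "length")
  ord <- order(-lens, vapply(out, `[[`, "", "sequence"))
  out <- out[ord]; lens <- lens[ord]
  keep <- rep(TRUE, length(out))
  for (i in seq_along(out)) {
    if (i == 1) next
    oc <- out[[i]]$occurrences
    inside <- vapply(seq_len(nrow(oc)), function(r) {
      for (j in seq_len(i - 1)) {
        if (!keep[j] || lens[j] <= lens[i]) next
        oj <- out[[j]]$occurrences
        if (any(oj$start <= oc$start[r] & oj$end >= oc$end[r])) return(TRUE)
      }
      FALSE
    }, TRUE)
    if (all(inside)) keep[i] <- FALSE
  }
  out[keep]
}

# canonical comparable form of a family set
repeat_signature <- function(fams) {
  if (inherits(fams, "repeat_families")) fams <- fams$families
  sig <- vapply(fams, function(f)
    paste(f$sequence,
          paste(f$occurrences$start, f$occurrences$end,
                f$occurrences$orientation, sep = ",", collapse = ";"),
          sep = "|"), "")
  sort(sig)
}

# ---- bounded edit-distance motif scan: adist window oracle ---------------

# per-end minimal semi-global distance via utils::adist over every window
# length the edit bound allows
oracle_end_dists <- function(pattern, text, max_edits) {
  m <- nchar(pattern); nt <- nchar(text)
  lens <- max(1, m - max_edits):(m + max_edits)
  d <- rep(Inf, nt)
  for (L in lens) {
    if (L > nt) next
    e <- L:nt
    w <- substring(text, e - L + 1, e)
    dd <- as.vector(utils::adist(pattern, w))
    d[e] <- pmin(d[e], dd)
  }
  d
}

# full independent scan: both strands, documented circular preprocessing,
# leftmost-minimal start, greedy (distance, start, strand) selection
oracle_bpu_scan <- function(seq, consensus_seq, max_edits, circular = TRUE) {
  m <- nchar(consensus_seq)
  n <- nchar(seq)
  wrapn <- if (circular) min(m + max_edits - 1, n) else 0
  text <- if (wrapn > 0) paste0(seq, substr(seq, 1, wrapn)) else seq
  nt <- nchar(text)
  cand <- NULL
  for (strand in c("+", "-")) {
    t2 <- if (strand == "+") text else mitostruct::rev_comp(text)
    d <- oracle_end_dists(consensus_seq, t2, max_edits)
    for (e in which(d <= max_edits)) {
      # tightest window achieving the minimum
      best_s <- NA
      for (L in max(1, m - max_edits):(m + max_edits)) {
        s <- e - L + 1
        if (s < 1 || L > nchar(t2)) next
        if (utils::adist(consensus_seq, substr(t2, s, e)) == d[e]) {
          best_s <- s; break
        }
      }
      gs <- if (strand == "+") best_s else nt - e + 1
      ge <- if (strand == "+") e else nt - best_s + 1
      cand <- rbind(cand, data.frame(start = gs, end = ge, strand = strand,
                                     edit_distance = d[e]))
    }
  }
  if (is.null(cand))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), edit_distance = integer(0)))
  sh <- cand$start > n
  cand$start[sh] <- cand$start[sh] - n
  cand$end[sh] <- cand$end[sh] - n
  cand <- cand[!duplicated(cand[, c("start", "end", "strand")]), , drop = FALSE]
  cand <- cand[order(cand$edit_distance, cand$start, cand$strand), , drop = FALSE]
  acc_s <- acc_e <- integer(0); take <- integer(0)
  for (i in seq_len(nrow(cand))) {
    s <- cand$start[i]; e <- cand$end[i]
    clash <- length(acc_s) > 0 &&
      (any(acc_s <= e & acc_e >= s) ||
         (circular && (any(acc_s <= e - n & acc_e >= s - n) ||
                         any(acc_s <= e + n & acc_e >= s + n))))
    if (!clash) {
      take <- c(take, i); acc_s <- c(acc_s, s); acc_e <- c(acc_e, e)
    }
  }
  out <- cand[take, , drop = FALSE]
  rownames(out) <- NULL
  out
}

hit_signature <- function(hits) {
  if (nrow(hits) == 0) return(character(0))
  sort(paste(hits$start, hits$end, hits$strand, hits$edit_distance, sep = "/"))
}

# ---- random signed circular orders ---------------------------------------

random_signed_order <- function(n, id = "G") {
  syms <- if (n <= 26) letters[seq_len(n)] else sprintf("m%02d", seq_len(n))
  mitostruct::gene_order(
    id, paste0(sample(c("+", "-"), n, replace = TRUE), sample(syms)))
}
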