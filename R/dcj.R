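## Double-cut-and-join (DCJ) rearrangement distances between signed
## circular gene orders. A genome over n single-copy markers is a set of n
## adjacencies between marker extremities (tail t, head h); the DCJ
## distance for two circular genomes is n minus the number of cycles of the
## adjacency graph.

## extremity coding: marker i -> tail 2i-1, head 2i
order_to_adjacencies <- function(markers, symbols) {
  idx <- match(vapply(markers, marker_symbol, ""), symbols)
  sign <- vapply(markers, marker_sign, "")
  n <- length(markers)
  right_ext <- ifelse(sign == "+", 2L * idx, 2L * idx - 1L)   # exit extremity
  left_ext <- ifelse(sign == "+", 2L * idx - 1L, 2L * idx)    # entry extremity
  a <- right_ext
  b <- left_ext[c(2:n, 1L)[seq_len(n)]]
  if (n == 1L) b <- left_ext                                  # self-adjacency
  cbind(pmin(a, b), pmax(a, b))
}

adjacency_partner <- function(adjs, n_ext) {
  partner <- integer(n_ext)
  partner[adjs[, 1L]] <- adjs[, 2L]
  partner[adjs[, 2L]] <- adjs[, 1L]
  partner
}

#' Restrict two gene orders to their shared single-copy markers
#'
#' Cross-genome matching is by base symbol (per-genome duplicate suffixes
#' `#k` stripped): a symbol is retained only when it occurs exactly once in
#' both genomes. Everything else is dropped with a reason (absent in the
#' partner genome, or multi-copy in either). Trans-spliced segment markers
#' (`_segK`) are distinct symbols and are matched as such.
#'
#' @param order_a,order_b [gene_order()] objects.
#' @return list with `shared` (character vector of retained base symbols),
#'   `dropped_a`, `dropped_b` (data.frames symbol/reason) and `reduced_a`,
#'   `reduced_b` (the reduced [gene_order()]s).
#' @export
build_marker_universe <- function(order_a, order_b) {
  base_a <- marker_base(vapply(order_a$markers, marker_symbol, ""))
  base_b <- marker_base(vapply(order_b$markers, marker_symbol, ""))
  ta <- table(base_a); tb <- table(base_b)
  shared <- intersect(names(ta)[ta == 1L], names(tb)[tb == 1L])
  reason <- function(base, own, other) {
    vapply(base, function(s) {
      if (own[s] > 1L) "multi-copy"
      else if (is.na(other[s]) || other[s] == 0L) "absent in partner"
      else "multi-copy in partner"
    }, "")
  }
  da <- unique(base_a[!base_a %in% shared])
  db <- unique(base_b[!base_b %in% shared])
  dropped_a <- data.frame(symbol = da,
                          reason = if (length(da)) reason(da, ta, tb) else character(0))
  dropped_b <- data.frame(symbol = db,
                          reason = if (length(db)) reason(db, tb, ta) else character(0))
  if (length(shared) == 0L)
    stop("no shared single-copy markers between '", order_a$genome_id,
         "' and '", order_b$genome_id, "'")
  reduce <- function(o, base) {
    keep <- base %in% shared
    gene_order(o$genome_id,
               paste0(vapply(o$markers[keep], marker_sign, ""), base[keep]),
               circular = o$circular)
  }
  list(shared = shared, dropped_a = dropped_a, dropped_b = dropped_b,
       reduced_a = reduce(order_a, base_a), reduced_b = reduce(order_b, base_b))
}

#' DCJ distance between two reduced circular gene orders
#'
#' Both orders must range over the same single-copy marker set. The
#' distance is `n - c`, with `c` the number of cycles of the adjacency
#' graph (for two fully circular genomes the graph has no paths).
#'
#' @param order_a,order_b [gene_order()] objects over identical marker sets.
#' @return list with `distance` (integer), `n_markers`, `cycles`, and
#'   `graph` (the adjacency matrices of both genomes for inspection).
#' @export
dcj_distance <- function(order_a, order_b) {
  sa <- sort(vapply(order_a$markers, marker_symbol, "", USE.NAMES = FALSE))
  sb <- sort(vapply(order_b$markers, marker_symbol, "", USE.NAMES = FALSE))
  if (!identical(sa, sb) || anyDuplicated(sa))
    stop("orders must range over the same single-copy marker set ",
         "(use build_marker_universe first)")
  if (!order_a$circular || !order_b$circular)
    stop("only circular chromosomes are supported")
  symbols <- sa
  n <- length(symbols)
  A <- order_to_adjacencies(order_a$markers, symbols)
  B <- order_to_adjacencies(order_b$markers, symbols)
  pa <- adjacency_partner(A, 2L * n)
  pb <- adjacency_partner(B, 2L * n)
  ## count cycles by alternating A/B-edge traversal (each extremity has
  ## exactly one partner in each genome, so components are cycles)
  seen <- rep(FALSE, 2L * n)
  cycles <- 0L
  for (v0 in seq_len(2L * n)) {
    if (seen[v0]) next
    cycles <- cycles + 1L
    v <- v0
    repeat {
      seen[v] <- TRUE
      v <- pa[v]; seen[v] <- TRUE
      v <- pb[v]
      if (v == v0) break
    }
  }
  list(distance = n - cycles, n_markers = n, cycles = cycles,
       graph = list(a_edges = A, b_edges = B))
}

## ---- brute-force oracle -------------------------------------------------

## cache of distance tables from the identity genome, one per n
.dcj_bfs_cache <- new.env(parent = emptyenv())

matching_key <- function(partner) {
  i <- seq_along(partner)
  paste(partner[i < partner], which(i < partner), sep = ":", collapse = "|")
}

identity_partner <- function(n) {
  ## identity circular order +1 +2 ... +n: adjacencies (head i, tail i+1)
  adjs <- order_to_adjacencies(paste0("+", seq_len(n)), as.character(seq_len(n)))
  adjacency_partner(adjs, 2L * n)
}

## full BFS over all perfect matchings of the 2n extremities, from identity
dcj_bfs_table <- function(n) {
  key <- as.character(n)
  if (!is.null(.dcj_bfs_cache[[key]])) return(.dcj_bfs_cache[[key]])
  start <- identity_partner(n)
  dist <- new.env(parent = emptyenv())
  assign(matching_key(start), 0L, envir = dist)
  frontier <- list(start)
  d <- 0L
  while (length(frontier) > 0L) {
    nxt <- list()
    for (partner in frontier) {
      adjs <- which(seq_along(partner) < partner)
      adjs <- cbind(adjs, partner[adjs])
      m <- nrow(adjs)
      if (m < 2L) next
      for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
        p <- adjs[i, 1L]; q <- adjs[i, 2L]; r <- adjs[j, 1L]; s <- adjs[j, 2L]
        for (swap in 1:2) {
          np <- partner
          if (swap == 1L) { np[p] <- r; np[r] <- p; np[q] <- s; np[s] <- q }
          else            { np[p] <- s; np[s] <- p; np[q] <- r; np[r] <- q }
          kk <- matching_key(np)
          if (is.null(dist[[kk]])) {
            assign(kk, d + 1L, envir = dist)
            nxt[[length(nxt) + 1L]] <- np
          }
        }
      }
    }
    frontier <- nxt
    d <- d + 1L
  }
  .dcj_bfs_cache[[key]] <- dist
  dist
}

#' Brute-force DCJ distance by breadth-first search
#'
#' Independent oracle: explores single DCJ operations (cut two adjacencies,
#' rejoin the four ends either way) over adjacency-set states. Order `a` is
#' relabelled to the identity genome, so distances come from one cached
#' exhaustive BFS per marker count.
#'
#' @param order_a,order_b [gene_order()] objects over the same marker set.
#' @param max_n refuse marker sets larger than this (state-space guard).
#' @return integer minimal DCJ operation count.
#' @export
dcj_distance_bruteforce <- function(order_a, order_b, max_n = 8L) {
  syms_a <- vapply(order_a$markers, marker_symbol, "")
  n <- length(syms_a)
  if (n > max_n) stop("brute-force oracle refuses n > ", max_n)
  ## relabel so that order_a reads +1 +2 ... +n
  signs_a <- vapply(order_a$markers, marker_sign, "")
  relabel <- setNames(seq_len(n), syms_a)
  flip <- setNames(signs_a == "-", syms_a)
  symb_b <- vapply(order_b$markers, marker_symbol, "")
  sign_b <- vapply(order_b$markers, marker_sign, "")
  new_sign <- ifelse(flip[symb_b], ifelse(sign_b == "+", "-", "+"), sign_b)
  b2 <- paste0(new_sign, relabel[symb_b])
  Bp <- adjacency_partner(
    order_to_adjacencies(b2, as.character(seq_len(n))), 2L * n)
  tab <- dcj_bfs_table(n)
  d <- tab[[matching_key(Bp)]]
  if (is.null(d)) stop("state not reached by BFS (internal error)")
  d
}

#' All-pairs DCJ distance matrix
#'
#' Every unordered pair is reduced with [build_marker_universe()] and
#' scored with [dcj_distance()]; pairs with no shared single-copy markers
#' are recorded as missing (NA), never fabricated.
#'
#' @param orders list of [gene_order()] objects.
#' @return object of class `dcj_matrix`: list with `ids`, `distance`
#'   (symmetric integer matrix, zero diagonal), `shared_markers` (matrix of
#'   per-pair reduced marker counts).
#' @export
pairwise_matrix <- function(orders) {
  if (length(orders) < 2L) stop("need at least two gene orders")
  ids <- vapply(orders, function(o) o$genome_id, "")
  if (anyDuplicated(ids)) stop("duplicate genome ids")
  m <- length(orders)
  D <- matrix(0L, m, m, dimnames = list(ids, ids))
  S <- matrix(NA_integer_, m, m, dimnames = list(ids, ids))
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    res <- tryCatch({
      u <- build_marker_universe(orders[[i]], orders[[j]])
      d <- dcj_distance(u$reduced_a, u$reduced_b)
      list(d = d$distance, s = d$n_markers)
    }, error = function(e) list(d = NA_integer_, s = 0L))
    D[i, j] <- D[j, i] <- res$d
    S[i, j] <- S[j, i] <- res$s
  }
  diag(S) <- vapply(orders, function(o) length(o$markers), 1L)
  structure(list(ids = ids, distance = D, shared_markers = S),
            class = "dcj_matrix")
}

#' Render a DCJ distance heatmap
#'
#' Writes the matrix as TSV and draws a linear-scale heatmap (missing
#' cells grey), with rows and columns in a supplied (e.g.
#' phylogeny-derived) leaf order.
#'
#' @param matrix a `dcj_matrix`.
#' @param path output image path (.png or .svg by extension).
#' @param tree_order optional character permutation of the genome ids.
#' @param tsv optional path for the matrix TSV.
#' @return invisibly, the plotted matrix.
#' @export
render_heatmap <- function(matrix, path, tree_order = NULL, tsv = NULL) {
  D <- matrix$distance
  if (!is.null(tree_order)) {
    if (!setequal(tree_order, matrix$ids) || length(tree_order) != length(matrix$ids))
      stop("tree_order must be a permutation of the genome ids")
    D <- D[tree_order, tree_order]
  }
  if (!is.null(tsv))
    write_tsv(data.frame(genome = rownames(D), D, check.names = FALSE), tsv)
  ext <- tolower(tools::file_ext(path))
  if (ext == "svg") grDevices::svg(path, width = 7, height = 6)
  else grDevices::png(path, width = 900, height = 800)
  on.exit(grDevices::dev.off())
  pheatmap::pheatmap(D, cluster_rows = FALSE, cluster_cols = FALSE,
                     na_col = "grey80", border_color = NA,
                     main = "Pairwise DCJ rearrangement distance")
  invisible(D)
}
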