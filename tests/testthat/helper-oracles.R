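# Independent oracles used by the test suite.  These deliberately take a
# different computational route than the package code they check.

# Brute-force AS event enumerator: per-pair interval scans applying each
# canonical definition directly (no segmentation).  Covers the five named
# types; `complex` segments are out of its scope.
brute_as_oracle <- function(txs) {
  rows <- list()
  emit <- function(type, lo, hi)
    rows[[length(rows) + 1L]] <<- data.frame(type = type, region_start = lo,
                                             region_end = hi)
  sites_of <- function(tx) {
    ii <- tx_introns(tx)
    if (nrow(ii) == 0L) numeric(0) else sort(c(ii[, 1L], ii[, 2L]))
  }
  n <- length(txs)
  for (i in seq_len(max(0L, n - 1L))) for (j in seq(i + 1L, n)) {
    X <- txs[[i]]; Y <- txs[[j]]
    lo <- max(tx_span(X)[1L], tx_span(Y)[1L])
    hi <- min(tx_span(X)[2L], tx_span(Y)[2L])
    if (hi <= lo) next
    inside <- function(...) all(c(...) > lo & c(...) < hi)
    for (swap in c(FALSE, TRUE)) {
      A <- if (swap) Y else X; B <- if (swap) X else Y
      ia <- tx_introns(A); ib <- tx_introns(B)
      # ES: intron of B spans >=2 consecutive introns of A with matching
      # outer boundaries; skipped exons of A lie strictly inside
      for (k in seq_len(nrow(ib))) {
        p <- ib[k, 1L]; q <- ib[k, 2L]
        s <- which(ia[, 1L] == p); e <- which(ia[, 2L] == q)
        if (length(s) == 1L && length(e) == 1L && e > s &&
            inside(ia[s, 2L], ia[e, 1L]))
          emit("ES", ia[s, 2L], ia[e, 1L])
      }
      # IR: intron of A fully inside an exon of B; no other A splice site
      # within that exon, and the exon's own boundaries are shared with A
      # (same role) or outside the common span, so the flanks line up
      sa <- sites_of(A)
      role_at <- function(tx, coord, role) {
        ii <- tx_introns(tx)
        if (nrow(ii) == 0L) return(FALSE)
        d <- if (tx$strand == "+") ii[, 1L] else ii[, 2L]
        a <- if (tx$strand == "+") ii[, 2L] else ii[, 1L]
        if (role == "D") coord %in% d else coord %in% a
      }
      for (k in seq_len(nrow(ia))) {
        s <- ia[k, 1L]; e <- ia[k, 2L]
        if (!inside(s, e)) next
        for (m in seq_len(nrow(B$exons))) {
          bs <- B$exons[m, 1L]; be <- B$exons[m, 2L]
          if (!(s >= bs && e <= be)) next
          if (any(sa > bs & sa < be & !(sa %in% c(s, e)))) next
          bs_role <- if (B$strand == "+") "A" else "D"  # exon start boundary
          be_role <- if (B$strand == "+") "D" else "A"
          left_ok <- bs <= lo || role_at(A, bs, bs_role)
          right_ok <- be >= hi || role_at(A, be, be_role)
          if (left_ok && right_ok) emit("IR", s, e)
        }
      }
      # MEE: consecutive intron pairs with shared outer boundaries and
      # disjoint internal exons
      if (nrow(ia) >= 2L && nrow(ib) >= 2L) {
        for (k in seq_len(nrow(ia) - 1L)) for (m in seq_len(nrow(ib) - 1L)) {
          f1a <- ia[k, 1L]; x1 <- ia[k, 2L]; x2 <- ia[k + 1L, 1L]; f2a <- ia[k + 1L, 2L]
          f1b <- ib[m, 1L]; y1 <- ib[m, 2L]; y2 <- ib[m + 1L, 1L]; f2b <- ib[m + 1L, 2L]
          if (f1a == f1b && f2a == f2b && inside(x1, x2, y1, y2) &&
              (x2 <= y1 || y2 <= x1) && !(x1 == y1 && x2 == y2))
            emit("MEE", min(x1, y1), max(x2, y2))
        }
      }
    }
    # AD/AA: overlapping intron pairs sharing exactly one boundary; the
    # differing boundaries must be the only sites in between, and the
    # neighbouring site on the differing side must be shared (or absent
    # within the common span for both), so the flanking context matches
    ia <- tx_introns(X); ib <- tx_introns(Y)
    allsites <- function(tx) {
      ii <- tx_introns(tx)
      if (nrow(ii) == 0L)
        return(data.frame(coord = numeric(0), role = character(0)))
      data.frame(coord = c(ii[, 1L], ii[, 2L]),
                 role = rep(if (tx$strand == "+") c("D", "A") else c("A", "D"),
                            each = nrow(ii)))
    }
    sX <- allsites(X); sY <- allsites(Y)
    neighbour <- function(ss, coord, dir) {
      keep <- ss[ss$coord > lo & ss$coord < hi, , drop = FALSE]
      cand <- if (dir > 0) keep[keep$coord > coord, , drop = FALSE]
              else keep[keep$coord < coord, , drop = FALSE]
      if (nrow(cand) == 0L) return(NA_character_)
      i <- if (dir > 0) which.min(cand$coord) else which.max(cand$coord)
      paste(cand$role[i], cand$coord[i])
    }
    between_clear <- function(a, b) {
      !any(c(sX$coord, sY$coord) > min(a, b) & c(sX$coord, sY$coord) < max(a, b))
    }
    for (k in seq_len(nrow(ia))) for (m in seq_len(nrow(ib))) {
      s1 <- ia[k, 1L]; e1 <- ia[k, 2L]; s2 <- ib[m, 1L]; e2 <- ib[m, 2L]
      if (min(e1, e2) <= max(s1, s2)) next  # need overlap
      if (e1 == e2 && s1 != s2 && inside(s1, s2) && between_clear(s1, s2)) {
        nb <- c(neighbour(sX, s1, -1L), neighbour(sY, s2, -1L))
        if (identical(nb[1], nb[2]) || all(is.na(nb))) {
          type <- if (X$strand == "+") "AD" else "AA"
          emit(type, min(s1, s2), max(s1, s2))
        }
      }
      if (s1 == s2 && e1 != e2 && inside(e1, e2) && between_clear(e1, e2)) {
        nb <- c(neighbour(sX, e1, 1L), neighbour(sY, e2, 1L))
        if (identical(nb[1], nb[2]) || all(is.na(nb))) {
          type <- if (X$strand == "+") "AA" else "AD"
          emit(type, min(e1, e2), max(e1, e2))
        }
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(type = character(0), region_start = numeric(0),
                      region_end = numeric(0)))
  unique(do.call(rbind, rows))
}

# canonical sortable representation of an event table for set comparison
event_set <- function(df, types = c("ES", "AA", "AD", "IR", "MEE")) {
  df <- df[df$type %in% types, c("type", "region_start", "region_end")]
  df <- unique(df)
  df[order(df$type, df$region_start, df$region_end), , drop = FALSE]
}

# retained multi-exon junction-chain set of a collapse result
retained_chain_set <- function(collapsed) {
  iso <- retained_isoforms(collapsed)
  keys <- vapply(iso, function(x)
    paste(x$tx$chrom, x$tx$strand, junction_key(x$tx)), "")
  sort(keys[vapply(iso, function(x) nrow(x$tx$exons) > 1L, FALSE)])
}

# junction-chain set of an annotation's multi-exon isoforms
annotation_chain_set <- function(ann) {
  iso <- ann_isoforms(ann)
  keys <- vapply(iso, function(tx) paste(tx$chrom, tx$strand, junction_key(tx)), "")
  sort(unique(keys[vapply(iso, function(tx) nrow(tx$exons) > 1L, FALSE)]))
}

# hand-rolled median-of-ratios (loop form; the middle of an even-length
# ratio vector is taken geometrically, the ratio-scale convention)
size_factors_oracle <- function(counts) {
  keep <- apply(counts, 1L, function(x) all(x > 0))
  sub <- counts[keep, , drop = FALSE]
  gm <- exp(rowMeans(log(sub)))
  sf <- numeric(ncol(sub))
  for (j in seq_len(ncol(sub))) {
    r <- sort(sub[, j] / gm)
    n <- length(r)
    sf[j] <- if (n %% 2L == 1L) r[(n + 1L) / 2L]
             else sqrt(r[n / 2L] * r[n / 2L + 1L])
  }
  sf / exp(mean(log(sf)))
}

# textbook Benjamini-Hochberg with the cumulative-minimum written out
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in seq(n - 1L, 1L)) adj[i] <- min(adj[i], adj[i + 1L])
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

phenomena_of <- function(reads) vapply(reads, function(r) r$truth$phenomenon, "")
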