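## Event detection: alternative splicing events from pairwise isoform
## comparison within a locus, alternative polyadenylation site clustering
## from read 3' ends, and fusion transcript calling from two-block reads.

# splice sites of a transcript as a data.frame in transcript orientation:
# coord, role ("D" donor / "A" acceptor).  On '+' genomic order equals
# transcript order; on '-' it is reversed and roles swap sides.
tx_sites <- function(tx) {
  ii <- tx_introns(tx)
  if (nrow(ii) == 0L)
    return(data.frame(coord = numeric(0), role = character(0)))
  if (tx$strand == "+") {
    df <- data.frame(coord = as.vector(t(ii)),
                     role = rep(c("D", "A"), nrow(ii)))
  } else {
    ii <- ii[rev(seq_len(nrow(ii))), , drop = FALSE]
    df <- data.frame(coord = as.vector(t(ii[, c(2L, 1L)])),
                     role = rep(c("D", "A"), nrow(ii)))
  }
  df
}

site_key <- function(df) paste(df$role, df$coord, sep = ":")

# classify the differing site subchains of one variable segment
classify_segment <- function(a, b, strand) {
  pat <- function(x) paste(x$role, collapse = "")
  pa <- pat(a); pb <- pat(b)
  # one empty side: the other either retains an intron (D..A) or includes
  # extra exon(s) (A..D, alternating)
  alt <- function(p, first, last) {
    n <- nchar(p)
    n >= 2L && n %% 2L == 0L &&
      substr(p, 1L, 1L) == first && substr(p, n, n) == last &&
      !grepl(paste0(first, first), p) && !grepl(paste0(last, last), p)
  }
  if (nrow(b) == 0L && alt(pa, "D", "A")) return("IR")
  if (nrow(a) == 0L && alt(pb, "D", "A")) return("IR")
  if (nrow(b) == 0L && alt(pa, "A", "D")) return("ES")
  if (nrow(a) == 0L && alt(pb, "A", "D")) return("ES")
  if (pa == "D" && pb == "D") return("AD")
  if (pa == "A" && pb == "A") return("AA")
  if (pa == "AD" && pb == "AD") {
    # exons between the flanking introns; MEE iff they do not overlap
    ea <- sort(a$coord); eb <- sort(b$coord)
    if (interval_overlap(ea[1L], ea[2L], eb[1L], eb[2L]) == 0) return("MEE")
  }
  "complex"
}

# AS events between one ordered pair of isoforms (helper for detect_as_events)
pair_as_events <- function(txA, txB) {
  spA <- tx_span(txA); spB <- tx_span(txB)
  lo <- max(spA[1L], spB[1L]); hi <- min(spA[2L], spB[2L])
  if (hi <= lo) return(list())
  sA <- tx_sites(txA); sB <- tx_sites(txB)
  inA <- sA[sA$coord > lo & sA$coord < hi, , drop = FALSE]
  inB <- sB[sB$coord > lo & sB$coord < hi, , drop = FALSE]
  kA <- site_key(inA); kB <- site_key(inB)
  anchors <- kA[kA %in% kB]
  # segment boundaries in transcript orientation; virtual anchors at the
  # common-span edges so purely terminal differences never form events
  bnd <- c(NA, anchors, NA)
  posA <- c(0L, match(anchors, kA), nrow(inA) + 1L)
  posB <- c(0L, match(anchors, kB), nrow(inB) + 1L)
  events <- list()
  for (s in seq_len(length(bnd) - 1L)) {
    ia <- if (posA[s + 1L] - posA[s] > 1L)
      inA[(posA[s] + 1L):(posA[s + 1L] - 1L), , drop = FALSE]
      else inA[0L, , drop = FALSE]
    ib <- if (posB[s + 1L] - posB[s] > 1L)
      inB[(posB[s] + 1L):(posB[s + 1L] - 1L), , drop = FALSE]
      else inB[0L, , drop = FALSE]
    if (nrow(ia) == 0L && nrow(ib) == 0L) next
    if (identical(site_key(ia), site_key(ib))) next
    type <- classify_segment(ia, ib, txA$strand)
    coords <- sort(c(ia$coord, ib$coord))
    events[[length(events) + 1L]] <- list(
      type = type, chrom = txA$chrom, strand = txA$strand,
      region = c(min(coords), max(coords)),
      key = paste(type, txA$chrom, txA$strand,
                  paste(sort(c(site_key(ia), "|", site_key(ib))), collapse = ","),
                  sep = "@"))
  }
  events
}

#' Detect alternative splicing events within a locus
#'
#' All isoform pairs are compared; within the common genomic span, shared
#' splice sites act as anchors and each differing segment between anchors is
#' one event, typed as ES (exon(s) present in one chain, absent in the
#' other, flanking junction boundaries shared), IR (one chain's intron fully
#' exonic in the other), AD (shared acceptor, differing donor; strand-aware
#' 5' side), AA (shared donor, differing acceptor), MEE (adjacent mutually
#' exclusive exons with shared outer flanks), or `complex` otherwise.
#' Events are deduplicated across pairs by type and variable-region sites.
#'
#' @param isoforms List of [tx_model] (the retained isoforms of one locus),
#'   or isoform-call lists carrying a `tx` field.
#' @param locus_id Optional locus label attached to the output.
#' @return data.frame with `type`, `chrom`, `strand`, `region_start`,
#'   `region_end`, `locus_id`; zero rows when fewer than two isoforms.
#' @export
detect_as_events <- function(isoforms, locus_id = NA_character_) {
  txs <- lapply(isoforms, function(x) if (!is.null(x$tx)) x$tx else x)
  empty <- data.frame(type = character(0), chrom = character(0),
                      strand = character(0), region_start = numeric(0),
                      region_end = numeric(0), locus_id = character(0),
                      stringsAsFactors = FALSE)
  if (length(txs) < 2L) return(empty)
  seen <- character(0)
  rows <- list()
  for (i in seq_len(length(txs) - 1L)) {
    for (j in seq(i + 1L, length(txs))) {
      for (ev in pair_as_events(txs[[i]], txs[[j]])) {
        if (ev$key %in% seen) next
        seen <- c(seen, ev$key)
        rows[[length(rows) + 1L]] <- data.frame(
          type = ev$type, chrom = ev$chrom, strand = ev$strand,
          region_start = ev$region[1L], region_end = ev$region[2L],
          locus_id = locus_id, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$region_start, out$type), , drop = FALSE]
}

#' Detect AS events across all loci of a collapse result
#' @param collapsed Output of [collapse_transcripts] (retained isoforms used).
#' @return data.frame as in [detect_as_events], concatenated over loci.
#' @export
detect_as_events_all <- function(collapsed) {
  isoforms <- retained_isoforms(collapsed)
  by_locus <- split(isoforms, vapply(isoforms, `[[`, "", "locus_id"))
  out <- lapply(names(by_locus), function(lid)
    detect_as_events(by_locus[[lid]], locus_id = lid))
  do.call(rbind, c(out, list(detect_as_events(list()))))
}

#' Cluster read 3' ends into alternative polyadenylation sites
#'
#' Strand-aware 3' terminal coordinates are clustered single-linkage: sorted
#' ends belong to one cluster while consecutive gaps are within
#' `cluster_window`.  Clusters supported by fewer than `min_support` reads
#' are discarded; a gene shows APA iff at least two sites survive.
#'
#' @param ends3 Numeric vector of 3'-end genomic coordinates of the reads
#'   assigned to one gene.
#' @param cluster_window Single-linkage window in bp (default 24, a common
#'   poly(A) microheterogeneity scale).
#' @param min_support Minimum reads per reported site (default 2).
#' @return data.frame with `site` (modal coordinate; smallest on ties) and
#'   `support`, ordered by coordinate.  Zero rows if nothing survives.
#' @export
detect_apa <- function(ends3, cluster_window = 24, min_support = 2L) {
  empty <- data.frame(site = numeric(0), support = integer(0))
  if (length(ends3) == 0L) return(empty)
  e <- sort(ends3)
  cl <- cumsum(c(1L, as.integer(diff(e) > cluster_window)))
  rows <- lapply(split(e, cl), function(x) {
    tb <- table(x)
    data.frame(site = as.numeric(names(tb)[which.max(tb)]),
               support = length(x))
  })
  out <- do.call(rbind, rows)
  out <- out[out$support >= min_support, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$site), , drop = FALSE]
}

# strand-aware 3' terminal coordinate of a transcript/read block
tx_end3 <- function(tx) {
  sp <- tx_span(tx)
  if (tx$strand == "+") sp[2L] else sp[1L]
}

#' APA analysis over all genes
#'
#' Assigns non-chimeric reads to annotated genes by best same-strand span
#' overlap and clusters their 3' ends per gene.
#'
#' @param reads List of [flnc_read] (two-block reads are ignored).
#' @param ann A [ref_annotation].
#' @param cluster_window,min_support Passed to [detect_apa].
#' @return List with `sites` (data.frame `gene_id`, `site`, `support`) and
#'   `genes` (data.frame `gene_id`, `n_sites`, `apa` flag).
#' @export
detect_apa_all <- function(reads, ann, cluster_window = 24, min_support = 2L) {
  tab <- ann_gene_table(ann)
  ends_by_gene <- list()
  for (r in reads) {
    if (length(r$blocks) != 1L) next
    b <- r$blocks[[1L]]
    sp <- tx_span(b)
    cand <- tab[tab$chrom == b$chrom & tab$strand == b$strand, , drop = FALSE]
    if (nrow(cand) == 0L) next
    ov <- interval_overlap(sp[1L], sp[2L], cand$start, cand$end)
    if (max(ov) <= 0) next
    gid <- cand$gene_id[which.max(ov)]
    ends_by_gene[[gid]] <- c(ends_by_gene[[gid]], tx_end3(b))
  }
  sites <- list()
  for (gid in names(ends_by_gene)) {
    s <- detect_apa(ends_by_gene[[gid]], cluster_window, min_support)
    if (nrow(s) > 0L)
      sites[[length(sites) + 1L]] <- cbind(gene_id = gid, s,
                                           stringsAsFactors = FALSE)
  }
  sites <- if (length(sites) > 0L) do.call(rbind, sites)
           else data.frame(gene_id = character(0), site = numeric(0),
                           support = integer(0), stringsAsFactors = FALSE)
  n_sites <- table(sites$gene_id)
  genes <- data.frame(gene_id = names(n_sites),
                      n_sites = as.integer(n_sites),
                      stringsAsFactors = FALSE)
  genes$apa <- genes$n_sites >= 2L
  list(sites = sites, genes = genes)
}

#' Call fusion transcripts from two-block reads
#'
#' A fusion is called when the 5' alignment block of a chimeric read
#' overlaps one annotated gene and the 3' block a different gene, each by at
#' least `min_partner_overlap` of the block span.  Intrachromosomal
#' candidates whose partner-gene spans are separated by less than `min_gap`
#' are dropped as likely read-through artifacts (set `min_gap = 0` to
#' disable).  Calls are grouped by partner pair and require `min_reads`
#' supporting reads.
#'
#' @param reads List of [flnc_read]; only two-block reads are considered.
#' @param ann A [ref_annotation].
#' @param min_partner_overlap Minimum block-span overlap fraction (default 0.5).
#' @param min_gap Minimum genomic gap between intrachromosomal partners.
#' @param min_reads Minimum supporting reads per call (default 1).
#' @return data.frame with `partner_5prime`, `partner_3prime`, `kind`
#'   (`intrachromosomal`/`interchromosomal`), `n_reads`, `read_ids`.
#' @export
detect_fusion <- function(reads, ann, min_partner_overlap = 0.5,
                          min_gap = 10000, min_reads = 1L) {
  tab <- ann_gene_table(ann)
  hit_gene <- function(b) {
    sp <- tx_span(b)
    cand <- tab[tab$chrom == b$chrom, , drop = FALSE]
    if (nrow(cand) == 0L) return(NA_character_)
    ov <- interval_overlap(sp[1L], sp[2L], cand$start, cand$end)
    frac <- ov / (sp[2L] - sp[1L])
    if (max(frac) < min_partner_overlap) return(NA_character_)
    cand$gene_id[which.max(frac)]
  }
  calls <- list()
  for (r in reads) {
    if (length(r$blocks) != 2L) next
    g5 <- hit_gene(r$blocks[[1L]])
    g3 <- hit_gene(r$blocks[[2L]])
    if (is.na(g5) || is.na(g3)) next
    if (identical(g5, g3)) next
    c5 <- tab[tab$gene_id == g5, ]; c3 <- tab[tab$gene_id == g3, ]
    same_chrom <- identical(c5$chrom, c3$chrom)
    if (same_chrom && min_gap > 0) {
      gap <- max(c5$start, c3$start) - min(c5$end, c3$end)
      if (gap < min_gap) next
    }
    calls[[length(calls) + 1L]] <- data.frame(
      partner_5prime = g5, partner_3prime = g3,
      kind = if (same_chrom) "intrachromosomal" else "interchromosomal",
      read_id = r$id, stringsAsFactors = FALSE)
  }
  empty <- data.frame(partner_5prime = character(0),
                      partner_3prime = character(0), kind = character(0),
                      n_reads = integer(0), read_ids = character(0),
                      stringsAsFactors = FALSE)
  if (length(calls) == 0L) return(empty)
  df <- do.call(rbind, calls)
  agg <- lapply(split(df, paste(df$partner_5prime, df$partner_3prime)),
                function(d) data.frame(
                  partner_5prime = d$partner_5prime[1L],
                  partner_3prime = d$partner_3prime[1L],
                  kind = d$kind[1L], n_reads = nrow(d),
                  read_ids = paste(sort(d$read_id), collapse = ","),
                  stringsAsFactors = FALSE))
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out <- out[out$n_reads >= min_reads, , drop = FALSE]
  out[order(out$partner_5prime, out$partner_3prime), , drop = FALSE]
}

#' Summarise AS events by type
#' @param events data.frame from [detect_as_events_all].
#' @return data.frame with `type`, `n`, `percent` over all six classes.
#' @export
as_type_summary <- function(events) {
  lev <- c("ES", "AA", "AD", "IR", "MEE", "complex")
  n <- vapply(lev, function(t) sum(events$type == t), 0L)
  data.frame(type = lev, n = n,
             percent = if (nrow(events) == 0L) rep(NA_real_, length(lev))
                       else vapply(n, ratio, 0, denominator = nrow(events)),
             stringsAsFactors = FALSE)
}
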