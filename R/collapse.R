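## Locus clustering and isoform collapse.  Transcripts (aligned read blocks)
## sharing direction, >20% span overlap and >20% overlap in at least one
## exon belong to the same locus; loci are the connected components of that
## relation.  Within a locus, reads with identical internal junction chains
## collapse into isoforms, then redundancy (5'-truncated sub-chains) and
## false-positive (unsupported singleton) filters run in that order.

#' Do two aligned transcripts originate from the same locus?
#'
#' True iff (i) same chromosome and strand, (ii) genomic-span overlap
#' exceeds `min_overlap` of the shorter span, and (iii) at least one exon
#' pair overlaps by more than `min_overlap` of the shorter exon.
#'
#' @param a,b [tx_model] objects.
#' @param min_overlap Overlap fraction threshold (default 0.2).
#' @return Logical scalar.
#' @export
same_locus <- function(a, b, min_overlap = 0.2) {
  if (!identical(a$chrom, b$chrom) || !identical(a$strand, b$strand))
    return(FALSE)
  sa <- tx_span(a); sb <- tx_span(b)
  ov <- interval_overlap(sa[1L], sa[2L], sb[1L], sb[2L])
  shorter <- min(sa[2L] - sa[1L], sb[2L] - sb[1L])
  if (ov <= min_overlap * shorter) return(FALSE)
  for (i in seq_len(nrow(a$exons))) {
    e1 <- a$exons[i, ]
    ovs <- interval_overlap(e1[1L], e1[2L], b$exons[, 1L], b$exons[, 2L])
    short_ex <- pmin(e1[2L] - e1[1L], b$exons[, 2L] - b$exons[, 1L])
    if (any(ovs > min_overlap * short_ex)) return(TRUE)
  }
  FALSE
}

# union-find
uf_new <- function(n) seq_len(n)
uf_find <- function(p, i) { while (p[i] != i) i <- p[i]; i }
uf_union <- function(p, i, j) {
  ri <- uf_find(p, i); rj <- uf_find(p, j)
  if (ri != rj) p[max(ri, rj)] <- min(ri, rj)
  p
}

#' Cluster aligned transcripts into loci
#'
#' Loci are the connected components (single-linkage transitive closure) of
#' the pairwise [same_locus] relation, so the output partitions the input.
#' Locus ids are assigned deterministically by (chrom, start).
#'
#' @param transcripts List of [tx_model].
#' @param min_overlap Passed to [same_locus].
#' @return List of loci; each is a list with `id`, `chrom`, `strand`,
#'   `span` and `members` (the member [tx_model]s).
#' @export
assign_loci <- function(transcripts, min_overlap = 0.2) {
  n <- length(transcripts)
  if (n == 0L) return(list())
  key <- vapply(transcripts, function(t) paste(t$chrom, t$strand), "")
  starts <- vapply(transcripts, function(t) tx_span(t)[1L], 0)
  ends <- vapply(transcripts, function(t) tx_span(t)[2L], 0)
  parent <- uf_new(n)
  for (grp in split(seq_len(n), key)) {
    grp <- grp[order(starts[grp])]
    # sweep: only span-overlapping candidates can satisfy same_locus
    active <- integer(0)
    for (i in grp) {
      active <- active[ends[active] > starts[i]]
      for (j in active)
        if (same_locus(transcripts[[i]], transcripts[[j]], min_overlap))
          parent <- uf_union(parent, i, j)
      active <- c(active, i)
    }
  }
  roots <- vapply(seq_len(n), function(i) uf_find(parent, i), 0L)
  comp <- split(seq_len(n), roots)
  loci <- lapply(comp, function(idx) {
    members <- transcripts[idx]
    list(chrom = members[[1L]]$chrom, strand = members[[1L]]$strand,
         span = c(min(starts[idx]), max(ends[idx])), members = members)
  })
  ord <- order(vapply(loci, `[[`, "", "chrom"),
               vapply(loci, function(l) l$span[1L], 0))
  loci <- loci[ord]
  for (i in seq_along(loci)) loci[[i]]$id <- sprintf("LOC%05d", i)
  loci
}

#' Collapse the transcripts of one locus into isoforms
#'
#' Multi-exon transcripts sharing an identical internal junction chain merge
#' into one isoform whose exon chain spans the widest observed 5'/3' ends;
#' single-exon transcripts merge single-linkage when one span contains the
#' other.  `flnc_support` counts the merged reads.
#'
#' @param locus A locus from [assign_loci].
#' @return List of isoform calls: lists with `id`, `locus_id`, `tx`
#'   (a [tx_model]), `flnc_support`, `read_ids`, and status flags
#'   `redundant`, `false_positive`, `retained` (all initialised FALSE/TRUE).
#' @export
collapse_to_isoforms <- function(locus) {
  stopifnot(length(locus$members) > 0L)
  members <- locus$members
  keys <- vapply(members, junction_key, "")
  isoforms <- list()
  add_iso <- function(tx, support, read_ids) {
    k <- length(isoforms) + 1L
    isoforms[[k]] <<- list(id = sprintf("%s.%d", locus$id, k),
                           locus_id = locus$id, tx = tx,
                           flnc_support = support, read_ids = read_ids,
                           redundant = FALSE, false_positive = FALSE,
                           retained = TRUE, absorbed_into = NA_character_)
  }
  multi <- which(keys != "")
  for (k in unique(keys[multi])) {
    idx <- multi[keys[multi] == k]
    grp <- members[idx]
    start <- min(vapply(grp, function(t) tx_span(t)[1L], 0))
    end <- max(vapply(grp, function(t) tx_span(t)[2L], 0))
    ex <- grp[[1L]]$exons
    ex[1L, 1L] <- start
    ex[nrow(ex), 2L] <- end
    add_iso(tx_model(grp[[1L]]$id, locus$chrom, locus$strand, ex),
            length(grp), vapply(grp, `[[`, "", "id"))
  }
  single <- which(keys == "")
  if (length(single) > 0L) {
    sp <- t(vapply(members[single], tx_span, numeric(2)))
    # single-linkage containment: widest spans absorb contained ones
    ord <- order(sp[, 2L] - sp[, 1L], decreasing = TRUE)
    taken <- rep(NA_integer_, length(single))
    reps <- integer(0)
    for (o in ord) {
      if (!is.na(taken[o])) next
      reps <- c(reps, o)
      taken[o] <- o
      inside <- which(is.na(taken) & sp[, 1L] >= sp[o, 1L] & sp[, 2L] <= sp[o, 2L])
      taken[inside] <- o
    }
    for (r in reps) {
      idx <- single[which(taken == r)]
      add_iso(tx_model(members[[single[r]]]$id, locus$chrom, locus$strand,
                       sp[r, , drop = FALSE]),
              length(idx), vapply(members[idx], `[[`, "", "id"))
    }
  }
  isoforms
}

# is chain `small` a 5'-truncated contiguous sub-chain of chain `big`?
# In transcript orientation that means `small`'s junctions equal the 3'-most
# junctions of `big`; genomically it is a suffix on '+' and a prefix on '-'.
is_5prime_truncation <- function(small, big) {
  si <- tx_introns(small); bi <- tx_introns(big)
  ns <- nrow(si); nb <- nrow(bi)
  if (ns >= nb) return(FALSE)
  idx <- if (small$strand == "+") seq(nb - ns + 1L, nb) else seq_len(ns)
  if (ns > 0L && !isTRUE(all.equal(unname(si), unname(bi[idx, , drop = FALSE]))))
    return(FALSE)
  ss <- tx_span(small); bs <- tx_span(big)
  if (ns == 0L) {
    # no junctions left: require containment in the 3'-terminal exon of big
    term <- if (small$strand == "+") big$exons[nrow(big$exons), ]
            else big$exons[1L, ]
    return(ss[1L] >= term[1L] && ss[2L] <= term[2L])
  }
  # 5' end must not extend beyond the absorbing chain
  if (small$strand == "+") ss[1L] >= bs[1L] else ss[2L] <= bs[2L]
}

#' Flag redundant isoforms within a locus
#'
#' An isoform is redundant iff its junction chain is a contiguous
#' 5'-truncated sub-chain of another isoform's chain (strand-aware) -- the
#' signature of RNA degradation during library preparation.  Support counts
#' of redundant isoforms are added to the absorbing isoform, so downstream
#' support-based filtering is order-independent.
#'
#' @param isoforms Output of [collapse_to_isoforms].
#' @return The isoform list with `redundant`, `retained`, `absorbed_into`
#'   and `flnc_support` updated.
#' @export
filter_redundant <- function(isoforms) {
  n <- length(isoforms)
  if (n < 2L) return(isoforms)
  nj <- vapply(isoforms, function(x) nrow(tx_introns(x$tx)), 0L)
  # try to absorb each isoform into the best candidate: most junctions,
  # then highest support, then id (deterministic)
  ord <- order(-nj, -vapply(isoforms, `[[`, 0, "flnc_support"),
               vapply(isoforms, `[[`, "", "id"))
  for (i in seq_len(n)) {
    if (isoforms[[i]]$redundant) next
    for (j in ord) {
      if (j == i || isoforms[[j]]$redundant) next
      if (is_5prime_truncation(isoforms[[i]]$tx, isoforms[[j]]$tx)) {
        isoforms[[i]]$redundant <- TRUE
        isoforms[[i]]$retained <- FALSE
        isoforms[[i]]$absorbed_into <- isoforms[[j]]$id
        isoforms[[j]]$flnc_support <-
          isoforms[[j]]$flnc_support + isoforms[[i]]$flnc_support
        break
      }
    }
  }
  isoforms
}

#' Flag false-positive isoforms
#'
#' An isoform is retained iff it is covered by at least two FLNC reads, or
#' every junction of its single-read chain is present in the reference
#' annotation or the short-read junction evidence; otherwise it is a false
#' positive.  (Junction-free single-exon chains pass the evidence test
#' vacuously.)
#'
#' @param isoforms Output of [filter_redundant].
#' @param annotated_junctions,short_read_junctions Character vectors of
#'   `chrom:strand:start-end` junction tags (see [ann_junctions]).
#' @return The isoform list with `false_positive`/`retained` updated.
#' @export
filter_false_positive <- function(isoforms, annotated_junctions = character(0),
                                  short_read_junctions = character(0)) {
  evidence <- unique(c(annotated_junctions, short_read_junctions))
  for (i in seq_along(isoforms)) {
    iso <- isoforms[[i]]
    if (iso$redundant) next
    if (iso$flnc_support >= 2L) next
    tags <- junction_tags(iso$tx)
    if (all(tags %in% evidence)) next
    isoforms[[i]]$false_positive <- TRUE
    isoforms[[i]]$retained <- FALSE
  }
  isoforms
}

#' Run the full collapse stage
#'
#' Locus assignment, isoform collapse, redundancy absorption and
#' false-positive filtering over a set of aligned (non-chimeric) transcript
#' blocks.
#'
#' @param transcripts List of [tx_model] (e.g. single-block FLNC reads).
#' @param annotated_junctions,short_read_junctions Junction evidence tags.
#' @param min_overlap Same-locus overlap fraction.
#' @return List with `loci` and `isoforms` (flat list across loci, filters
#'   applied).
#' @export
collapse_transcripts <- function(transcripts,
                                 annotated_junctions = character(0),
                                 short_read_junctions = character(0),
                                 min_overlap = 0.2) {
  loci <- assign_loci(transcripts, min_overlap)
  isoforms <- list()
  for (loc in loci) {
    iso <- collapse_to_isoforms(loc)
    iso <- filter_redundant(iso)
    iso <- filter_false_positive(iso, annotated_junctions, short_read_junctions)
    isoforms <- c(isoforms, iso)
  }
  list(loci = loci, isoforms = isoforms)
}

#' Retained isoforms of a collapse result
#' @param collapsed Output of [collapse_transcripts].
#' @return List of retained isoform calls.
#' @export
retained_isoforms <- function(collapsed) {
  Filter(function(x) x$retained, collapsed$isoforms)
}
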