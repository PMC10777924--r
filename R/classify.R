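## Classification of collapsed isoforms against the reference annotation:
## full-length status (donor coverage), novelty at the locus and isoform
## level, seven structural categories A-G, and the locus length-bin report.

# annotated isoforms on one chrom/strand, cached per call via environment
ref_iso_by_cs <- function(ann) {
  isoforms <- ann_isoforms(ann)
  split(isoforms, vapply(isoforms, function(t) paste(t$chrom, t$strand), ""))
}

#' Full-length status of an isoform
#'
#' A multi-exon isoform is full-length iff some annotated multi-exon isoform
#' on the same chromosome and strand has its complete donor-site set
#' contained in the isoform's donor-site set (`mode = "all"`, the default).
#' `mode = "any"` relaxes this to sharing at least one donor, for
#' sensitivity analysis.  Single-exon isoforms return `NA`.
#'
#' @param tx A [tx_model] (collapsed isoform or read chain).
#' @param ann A [ref_annotation].
#' @param mode `"all"` or `"any"`.
#' @return Logical, or `NA` for single-exon input.
#' @export
full_length_status <- function(tx, ann, mode = c("all", "any")) {
  mode <- match.arg(mode)
  donors <- tx_donors(tx)
  if (length(donors) == 0L) return(NA)
  for (g in ann$genes) {
    if (!identical(g$chrom, tx$chrom) || !identical(g$strand, tx$strand)) next
    for (ref in g$isoforms) {
      rd <- tx_donors(ref)
      if (length(rd) == 0L) next
      hit <- if (mode == "all") all(rd %in% donors) else any(rd %in% donors)
      if (hit) return(TRUE)
    }
  }
  FALSE
}

#' Is a locus a novel gene?
#'
#' Novel iff its best span overlap with any same-strand annotated gene is
#' below `min_overlap` of the shorter span -- i.e. the locus is essentially
#' intergenic, or overlaps annotation only in the antisense orientation.
#'
#' @param locus A locus from [assign_loci] (needs `chrom`, `strand`, `span`).
#' @param ann A [ref_annotation].
#' @param min_overlap Overlap fraction threshold (default 0.2).
#' @return Logical scalar.
#' @export
call_novel_gene <- function(locus, ann, min_overlap = 0.2) {
  tab <- ann_gene_table(ann)
  tab <- tab[tab$chrom == locus$chrom & tab$strand == locus$strand, , drop = FALSE]
  if (nrow(tab) == 0L) return(TRUE)
  ov <- interval_overlap(locus$span[1L], locus$span[2L], tab$start, tab$end)
  shorter <- pmin(locus$span[2L] - locus$span[1L], tab$end - tab$start)
  !any(ov >= min_overlap * shorter & ov > 0)
}

#' Is an isoform a novel isoform?
#'
#' Novel iff any of its splice-site coordinates (donor or acceptor) is
#' absent from the annotated splice-site set of its chromosome/strand.
#' Junction-free single-exon isoforms are never novel by this rule.
#'
#' @param tx A [tx_model].
#' @param ann A [ref_annotation].
#' @return Logical scalar.
#' @export
call_novel_isoform <- function(tx, ann) {
  ii <- tx_introns(tx)
  if (nrow(ii) == 0L) return(FALSE)
  sites <- unique(c(ii[, 1L], ii[, 2L]))
  ref_sites <- numeric(0)
  for (g in ann$genes) {
    if (!identical(g$chrom, tx$chrom) || !identical(g$strand, tx$strand)) next
    for (ref in g$isoforms) {
      ri <- tx_introns(ref)
      if (nrow(ri) > 0L) ref_sites <- c(ref_sites, ri[, 1L], ri[, 2L])
    }
  }
  !all(sites %in% ref_sites)
}

# is `sub` a contiguous run of `full`? (matrices of introns, genomic order)
is_contiguous_subchain <- function(sub, full) {
  ns <- nrow(sub); nf <- nrow(full)
  if (ns == 0L || ns > nf) return(FALSE)
  for (off in 0:(nf - ns)) {
    if (isTRUE(all.equal(unname(sub),
                         unname(full[(off + 1L):(off + ns), , drop = FALSE]))))
      return(TRUE)
  }
  FALSE
}

#' Structural category of an isoform
#'
#' Categories, checked in order with first match winning:
#' \describe{
#'   \item{A}{junction chain identical to a reference isoform (single-exon:
#'     reciprocal >= 50\% span overlap with a single-exon reference isoform)}
#'   \item{B}{chain is a proper contiguous sub-chain of a reference chain}
#'   \item{C}{chain strictly contains a complete reference chain}
#'   \item{D}{shares >= 1 junction with a reference isoform but is neither
#'     sub- nor super-chain}
#'   \item{E}{exonic overlap with a same-strand reference isoform but zero
#'     shared junctions}
#'   \item{F}{novel locus (intergenic or antisense-only overlap)}
#'   \item{G}{inside an annotated gene's span but without exonic overlap
#'     with any reference isoform (e.g. fully intronic)}
#' }
#'
#' @param tx A [tx_model] (collapsed isoform).
#' @param ann A [ref_annotation].
#' @param locus_novel Logical from [call_novel_gene] for the isoform's locus.
#' @return One of `"A"`..`"G"`.
#' @export
categorize_structure <- function(tx, ann, locus_novel = FALSE) {
  ii <- tx_introns(tx)
  sp <- tx_span(tx)
  refs <- list()
  for (g in ann$genes)
    if (identical(g$chrom, tx$chrom) && identical(g$strand, tx$strand))
      refs <- c(refs, g$isoforms)
  if (nrow(ii) > 0L) {
    key <- junction_key(tx)
    for (ref in refs) if (identical(junction_key(ref), key)) return("A")
    for (ref in refs) {
      ri <- tx_introns(ref)
      if (nrow(ri) > nrow(ii) && is_contiguous_subchain(ii, ri)) return("B")
    }
    for (ref in refs) {
      ri <- tx_introns(ref)
      if (nrow(ri) > 0L && nrow(ri) < nrow(ii) &&
          is_contiguous_subchain(ri, ii)) return("C")
    }
    tags <- junction_tags(tx)
    for (ref in refs) if (any(tags %in% junction_tags(ref))) return("D")
  } else {
    for (ref in refs) {
      if (nrow(tx_introns(ref)) > 0L) next
      rs <- tx_span(ref)
      ov <- interval_overlap(sp[1L], sp[2L], rs[1L], rs[2L])
      shorter <- min(sp[2L] - sp[1L], rs[2L] - rs[1L])
      if (shorter > 0 && ov >= 0.5 * shorter) return("A")
    }
  }
  # no shared junctions: exonic overlap with a same-strand reference isoform?
  for (ref in refs) {
    for (i in seq_len(nrow(tx$exons))) {
      if (any(interval_overlap(tx$exons[i, 1L], tx$exons[i, 2L],
                               ref$exons[, 1L], ref$exons[, 2L]) > 0))
        return("E")
    }
  }
  if (locus_novel) return("F")
  # within a gene span (either strand) but no exonic overlap
  tab <- ann_gene_table(ann)
  tab <- tab[tab$chrom == tx$chrom, , drop = FALSE]
  inside <- any(interval_overlap(sp[1L], sp[2L], tab$start, tab$end) > 0)
  if (inside) "G" else "F"
}

#' Classify a set of collapsed isoforms
#'
#' Adds full-length status, novelty (`known` / `novel_isoform` /
#' `novel_gene`) and structural category to every retained isoform.
#'
#' @param collapsed Output of [collapse_transcripts].
#' @param ann A [ref_annotation].
#' @param fl_mode Donor-coverage mode for [full_length_status].
#' @return data.frame with one row per retained isoform: `isoform_id`,
#'   `locus_id`, `n_exons`, `exonic_length`, `flnc_support`, `full_length`,
#'   `novelty`, `category`.
#' @export
classify_isoforms <- function(collapsed, ann, fl_mode = "all") {
  isoforms <- retained_isoforms(collapsed)
  loci <- collapsed$loci
  novel_locus <- stats::setNames(
    vapply(loci, call_novel_gene, FALSE, ann = ann),
    vapply(loci, `[[`, "", "id"))
  rows <- lapply(isoforms, function(iso) {
    tx <- iso$tx
    ln <- novel_locus[[iso$locus_id]]
    cat_ <- categorize_structure(tx, ann, locus_novel = ln)
    novelty <- if (ln) "novel_gene"
               else if (call_novel_isoform(tx, ann)) "novel_isoform"
               else "known"
    data.frame(isoform_id = iso$id, locus_id = iso$locus_id,
               n_exons = nrow(tx$exons), exonic_length = tx_exonic_length(tx),
               flnc_support = iso$flnc_support,
               full_length = full_length_status(tx, ann, fl_mode),
               novelty = novelty, category = cat_,
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L)
    return(data.frame(isoform_id = character(0), locus_id = character(0),
                      n_exons = integer(0), exonic_length = numeric(0),
                      flnc_support = integer(0), full_length = logical(0),
                      novelty = character(0), category = character(0)))
  do.call(rbind, rows)
}

#' Length-bin report for loci
#'
#' Bins locus lengths (exonic length of the longest isoform per locus, the
#' transcript-length convention) into `[0,1k)`, `[1k,2k)`, `[2k,3k)`,
#' `[3k,Inf)` with counts and percentages of total loci.
#'
#' @param lengths Numeric vector of per-locus lengths, or the data.frame
#'   from [classify_isoforms] (longest isoform per `locus_id` is used).
#' @return data.frame with `bin`, `n`, `percent` (2 decimals).
#' @export
length_bin_report <- function(lengths) {
  if (is.data.frame(lengths)) {
    lengths <- vapply(split(lengths$exonic_length, lengths$locus_id), max, 0)
  }
  bins <- cut(lengths, breaks = c(0, 1000, 2000, 3000, Inf),
              labels = c("<1K", "1-2K", "2-3K", ">=3K"), right = FALSE)
  n <- as.integer(table(bins))
  data.frame(bin = levels(bins), n = n,
             percent = if (length(lengths) == 0L) rep(NA_real_, 4L)
                       else vapply(n, ratio, 0, denominator = length(lengths)),
             stringsAsFactors = FALSE)
}

#' Length-bin report from pre-tabulated bin counts
#'
#' Report-layer variant of [length_bin_report] for published per-bin counts:
#' percentages are recomputed from the counts alone.
#'
#' @param counts Numeric vector of 4 bin counts (`<1K`, `1-2K`, `2-3K`, `>=3K`).
#' @param total Denominator; defaults to `sum(counts)`.
#' @return data.frame with `bin`, `n`, `percent`.
#' @export
length_bin_table <- function(counts, total = sum(counts)) {
  stopifnot(length(counts) == 4L)
  data.frame(bin = c("<1K", "1-2K", "2-3K", ">=3K"), n = as.integer(counts),
             percent = vapply(counts, ratio, 0, denominator = total),
             stringsAsFactors = FALSE)
}

#' Write the isoform classification table
#' @param classified data.frame from [classify_isoforms].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_classification_tsv <- function(classified, path) {
  data.table::fwrite(data.table::as.data.table(classified), path,
                     sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}
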