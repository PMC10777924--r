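#' Construct a transcript model
#'
#' A transcript model is an exon chain on one chromosome and strand.  Exons
#' are stored as a two-column integer matrix of 0-based half-open
#' `[start, end)` genome coordinates, sorted and non-overlapping.  The same
#' representation is used for reference isoforms, aligned FLNC read blocks
#' and collapsed isoforms.
#'
#' @param id Character scalar identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column numeric matrix (start, end), 0-based half-open,
#'   or a data.frame with columns `start`, `end`.
#' @return An object of class `tx_model`.
#' @export
tx_model <- function(id, chrom, strand, exons) {
  if (is.data.frame(exons)) exons <- cbind(exons$start, exons$end)
  exons <- matrix(as.numeric(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) == 0L) stop("transcript must have at least one exon")
  o <- order(exons[, 1L])
  exons <- exons[o, , drop = FALSE]
  if (any(exons[, 2L] <= exons[, 1L]))
    stop("exon end must exceed exon start (0-based half-open)")
  if (nrow(exons) > 1L && any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
    stop("exons must be disjoint")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(id = as.character(id), chrom = as.character(chrom),
                 strand = strand, exons = exons),
            class = "tx_model")
}

#' @export
print.tx_model <- function(x, ...) {
  cat(sprintf("<tx_model> %s %s:%s %d exon(s) span [%d,%d)\n",
              x$id, x$chrom, x$strand, nrow(x$exons),
              min(x$exons[, 1L]), max(x$exons[, 2L])))
  invisible(x)
}

#' Intron coordinates of a transcript
#'
#' @param tx A `tx_model`.
#' @return Two-column matrix of `(start, end)` intron intervals (0-based
#'   half-open), one row per junction; zero rows for single-exon models.
#' @export
tx_introns <- function(tx) {
  ex <- tx$exons
  n <- nrow(ex)
  if (n < 2L)
    return(matrix(numeric(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  cbind(start = ex[-n, 2L], end = ex[-1L, 1L])
}

#' Strand-aware splice donor coordinates
#'
#' On the plus strand the donor of an intron is its start (the 5' side in
#' transcript orientation); on the minus strand it is the intron end.
#' @param tx A `tx_model`.
#' @return Numeric vector of donor coordinates (possibly empty).
#' @export
tx_donors <- function(tx) {
  ii <- tx_introns(tx)
  if (nrow(ii) == 0L) return(numeric(0))
  if (tx$strand == "+") ii[, 1L] else ii[, 2L]
}

#' Strand-aware splice acceptor coordinates
#' @param tx A `tx_model`.
#' @return Numeric vector of acceptor coordinates (possibly empty).
#' @export
tx_acceptors <- function(tx) {
  ii <- tx_introns(tx)
  if (nrow(ii) == 0L) return(numeric(0))
  if (tx$strand == "+") ii[, 2L] else ii[, 1L]
}

#' Summed exonic length of a transcript
#' @param tx A `tx_model`.
#' @return Length in bp.
#' @export
tx_exonic_length <- function(tx) sum(tx$exons[, 2L] - tx$exons[, 1L])

#' Genomic span of a transcript
#' @param tx A `tx_model`.
#' @return Numeric `(start, end)`.
#' @export
tx_span <- function(tx) c(min(tx$exons[, 1L]), max(tx$exons[, 2L]))

# canonical string key for a junction chain (genomic order); "" = no junctions
junction_key <- function(tx) {
  ii <- tx_introns(tx)
  if (nrow(ii) == 0L) return("")
  paste(sprintf("%d-%d", as.integer(ii[, 1L]), as.integer(ii[, 2L])),
        collapse = ";")
}

# junctions as "chrom:strand:start-end" strings, for evidence-set membership
junction_tags <- function(tx) {
  ii <- tx_introns(tx)
  if (nrow(ii) == 0L) return(character(0))
  sprintf("%s:%s:%d-%d", tx$chrom, tx$strand,
          as.integer(ii[, 1L]), as.integer(ii[, 2L]))
}

# overlap length of two [s,e) intervals
interval_overlap <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2))

#' Construct a reference annotation
#'
#' @param genes List of gene models, each a list with fields `id`, `chrom`,
#'   `strand` and `isoforms` (a list of [tx_model] sharing the gene's
#'   chromosome and strand).
#' @return An object of class `ref_annotation`.
#' @export
ref_annotation <- function(genes) {
  ids <- vapply(genes, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("gene ids must be unique")
  for (g in genes) {
    for (tx in g$isoforms) {
      if (!identical(tx$chrom, g$chrom) || !identical(tx$strand, g$strand))
        stop("all isoforms of a gene must share its chromosome and strand")
    }
  }
  structure(list(genes = genes), class = "ref_annotation")
}

#' @export
print.ref_annotation <- function(x, ...) {
  n_iso <- sum(vapply(x$genes, function(g) length(g$isoforms), 0L))
  cat(sprintf("<ref_annotation> %d gene(s), %d isoform(s)\n",
              length(x$genes), n_iso))
  invisible(x)
}

#' All isoforms of an annotation as a flat list
#' @param ann A `ref_annotation`.
#' @return Named list of `tx_model` keyed by transcript id.
#' @export
ann_isoforms <- function(ann) {
  out <- list()
  for (g in ann$genes) for (tx in g$isoforms) out[[tx$id]] <- tx
  out
}

#' Transcript-to-gene map of an annotation
#' @param ann A `ref_annotation`.
#' @return Named character vector: names are transcript ids, values gene ids.
#' @export
ann_tx2gene <- function(ann) {
  out <- character(0)
  for (g in ann$genes)
    for (tx in g$isoforms) out[[tx$id]] <- g$id
  out
}

#' All annotated junctions of an annotation
#' @param ann A `ref_annotation`.
#' @return Character vector of `chrom:strand:start-end` junction tags.
#' @export
ann_junctions <- function(ann) {
  unique(unlist(lapply(ann_isoforms(ann), junction_tags), use.names = FALSE))
}

# per-gene span table used by classification and fusion calling
ann_gene_table <- function(ann) {
  if (length(ann$genes) == 0L)
    return(data.frame(gene_id = character(0), chrom = character(0),
                      strand = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, lapply(ann$genes, function(g) {
    sp <- range(unlist(lapply(g$isoforms, function(tx) tx_span(tx))))
    data.frame(gene_id = g$id, chrom = g$chrom, strand = g$strand,
               start = sp[1L], end = sp[2L], stringsAsFactors = FALSE)
  }))
}

#' Construct an FLNC read
#'
#' One aligned full-length non-chimeric read.  Normal reads carry one
#' alignment block; chimeric (fusion-candidate) reads carry two, ordered
#' 5' then 3' in read orientation.
#'
#' @param id Read identifier.
#' @param blocks List of one or two [tx_model] alignment blocks.
#' @param pid_pre,pid_post Percent identity against the genome before/after
#'   hybrid correction; `NA` means unmapped in that library.
#' @param has_polya Logical; read carries a poly(A) tail.
#' @param multimap Logical; flagged as multiply-best-mapped.
#' @param truth Optional list with `source_transcript`, `phenomenon`,
#'   `apa_site` (simulation ground truth).
#' @return Object of class `flnc_read`.
#' @export
flnc_read <- function(id, blocks, pid_pre = NA_real_, pid_post = NA_real_,
                      has_polya = TRUE, multimap = FALSE, truth = NULL) {
  stopifnot(length(blocks) %in% c(1L, 2L))
  for (p in c(pid_pre, pid_post))
    if (!is.na(p) && (p < 0 || p > 100)) stop("PID must lie in [0,100]")
  structure(list(id = as.character(id), blocks = blocks,
                 pid_pre = pid_pre, pid_post = pid_post,
                 has_polya = isTRUE(has_polya), multimap = isTRUE(multimap),
                 truth = truth),
            class = "flnc_read")
}
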