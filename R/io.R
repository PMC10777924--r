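#' Write a reference annotation to GTF
#'
#' Internal coordinates are 0-based half-open; GTF is 1-based inclusive, so
#' starts are shifted by +1 on output (and back on input).  One `exon`
#' feature per exon with `gene_id` and `transcript_id` attributes.
#'
#' @param ann A [ref_annotation].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotation_gtf <- function(ann, path) {
  rows <- list()
  for (g in ann$genes) {
    for (tx in g$isoforms) {
      ex <- tx$exons
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = g$chrom, start = ex[, 1L] + 1, end = ex[, 2L],
        strand = g$strand, gene_id = g$id, transcript_id = tx$id,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand)
  S4Vectors::mcols(gr)$type <- "exon"
  S4Vectors::mcols(gr)$source <- "isocollapse"
  S4Vectors::mcols(gr)$gene_id <- df$gene_id
  S4Vectors::mcols(gr)$transcript_id <- df$transcript_id
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read a reference annotation from GTF
#'
#' Exon features are grouped by `transcript_id` and genes reassembled from
#' `gene_id`.  Coordinates are converted to the package's 0-based half-open
#' convention.
#'
#' @param path GTF file path.
#' @return A [ref_annotation].
#' @export
read_annotation_gtf <- function(path) {
  if (file.size(path) == 0L) return(ref_annotation(list()))
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   gene_id = S4Vectors::mcols(gr)$gene_id,
                   transcript_id = S4Vectors::mcols(gr)$transcript_id,
                   stringsAsFactors = FALSE)
  genes <- list()
  for (gid in unique(df$gene_id)) {
    gdf <- df[df$gene_id == gid, , drop = FALSE]
    isoforms <- lapply(split(gdf, gdf$transcript_id), function(tdf) {
      tx_model(tdf$transcript_id[1L], tdf$chrom[1L], tdf$strand[1L],
               cbind(tdf$start, tdf$end))
    })
    names(isoforms) <- NULL
    genes[[length(genes) + 1L]] <- list(id = gid, chrom = gdf$chrom[1L],
                                        strand = gdf$strand[1L],
                                        isoforms = isoforms)
  }
  ref_annotation(genes)
}

#' Write FLNC reads as BED12
#'
#' One BED12 line per alignment block.  Fusion (two-block) reads emit two
#' lines whose names carry `/1` and `/2` suffixes for the 5' and 3' halves.
#'
#' @param reads List of [flnc_read].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_flnc_bed <- function(reads, path) {
  recs <- list()
  for (r in reads) {
    nb <- length(r$blocks)
    for (k in seq_len(nb)) {
      b <- r$blocks[[k]]
      nm <- if (nb == 2L) sprintf("%s/%d", r$id, k) else r$id
      recs[[length(recs) + 1L]] <- list(b = b, name = nm)
    }
  }
  if (length(recs) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  chrom <- vapply(recs, function(x) x$b$chrom, "")
  strand <- vapply(recs, function(x) x$b$strand, "")
  spans <- t(vapply(recs, function(x) tx_span(x$b), numeric(2)))
  blocks <- IRanges::IRangesList(lapply(recs, function(x) {
    ex <- x$b$exons
    # block starts relative to chromStart, 1-based within rtracklayer
    IRanges::IRanges(start = ex[, 1L] - min(ex[, 1L]) + 1L,
                     width = ex[, 2L] - ex[, 1L])
  }))
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = spans[, 1L] + 1, end = spans[, 2L]),
    strand = strand)
  S4Vectors::mcols(gr)$name <- vapply(recs, function(x) x$name, "")
  S4Vectors::mcols(gr)$score <- 0L
  S4Vectors::mcols(gr)$blocks <- blocks
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read BED12 alignment records
#'
#' Inverse of [write_flnc_bed]: reassembles two-block fusion reads from
#' `/1`,`/2` name suffixes.  PID and truth fields are not part of BED and
#' come back `NA`/`NULL`.
#'
#' @param path BED12 file path.
#' @return List of [flnc_read].
#' @export
read_flnc_bed <- function(path) {
  if (file.size(path) == 0L) return(list())
  gr <- rtracklayer::import(path, format = "bed")
  nm <- S4Vectors::mcols(gr)$name
  base <- sub("/[12]$", "", nm)
  half <- ifelse(grepl("/2$", nm), 2L, 1L)
  blocks_l <- S4Vectors::mcols(gr)$blocks
  mk_block <- function(i) {
    bl <- blocks_l[[i]]
    off <- GenomicRanges::start(gr)[i] - 1  # back to 0-based
    tx_model(nm[i], as.character(GenomicRanges::seqnames(gr))[i],
             as.character(GenomicRanges::strand(gr))[i],
             cbind(off + IRanges::start(bl) - 1L,
                   off + IRanges::end(bl)))
  }
  out <- list()
  for (rid in unique(base)) {
    idx <- which(base == rid)
    idx <- idx[order(half[idx])]
    out[[length(out) + 1L]] <-
      flnc_read(rid, lapply(idx, mk_block))
  }
  out
}

#' Write the per-read PID table
#' @param reads List of [flnc_read].
#' @param path Output TSV path (`read_id`, `pid_pre`, `pid_post`).
#' @return `path`, invisibly.
#' @export
write_pid_tsv <- function(reads, path) {
  dt <- data.table::data.table(
    read_id = vapply(reads, `[[`, "", "id"),
    pid_pre = vapply(reads, `[[`, 0, "pid_pre"),
    pid_post = vapply(reads, `[[`, 0, "pid_post"))
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a PID table
#' @param path TSV with columns `read_id`, `pid_pre`, `pid_post`.
#' @return data.frame.
#' @export
read_pid_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", na.strings = "NA"))
}

#' Write simulation truth labels
#' @param reads List of [flnc_read] carrying `truth`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(reads, path) {
  dt <- data.table::data.table(
    read_id = vapply(reads, `[[`, "", "id"),
    phenomenon = vapply(reads, function(r)
      if (is.null(r$truth)) NA_character_ else r$truth$phenomenon, ""),
    source_transcript = vapply(reads, function(r)
      if (is.null(r$truth) || is.null(r$truth$source_transcript))
        NA_character_ else r$truth$source_transcript, ""),
    apa_site = vapply(reads, function(r)
      if (is.null(r$truth) || is.null(r$truth$apa_site)) NA_real_
      else as.numeric(r$truth$apa_site), 0))
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Write a count matrix with its design
#' @param sim A `sim_counts` object (see [simulate_counts]).
#' @param counts_path,design_path Output TSV paths.
#' @return `counts_path`, invisibly.
#' @export
write_counts_tsv <- function(sim, counts_path, design_path) {
  dt <- data.table::data.table(transcript_id = rownames(sim$counts))
  for (s in colnames(sim$counts)) dt[[s]] <- sim$counts[, s]
  data.table::fwrite(dt, counts_path, sep = "\t", quote = FALSE)
  des <- data.table::data.table(sample = names(sim$design),
                                tissue = unname(sim$design))
  data.table::fwrite(des, design_path, sep = "\t", quote = FALSE)
  invisible(counts_path)
}

#' Read a count matrix and design
#' @param counts_path TSV with `transcript_id` then one column per sample.
#' @param design_path TSV with columns `sample`, `tissue`.
#' @return List with `counts` (integer matrix) and `design` (named vector).
#' @export
read_counts_tsv <- function(counts_path, design_path) {
  dt <- data.table::fread(counts_path, sep = "\t")
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1L]]
  des <- data.table::fread(design_path, sep = "\t")
  design <- stats::setNames(des$tissue, des$sample)
  list(counts = m, design = design)
}
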