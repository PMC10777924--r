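## Synthetic-data module: a toy reference annotation, FLNC read sets with
## planted phenomena and truth labels, and NB count matrices with planted
## log-fold-changes.  One global seed; sub-generators derive child seeds
## deterministically so each stage is reproducible in isolation.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# deterministic child seed, kept below 2^31
child_seed <- function(seed, k) (as.integer(seed) * 1009L + k * 9973L) %% 2147483629L

# sample() without the scalar-x surprise
resample <- function(x, n = 1L) x[sample.int(length(x), n)]

#' Simulate a toy reference annotation
#'
#' Genes are laid out left to right on a small number of chromosomes with
#' intergenic gaps, so genes never overlap.  Each gene gets an exon
#' scaffold; isoforms are subsets of scaffold exons that always keep the
#' terminal exons, so all isoforms of a gene overlap and share the locus.
#'
#' @param n_genes Number of genes (>= 0).
#' @param exons_per_isoform Integer range `c(min, max)` of exons per isoform.
#' @param isoforms_per_gene Integer range `c(min, max)` of isoforms per gene.
#' @param seed Integer seed; the output is deterministic given the seed.
#' @param genes_per_chrom Genes placed per chromosome before starting a new one.
#' @return A [ref_annotation].
#' @export
simulate_annotation <- function(n_genes,
                                exons_per_isoform = c(2L, 8L),
                                isoforms_per_gene = c(1L, 4L),
                                seed = 1L,
                                genes_per_chrom = 25L) {
  if (length(n_genes) != 1L || is.na(n_genes) || n_genes < 0)
    stop("n_genes must be a non-negative count")
  stopifnot(length(exons_per_isoform) == 2L, exons_per_isoform[1L] >= 1L,
            length(isoforms_per_gene) == 2L, isoforms_per_gene[1L] >= 1L)
  n_genes <- as.integer(n_genes)
  with_seed(seed, {
    genes <- vector("list", n_genes)
    cursor <- c()  # per-chrom layout cursor
    for (i in seq_len(n_genes)) {
      chrom <- sprintf("chr%d", (i - 1L) %/% genes_per_chrom + 1L)
      if (is.null(cursor[chrom]) || is.na(cursor[chrom])) cursor[chrom] <- 1000
      strand <- sample(c("+", "-"), 1L)
      n_iso <- sample(seq(isoforms_per_gene[1L], isoforms_per_gene[2L]), 1L)
      sizes <- sample(seq(exons_per_isoform[1L], exons_per_isoform[2L]),
                      n_iso, replace = TRUE)
      E <- max(sizes)
      ex_len <- sample(100:500, E, replace = TRUE)
      in_len <- if (E > 1L) sample(300:3000, E - 1L, replace = TRUE) else integer(0)
      starts <- cursor[chrom] + cumsum(c(0, ex_len[-E] + in_len))
      scaffold <- cbind(starts, starts + ex_len)
      gid <- sprintf("G%04d", i)
      isoforms <- list(); seen <- character(0)
      for (k in seq_len(n_iso)) {
        m <- sizes[k]
        idx <- if (E <= 2L || m >= E) seq_len(E)
               else sort(c(1L, E, resample(2:(E - 1L), max(0L, m - 2L))))
        key <- paste(idx, collapse = ",")
        if (key %in% seen) next
        seen <- c(seen, key)
        tid <- sprintf("%s.%d", gid, length(isoforms) + 1L)
        isoforms[[length(isoforms) + 1L]] <-
          tx_model(tid, chrom, strand, scaffold[idx, , drop = FALSE])
      }
      genes[[i]] <- list(id = gid, chrom = chrom, strand = strand,
                         isoforms = isoforms)
      cursor[chrom] <- max(scaffold[, 2L]) + sample(5000:20000, 1L)
    }
    ref_annotation(genes)
  })
}

# planted alternative poly(A) sites per gene: site 1 is the annotated 3' end
# of each isoform; extra sites extend the 3' terminal exon outward in steps,
# so junctions are untouched and sites stay well separated (> any sane
# clustering window).
plant_apa_sites <- function(ann, apa_sites_per_gene) {
  sites <- list()
  for (g in ann$genes) {
    if (apa_sites_per_gene < 2L) { sites[[g$id]] <- numeric(0); next }
    ends <- vapply(g$isoforms, function(tx) {
      sp <- tx_span(tx); if (g$strand == "+") sp[2L] else sp[1L]
    }, 0)
    anchor <- if (g$strand == "+") max(ends) else min(ends)
    off <- 200 * seq_len(apa_sites_per_gene - 1L)
    sites[[g$id]] <- if (g$strand == "+") anchor + off else anchor - off
  }
  sites
}

# one deterministic novel splice variant per multi-junction isoform: shift one
# internal acceptor 12 bp into its intron, creating an unannotated site.
plant_novel_variant <- function(tx) {
  ii <- tx_introns(tx)
  if (nrow(ii) == 0L) return(NULL)
  ex <- tx$exons
  shift <- 12
  if (tx$strand == "+") {
    # acceptor = intron end = start of a downstream exon
    j <- nrow(ii)  # last intron: its end is start of last exon
    if (ii[j, 2L] - ii[j, 1L] <= shift + 5) return(NULL)
    ex2 <- ex; ex2[j + 1L, 1L] <- ex2[j + 1L, 1L] - shift
  } else {
    j <- 1L        # first genomic intron; acceptor is its start side
    if (ii[j, 2L] - ii[j, 1L] <= shift + 5) return(NULL)
    ex2 <- ex; ex2[j, 2L] <- ex2[j, 2L] + shift
  }
  tx_model(paste0(tx$id, ".nv"), tx$chrom, tx$strand, ex2)
}

# planted novel intergenic gene models, placed beyond all annotated genes on
# chr1 (or on a fresh chromosome if the annotation is empty on chr1)
plant_novel_genes <- function(ann, n) {
  tab <- ann_gene_table(ann)
  chrom <- if (nrow(tab) > 0L) tab$chrom[1L] else "chr1"
  base <- if (nrow(tab) > 0L) max(tab$end[tab$chrom == chrom]) + 50000 else 50000
  out <- list()
  for (k in seq_len(n)) {
    start <- base + (k - 1L) * 30000
    ex <- rbind(c(start, start + 300),
                c(start + 1500, start + 1900),
                c(start + 3000, start + 3400))
    out[[k]] <- tx_model(sprintf("NOVG%03d.1", k), chrom,
                         if (k %% 2L == 0L) "-" else "+", ex)
  }
  out
}

# 5'-truncate a transcript chain (transcript orientation): drop k 5' exons
# and trim into the new 5' terminal exon.  Junctions downstream of the
# truncation point are untouched.
degrade_5prime <- function(tx, rid) {
  ex <- tx$exons
  n <- nrow(ex)
  k <- if (n > 1L) sample(0:(n - 1L), 1L) else 0L
  if (tx$strand == "+") {
    if (k > 0L) ex <- ex[-seq_len(k), , drop = FALSE]
    w <- ex[1L, 2L] - ex[1L, 1L]
    trim <- sample.int(max(1L, floor(w / 2)), 1L)
    ex[1L, 1L] <- ex[1L, 1L] + trim
  } else {
    if (k > 0L) ex <- ex[seq_len(nrow(ex) - k), , drop = FALSE]
    m <- nrow(ex)
    w <- ex[m, 2L] - ex[m, 1L]
    trim <- sample.int(max(1L, floor(w / 2)), 1L)
    ex[m, 2L] <- ex[m, 2L] - trim
  }
  tx_model(rid, tx$chrom, tx$strand, ex)
}

#' Simulate aligned FLNC reads with planted phenomena
#'
#' Every read is a coordinate-level copy of a source isoform, modified
#' according to a phenomenon drawn per read: `full_length` (exact chain),
#' `degraded_5prime` (5'-truncated, strand-aware), `novel_isoform` (one
#' shifted acceptor, shared by all novel reads of that isoform so they can
#' support each other), `novel_gene` (read from a planted intergenic model),
#' `apa_shifted` (3' terminal coordinate moved to a planted alternative
#' poly(A) site), or `fusion` (two alignment blocks, 5' half in one gene and
#' 3' half in another).  PID pairs are drawn from truncated normals clipped
#' to [50, 100]; small fractions are unmapped pre- or post-correction.
#'
#' @param ann A [ref_annotation].
#' @param reads_per_isoform Reads generated per annotated isoform.
#' @param p_degraded,p_novel_isoform,p_novel_gene,p_fusion,p_apa_shift
#'   Per-read phenomenon probabilities; must sum to <= 1.
#' @param apa_sites_per_gene Number of planted poly(A) sites per gene
#'   (1 = no APA heterogeneity); `p_apa_shift` is forced to 0 when 1.
#' @param pid_model Numeric `c(mean_pre, mean_post, sd)` of the PID draws.
#' @param p_pid_equal Probability that correction leaves the PID unchanged.
#' @param p_only_post,p_only_pre Fractions unmapped pre-/post-correction.
#' @param p_multimap Fraction flagged as multiply-best-mapped.
#' @param seed Integer seed.
#' @return List of [flnc_read] with truth labels.
#' @export
simulate_flnc <- function(ann, reads_per_isoform = 5L,
                          p_degraded = 0, p_novel_isoform = 0,
                          p_novel_gene = 0, p_fusion = 0, p_apa_shift = 0,
                          apa_sites_per_gene = 1L,
                          pid_model = c(99.0, 99.1, 0.8),
                          p_pid_equal = 0.5,
                          p_only_post = 0.002, p_only_pre = 5e-4,
                          p_multimap = 0.008,
                          seed = 1L) {
  probs <- c(p_degraded, p_novel_isoform, p_novel_gene, p_fusion, p_apa_shift)
  if (any(probs < 0) || any(probs > 1) || sum(probs) > 1)
    stop("phenomenon probabilities must lie in [0,1] and sum to <= 1")
  isoforms <- ann_isoforms(ann)
  if (length(isoforms) == 0L && reads_per_isoform > 0L)
    stop("cannot simulate reads from an empty annotation")
  tx2gene <- ann_tx2gene(ann)
  apa_sites <- plant_apa_sites(ann, apa_sites_per_gene)
  if (apa_sites_per_gene < 2L) p_apa_shift <- 0
  with_seed(child_seed(seed, 1L), {
    variants <- lapply(isoforms, plant_novel_variant)
    n_total <- length(isoforms) * reads_per_isoform
    n_novg <- max(1L, ceiling(n_total * p_novel_gene / 3))
    novel_genes <- if (p_novel_gene > 0) plant_novel_genes(ann, n_novg) else list()
    gene_ids <- vapply(ann$genes, `[[`, "", "id")
    reads <- vector("list", n_total)
    ridx <- 0L; novg_next <- 1L
    draw_pid <- function() {
      clip <- function(x) pmin(100, pmax(50, x))
      pre <- clip(stats::rnorm(1, pid_model[1L], pid_model[3L]))
      post <- if (stats::runif(1) < p_pid_equal) pre
              else clip(stats::rnorm(1, pid_model[2L], pid_model[3L]))
      u <- stats::runif(1)
      if (u < p_only_post) pre <- NA_real_
      else if (u < p_only_post + p_only_pre) post <- NA_real_
      c(pre, post)
    }
    phen_levels <- c("degraded_5prime", "novel_isoform", "novel_gene",
                     "fusion", "apa_shifted", "full_length")
    for (tid in names(isoforms)) {
      tx <- isoforms[[tid]]
      gid <- tx2gene[[tid]]
      for (j in seq_len(reads_per_isoform)) {
        ridx <- ridx + 1L
        rid <- sprintf("read%06d", ridx)
        phen <- sample(phen_levels, 1L,
                       prob = c(probs, 1 - sum(probs)))
        # phenomena that cannot be realised for this source fall back to
        # full_length (single-exon sources cannot host a splice variant)
        if (phen == "novel_isoform" && is.null(variants[[tid]]))
          phen <- "full_length"
        if (phen == "fusion" && length(gene_ids) < 2L) phen <- "full_length"
        pid <- draw_pid()
        mm <- stats::runif(1) < p_multimap
        blk <- switch(phen,
          full_length = tx_model(rid, tx$chrom, tx$strand, tx$exons),
          degraded_5prime = degrade_5prime(tx, rid),
          novel_isoform = {
            v <- variants[[tid]]
            tx_model(rid, v$chrom, v$strand, v$exons)
          },
          apa_shifted = NULL, novel_gene = NULL, fusion = NULL)
        truth <- list(source_transcript = tid, phenomenon = phen,
                      apa_site = NULL)
        if (phen == "apa_shifted") {
          site <- resample(apa_sites[[gid]])
          ex <- tx$exons
          if (tx$strand == "+") ex[nrow(ex), 2L] <- site
          else ex[1L, 1L] <- site
          blk <- tx_model(rid, tx$chrom, tx$strand, ex)
          truth$apa_site <- site
        }
        if (phen == "novel_gene") {
          src <- novel_genes[[novg_next]]
          novg_next <- if (novg_next >= length(novel_genes)) 1L else novg_next + 1L
          blk <- tx_model(rid, src$chrom, src$strand, src$exons)
          truth$source_transcript <- src$id
        }
        if (phen == "fusion") {
          other <- resample(setdiff(gene_ids, gid))
          gB <- ann$genes[[match(other, gene_ids)]]
          txB <- gB$isoforms[[1L]]
          half5 <- tx_half(tx, "5prime")
          half3 <- tx_half(txB, "3prime")
          b1 <- tx_model(paste0(rid, "/1"), tx$chrom, tx$strand, half5)
          b2 <- tx_model(paste0(rid, "/2"), txB$chrom, txB$strand, half3)
          truth$source_transcript <- paste(tid, txB$id, sep = "|")
          reads[[ridx]] <- flnc_read(rid, list(b1, b2), pid[1L], pid[2L],
                                     multimap = mm, truth = truth)
          next
        }
        reads[[ridx]] <- flnc_read(rid, list(blk), pid[1L], pid[2L],
                                   multimap = mm, truth = truth)
      }
    }
    reads
  })
}

# 5' or 3' half of an exon chain in transcript orientation
tx_half <- function(tx, side = c("5prime", "3prime")) {
  side <- match.arg(side)
  ex <- tx$exons
  n <- nrow(ex)
  k <- max(1L, ceiling(n / 2))
  left <- (tx$strand == "+") == (side == "5prime")
  if (left) ex[seq_len(k), , drop = FALSE]
  else ex[seq(n - k + 1L, n), , drop = FALSE]
}

#' Simulate a transcript-by-sample NB count matrix with planted effects
#'
#' Baseline means are gamma-distributed around `baseline_mean`; a fraction
#' `frac_de` of transcripts get their mean multiplied by
#' `2^(+/- lfc_magnitude)` in one randomly chosen tissue.  Counts are drawn
#' NB with dispersion `alpha` (`alpha = 0` gives Poisson), after per-sample
#' depth factors that exercise normalisation downstream.
#'
#' @param ann A [ref_annotation]; one row per annotated transcript.
#' @param design Named character vector sample -> tissue (>= 2 tissues,
#'   >= 2 replicates each).
#' @param baseline_mean Mean of the baseline expression distribution.
#' @param dispersion NB dispersion alpha >= 0 (variance = mu + alpha mu^2).
#' @param frac_de Fraction of transcripts with a planted effect.
#' @param lfc_magnitude Absolute planted log2 fold-change.
#' @param depth_range Range of per-sample depth multipliers.
#' @param seed Integer seed.
#' @return Object of class `sim_counts`: list with `counts`, `design`,
#'   `truth_lfc` (rows x tissue-pairs, log2 ratios second/first),
#'   `dispersion`, `lengths` (per-transcript exonic length).
#' @export
simulate_counts <- function(ann,
                            design = default_design(),
                            baseline_mean = 100,
                            dispersion = 0.05,
                            frac_de = 0.1,
                            lfc_magnitude = 2,
                            depth_range = c(0.7, 1.4),
                            seed = 1L) {
  if (dispersion < 0) stop("dispersion must be >= 0")
  tissues <- unique(unname(design))
  if (length(tissues) < 2L) stop("design needs >= 2 tissues")
  if (any(table(unname(design)) < 2L)) stop("design needs >= 2 replicates per tissue")
  isoforms <- ann_isoforms(ann)
  ids <- names(isoforms)
  n <- length(ids)
  lengths <- vapply(isoforms, tx_exonic_length, 0)
  with_seed(child_seed(seed, 2L), {
    base_mu <- stats::rgamma(n, shape = 2, scale = baseline_mean / 2) + 1
    de <- stats::runif(n) < frac_de
    de_tissue <- sample(tissues, n, replace = TRUE)
    de_sign <- sample(c(-1, 1), n, replace = TRUE)
    mu <- matrix(base_mu, nrow = n, ncol = length(tissues),
                 dimnames = list(ids, tissues))
    for (i in which(de))
      mu[i, de_tissue[i]] <- mu[i, de_tissue[i]] * 2^(de_sign[i] * lfc_magnitude)
    depth <- stats::runif(length(design), depth_range[1L], depth_range[2L])
    counts <- matrix(0L, nrow = n, ncol = length(design),
                     dimnames = list(ids, names(design)))
    for (j in seq_along(design)) {
      m <- mu[, design[[j]]] * depth[j]
      counts[, j] <- if (dispersion == 0) stats::rpois(n, m)
                     else stats::rnbinom(n, mu = m, size = 1 / dispersion)
    }
    pairs <- utils::combn(tissues, 2L)
    truth_lfc <- matrix(0, nrow = n, ncol = ncol(pairs),
                        dimnames = list(ids, apply(pairs, 2L, paste, collapse = "_vs_")))
    for (k in seq_len(ncol(pairs)))
      truth_lfc[, k] <- log2(mu[, pairs[2L, k]] / mu[, pairs[1L, k]])
    structure(list(counts = counts, design = design, truth_lfc = truth_lfc,
                   dispersion = rep(dispersion, n), lengths = lengths),
              class = "sim_counts")
  })
}

#' Default 3-tissue, 4-replicate design
#'
#' Twelve samples across tail (TF), subcutaneous (SF) and visceral (VF)
#' adipose tissue, four replicates each.
#' @return Named character vector sample -> tissue.
#' @export
default_design <- function() {
  tissues <- c("TF", "SF", "VF")
  stats::setNames(rep(tissues, each = 4L),
                  paste0(rep(tissues, each = 4L), 1:4))
}
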