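## Expression quantification and differential expression: FPKM, expression
## classes, median-of-ratios normalisation and a negative-binomial Wald test
## with method-of-moments dispersion shrunk toward a parametric trend.
## DESeq2-equivalent in design, not bit-identical; validated by
## planted-effect recovery.

#' FPKM matrix from raw counts
#'
#' `FPKM[i,j] = counts[i,j] * 1e9 / (length[i] * total[j])` where `total[j]`
#' is the per-sample sum of mapped read counts.
#'
#' @param counts Non-negative integer matrix (rows = transcripts or genes).
#' @param lengths Per-row exonic length in bp (> 0).
#' @return Numeric matrix of the same shape.
#' @export
fpkm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (length(lengths) != nrow(counts)) stop("one length per row required")
  if (any(lengths <= 0)) stop("lengths must be > 0")
  totals <- colSums(counts)
  if (any(totals <= 0)) stop("zero library size")
  sweep(counts * 1e9 / lengths, 2L, totals, "/")
}

#' Expression-class report
#'
#' Per sample, rows with FPKM strictly above `high_cutoff` are highly
#' expressed.  Per tissue, rows with FPKM > 0 in every replicate are
#' commonly expressed; the Venn-style intersection counts across tissues are
#' tabulated.
#'
#' @param fpkm_mat Matrix from [fpkm].
#' @param design Named vector sample -> tissue covering all columns.
#' @param high_cutoff Strict threshold for "highly expressed" (default 60).
#' @return List with `highly_expressed` (named integer per sample),
#'   `common_by_tissue` (named integer per tissue), `venn` (named integer
#'   per tissue combination, names like `"TF"`, `"TF&SF"`, ...), and
#'   `common_ids` (list of row-id vectors per tissue).
#' @export
expression_classes <- function(fpkm_mat, design, high_cutoff = 60) {
  stopifnot(all(colnames(fpkm_mat) %in% names(design)))
  tissues <- unique(unname(design[colnames(fpkm_mat)]))
  high <- colSums(fpkm_mat > high_cutoff)
  common <- lapply(tissues, function(tt) {
    cols <- colnames(fpkm_mat)[design[colnames(fpkm_mat)] == tt]
    rownames(fpkm_mat)[rowSums(fpkm_mat[, cols, drop = FALSE] > 0) == length(cols)]
  })
  names(common) <- tissues
  member <- vapply(common, function(ids) rownames(fpkm_mat) %in% ids,
                   logical(nrow(fpkm_mat)))
  combos <- character(nrow(fpkm_mat))
  for (i in seq_len(nrow(fpkm_mat)))
    combos[i] <- paste(tissues[member[i, ]], collapse = "&")
  venn <- table(combos[combos != ""])
  list(highly_expressed = high,
       common_by_tissue = vapply(common, length, 0L),
       venn = stats::setNames(as.integer(venn), names(venn)),
       common_ids = common)
}

#' Median-of-ratios size factors
#'
#' For rows with all-positive counts, the per-sample factor is the median of
#' `counts[i, j] / geometric_mean_i`.  With `normalize = TRUE` (default)
#' factors are divided by their geometric mean so they multiply to 1.
#'
#' @param counts Count matrix.
#' @param normalize Rescale factors to unit geometric mean.
#' @return Positive numeric vector, one per column.
#' @export
size_factors <- function(counts, normalize = TRUE) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no row with all-positive counts; supply a pseudo-reference instead")
  logc <- log(counts[pos, , drop = FALSE])
  logmean <- rowMeans(logc)
  sf <- apply(logc, 2L, function(x) exp(stats::median(x - logmean)))
  if (normalize) sf <- sf / exp(mean(log(sf)))
  sf
}

# parametric dispersion trend alpha(mu) = a0 + a1/mu, fitted by least
# squares on moment estimates (coefficients clamped non-negative)
fit_dispersion_trend <- function(mu, alpha_hat) {
  ok <- is.finite(mu) & is.finite(alpha_hat) & mu > 0 & alpha_hat > 0
  if (sum(ok) < 10L) {
    a0 <- stats::median(alpha_hat[ok], na.rm = TRUE)
    if (!is.finite(a0)) a0 <- 0.1
    return(c(a0 = max(a0, 1e-4), a1 = 0))
  }
  fit <- stats::lm(alpha_hat[ok] ~ I(1 / mu[ok]))
  co <- pmax(stats::coef(fit), 0)
  if (!any(co > 0)) co[1L] <- 1e-4
  c(a0 = unname(co[1L]), a1 = unname(co[2L]))
}

#' Negative-binomial Wald test between two tissues
#'
#' Counts are normalised by [size_factors]; per-row dispersions are
#' method-of-moments estimates shrunk toward a parametric trend
#' `alpha = a0 + a1/mean` (weight `prior_weight` on the trend).  The Wald
#' statistic tests `log2fc = log2((meanB + pseudo)/(meanA + pseudo))`
#' against zero with a delta-method standard error; p-values are adjusted
#' by Benjamini-Hochberg across rows.  Rows that are all zero in both
#' groups get `p = 1`, `log2fc = 0` by convention.
#'
#' @param counts Integer count matrix (rows = genes or transcripts).
#' @param design Named vector sample -> tissue.
#' @param pair Character vector of two tissues `c(reference, treatment)`;
#'   `log2fc` is treatment over reference.
#' @param lfc_threshold,alpha_threshold Call thresholds: `is_de` iff
#'   `|log2fc| > lfc_threshold` and `padj < alpha_threshold`.
#' @param pseudo Pseudocount on normalised means (default 0.5).
#' @param prior_weight Shrinkage weight on the dispersion trend in [0, 1].
#' @return data.frame with `id`, `baseMean`, `log2fc`, `p`, `padj`, `is_de`.
#' @export
nb_test <- function(counts, design, pair,
                    lfc_threshold = 1, alpha_threshold = 0.05,
                    pseudo = 0.5, prior_weight = 0.6) {
  counts <- as.matrix(counts)
  stopifnot(length(pair) == 2L, all(pair %in% design))
  colsA <- names(design)[design == pair[1L]]
  colsA <- intersect(colsA, colnames(counts))
  colsB <- intersect(names(design)[design == pair[2L]], colnames(counts))
  if (length(colsA) < 2L || length(colsB) < 2L)
    stop("need >= 2 replicates per tissue")
  sub <- counts[, c(colsA, colsB), drop = FALSE]
  sf <- size_factors(sub)
  norm <- sweep(sub, 2L, sf, "/")
  nA <- length(colsA); nB <- length(colsB)
  mA <- rowMeans(norm[, colsA, drop = FALSE])
  mB <- rowMeans(norm[, colsB, drop = FALSE])
  vA <- apply(norm[, colsA, drop = FALSE], 1L, stats::var)
  vB <- apply(norm[, colsB, drop = FALSE], 1L, stats::var)
  # pooled moment estimate of alpha from var = mu + alpha mu^2
  mu_pool <- (nA * mA + nB * mB) / (nA + nB)
  v_pool <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
  alpha_hat <- (v_pool - mu_pool) / mu_pool^2
  alpha_hat[!is.finite(alpha_hat)] <- NA
  trend <- fit_dispersion_trend(mu_pool, pmax(alpha_hat, 1e-8))
  alpha_trend <- trend[["a0"]] + trend[["a1"]] / pmax(mu_pool, 1e-8)
  alpha <- (1 - prior_weight) * pmax(alpha_hat, 0) + prior_weight * alpha_trend
  alpha[is.na(alpha_hat)] <- alpha_trend[is.na(alpha_hat)]
  alpha <- pmax(alpha, 1e-8)
  mAp <- mA + pseudo; mBp <- mB + pseudo
  log2fc <- log2(mBp / mAp)
  # delta method: var(log2 mean) = var(mean) / (mean^2 ln(2)^2),
  # var(mean_group) = (mu + alpha mu^2) / n on the normalised scale
  se2 <- ((mAp + alpha * mAp^2) / (nA * mAp^2) +
          (mBp + alpha * mBp^2) / (nB * mBp^2)) / log(2)^2
  z <- log2fc / sqrt(se2)
  p <- 2 * stats::pnorm(-abs(z))
  allzero <- mA == 0 & mB == 0
  log2fc[allzero] <- 0
  p[allzero] <- 1
  padj <- stats::p.adjust(p, method = "BH")
  data.frame(id = rownames(counts), baseMean = mu_pool, log2fc = log2fc,
             p = p, padj = padj,
             is_de = abs(log2fc) > lfc_threshold & padj < alpha_threshold,
             stringsAsFactors = FALSE)
}

#' Differential expression over all tissue pairs
#' @param counts,design As in [nb_test].
#' @param ... Passed to [nb_test].
#' @return Named list of [nb_test] results, one per tissue pair
#'   (`"A_vs_B"` = B over A).
#' @export
nb_test_all_pairs <- function(counts, design, ...) {
  tissues <- unique(unname(design))
  pairs <- utils::combn(tissues, 2L)
  out <- list()
  for (k in seq_len(ncol(pairs))) {
    nm <- paste(pairs[1L, k], pairs[2L, k], sep = "_vs_")
    out[[nm]] <- nb_test(counts, design, pairs[, k], ...)
  }
  out
}

#' Aggregate transcript counts to gene level
#' @param counts Transcript count matrix.
#' @param tx2gene Named vector transcript -> gene (see [ann_tx2gene]).
#' @return Gene-level count matrix (sum of member transcripts).
#' @export
gene_counts <- function(counts, tx2gene) {
  counts <- as.matrix(counts)
  g <- tx2gene[rownames(counts)]
  keep <- !is.na(g)
  rowsum(counts[keep, , drop = FALSE], group = g[keep])
}

#' Union-exon gene lengths
#' @param ann A [ref_annotation].
#' @return Named numeric vector of per-gene union-exon lengths in bp.
#' @export
gene_lengths <- function(ann) {
  out <- numeric(0)
  for (g in ann$genes) {
    ir <- IRanges::reduce(do.call(c, lapply(g$isoforms, function(tx)
      IRanges::IRanges(start = tx$exons[, 1L] + 1L, end = tx$exons[, 2L]))))
    out[[g$id]] <- sum(IRanges::width(ir))
  }
  out
}
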