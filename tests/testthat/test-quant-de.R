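test_that("fpkm is the unit-conversion ratio and scales with library size", {
  m <- matrix(c(10, 0, 250), ncol = 1, dimnames = list(c("a", "b", "c"), "s1"))
  # pad the library to the stated totals with a filler row
  m <- rbind(m, filler = 1e6 - sum(m[, 1]))
  f <- fpkm(m, lengths = c(1000, 500, 2500, 1000))
  expect_equal(f["a", 1], 10.0)
  expect_equal(f["b", 1], 0)
  m2 <- rbind(m[1:3, , drop = FALSE], filler = 5e6 - sum(m[1:3, 1]))
  f2 <- fpkm(m2, lengths = c(1000, 500, 2500, 1000))
  expect_equal(f2["c", 1], 20.0)
  # doubling the library halves every FPKM
  expect_equal(fpkm(m * 2, c(1000, 500, 2500, 1000))["a", 1], f["a", 1])
  big <- cbind(m, s2 = m[, 1] * 2)
  fb <- fpkm(big, c(1000, 500, 2500, 1000))
  expect_equal(fb[, "s1"], fb[, "s2"])
  expect_error(fpkm(m * 0, c(1000, 500, 2500, 1000)), "library")
  # row order invariance
  perm <- c(3, 1, 4, 2)
  fp <- fpkm(m[perm, , drop = FALSE], c(1000, 500, 2500, 1000)[perm])
  expect_equal(fp[rownames(f), 1], f[, 1])
})

test_that("expression classes use strict cutoffs and per-tissue presence", {
  design <- stats::setNames(rep(c("TF", "SF", "VF"), each = 2), paste0("s", 1:6))
  f <- rbind(at60 = rep(60, 6), hi = rep(61, 6),
             tf_only = c(5, 5, 0, 1, 0, 0), all_on = rep(1, 6))
  colnames(f) <- names(design)
  cls <- expression_classes(f, design)
  # exactly 60 is NOT highly expressed (strict >)
  expect_equal(unname(cls$highly_expressed), rep(1L, 6))
  expect_equal(cls$common_by_tissue[["TF"]], 4L)
  expect_equal(sort(cls$common_ids$TF), c("all_on", "at60", "hi", "tf_only"))
  expect_false("tf_only" %in% cls$common_ids$VF)
  expect_equal(cls$venn[["TF"]], 1L)
  expect_equal(cls$venn[["TF&SF&VF"]], 3L)
})

test_that("venn counts match an exhaustive recount on planted data", {
  ann <- simulate_annotation(20, seed = 71)
  sim <- simulate_counts(ann, frac_de = 0, seed = 71)
  # silence some transcripts per tissue
  cnt <- sim$counts
  ids <- rownames(cnt)
  tf_cols <- names(sim$design)[sim$design == "TF"]
  cnt[ids[1:5], tf_cols] <- 0L
  f <- fpkm(cnt, sim$lengths)
  cls <- expression_classes(f, sim$design)
  # brute-force recount
  tissues <- unique(unname(sim$design))
  member <- sapply(tissues, function(tt) {
    cols <- names(sim$design)[sim$design == tt]
    apply(f[, cols, drop = FALSE], 1, function(x) all(x > 0))
  })
  for (tt in tissues)
    expect_equal(cls$common_by_tissue[[tt]], sum(member[, tt]))
  combo <- apply(member, 1, function(m) paste(tissues[m], collapse = "&"))
  for (nm in names(cls$venn))
    expect_equal(cls$venn[[nm]], sum(combo == nm))
})

test_that("size factors are median-of-ratios and recover scaled columns", {
  m <- matrix(c(10, 30, 5, 20, 60, 10), ncol = 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  sf <- size_factors(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))
  # identical columns
  expect_equal(unname(size_factors(cbind(m[, 1], m[, 1]))), c(1, 1))
  # agrees with the hand-rolled oracle on random matrices
  set.seed(3)
  r <- matrix(rnbinom(600, mu = 50, size = 2) + 1L, ncol = 6)
  expect_equal(unname(size_factors(r)), size_factors_oracle(r))
  # scaled copies of one column recover the scales up to a constant
  base <- rnbinom(200, mu = 100, size = 5) + 1
  scales <- c(0.5, 1, 2, 4)
  sm <- sapply(scales, function(s) round(base * s))
  sf2 <- size_factors(sm)
  expect_equal(unname(sf2 / sf2[2]), scales / scales[2], tolerance = 0.02)
  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2)), "all-positive")
})

test_that("size factors match DESeq2's median-of-ratios", {
  set.seed(4)
  m <- matrix(rnbinom(1200, mu = 80, size = 3) + 1L, ncol = 6,
              dimnames = list(NULL, paste0("s", 1:6)))
  ours <- size_factors(m, normalize = FALSE)
  theirs <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-8)
})

test_that("BH adjustment matches the hand oracle and is monotone", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(stats::p.adjust(p, "BH"), rep(0.04, 4))
  expect_equal(bh_oracle(p), rep(0.04, 4))
  set.seed(5)
  p2 <- runif(200)
  adj <- stats::p.adjust(p2, "BH")
  expect_equal(adj, bh_oracle(p2))
  expect_true(all(adj >= p2))
  o <- order(p2)
  expect_false(is.unsorted(adj[o]))
})

test_that("nb_test handles degenerate inputs by convention", {
  design <- stats::setNames(rep(c("A", "B"), each = 3), paste0("s", 1:6))
  one <- c(5, 9, 14, 5, 9, 14)
  cnt <- rbind(g1 = one * 2, g2 = one, zero = 0, g3 = one + 3)
  colnames(cnt) <- names(design)
  r <- nb_test(cnt, design, c("A", "B"))
  expect_equal(r$log2fc, rep(0, 4))
  expect_false(any(r$is_de))
  expect_equal(r[r$id == "zero", "p"], 1)
  expect_true(all(r$padj >= r$p))
  expect_error(nb_test(cnt[, 1:4], design[c(1, 2, 3, 4)], c("A", "B")),
               "replicates")
})

test_that("swapping tissue labels negates every log2fc", {
  ann <- simulate_annotation(20, seed = 72)
  sim <- simulate_counts(ann, frac_de = 0.2, seed = 72)
  a <- nb_test(sim$counts, sim$design, c("TF", "SF"))
  b <- nb_test(sim$counts, sim$design, c("SF", "TF"))
  expect_equal(a$log2fc, -b$log2fc)
  expect_equal(a$p, b$p)
})

test_that("type-I error is near nominal on null NB data", {
  design <- stats::setNames(rep(c("A", "B"), each = 4), paste0("s", 1:8))
  set.seed(81)
  rates <- replicate(20, {
    mu <- rgamma(2000, 2, scale = 50) + 1
    cnt <- matrix(rnbinom(2000 * 8, mu = rep(mu, 8), size = 1 / 0.05),
                  nrow = 2000, dimnames = list(paste0("g", 1:2000),
                                               names(design)))
    mean(nb_test(cnt, design, c("A", "B"))$p < 0.05)
  })
  expect_gte(mean(rates), 0.03)
  expect_lte(mean(rates), 0.07)
})

test_that("planted effects are recovered with controlled FDR and power", {
  ann <- simulate_annotation(30, isoforms_per_gene = c(1, 2), seed = 73)
  # expand to ~2000 rows by repeated simulation under one seed
  design <- stats::setNames(rep(c("A", "B"), each = 4), paste0("s", 1:8))
  set.seed(82)
  n <- 2000
  mu <- rgamma(n, 2, scale = 50) + 1
  de <- sort(sample(n, round(0.1 * n)))
  muB <- mu
  muB[de] <- muB[de] * 2^(sample(c(-2, 2), length(de), replace = TRUE))
  cnt <- cbind(matrix(rnbinom(n * 4, mu = rep(mu, 4), size = 1 / 0.05), n),
               matrix(rnbinom(n * 4, mu = rep(muB, 4), size = 1 / 0.05), n))
  dimnames(cnt) <- list(paste0("g", seq_len(n)), names(design))
  r <- nb_test(cnt, design, c("A", "B"))
  calls <- which(r$is_de)
  expect_gte(mean(de %in% calls), 0.7)            # power
  expect_lte(mean(!(calls %in% de)), 0.10)        # empirical FDR
})

test_that("gene aggregation sums member transcripts", {
  ann <- simulate_annotation(8, isoforms_per_gene = c(2, 3), seed = 74)
  sim <- simulate_counts(ann, seed = 74)
  t2g <- ann_tx2gene(ann)
  g <- gene_counts(sim$counts, t2g)
  gid <- unname(t2g[rownames(sim$counts)[1]])
  members <- names(t2g)[t2g == gid]
  expect_equal(g[gid, ],
               colSums(sim$counts[members, , drop = FALSE]))
  gl <- gene_lengths(ann)
  expect_setequal(names(gl), vapply(ann$genes, `[[`, "", "id"))
  # union length bounded by the longest isoform and the exon sum
  for (gg in ann$genes) {
    lens <- vapply(gg$isoforms, tx_exonic_length, 0)
    expect_gte(gl[[gg$id]], max(lens))
  }
})
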