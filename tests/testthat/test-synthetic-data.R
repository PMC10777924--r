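test_that("simulate_annotation handles edge cases and is deterministic", {
  expect_length(simulate_annotation(0, seed = 1)$genes, 0L)
  expect_error(simulate_annotation(-1), "non-negative")
  a1 <- simulate_annotation(20, seed = 4)
  a2 <- simulate_annotation(20, seed = 4)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_annotation_gtf(a1, f1); write_annotation_gtf(a2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_false(identical(
    ann_isoforms(simulate_annotation(20, seed = 5))[[1]]$exons,
    ann_isoforms(a1)[[1]]$exons))
})

test_that("emitted GTF passes an independent record scan", {
  ann <- simulate_annotation(50, seed = 1)
  f <- withr::local_tempfile(fileext = ".gtf")
  write_annotation_gtf(ann, f)
  # independent scan: parse raw lines, not the io layer
  lines <- readLines(f)
  lines <- lines[!startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  expect_true(all(lengths(fields) == 9L))
  gene_ids <- unique(sub('.*gene_id "([^"]+)".*', "\\1",
                         vapply(fields, `[[`, "", 9L)))
  expect_length(gene_ids, 50L)
  tx_ids <- sub('.*transcript_id "([^"]+)".*', "\\1",
                vapply(fields, `[[`, "", 9L))
  starts <- as.integer(vapply(fields, `[[`, "", 4L))
  ends <- as.integer(vapply(fields, `[[`, "", 5L))
  expect_true(all(ends >= starts))
  for (id in unique(tx_ids)) {
    s <- starts[tx_ids == id]; e <- ends[tx_ids == id]
    o <- order(s)
    s <- s[o]; e <- e[o]
    if (length(s) > 1L) expect_true(all(s[-1L] > e[-length(e)]))
  }
})

test_that("no-noise reads copy their source chains exactly", {
  ann <- simulate_annotation(10, seed = 2)
  reads <- simulate_flnc(ann, 3, seed = 2)
  iso <- ann_isoforms(ann)
  expect_true(all(phenomena_of(reads) == "full_length"))
  for (r in reads) {
    src <- iso[[r$truth$source_transcript]]
    expect_equal(unname(r$blocks[[1]]$exons), unname(src$exons))
  }
})

test_that("simulate_flnc validates arguments", {
  ann <- simulate_annotation(2, seed = 1)
  expect_error(simulate_flnc(ann, 2, p_degraded = 0.8, p_fusion = 0.4),
               "sum to")
  expect_error(simulate_flnc(ref_annotation(list()), 2), "empty annotation")
})

test_that("truth labels partition reads and frequencies match requests", {
  ann <- simulate_annotation(25, seed = 3)
  n_iso <- length(ann_isoforms(ann))
  rpi <- ceiling(10000 / n_iso)
  probs <- c(degraded_5prime = 0.2, novel_isoform = 0.1, novel_gene = 0.05,
             fusion = 0.1, apa_shifted = 0.1)
  reads <- simulate_flnc(ann, rpi, p_degraded = probs[[1]],
                         p_novel_isoform = probs[[2]],
                         p_novel_gene = probs[[3]], p_fusion = probs[[4]],
                         p_apa_shift = probs[[5]], apa_sites_per_gene = 2,
                         seed = 8)
  ph <- phenomena_of(reads)
  expect_true(all(table(vapply(reads, `[[`, "", "id")) == 1L))
  lev <- c(names(probs), "full_length")
  obs <- vapply(lev, function(l) sum(ph == l), 0L)
  exp_p <- c(probs, full_length = 1 - sum(probs))
  gof <- suppressWarnings(stats::chisq.test(obs, p = exp_p))
  expect_gt(gof$p.value, 0.01)
})

test_that("planted fusion fraction stays within exact binomial bounds", {
  ann <- simulate_annotation(20, seed = 6)
  n_iso <- length(ann_isoforms(ann))
  rpi <- ceiling(1000 / n_iso)
  reads <- simulate_flnc(ann, rpi, p_fusion = 0.1, seed = 9)
  n <- length(reads)
  k <- sum(phenomena_of(reads) == "fusion")
  bounds <- stats::qbinom(c(0.005, 0.995), n, 0.1)
  expect_gte(k, bounds[1])
  expect_lte(k, bounds[2])
  for (r in reads[phenomena_of(reads) == "fusion"]) {
    expect_length(r$blocks, 2L)
    expect_length(strsplit(r$truth$source_transcript, "|", fixed = TRUE)[[1]], 2L)
  }
})

test_that("degraded reads are 5'-truncations with intact downstream junctions", {
  ann <- simulate_annotation(15, seed = 7)
  reads <- simulate_flnc(ann, 5, p_degraded = 1, seed = 10)
  iso <- ann_isoforms(ann)
  for (r in reads) {
    expect_identical(r$truth$phenomenon, "degraded_5prime")
    src <- iso[[r$truth$source_transcript]]
    b <- r$blocks[[1]]
    ji <- tx_introns(b); js <- tx_introns(src)
    n <- nrow(ji)
    if (src$strand == "+") {
      expect_gte(b$exons[1, 1], src$exons[1, 1])
      expect_equal(tx_span(b)[2], tx_span(src)[2])
      if (n > 0)
        expect_equal(unname(ji),
                     unname(js[seq(nrow(js) - n + 1L, nrow(js)), , drop = FALSE]))
    } else {
      expect_lte(tx_span(b)[2], tx_span(src)[2])
      expect_equal(tx_span(b)[1], tx_span(src)[1])
      if (n > 0) expect_equal(unname(ji), unname(js[seq_len(n), , drop = FALSE]))
    }
  }
})

test_that("novel-isoform reads alter at least one splice site", {
  ann <- simulate_annotation(10, seed = 8)
  reads <- simulate_flnc(ann, 4, p_novel_isoform = 1, seed = 11)
  novel <- reads[phenomena_of(reads) == "novel_isoform"]
  expect_gt(length(novel), 0L)
  for (r in novel) expect_true(call_novel_isoform(r$blocks[[1]], ann))
})

test_that("novel-gene reads fall outside annotated same-strand space", {
  ann <- simulate_annotation(10, seed = 9)
  reads <- simulate_flnc(ann, 3, p_novel_gene = 0.3, seed = 12)
  novel <- reads[phenomena_of(reads) == "novel_gene"]
  expect_gt(length(novel), 0L)
  tab <- ann_gene_table(ann)
  for (r in novel) {
    sp <- tx_span(r$blocks[[1]])
    same <- tab[tab$chrom == r$blocks[[1]]$chrom, , drop = FALSE]
    ov <- interval_overlap(sp[1], sp[2], same$start, same$end)
    expect_true(all(ov == 0))
  }
})

test_that("apa-shifted reads end at a planted alternative site", {
  ann <- simulate_annotation(10, seed = 10)
  reads <- simulate_flnc(ann, 4, p_apa_shift = 0.5, apa_sites_per_gene = 3,
                         seed = 13)
  shifted <- reads[phenomena_of(reads) == "apa_shifted"]
  expect_gt(length(shifted), 0L)
  iso <- ann_isoforms(ann)
  for (r in shifted) {
    b <- r$blocks[[1]]
    expect_equal(tx_end3(b), r$truth$apa_site)
    src <- iso[[r$truth$source_transcript]]
    expect_equal(unname(tx_introns(b)), unname(tx_introns(src)))
  }
})

test_that("simulate_counts plants effects and respects the null design", {
  ann <- simulate_annotation(10, seed = 4)
  null_sim <- simulate_counts(ann, frac_de = 0, seed = 5)
  expect_true(all(null_sim$truth_lfc == 0))
  sim <- simulate_counts(ann, frac_de = 0.3, lfc_magnitude = 2, seed = 5)
  planted <- sim$truth_lfc[sim$truth_lfc != 0]
  expect_true(all(abs(abs(planted) - 2) < 1e-12))
  sim2 <- simulate_counts(ann, frac_de = 0.3, lfc_magnitude = 2, seed = 5)
  expect_identical(sim$counts, sim2$counts)
  expect_error(simulate_counts(ann, dispersion = -1), "dispersion")
  expect_error(simulate_counts(ann, design = c(s1 = "A", s2 = "A")), "tissue")
})

test_that("dispersion 0 gives Poisson-like moments", {
  ann <- simulate_annotation(1, exons_per_isoform = c(2, 2),
                             isoforms_per_gene = c(1, 1), seed = 6)
  design <- stats::setNames(rep(c("A", "B"), each = 5000), paste0("s", 1:10000))
  sim <- simulate_counts(ann, design = design, baseline_mean = 50,
                         dispersion = 0, frac_de = 0, depth_range = c(1, 1),
                         seed = 7)
  x <- as.numeric(sim$counts[1, ])
  # Poisson: variance equals the mean; 10,000 draws bound the ratio tightly
  expect_lt(abs(stats::var(x) / mean(x) - 1), 0.1)
})
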