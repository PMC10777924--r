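tx4 <- function(id, strand, ...) tx_model(id, "chr1", strand, rbind(...))

test_that("canonical AS events are typed from exon chains", {
  # ES
  a <- tx4("a", "+", c(0, 100), c(200, 300), c(400, 500))
  b <- tx4("b", "+", c(0, 100), c(400, 500))
  ev <- detect_as_events(list(a, b))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$type, "ES")
  expect_equal(c(ev$region_start, ev$region_end), c(200, 300))
  # IR
  ev <- detect_as_events(list(tx4("a", "+", c(0, 100), c(200, 300)),
                              tx4("b", "+", c(0, 300))))
  expect_equal(ev$type, "IR")
  expect_equal(c(ev$region_start, ev$region_end), c(100, 200))
  # AD on '+': shared acceptor, differing donors
  ev <- detect_as_events(list(tx4("a", "+", c(0, 100), c(200, 300)),
                              tx4("b", "+", c(0, 150), c(200, 300))))
  expect_equal(ev$type, "AD")
  expect_equal(c(ev$region_start, ev$region_end), c(100, 150))
  # the same coordinates on '-' are an acceptor difference
  ev <- detect_as_events(list(tx4("a", "-", c(0, 100), c(200, 300)),
                              tx4("b", "-", c(0, 150), c(200, 300))))
  expect_equal(ev$type, "AA")
  # AA on '+': shared donor, differing acceptors
  ev <- detect_as_events(list(tx4("a", "+", c(0, 100), c(200, 300)),
                              tx4("b", "+", c(0, 100), c(250, 300))))
  expect_equal(ev$type, "AA")
  # MEE: disjoint middle exons with shared outer flanks
  ev <- detect_as_events(list(tx4("a", "+", c(0, 100), c(200, 300), c(600, 700)),
                              tx4("b", "+", c(0, 100), c(400, 500), c(600, 700))))
  expect_equal(ev$type, "MEE")
  # overlapping alternative middle exons are complex
  ev <- detect_as_events(list(tx4("a", "+", c(0, 100), c(200, 320), c(600, 700)),
                              tx4("b", "+", c(0, 100), c(280, 500), c(600, 700))))
  expect_equal(ev$type, "complex")
  # single isoform: no events
  expect_equal(nrow(detect_as_events(list(a))), 0L)
})

test_that("terminal differences are not AS events", {
  # 5'-degraded copy: missing first exon entirely outside the common span
  full <- tx4("f", "+", c(0, 100), c(200, 300), c(400, 500))
  deg <- tx4("d", "+", c(250, 300), c(400, 500))
  expect_equal(nrow(detect_as_events(list(full, deg))), 0L)
  # APA-extended 3' exon
  apa <- tx4("p", "+", c(0, 100), c(200, 300), c(400, 900))
  expect_equal(nrow(detect_as_events(list(full, apa))), 0L)
})

test_that("AS detection agrees with the brute-force oracle", {
  # hand-built locus mixing all canonical types across 5 isoforms
  txs <- list(
    tx4("t1", "+", c(0, 100), c(200, 300), c(400, 500), c(700, 800)),
    tx4("t2", "+", c(0, 100), c(400, 500), c(700, 800)),
    tx4("t3", "+", c(0, 100), c(200, 300), c(400, 800)),
    tx4("t4", "+", c(0, 150), c(200, 300), c(400, 500), c(700, 800)),
    tx4("t5", "+", c(0, 100), c(200, 300), c(400, 500), c(550, 620), c(700, 800)))
  main <- event_set(detect_as_events(txs))
  oracle <- event_set(brute_as_oracle(txs))
  expect_equal(main, oracle, ignore_attr = TRUE)
  # simulated loci (<=5 isoforms, <=8 exons by construction)
  for (s in 1:5) {
    ann <- simulate_annotation(10, exons_per_isoform = c(2, 8),
                               isoforms_per_gene = c(2, 5), seed = 100 + s)
    for (g in ann$genes) {
      if (length(g$isoforms) < 2) next
      main <- event_set(detect_as_events(g$isoforms))
      oracle <- event_set(brute_as_oracle(g$isoforms))
      expect_equal(main, oracle, ignore_attr = TRUE)
    }
  }
})

test_that("event detection is invariant to isoform input order", {
  ann <- simulate_annotation(6, isoforms_per_gene = c(3, 5), seed = 55)
  for (g in ann$genes) {
    if (length(g$isoforms) < 2) next
    e1 <- event_set(detect_as_events(g$isoforms), types = unique(c("complex",
      "ES", "AA", "AD", "IR", "MEE")))
    e2 <- event_set(detect_as_events(rev(g$isoforms)), types = unique(c("complex",
      "ES", "AA", "AD", "IR", "MEE")))
    expect_equal(e1, e2, ignore_attr = TRUE)
  }
})

test_that("detect_apa clusters 3' ends single-linkage with min support", {
  ends <- c(rep(1000, 3), rep(1500, 2), 2000)
  out <- detect_apa(ends, cluster_window = 30, min_support = 2)
  expect_equal(out$site, c(1000, 1500))
  expect_equal(out$support, c(3L, 2L))
  # chained ends within the window merge into one cluster
  out2 <- detect_apa(c(100, 120, 140, 160), cluster_window = 24)
  expect_equal(nrow(out2), 1L)
  expect_equal(out2$support, 4L)
  # all reads at one coordinate: one site, no APA
  one <- detect_apa(rep(500, 5))
  expect_equal(nrow(one), 1L)
  expect_equal(detect_apa(numeric(0))$site, numeric(0))
  # every reported site satisfies the support floor
  set.seed(1)
  rnd <- detect_apa(sample(1:2000, 300, replace = TRUE), 24, 2)
  expect_true(all(rnd$support >= 2))
})

test_that("planted APA sites are recovered per gene", {
  ann <- simulate_annotation(10, seed = 61)
  reads <- simulate_flnc(ann, 12, p_apa_shift = 0.5, apa_sites_per_gene = 3,
                         seed = 61)
  apa <- detect_apa_all(reads, ann, cluster_window = 24, min_support = 2)
  planted <- plant_apa_sites(ann, 3L)
  # genes with enough shifted reads show APA; all reported sites are planted
  for (i in seq_len(nrow(apa$sites))) {
    gid <- apa$sites$gene_id[i]
    site <- apa$sites$site[i]
    g <- ann$genes[[match(gid, vapply(ann$genes, `[[`, "", "id"))]]
    ends <- vapply(g$isoforms, function(tx) tx_end3(tx), 0)
    expect_true(min(abs(c(ends, planted[[gid]]) - site)) <= 24)
  }
  expect_gt(sum(apa$genes$apa), 0)
})

test_that("fusion calls identify partners and chromosome kind", {
  g <- function(id, chrom, lo) list(id = id, chrom = chrom, strand = "+",
    isoforms = list(tx_model(paste0(id, ".1"), chrom, "+",
                             rbind(c(lo, lo + 400), c(lo + 1000, lo + 1400)))))
  ann <- ref_annotation(list(g("GA", "chr1", 0), g("GB", "chr2", 0),
                             g("GC", "chr1", 100000)))
  mk_read <- function(id, b1, b2) flnc_read(id, list(b1, b2))
  b <- function(chrom, lo) tx_model("b", chrom, "+", rbind(c(lo, lo + 300)))
  inter <- mk_read("r1", b("chr1", 50), b("chr2", 1050))
  intra <- mk_read("r2", b("chr1", 50), b("chr1", 101050))
  same <- mk_read("r3", b("chr1", 50), b("chr1", 1050))
  close_ <- mk_read("r4", b("chr1", 50), b("chr1", 2000))
  calls <- detect_fusion(list(inter, intra, same, close_), ann)
  expect_equal(nrow(calls), 2L)
  inter_call <- calls[calls$kind == "interchromosomal", ]
  expect_equal(inter_call$partner_5prime, "GA")
  expect_equal(inter_call$partner_3prime, "GB")
  intra_call <- calls[calls$kind == "intrachromosomal", ]
  expect_equal(intra_call$partner_3prime, "GC")
  # same-gene chimeras never call; read-through guard can be disabled
  expect_equal(nrow(detect_fusion(list(same), ann)), 0L)
  # r4 joins GA and GC? no -- second block lands between genes, skipped
  calls0 <- detect_fusion(list(close_), ann, min_gap = 0)
  expect_equal(nrow(calls0), 0L)
})

test_that("planted fusions are recovered with no false calls", {
  ann <- simulate_annotation(12, seed = 62)
  reads <- simulate_flnc(ann, 6, p_fusion = 0.15, seed = 62)
  truth_fusion <- vapply(reads, function(r)
    r$truth$phenomenon == "fusion", FALSE)
  calls <- detect_fusion(reads, ann, min_gap = 0)
  called_reads <- unlist(strsplit(calls$read_ids, ","))
  expect_setequal(called_reads, vapply(reads[truth_fusion], `[[`, "", "id"))
  # partner pairs match the planted sources
  t2g <- ann_tx2gene(ann)
  for (r in reads[truth_fusion]) {
    src <- strsplit(r$truth$source_transcript, "|", fixed = TRUE)[[1]]
    row <- calls[grepl(r$id, calls$read_ids, fixed = TRUE), ]
    expect_equal(row$partner_5prime[1], unname(t2g[src[1]]))
    expect_equal(row$partner_3prime[1], unname(t2g[src[2]]))
  }
})
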