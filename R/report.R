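## Pipeline orchestration and the summary-report layer.  Every percentage
## printed anywhere in the package goes through ratio(): 2 decimals,
## round-half-even, matching standard report precision.

#' Percentage at two decimals, round-half-even
#' @param numerator,denominator Counts; `denominator > 0`.
#' @return `round(100 * numerator / denominator, 2)`.
#' @export
ratio <- function(numerator, denominator) {
  if (denominator <= 0) stop("denominator must be > 0")
  round(100 * numerator / denominator, 2)
}

#' Default pipeline configuration
#'
#' All thresholds of the pipeline in one declarative list: same-locus
#' overlap fraction, junction wobble (0 = exact), PID merge threshold, APA
#' clustering window and support, fusion guards, DE thresholds, simulation
#' parameters and seed.
#'
#' @param ... Overrides for any field.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    n_genes = 30L,
    exons_per_isoform = c(2L, 6L),
    isoforms_per_gene = c(1L, 3L),
    reads_per_isoform = 6L,
    p_degraded = 0.15,
    p_novel_isoform = 0.05,
    p_novel_gene = 0.03,
    p_fusion = 0.02,
    p_apa_shift = 0.1,
    apa_sites_per_gene = 2L,
    low_pid_threshold = 90,
    min_overlap = 0.2,
    apa_window = 24,
    apa_min_support = 2L,
    fusion_min_gap = 10000,
    fusion_min_reads = 1L,
    de_lfc_threshold = 1,
    de_alpha = 0.05,
    baseline_mean = 100,
    dispersion = 0.05,
    frac_de = 0.1,
    lfc_magnitude = 2,
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0L) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Run the pipeline end to end on simulated data
#'
#' Simulates an annotation, FLNC reads and counts from `config`, then runs
#' the merge, collapse, classification, event and quantification stages and
#' assembles the summary report.  Deterministic for a fixed seed.  When
#' `out_dir` is given, every stage writes its table there and the report is
#' serialised as JSON and TSV.
#'
#' @param config A [pipeline_config].
#' @param out_dir Optional output directory.
#' @return List of class `pipeline_result` with elements `ann`, `reads`,
#'   `merge`, `mapping`, `collapsed`, `classified`, `as_events`, `apa`,
#'   `fusions`, `sim_counts`, `de`, and `report` (the summary report).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  cfg <- config
  ann <- simulate_annotation(cfg$n_genes, cfg$exons_per_isoform,
                             cfg$isoforms_per_gene, seed = cfg$seed)
  reads <- simulate_flnc(ann, cfg$reads_per_isoform,
                         p_degraded = cfg$p_degraded,
                         p_novel_isoform = cfg$p_novel_isoform,
                         p_novel_gene = cfg$p_novel_gene,
                         p_fusion = cfg$p_fusion,
                         p_apa_shift = cfg$p_apa_shift,
                         apa_sites_per_gene = cfg$apa_sites_per_gene,
                         seed = cfg$seed)
  mrg <- merge_libraries(reads)
  mapping <- classify_mapping(reads, cfg$low_pid_threshold)
  # collapse uses the non-chimeric blocks of merged reads
  simple <- Filter(function(r) length(r$blocks) == 1L, reads)
  blocks <- lapply(simple, function(r) r$blocks[[1L]])
  evidence <- ann_junctions(ann)
  collapsed <- collapse_transcripts(blocks, annotated_junctions = evidence,
                                    min_overlap = cfg$min_overlap)
  classified <- classify_isoforms(collapsed, ann)
  as_events <- detect_as_events_all(collapsed)
  apa <- detect_apa_all(simple, ann, cfg$apa_window, cfg$apa_min_support)
  fusions <- detect_fusion(reads, ann, min_gap = cfg$fusion_min_gap,
                           min_reads = cfg$fusion_min_reads)
  sim_counts <- simulate_counts(ann, baseline_mean = cfg$baseline_mean,
                                dispersion = cfg$dispersion,
                                frac_de = cfg$frac_de,
                                lfc_magnitude = cfg$lfc_magnitude,
                                seed = cfg$seed)
  tx2gene <- ann_tx2gene(ann)
  de_tx <- nb_test_all_pairs(sim_counts$counts, sim_counts$design,
                             lfc_threshold = cfg$de_lfc_threshold,
                             alpha_threshold = cfg$de_alpha)
  gc_mat <- gene_counts(sim_counts$counts, tx2gene)
  de_gene <- nb_test_all_pairs(gc_mat, sim_counts$design,
                               lfc_threshold = cfg$de_lfc_threshold,
                               alpha_threshold = cfg$de_alpha)
  # read-level full-length ratio over multi-exon non-chimeric reads
  multi <- Filter(function(b) nrow(b$exons) > 1L, blocks)
  fl_reads <- vapply(multi, function(b) isTRUE(full_length_status(b, ann)), FALSE)
  report <- build_summary_report(cfg, mrg$report, mapping, collapsed,
                                 classified, as_events, apa, fusions,
                                 de_gene, de_tx,
                                 n_multi_reads = length(multi),
                                 n_fl_reads = sum(fl_reads))
  res <- structure(list(ann = ann, reads = reads, merge = mrg,
                        mapping = mapping, collapsed = collapsed,
                        classified = classified, as_events = as_events,
                        apa = apa, fusions = fusions,
                        sim_counts = sim_counts,
                        de = list(gene = de_gene, transcript = de_tx),
                        report = report, config = cfg),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

summary_pct <- function(n, d) if (d > 0) ratio(n, d) else NA_real_

# assemble the summary report: every percentage is recomputed from its own
# count pair via ratio()
build_summary_report <- function(cfg, pid_report, mapping, collapsed,
                                 classified, as_events, apa, fusions,
                                 de_gene, de_tx, n_multi_reads, n_fl_reads) {
  n_iso <- nrow(classified)
  cat_n <- vapply(LETTERS[1:7], function(cc)
    sum(classified$category == cc), 0L)
  novelty_n <- vapply(c("known", "novel_isoform", "novel_gene"), function(v)
    sum(classified$novelty == v), 0L)
  multi <- classified[classified$n_exons > 1L, , drop = FALSE]
  n_loci <- length(collapsed$loci)
  lb <- length_bin_report(classified)
  list(
    pid_categories = pid_report$counts,
    pct_improved = pct_improved(pid_report),
    mapping_counts = mapping$counts,
    mapping_percent = mapping$percent,
    n_loci = n_loci,
    n_isoforms = n_iso,
    novelty_counts = novelty_n,
    pct_novel_isoforms = summary_pct(novelty_n[["novel_isoform"]], n_iso),
    n_multi_exon_isoforms = nrow(multi),
    n_full_length_isoforms = sum(multi$full_length, na.rm = TRUE),
    pct_full_length_isoforms = summary_pct(sum(multi$full_length, na.rm = TRUE),
                                           max(nrow(multi), 1L)),
    n_multi_exon_reads = n_multi_reads,
    n_full_length_reads = n_fl_reads,
    pct_full_length_reads = summary_pct(n_fl_reads, max(n_multi_reads, 1L)),
    category_counts = cat_n,
    category_percent = vapply(cat_n, summary_pct, 0, d = max(n_iso, 1L)),
    length_bins = lb,
    as_type_summary = as_type_summary(as_events),
    n_as_events = nrow(as_events),
    n_apa_genes = sum(apa$genes$apa),
    n_apa_genes_gt5 = sum(apa$genes$n_sites > 5L),
    fusion_counts = c(
      intrachromosomal = sum(fusions$kind == "intrachromosomal"),
      interchromosomal = sum(fusions$kind == "interchromosomal")),
    deg_counts = vapply(de_gene, function(d) sum(d$is_de), 0L),
    dei_counts = vapply(de_tx, function(d) sum(d$is_de), 0L))
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_annotation_gtf(res$ann, p("annotation.gtf"))
  write_flnc_bed(res$reads, p("flnc.bed"))
  write_pid_tsv(res$reads, p("pid.tsv"))
  write_truth_tsv(res$reads, p("truth.tsv"))
  write_pid_comparison_tsv(res$merge$report, p("pid_comparison.tsv"))
  write_mapping_report_tsv(res$mapping, p("mapping_report.tsv"))
  write_classification_tsv(res$classified, p("isoform_classification.tsv"))
  data.table::fwrite(data.table::as.data.table(res$report$length_bins),
                     p("length_bins.tsv"), sep = "\t", quote = FALSE)
  data.table::fwrite(data.table::as.data.table(res$as_events),
                     p("as_events.tsv"), sep = "\t", quote = FALSE)
  data.table::fwrite(data.table::as.data.table(res$apa$sites),
                     p("apa_sites.tsv"), sep = "\t", quote = FALSE)
  data.table::fwrite(data.table::as.data.table(res$fusions),
                     p("fusions.tsv"), sep = "\t", quote = FALSE)
  write_counts_tsv(res$sim_counts, p("counts.tsv"), p("design.tsv"))
  fpkm_mat <- fpkm(res$sim_counts$counts, res$sim_counts$lengths)
  fp <- data.table::as.data.table(fpkm_mat, keep.rownames = "transcript_id")
  data.table::fwrite(fp, p("fpkm.tsv"), sep = "\t", quote = FALSE)
  for (nm in names(res$de$gene))
    data.table::fwrite(data.table::as.data.table(res$de$gene[[nm]]),
                       p(sprintf("de_gene_%s.tsv", nm)), sep = "\t", quote = FALSE)
  for (nm in names(res$de$transcript))
    data.table::fwrite(data.table::as.data.table(res$de$transcript[[nm]]),
                       p(sprintf("de_transcript_%s.tsv", nm)), sep = "\t",
                       quote = FALSE)
  jsonlite::write_json(report_as_json(res$report), p("report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(unclass(res$config), p("config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

# flatten report into JSON-friendly structures (data.frames -> lists)
report_as_json <- function(report) {
  lapply(report, function(x) {
    if (is.data.frame(x)) x
    else if (!is.null(names(x))) as.list(x)
    else x
  })
}

#' @export
print.pipeline_result <- function(x, ...) {
  r <- x$report
  cat("Pipeline summary\n")
  cat(sprintf("  reads merged: %d (PID improved: %.2f%%)\n",
              sum(r$pid_categories), r$pct_improved))
  cat(sprintf("  loci: %d  isoforms: %d (novel isoforms: %d, novel genes: %d)\n",
              r$n_loci, r$n_isoforms,
              r$novelty_counts[["novel_isoform"]],
              r$novelty_counts[["novel_gene"]]))
  cat(sprintf("  full-length: %d/%d multi-exon isoforms (%.2f%%)\n",
              r$n_full_length_isoforms, r$n_multi_exon_isoforms,
              r$pct_full_length_isoforms))
  cat(sprintf("  AS events: %d  APA genes: %d  fusions: %d\n",
              r$n_as_events, r$n_apa_genes, sum(r$fusion_counts)))
  cat(sprintf("  DEGs per pair: %s\n",
              paste(sprintf("%s=%d", names(r$deg_counts), r$deg_counts),
                    collapse = ", ")))
  invisible(x)
}
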