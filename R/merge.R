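## Hybrid-correction merge: per-read comparison of pre- vs post-correction
## percent identity, selection of the better version into a merged library,
## and mapping-quality classification of the merged library.

#' Percent identity of an alignment
#'
#' @param matches Number of matching columns.
#' @param aligned_columns Number of aligned columns (> 0).
#' @return `100 * matches / aligned_columns`.
#' @export
compute_pid <- function(matches, aligned_columns) {
  if (any(aligned_columns <= 0)) stop("aligned_columns must be > 0")
  if (any(matches > aligned_columns)) stop("matches cannot exceed aligned_columns")
  if (any(matches < 0)) stop("matches must be >= 0")
  100 * matches / aligned_columns
}

as_pid_table <- function(reads) {
  if (is.data.frame(reads)) {
    stopifnot(all(c("read_id", "pid_pre", "pid_post") %in% names(reads)))
    return(reads)
  }
  data.frame(
    read_id = vapply(reads, `[[`, "", "id"),
    pid_pre = vapply(reads, `[[`, 0, "pid_pre"),
    pid_post = vapply(reads, `[[`, 0, "pid_post"),
    stringsAsFactors = FALSE)
}

pid_category_levels <- c("only_pre_mapped", "only_post_mapped",
                         "pre_gt_post", "pre_eq_post", "pre_lt_post")

#' Merge pre- and post-correction libraries by percent identity
#'
#' Per read, the version with the higher PID is retained in the merged
#' library; ties keep the post-correction version (short-read-corrected
#' bases are more accurate).  Reads mapped in only one library are merged
#' from that library.  Reads mapped in neither are excluded with a warning
#' and counted in `n_excluded`.
#'
#' @param reads List of [flnc_read], or a data.frame with columns
#'   `read_id`, `pid_pre`, `pid_post` (`NA` = unmapped in that library).
#' @return List with `merged` (data.frame `read_id`, `pid`, `source`,
#'   `category`) and `report` (a `pid_comparison` object mirroring the
#'   five-category comparison table: counts and mean PIDs per category).
#' @export
merge_libraries <- function(reads) {
  tab <- as_pid_table(reads)
  neither <- is.na(tab$pid_pre) & is.na(tab$pid_post)
  n_excluded <- sum(neither)
  if (n_excluded > 0L) {
    warning(sprintf("%d read(s) mapped in neither library; excluded from merge",
                    n_excluded))
    tab <- tab[!neither, , drop = FALSE]
  }
  category <- ifelse(is.na(tab$pid_post), "only_pre_mapped",
              ifelse(is.na(tab$pid_pre), "only_post_mapped",
              ifelse(tab$pid_pre > tab$pid_post, "pre_gt_post",
              ifelse(tab$pid_pre == tab$pid_post, "pre_eq_post",
                     "pre_lt_post"))))
  source <- ifelse(category %in% c("only_pre_mapped", "pre_gt_post"),
                   "pre", "post")
  pid <- pmax(tab$pid_pre, tab$pid_post, na.rm = TRUE)
  merged <- data.frame(read_id = tab$read_id, pid = pid, source = source,
                       category = factor(category, levels = pid_category_levels),
                       stringsAsFactors = FALSE)
  counts <- table(merged$category)
  mean_by <- function(x, cat) {
    sel <- merged$category == cat & !is.na(x)
    if (!any(sel)) NA_real_ else mean(x[sel])
  }
  report <- structure(list(
    counts = stats::setNames(as.integer(counts), names(counts)),
    mean_pre = vapply(pid_category_levels, function(cc) mean_by(tab$pid_pre, cc), 0),
    mean_post = vapply(pid_category_levels, function(cc) mean_by(tab$pid_post, cc), 0),
    total = nrow(merged),
    mean_pre_total = if (all(is.na(tab$pid_pre))) NA_real_
                     else mean(tab$pid_pre, na.rm = TRUE),
    mean_post_total = if (all(is.na(tab$pid_post))) NA_real_
                      else mean(tab$pid_post, na.rm = TRUE),
    n_excluded = n_excluded), class = "pid_comparison")
  list(merged = merged, report = report)
}

#' Build a PID comparison report from category counts
#'
#' Report layer for the five-category comparison table when only the counts
#' are known (e.g. published tables): mean PIDs are `NA`, percentages are
#' recomputed from the counts.
#'
#' @param counts Named numeric vector with entries `only_pre_mapped`,
#'   `only_post_mapped`, `pre_gt_post`, `pre_eq_post`, `pre_lt_post`.
#' @return A `pid_comparison` object; `total` is the sum of counts.
#' @export
pid_comparison <- function(counts) {
  stopifnot(setequal(names(counts), pid_category_levels))
  counts <- counts[pid_category_levels]
  structure(list(counts = stats::setNames(as.integer(counts), names(counts)),
                 mean_pre = stats::setNames(rep(NA_real_, 5L), names(counts)),
                 mean_post = stats::setNames(rep(NA_real_, 5L), names(counts)),
                 total = sum(counts),
                 mean_pre_total = NA_real_, mean_post_total = NA_real_,
                 n_excluded = 0L),
            class = "pid_comparison")
}

#' @export
print.pid_comparison <- function(x, ...) {
  cat("PID comparison pre- vs post-correction\n")
  for (cc in names(x$counts))
    cat(sprintf("  %-18s %8d  pre %6s  post %6s\n", cc, x$counts[[cc]],
                ifelse(is.na(x$mean_pre[[cc]]), "-", sprintf("%.2f", x$mean_pre[[cc]])),
                ifelse(is.na(x$mean_post[[cc]]), "-", sprintf("%.2f", x$mean_post[[cc]]))))
  cat(sprintf("  total %d (improved: %.2f%%)\n", x$total, pct_improved(x)))
  invisible(x)
}

#' Fraction of reads whose PID improved with correction
#' @param report A `pid_comparison` object.
#' @return Percentage (2 decimals, round-half-even) of reads in the
#'   `pre_lt_post` category.
#' @export
pct_improved <- function(report) {
  ratio(report$counts[["pre_lt_post"]], report$total)
}

mapping_class_levels <- c("unmapped", "multiple_best_mapped", "low_pid",
                          "high_quality")

#' Build a mapping-quality report from class counts
#'
#' The report layer for the four-way mapping classification: counts for
#' unmapped, multiply-best-mapped and low-PID reads plus an explicit
#' denominator (total poly(A) FLNC reads); the high-quality count is the
#' remainder.  Percentages are count/denominator at 2 decimals.
#'
#' @param unmapped,multiple_best_mapped,low_pid Class counts.
#' @param denominator Total reads the percentages refer to.
#' @return Object of class `mapping_report` with `counts`, `percent`,
#'   `denominator`.
#' @export
mapping_report <- function(unmapped, multiple_best_mapped, low_pid,
                           denominator) {
  if (denominator <= 0) stop("denominator must be > 0")
  hq <- denominator - unmapped - multiple_best_mapped - low_pid
  if (hq < 0) stop("class counts exceed denominator")
  counts <- c(unmapped = unmapped,
              multiple_best_mapped = multiple_best_mapped,
              low_pid = low_pid, high_quality = hq)
  structure(list(counts = counts,
                 percent = vapply(counts, ratio, 0, denominator = denominator),
                 denominator = denominator),
            class = "mapping_report")
}

#' @export
print.mapping_report <- function(x, ...) {
  cat(sprintf("Mapping classification (n = %d)\n", x$denominator))
  for (cc in names(x$counts))
    cat(sprintf("  %-22s %8d (%.2f%%)\n", cc, x$counts[[cc]], x$percent[[cc]]))
  invisible(x)
}

#' Classify merged reads by mapping quality
#'
#' Each read falls in exactly one class: `unmapped` (no alignment in either
#' library), `multiple_best_mapped` (flagged multimapper), `low_pid`
#' (uniquely mapped with merged PID below the threshold) or `high_quality`
#' (the remainder).
#'
#' @param reads List of [flnc_read] or a data.frame with columns `read_id`,
#'   `pid` (merged PID, `NA` = unmapped) and `multimap` (logical).
#' @param low_pid_threshold Percent threshold in (0, 100); default 90.
#' @return A `mapping_report` (denominator = number of input reads), plus a
#'   `class` attribute column accessible via `attr(, "classes")`.
#' @export
classify_mapping <- function(reads, low_pid_threshold = 90) {
  if (low_pid_threshold <= 0 || low_pid_threshold >= 100)
    stop("low_pid_threshold must lie in (0, 100)")
  if (!is.data.frame(reads)) {
    tab <- as_pid_table(reads)
    reads <- data.frame(
      read_id = tab$read_id,
      pid = pmax(tab$pid_pre, tab$pid_post, na.rm = TRUE),
      multimap = vapply(reads, `[[`, FALSE, "multimap"),
      stringsAsFactors = FALSE)
    reads$pid[is.na(tab$pid_pre) & is.na(tab$pid_post)] <- NA_real_
  }
  cls <- ifelse(is.na(reads$pid), "unmapped",
         ifelse(reads$multimap, "multiple_best_mapped",
         ifelse(reads$pid < low_pid_threshold, "low_pid", "high_quality")))
  rep <- mapping_report(sum(cls == "unmapped"),
                        sum(cls == "multiple_best_mapped"),
                        sum(cls == "low_pid"),
                        denominator = nrow(reads))
  attr(rep, "classes") <- stats::setNames(cls, reads$read_id)
  rep
}

#' Write the PID comparison table
#' @param report A `pid_comparison`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_pid_comparison_tsv <- function(report, path) {
  dt <- data.table::data.table(
    category = names(report$counts),
    n_reads = unname(report$counts),
    mean_pid_pre = round(unname(report$mean_pre), 2),
    mean_pid_post = round(unname(report$mean_post), 2))
  data.table::fwrite(dt, path, sep = "\t", na = "-", quote = FALSE)
  invisible(path)
}

#' Write the mapping-quality report
#' @param report A `mapping_report`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_mapping_report_tsv <- function(report, path) {
  dt <- data.table::data.table(
    class = names(report$counts),
    n_reads = unname(report$counts),
    percent = unname(report$percent))
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}
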