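# The cleaning cascade: proportional thresholds, blank-maximum subtraction,
# taxon aggregation, presence-absence conversion, empty-sample removal.
# Every stage returns the filtered table plus an auditable report; all
# thresholds are computed from pre-stage totals so a stage never feeds back
# into itself.

new_filter_report <- function(stage, before, after, cells_zeroed = NULL,
                              samples_dropped = character(),
                              zotus_dropped = character()) {
  if (is.null(cells_zeroed)) cells_zeroed <- sum(before > 0 & after == 0)
  structure(list(stage = stage,
                 reads_removed = sum(before) - sum(after),
                 cells_zeroed = cells_zeroed,
                 samples_dropped = samples_dropped,
                 zotus_dropped = zotus_dropped),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %-12s reads removed: %s; cells zeroed: %d",
              x$stage, format(x$reads_removed, big.mark = ","), x$cells_zeroed))
  if (length(x$samples_dropped) > 0)
    cat(sprintf("; samples dropped: %d", length(x$samples_dropped)))
  if (length(x$zotus_dropped) > 0)
    cat(sprintf("; rows dropped: %d", length(x$zotus_dropped)))
  cat("\n")
  invisible(x)
}

#' Per-sample proportional read threshold
#'
#' Zeroes every cell whose count is strictly below `pct` of its sample's
#' (column's) pre-stage read total, removing low-frequency laboratory
#' contaminants and sequencing errors. Reads exactly at the threshold
#' survive.
#'
#' @param table a [zotu_table()].
#' @param pct fraction of the sample total (default 0.003, i.e. 0.3%).
#' @return list with elements `table` (filtered) and `report`.
#' @export
apply_per_sample_threshold <- function(table, pct = 0.003) {
  stopifnot(inherits(table, "zotu_table"), pct >= 0, pct <= 1)
  before <- table$counts
  thresh <- pct * colSums(before)
  after <- before
  after[sweep(before, 2, thresh, "<")] <- 0
  table$counts <- after
  list(table = table, report = new_filter_report("per_sample", before, after))
}

#' Blank/negative-control maximum filter
#'
#' For each ZOTU, finds its highest read count across blank and negative
#' control samples and zeroes diet-sample reads below that maximum
#' (`strict_below`; `at_or_below` also zeroes ties). Control columns are
#' left untouched here and are excluded when the table is converted to a
#' presence-absence matrix. Positive controls never contribute to the
#' blank maximum.
#'
#' @param table a [zotu_table()].
#' @param blank_roles roles treated as blanks/negatives.
#' @param rule comparison rule for the blank maximum.
#' @return list with elements `table` and `report`.
#' @export
apply_blank_max_filter <- function(table,
                                   blank_roles = c("pcr_blank", "extraction_blank"),
                                   rule = c("strict_below", "at_or_below")) {
  stopifnot(inherits(table, "zotu_table"))
  rule <- match.arg(rule)
  .check_enum(blank_roles, .dietmb_roles, "blank role")
  before <- table$counts
  is_blank <- table$samples$role %in% blank_roles
  if (!any(is_blank)) {
    warning("no samples with a blank role; blank-max filter is a no-op",
            call. = FALSE)
    return(list(table = table,
                report = new_filter_report("blank_max", before, before)))
  }
  bmax <- apply(before[, is_blank, drop = FALSE], 1, max)
  is_diet <- table$samples$role == "diet"
  after <- before
  diet <- before[, is_diet, drop = FALSE]
  mask <- if (rule == "strict_below") diet < bmax else diet <= bmax
  diet[mask] <- 0
  after[, is_diet] <- diet
  table$counts <- after
  list(table = table, report = new_filter_report("blank_max", before, after))
}

#' Per-ZOTU proportional read threshold
#'
#' Zeroes every cell strictly below `pct` of its ZOTU's (row's) pre-stage
#' read total across all retained samples — a guard against tag-jumping,
#' where a small fraction of an abundant ZOTU's reads bleed into other
#' samples. A row's single non-zero cell always survives.
#'
#' @param table a [zotu_table()].
#' @param pct fraction of the ZOTU total (default 0.0074, i.e. 0.74%).
#' @return list with elements `table` and `report`.
#' @export
apply_per_zotu_threshold <- function(table, pct = 0.0074) {
  stopifnot(inherits(table, "zotu_table"), pct >= 0, pct <= 1)
  before <- table$counts
  thresh <- pct * rowSums(before)
  after <- before
  after[sweep(before, 1, thresh, "<")] <- 0
  table$counts <- after
  list(table = table, report = new_filter_report("per_zotu", before, after))
}

#' Aggregate ZOTU rows into taxon rows
#'
#' Rows assigned to the same taxon are summed elementwise. ZOTUs absent
#' from the annotation are dropped and listed in the report; the grand
#' total over mapped ZOTUs is conserved. Taxon order follows first
#' appearance among the ZOTU rows.
#'
#' @param table a [zotu_table()].
#' @param taxa annotation data frame with columns `zotu_id` and `taxon`
#'   (see [read_taxon_table()]).
#' @return list with elements `table` (taxon-level `zotu_table`) and
#'   `report`.
#' @export
aggregate_zotus_to_taxa <- function(table, taxa) {
  stopifnot(inherits(table, "zotu_table"), is.data.frame(taxa))
  .stop_if(!all(c("zotu_id", "taxon") %in% colnames(taxa)),
           "`taxa` needs columns zotu_id and taxon")
  before <- table$counts
  idx <- match(rownames(before), taxa$zotu_id)
  unmapped <- rownames(before)[is.na(idx)]
  keep <- !is.na(idx)
  mapped <- before[keep, , drop = FALSE]
  grp <- taxa$taxon[idx[keep]]
  agg <- rowsum(mapped, group = grp, reorder = FALSE)
  agg <- agg[match(unique(grp), rownames(agg)), , drop = FALSE]
  table$counts <- agg
  list(table = table,
       report = new_filter_report("aggregate", before, agg, cells_zeroed = 0L,
                                  zotus_dropped = unmapped))
}

#' Convert a (taxon-level) count table to a presence-absence matrix
#'
#' A taxon is present in a sample iff its read count is positive. Only
#' diet-role samples are kept; blanks and positive controls are excluded
#' from all downstream statistics.
#'
#' @param table a [zotu_table()], usually taxon-level after aggregation.
#' @return logical matrix, taxa x diet samples.
#' @export
to_presence_absence <- function(table) {
  stopifnot(inherits(table, "zotu_table"))
  is_diet <- table$samples$role == "diet"
  table$counts[, is_diet, drop = FALSE] > 0
}

#' Remove samples and taxa with zero detections
#'
#' @param matrix logical presence-absence matrix (taxa x samples).
#' @return list with elements `matrix` and `report` (dropped sample and
#'   taxon ids).
#' @export
drop_empty_samples <- function(matrix) {
  stopifnot(is.matrix(matrix), is.logical(matrix))
  empty_s <- colSums(matrix) == 0
  empty_t <- rowSums(matrix) == 0
  out <- matrix[!empty_t, !empty_s, drop = FALSE]
  # dropped rows/columns were all-absent, so detections are conserved
  list(matrix = out,
       report = new_filter_report("drop_empty", matrix, out, cells_zeroed = 0L,
                                  samples_dropped = colnames(matrix)[empty_s],
                                  zotus_dropped = rownames(matrix)[empty_t]))
}

#' Run the full cleaning cascade
#'
#' Applies, in the configured order, the per-sample proportional threshold,
#' the blank-maximum filter and the per-ZOTU proportional threshold, then
#' aggregates ZOTUs to taxa, converts to presence-absence over diet samples
#' and drops empty samples/taxa. The stage order matters (thresholds see
#' each other's output) and is recorded in the report chain.
#'
#' @param table raw [zotu_table()].
#' @param taxa ZOTU annotation (see [read_taxon_table()]).
#' @param config a [filter_config()].
#' @param verbose log row/column counts per stage to stderr.
#' @return list with `matrix` (presence-absence, taxa x diet samples),
#'   `reports` (one per stage, in execution order), and `taxa` (annotation
#'   rows for the retained taxa, one per taxon).
#' @export
run_filter_cascade <- function(table, taxa, config = filter_config(),
                               verbose = FALSE) {
  stopifnot(inherits(table, "zotu_table"), inherits(config, "filter_config"))
  reports <- list()
  log_dims <- function(stage, tab) {
    if (verbose)
      message(sprintf("[dietmb] after %-10s: %d rows x %d cols, %s reads",
                      stage, nrow(tab$counts), ncol(tab$counts),
                      format(sum(tab$counts), big.mark = ",")))
  }
  for (stage in config$stage_order) {
    step <- switch(stage,
      per_sample = apply_per_sample_threshold(table, config$per_sample_pct),
      blank_max  = apply_blank_max_filter(table, rule = config$blank_rule),
      per_zotu   = apply_per_zotu_threshold(table, config$per_zotu_pct))
    table <- step$table
    reports[[stage]] <- step$report
    log_dims(stage, table)
  }
  step <- aggregate_zotus_to_taxa(table, taxa)
  table <- step$table
  reports[["aggregate"]] <- step$report
  log_dims("aggregate", table)

  pres <- to_presence_absence(table)
  step <- drop_empty_samples(pres)
  reports[["drop_empty"]] <- step$report
  if (verbose)
    message(sprintf("[dietmb] final matrix: %d taxa x %d samples, %d detections",
                    nrow(step$matrix), ncol(step$matrix), sum(step$matrix)))
  tax_rows <- taxa[match(rownames(step$matrix), taxa$taxon), , drop = FALSE]
  tax_rows$zotu_id <- NULL
  rownames(tax_rows) <- NULL
  list(matrix = step$matrix, reports = reports, taxa = tax_rows)
}
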