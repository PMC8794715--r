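# Readers, writers and validated containers for count tables, sample
# metadata, taxon annotations and filter configuration.

.stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)

.check_enum <- function(x, allowed, field) {
  bad <- setdiff(unique(x), allowed)
  .stop_if(length(bad) > 0,
           sprintf("invalid %s value(s): %s (allowed: %s)",
                   field, paste(sQuote(bad), collapse = ", "),
                   paste(allowed, collapse = ", ")))
  x
}

#' Construct a validated ZOTU count table
#'
#' Bundles a non-negative integer read-count matrix (ZOTU rows, sample
#' columns) with per-sample metadata. All filtering stages operate on this
#' container.
#'
#' @param counts integer matrix of read counts; rownames are ZOTU ids,
#'   colnames are sample ids.
#' @param samples data frame with columns `sample_id`, `role`, `season`,
#'   `sex` (see [read_metadata()]); rows must match the columns of `counts`
#'   (matched by `sample_id`, order taken from `counts`).
#' @return object of class `zotu_table` with elements `counts` and `samples`.
#' @export
zotu_table <- function(counts, samples) {
  .stop_if(!is.matrix(counts), "`counts` must be a matrix")
  .stop_if(is.null(rownames(counts)) || is.null(colnames(counts)),
           "`counts` must have ZOTU rownames and sample colnames")
  .stop_if(anyDuplicated(rownames(counts)) > 0, "duplicate ZOTU ids")
  .stop_if(anyDuplicated(colnames(counts)) > 0, "duplicate sample ids")
  .stop_if(any(counts < 0) || any(counts != round(counts)),
           "counts must be non-negative integers")
  storage.mode(counts) <- "double" # large totals can exceed .Machine$integer.max
  samples <- validate_metadata(samples)
  .stop_if(!setequal(samples$sample_id, colnames(counts)),
           "sample ids in `samples` do not match columns of `counts`")
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(counts = counts, samples = samples), class = "zotu_table")
}

#' @export
print.zotu_table <- function(x, ...) {
  cat(sprintf("<zotu_table> %d ZOTUs x %d samples (%s reads)\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  cat("roles:", paste(sprintf("%s=%d", names(table(x$samples$role)),
                              table(x$samples$role)), collapse = " "), "\n")
  invisible(x)
}

#' Read a ZOTU x sample read-count matrix from TSV
#'
#' Expects ZOTU rows and sample columns (the layout most denoisers emit):
#' a header of sample ids preceded by one id column for the ZOTUs. Cells
#' must be non-negative integers; anything else is an error naming the
#' offending cell.
#'
#' @param path TSV file path.
#' @param transpose set `TRUE` for tables stored samples x ZOTUs.
#' @return numeric matrix with ZOTU rownames and sample colnames, in file
#'   order. Combine with metadata via [zotu_table()].
#' @export
read_count_table <- function(path, transpose = FALSE) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           quote = "")
  .stop_if(ncol(raw) < 2, "count table needs an id column plus data columns")
  ids <- raw[[1]]
  .stop_if(anyDuplicated(ids) > 0,
           sprintf("duplicate row id(s): %s",
                   paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  .stop_if(anyDuplicated(colnames(raw)[-1]) > 0, "duplicate column ids")
  m <- as.matrix(raw[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(m), nrow = nrow(m)))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-integer or negative count at row %s, column %s (value %s)",
                 sQuote(ids[bad[1, 1]]), sQuote(colnames(m)[bad[1, 2]]),
                 sQuote(m[bad[1, 1], bad[1, 2]])), call. = FALSE)
  }
  dimnames(num) <- list(ids, colnames(m))
  if (transpose) num <- t(num)
  num
}

#' Write a count matrix as TSV (inverse of [read_count_table()])
#'
#' @param counts matrix with rownames and colnames.
#' @param path output path.
#' @param id_column header for the id column.
#' @export
write_count_table <- function(counts, path, id_column = "zotu_id") {
  df <- data.frame(rownames(counts), counts, check.names = FALSE)
  colnames(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_metadata <- function(samples) {
  .stop_if(!is.data.frame(samples), "metadata must be a data frame")
  need <- c("sample_id", "role", "season", "sex")
  missing <- setdiff(need, colnames(samples))
  .stop_if(length(missing) > 0,
           "metadata missing column(s): ", paste(missing, collapse = ", "))
  samples <- samples[, need, drop = FALSE]
  for (col in need) samples[[col]] <- as.character(samples[[col]])
  # absent season/sex is legitimate field reality, not an error
  samples$season[is.na(samples$season) | samples$season == ""] <- "unknown"
  samples$sex[is.na(samples$sex) | samples$sex == ""] <- "unknown"
  .stop_if(anyDuplicated(samples$sample_id) > 0, "duplicate sample ids")
  .check_enum(samples$role, .dietmb_roles, "role")
  .check_enum(samples$season, .dietmb_seasons, "season")
  .check_enum(samples$sex, .dietmb_sexes, "sex")
  ctrl <- samples$role != "diet"
  .stop_if(any(ctrl & (samples$season != "unknown" | samples$sex != "unknown")),
           "control samples must have season and sex 'unknown'")
  samples
}

#' Read sample metadata from CSV
#'
#' Columns `sample_id`, `role` (diet / pcr_blank / extraction_blank /
#' positive), `season` (wet / dry / unknown), `sex` (female / male /
#' unknown). Empty season or sex cells become `"unknown"`; control samples
#' must not carry a known season or sex.
#'
#' @param path CSV file path.
#' @return validated data frame of sample records.
#' @export
read_metadata <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  validate_metadata(df)
}

#' @rdname read_metadata
#' @param samples metadata data frame.
#' @export
write_metadata <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_taxon_table <- function(df, statuses = .dietmb_statuses) {
  need <- c("zotu_id", "taxon", "rank", "kingdom", "status")
  missing <- setdiff(need, colnames(df))
  .stop_if(length(missing) > 0,
           "taxon table missing column(s): ", paste(missing, collapse = ", "))
  df <- df[, need, drop = FALSE]
  for (col in need) df[[col]] <- as.character(df[[col]])
  .stop_if(anyDuplicated(df$zotu_id) > 0, "duplicate zotu ids in taxon table")
  .check_enum(df$rank, .dietmb_ranks, "rank")
  .check_enum(df$kingdom, .dietmb_kingdoms, "kingdom")
  .check_enum(df$status, statuses, "status")
  df
}

#' Read the ZOTU-to-taxon annotation table from CSV
#'
#' Columns `zotu_id`, `taxon`, `rank` (species / genus / family / order),
#' `kingdom` (Animalia / Plantae), `status` relative to the study site
#' (cryptogenic / endemic / introduced / native). Several ZOTUs may map to
#' the same taxon; they are pooled during aggregation.
#'
#' @param path CSV file path.
#' @return validated data frame, one row per ZOTU.
#' @export
read_taxon_table <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  validate_taxon_table(df)
}

#' @rdname read_taxon_table
#' @param taxa annotation data frame.
#' @export
write_taxon_table <- function(taxa, path) {
  utils::write.csv(taxa, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filtering configuration
#'
#' Thresholds and ordering for the read-count cleaning cascade. The
#' per-sample threshold (default 0.3% of each sample's total reads) removes
#' low-frequency laboratory contaminants and sequencing errors; the
#' per-ZOTU threshold (default 0.74% of each ZOTU's total reads) removes
#' residual tag-jump signal; the blank rule controls whether reads equal to
#' a ZOTU's maximum count in blanks survive.
#'
#' @param per_sample_pct fraction of the sample (column) total below which a
#'   cell is zeroed.
#' @param per_zotu_pct fraction of the ZOTU (row) total below which a cell
#'   is zeroed.
#' @param blank_rule `"strict_below"` zeroes diet reads strictly below the
#'   blank maximum; `"at_or_below"` also zeroes ties.
#' @param stage_order permutation of `c("per_sample", "blank_max",
#'   "per_zotu")`; aggregation, presence-absence conversion and
#'   empty-sample removal always follow, in that order.
#' @return list of class `filter_config`.
#' @export
filter_config <- function(per_sample_pct = 0.003,
                          per_zotu_pct = 0.0074,
                          blank_rule = c("strict_below", "at_or_below"),
                          stage_order = c("per_sample", "blank_max", "per_zotu")) {
  blank_rule <- match.arg(blank_rule)
  .stop_if(!is.numeric(per_sample_pct) || per_sample_pct < 0 || per_sample_pct > 1,
           "`per_sample_pct` must be in [0, 1]")
  .stop_if(!is.numeric(per_zotu_pct) || per_zotu_pct < 0 || per_zotu_pct > 1,
           "`per_zotu_pct` must be in [0, 1]")
  .stop_if(!setequal(stage_order, c("per_sample", "blank_max", "per_zotu")) ||
             length(stage_order) != 3,
           "`stage_order` must be a permutation of per_sample, blank_max, per_zotu")
  structure(list(per_sample_pct = per_sample_pct,
                 per_zotu_pct = per_zotu_pct,
                 blank_rule = blank_rule,
                 stage_order = stage_order),
            class = "filter_config")
}

#' Read a filter configuration from YAML or JSON
#'
#' Keys mirror the arguments of [filter_config()]; absent keys take the
#' defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return `filter_config` object.
#' @export
read_filter_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(filter_config))
  bad <- setdiff(names(vals), known)
  .stop_if(length(bad) > 0, "unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(filter_config, vals)
}
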