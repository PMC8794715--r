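# Frequency-of-occurrence accounting, origin-status composition and
# rank-based group comparisons on the presence-absence diet matrix.

#' Per-taxon detection summaries
#'
#' Counts, for each taxon, the diet samples in which it was detected and
#' expresses this as frequency of occurrence (FO, percent of samples).
#' Percentages are rounded to two decimals at report time only; raw counts
#' are kept alongside.
#'
#' @param matrix logical presence-absence matrix (taxa x diet samples).
#' @param taxa annotation data frame with columns `taxon`, `kingdom`,
#'   `status`, covering every taxon in the matrix.
#' @return data frame with columns `taxon`, `detections`, `fo_pct`,
#'   `kingdom`, `status`, ordered by kingdom then decreasing detections.
#' @export
detection_summaries <- function(matrix, taxa) {
  stopifnot(is.matrix(matrix), is.logical(matrix))
  .stop_if(ncol(matrix) == 0 || nrow(matrix) == 0, "empty presence matrix")
  .stop_if(!all(c("taxon", "kingdom", "status") %in% colnames(taxa)),
           "`taxa` needs columns taxon, kingdom, status")
  idx <- match(rownames(matrix), taxa$taxon)
  .stop_if(anyNA(idx), "taxa without annotation: ",
           paste(rownames(matrix)[is.na(idx)], collapse = ", "))
  det <- rowSums(matrix)
  out <- data.frame(taxon = rownames(matrix),
                    detections = as.integer(det),
                    fo_pct = round(100 * det / ncol(matrix), 2),
                    kingdom = taxa$kingdom[idx],
                    status = taxa$status[idx],
                    row.names = NULL)
  out[order(out$kingdom, -out$detections, out$taxon), , drop = FALSE]
}

#' Detection totals and percentage shares by origin status
#'
#' @param summaries output of [detection_summaries()] (or any data frame
#'   with `detections` and `status`).
#' @return data frame with one row per status present, columns `status`,
#'   `detections`, `pct` (share of all detections, full precision).
#' @export
status_composition <- function(summaries) {
  stopifnot(all(c("detections", "status") %in% colnames(summaries)))
  tot <- tapply(summaries$detections, summaries$status, sum)
  data.frame(status = names(tot),
             detections = as.integer(tot),
             pct = 100 * as.numeric(tot) / sum(summaries$detections),
             row.names = NULL)
}

#' Mean detections per taxon by kingdom or status
#'
#' The group mean is total detections in the group divided by the number
#' of taxa detected in it; the standard error is the sample SD of per-taxon
#' counts over the square root of the taxon count (NA for singleton
#' groups).
#'
#' @param summaries output of [detection_summaries()].
#' @param by grouping variable, `"kingdom"` or `"status"`.
#' @return data frame with columns `group`, `n_taxa`, `mean`, `se`.
#' @export
group_mean_detections <- function(summaries, by = c("kingdom", "status")) {
  by <- match.arg(by)
  stopifnot(all(c("detections", by) %in% colnames(summaries)))
  g <- summaries[[by]]
  split_counts <- split(summaries$detections, g)
  data.frame(group = names(split_counts),
             n_taxa = vapply(split_counts, length, integer(1)),
             mean = vapply(split_counts, mean, numeric(1)),
             se = vapply(split_counts, function(v) {
               if (length(v) < 2) NA_real_ else stats::sd(v) / sqrt(length(v))
             }, numeric(1)),
             row.names = NULL)
}

#' Tie-corrected Kruskal-Wallis rank test
#'
#' Detection counts are heavily tied, so the tie-corrected statistic is
#' used throughout. When every value is identical the test carries no
#' information and (H = 0, p = 1) is returned rather than an error.
#'
#' @param values numeric vector.
#' @param groups group labels, same length.
#' @return list with `H` (statistic), `df`, `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  .stop_if(length(values) != length(groups), "length mismatch")
  .stop_if(nlevels(groups) < 2, "need at least two groups")
  if (length(unique(values)) == 1L)
    return(list(H = 0, df = nlevels(groups) - 1L, p = 1))
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = unname(kt$p.value))
}

#' Shapiro-Wilk normality check
#'
#' @param values numeric vector, 3 to 5000 observations.
#' @return list with `W` and `p`.
#' @export
normality_check <- function(values) {
  .stop_if(length(values) < 3 || length(values) > 5000,
           "Shapiro-Wilk requires between 3 and 5000 observations")
  sw <- stats::shapiro.test(values)
  list(W = unname(sw$statistic), p = unname(sw$p.value))
}
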