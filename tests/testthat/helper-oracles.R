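# Independent brute-force oracles used to cross-check the package
# implementations. These are deliberately naive (explicit loops, exhaustive
# enumeration) and share no code with the package internals.

oracle_per_sample <- function(counts, pct) {
  out <- counts
  for (s in seq_len(ncol(counts))) {
    thr <- pct * sum(counts[, s])
    for (z in seq_len(nrow(counts)))
      if (counts[z, s] < thr) out[z, s] <- 0
  }
  out
}

oracle_per_zotu <- function(counts, pct) {
  out <- counts
  for (z in seq_len(nrow(counts))) {
    thr <- pct * sum(counts[z, ])
    for (s in seq_len(ncol(counts)))
      if (counts[z, s] < thr) out[z, s] <- 0
  }
  out
}

oracle_blank_max <- function(counts, blank_cols, diet_cols, strict = TRUE) {
  out <- counts
  for (z in seq_len(nrow(counts))) {
    b <- max(counts[z, blank_cols])
    for (s in diet_cols) {
      below <- if (strict) counts[z, s] < b else counts[z, s] <= b
      if (below) out[z, s] <- 0
    }
  }
  out
}

oracle_aggregate <- function(counts, zotu_to_taxon) {
  taxa <- unique(zotu_to_taxon[rownames(counts)])
  taxa <- taxa[!is.na(taxa)]
  out <- matrix(0, length(taxa), ncol(counts),
                dimnames = list(taxa, colnames(counts)))
  for (z in rownames(counts)) {
    t <- zotu_to_taxon[z]
    if (!is.na(t)) out[t, ] <- out[t, ] + counts[z, ]
  }
  out
}

# tie-corrected Kruskal-Wallis from first principles
oracle_kruskal <- function(values, groups) {
  N <- length(values)
  r <- rank(values)
  groups <- factor(groups)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(ri) length(ri) * mean(ri)^2)) -
    3 * (N + 1)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H / corr
}

# expected number of distinct species in a size-m subsample, by exhaustive
# enumeration over all subsets of individuals (communities with n <= ~10)
oracle_expected_richness <- function(x, m) {
  individuals <- rep(seq_along(x), x)
  subsets <- utils::combn(length(individuals), m)
  mean(apply(subsets, 2, function(idx)
    length(unique(individuals[idx]))))
}

# all partitions of n into unordered positive parts (community shapes)
all_partitions <- function(n, max_part = n) {
  if (n == 0) return(list(integer()))
  out <- list()
  for (k in seq_len(min(n, max_part))) {
    for (rest in all_partitions(n - k, k)) out <- c(out, list(c(k, rest)))
  }
  out
}

random_count_matrix <- function(nr, nc, max_count = 2000, p_zero = 0.3) {
  matrix(as.numeric(rbinom(nr * nc, 1, 1 - p_zero) *
                      sample.int(max_count, nr * nc, replace = TRUE)),
         nrow = nr,
         dimnames = list(sprintf("Z%02d", seq_len(nr)),
                         sprintf("S%02d", seq_len(nc))))
}

make_table <- function(counts, roles = NULL) {
  if (is.null(roles)) roles <- rep("diet", ncol(counts))
  zotu_table(counts, data.frame(sample_id = colnames(counts), role = roles,
                                season = "unknown", sex = "unknown"))
}
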