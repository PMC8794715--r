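test_that("per-sample threshold zeroes strictly below the pre-stage column fraction", {
  counts <- matrix(c(2, 3, 995,
                     0, 40, 60), ncol = 2,
                   dimnames = list(c("Z1", "Z2", "Z3"), c("S1", "S2")))
  # S1 totals 1000 at 0.3%: threshold 3; cell 2 goes, boundary cell 3 stays
  res <- apply_per_sample_threshold(make_table(counts), 0.003)
  expect_identical(res$table$counts[, "S1"], c(Z1 = 0, Z2 = 3, Z3 = 995))
  expect_identical(res$report$reads_removed, 2)
  expect_identical(res$report$cells_zeroed, 1L)

  zero <- make_table(matrix(0, 2, 2, dimnames = list(c("Z1", "Z2"),
                                                     c("S1", "S2"))))
  res0 <- apply_per_sample_threshold(zero, 0.003)
  expect_identical(res0$table$counts, zero$counts)
  expect_identical(res0$report$reads_removed, 0)
})

test_that("blank-max filter masks diet reads below the per-ZOTU blank maximum", {
  counts <- matrix(c(4, 5, 6, 5, 0,
                     9, 9, 9, 0, 0), nrow = 2, byrow = TRUE,
                   dimnames = list(c("Z1", "Z2"),
                                   c("D1", "D2", "D3", "B1", "B2")))
  roles <- c("diet", "diet", "diet", "pcr_blank", "extraction_blank")
  tbl <- make_table(counts, roles)

  strict <- apply_blank_max_filter(tbl)$table$counts
  expect_identical(strict["Z1", 1:3], c(D1 = 0, D2 = 5, D3 = 6))
  expect_identical(strict["Z2", 1:3], c(D1 = 9, D2 = 9, D3 = 9)) # b(Z2) = 0
  expect_identical(strict[, 4:5], counts[, 4:5]) # blanks untouched

  inclusive <- apply_blank_max_filter(tbl, rule = "at_or_below")$table$counts
  expect_identical(inclusive["Z1", 1:3], c(D1 = 0, D2 = 0, D3 = 6))

  no_blanks <- make_table(counts[, 1:3], rep("diet", 3))
  expect_warning(res <- apply_blank_max_filter(no_blanks), "no-op")
  expect_identical(res$table$counts, no_blanks$counts)
})

test_that("per-ZOTU threshold uses the pre-stage row total", {
  counts <- matrix(c(1000, 5, 0), nrow = 1,
                   dimnames = list("Z1", c("S1", "S2", "S3")))
  res <- apply_per_zotu_threshold(make_table(counts), 0.0074)
  expect_identical(res$table$counts[1, ], c(S1 = 1000, S2 = 0, S3 = 0))

  # a row's only non-zero cell always survives
  single <- matrix(c(0, 7, 0), nrow = 1,
                   dimnames = list("Z1", c("S1", "S2", "S3")))
  res1 <- apply_per_zotu_threshold(make_table(single), 0.0074)
  expect_identical(res1$table$counts, single * 1)
})

test_that("all three filters match their brute-force oracles on random tables", {
  set.seed(101)
  for (rep in 1:15) {
    nr <- sample(2:20, 1); nc <- sample(3:20, 1)
    counts <- random_count_matrix(nr, nc)
    pct_s <- runif(1, 0, 0.1); pct_z <- runif(1, 0, 0.1)

    expect_equal(apply_per_sample_threshold(make_table(counts),
                                            pct_s)$table$counts,
                 oracle_per_sample(counts, pct_s))
    expect_equal(apply_per_zotu_threshold(make_table(counts),
                                          pct_z)$table$counts,
                 oracle_per_zotu(counts, pct_z))

    roles <- c(rep("diet", nc - 2), "pcr_blank", "extraction_blank")
    for (strict in c(TRUE, FALSE)) {
      got <- apply_blank_max_filter(
        make_table(counts, roles),
        rule = if (strict) "strict_below" else "at_or_below")$table$counts
      expect_equal(got, oracle_blank_max(counts, (nc - 1):nc,
                                         seq_len(nc - 2), strict))
    }
  }
})

test_that("aggregation sums ZOTU rows per taxon and conserves mapped reads", {
  counts <- matrix(c(1, 0, 2,
                     0, 3, 0,
                     5, 5, 5), nrow = 3, byrow = TRUE,
                   dimnames = list(c("Z1", "Z2", "Z3"), c("S1", "S2", "S3")))
  taxa <- data.frame(zotu_id = c("Z1", "Z2"), taxon = c("tA", "tA"))
  res <- aggregate_zotus_to_taxa(make_table(counts), taxa)
  expect_identical(res$table$counts["tA", ], c(S1 = 1, S2 = 3, S3 = 2))
  expect_identical(res$report$zotus_dropped, "Z3") # unmapped dropped, reported
  expect_identical(res$report$reads_removed, 15)

  # identity mapping changes nothing but labels
  id_map <- data.frame(zotu_id = rownames(counts), taxon = rownames(counts))
  expect_identical(aggregate_zotus_to_taxa(make_table(counts),
                                           id_map)$table$counts, counts * 1)

  set.seed(7)
  counts <- random_count_matrix(12, 6)
  map <- setNames(sample(c("tA", "tB", "tC"), 12, replace = TRUE),
                  rownames(counts))
  taxa <- data.frame(zotu_id = names(map), taxon = unname(map))
  agg <- aggregate_zotus_to_taxa(make_table(counts), taxa)$table$counts
  expect_equal(sum(agg), sum(counts))
  expect_equal(agg[sort(rownames(agg)), ],
               oracle_aggregate(counts, map)[sort(unique(map)), ])
})

test_that("presence conversion keeps diet samples only and is elementwise positivity", {
  counts <- matrix(c(0, 1, 250, 4), nrow = 1,
                   dimnames = list("t1", c("D1", "D2", "D3", "B1")))
  tbl <- make_table(counts, c("diet", "diet", "diet", "pcr_blank"))
  pres <- to_presence_absence(tbl)
  expect_identical(pres[1, ], c(D1 = FALSE, D2 = TRUE, D3 = TRUE))

  set.seed(3)
  counts <- random_count_matrix(8, 6)
  expect_identical(to_presence_absence(make_table(counts)),
                   counts > 0)
})

test_that("empty samples and taxa are dropped and reported", {
  m <- matrix(c(TRUE, FALSE, FALSE,
                TRUE, FALSE, TRUE,
                FALSE, FALSE, FALSE), nrow = 3, byrow = TRUE,
              dimnames = list(c("t1", "t2", "t3"), c("S1", "S2", "S3")))
  res <- drop_empty_samples(m)
  expect_identical(res$report$samples_dropped, "S2")
  expect_identical(res$report$zotus_dropped, "t3")
  expect_identical(dim(res$matrix), c(2L, 2L))

  full <- m[1:2, c(1, 3)]
  expect_identical(drop_empty_samples(full)$matrix, full)

  # constructed fixture with exactly k empty samples
  set.seed(11)
  k <- 4
  big <- matrix(runif(10 * 12) < 0.4, 10, 12,
                dimnames = list(sprintf("t%02d", 1:10),
                                sprintf("S%02d", 1:12)))
  big[1, ] <- TRUE     # no empty taxa outside the emptied block
  big[, 1:k] <- FALSE
  big[, k + 1] <- TRUE # guarantee the remaining samples are non-empty
  expect_length(drop_empty_samples(big)$report$samples_dropped, k)
})

test_that("raising a threshold never increases any cell or the detection count", {
  set.seed(23)
  counts <- random_count_matrix(15, 10)
  for (op in list(apply_per_sample_threshold, apply_per_zotu_threshold)) {
    prev <- op(make_table(counts), 0.001)$table$counts
    for (pct in c(0.005, 0.02, 0.1)) {
      cur <- op(make_table(counts), pct)$table$counts
      expect_true(all(cur <= prev))
      expect_lte(sum(cur > 0), sum(prev > 0))
      prev <- cur
    }
  }
})

test_that("cascade reports conserve reads and the cascade is idempotent", {
  set.seed(31)
  sim <- simulate_presence(diet_sim_params(n_samples = 30,
                                           base_fo = rep(0.3, 12),
                                           season_effects = rep(0, 12),
                                           sex_effects = rep(0, 12),
                                           n_wet = 15, seed = 31))
  zt <- simulate_zotu_table(sim$matrix, read_sim_params(seed = 31))
  res <- run_filter_cascade(zt$table, zt$taxa)

  removed <- sum(vapply(res$reports[c("per_sample", "blank_max", "per_zotu",
                                      "aggregate")],
                        `[[`, numeric(1), "reads_removed"))
  # conservation: stage removals account for initial minus post-aggregation total
  agg_again <- apply_per_zotu_threshold(
    apply_blank_max_filter(
      apply_per_sample_threshold(zt$table, 0.003)$table)$table, 0.0074)$table
  mapped_total <- sum(aggregate_zotus_to_taxa(agg_again, zt$taxa)$table$counts)
  expect_equal(sum(zt$table$counts) - mapped_total, removed)

  # idempotence: a second pass over the cleaned counts removes nothing
  clean <- aggregate_zotus_to_taxa(agg_again, zt$taxa)$table
  second <- run_filter_cascade(clean,
                               data.frame(zotu_id = rownames(clean$counts),
                                          taxon = rownames(clean$counts)))
  expect_identical(sort(rownames(second$matrix)), sort(rownames(res$matrix)))
  expect_identical(sum(second$matrix), sum(res$matrix))
})

test_that("stage order changes the outcome on a constructed counterexample", {
  counts <- matrix(c(3, 4,
                     997, 1996), nrow = 2, byrow = TRUE,
                   dimnames = list(c("Z1", "Z2"), c("D1", "B1")))
  tbl <- make_table(counts, c("diet", "pcr_blank"))
  taxa <- data.frame(zotu_id = c("Z1", "Z2"), taxon = c("Z1", "Z2"))
  # per-sample first: the blank's Z1 count (4 < 0.3% of 2000 = 6) is wiped,
  # so the blank maximum is 0 and the diet read of 3 (= 0.3% of 1000) survives
  keep <- run_filter_cascade(tbl, taxa,
                             filter_config(stage_order = c("per_sample",
                                                           "blank_max",
                                                           "per_zotu")))
  # blank-max first: 3 < 4 is wiped before the blank is cleaned
  drop <- run_filter_cascade(tbl, taxa,
                             filter_config(stage_order = c("blank_max",
                                                           "per_sample",
                                                           "per_zotu")))
  expect_true("Z1" %in% rownames(keep$matrix))
  expect_false("Z1" %in% rownames(drop$matrix))
})

test_that("on simulated reads the cascade recovers truth with no false positives", {
  for (seed in c(7, 11)) {
    sim <- simulate_presence(diet_sim_params(seed = seed))
    zt <- simulate_zotu_table(sim$matrix, read_sim_params(seed = seed),
                              sim$metadata)
    res <- run_filter_cascade(zt$table, zt$taxa)
    truth <- sim$matrix[rownames(res$matrix), colnames(res$matrix)]
    # contaminant and tag-jump reads sit far below the thresholds, so every
    # surviving detection must be a true one (some low-depth true
    # detections are sacrificed by the per-ZOTU filter, as intended)
    expect_identical(sum(res$matrix & !truth), 0L)
    expect_gt(sum(res$matrix & truth) / sum(sim$matrix), 0.8)
  }

  # with no artifacts at all, positivity recovers the truth exactly
  sim <- simulate_presence(diet_sim_params(n_samples = 20,
                                           base_fo = rep(0.4, 6),
                                           season_effects = rep(0, 6),
                                           sex_effects = rep(0, 6),
                                           n_wet = 10, seed = 5))
  zt <- simulate_zotu_table(sim$matrix,
                            read_sim_params(n_contaminants = 0,
                                            tag_jump_rate = 0, seed = 5))
  pres <- to_presence_absence(zt$table)
  rownames(pres) <- zt$taxa$taxon[match(rownames(pres), zt$taxa$zotu_id)]
  expect_identical(pres[!is.na(rownames(pres)), ], sim$matrix)
  # blanks carry no reads at all in this regime
  blank_cols <- zt$table$samples$role %in% c("pcr_blank", "extraction_blank")
  expect_true(all(zt$table$counts[, blank_cols] == 0))
})
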