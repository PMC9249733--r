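# Columns of the helper count matrix, in order:
# input_r1, antigen_pos_r1, psr_pos_r1, psr_neg_r1, ova_pos_r1, ova_neg_r1,
# then the same six for replicate 2.
sample_cols <- function() {
  paste0(rep(c("input", "antigen_pos", "psr_pos", "psr_neg", "ova_pos", "ova_neg"), 2),
         "_r", rep(1:2, each = 6))
}

counts_mat <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  m
}

test_that("antigen labels follow the both/one/neither presence rule", {
  m <- counts_mat(
    both   = c(5, 3, 0, 0, 0, 0, 5, 2, 0, 0, 0, 0),   # in both antigen_pos
    onerep = c(5, 3, 0, 0, 0, 0, 5, 0, 0, 0, 0, 0),   # rep1 only
    neither = c(5, 0, 0, 0, 0, 0, 5, 0, 0, 0, 0, 0),  # input only
    nowhere = c(0, 0, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0)   # psr_pos only
  )
  ex <- experiment_from_counts(m)
  lab <- assign_antigen_label(ex)
  expect_equal(unname(lab[c("both", "onerep", "neither")]),
               c("positive", "discarded", "negative"))
  expect_true(is.na(lab["nowhere"]))
  expect_true(all(names(lab) == sort(rownames(m))) || setequal(names(lab), rownames(m)))
})

test_that("specificity labels need >=3 of 4 positives and zero negatives (and vice versa)", {
  m <- counts_mat(
    pos3 = c(1, 0, 2, 0, 3, 0, 1, 0, 4, 0, 0, 0),  # psr_pos x2 + ova_pos r1, no negatives
    neg3 = c(1, 0, 0, 2, 0, 0, 1, 0, 0, 3, 0, 4),  # psr_neg x2 + ova_neg r2, no positives
    mixed = c(1, 0, 2, 5, 3, 0, 1, 0, 4, 0, 0, 0), # 3 positives but 1 negative
    pos2 = c(1, 0, 2, 0, 0, 0, 1, 0, 4, 0, 0, 0)   # only 2 of 4 positives
  )
  ex <- experiment_from_counts(m)
  lab <- assign_specificity_label(ex)
  expect_equal(unname(lab[c("pos3", "neg3", "mixed", "pos2")]),
               c("positive", "negative", "unlabeled", "unlabeled"))
})

test_that("labels are pure functions of presence patterns, invariant to sample order", {
  set.seed(21)
  m <- matrix(rpois(8 * 12, 1), 8, 12)
  rownames(m) <- paste0("v", 1:8)
  m[, 1] <- pmax(m[, 1], 1)  # keep the input populated
  ex <- experiment_from_counts(m)
  lab1a <- assign_antigen_label(ex)
  lab1s <- assign_specificity_label(ex)
  perm <- sample(nrow(ex$counts))
  ex2 <- sort_experiment(ex$counts[perm, ])
  expect_equal(assign_antigen_label(ex2)[names(lab1a)], lab1a)
  expect_equal(assign_specificity_label(ex2)[names(lab1s)], lab1s)
  # assertable invariants of the rules themselves
  pos <- names(lab1s)[lab1s == "positive"]
  negsam <- paste0(c("psr_neg", "ova_neg"), "_r", rep(1:2, each = 2))
  expect_true(all(!ex$counts$sequence_id[ex$counts$sample_id %in% negsam] %in% pos))
})

test_that("occurrence frequency and relative abundance behave as documented", {
  m <- counts_mat(v = c(2, 3, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0),
                  w = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1))
  ex <- experiment_from_counts(m)
  all_ids <- ex$samples$sample_id
  expect_equal(unname(occurrence_frequency(ex, "v", all_ids[1:6])), 0.5)  # 3 of 6
  expect_equal(unname(occurrence_frequency(ex, "w", all_ids)), 1.0)
  m2 <- counts_mat(a = c(50, rep(0, 11)), b = c(4950, rep(0, 11)))
  ex2 <- experiment_from_counts(m2)
  ab <- occurrence_frequency(ex2, c("a", "b"), "input_r1", mode = "abundance")
  expect_equal(unname(ab["a", "input_r1"]), 0.01)  # 50 / 5000
})

test_that("enrichment ratio is the replicate mean of log2 abundance ratios", {
  # equal relative frequencies in input and output of both replicates -> 0
  m <- counts_mat(v = c(10, 10, 0, 0, 0, 0, 10, 10, 0, 0, 0, 0),
                  w = c(10, 10, 0, 0, 0, 0, 10, 10, 0, 0, 0, 0))
  ex <- experiment_from_counts(m)
  expect_equal(unname(enrichment_ratio(ex, "antigen_pos", "v")), 0)
  # fourfold output frequency in both replicates -> 2
  m2 <- counts_mat(v = c(10, 40, 0, 0, 0, 0, 10, 40, 0, 0, 0, 0),
                   w = c(90, 60, 0, 0, 0, 0, 90, 60, 0, 0, 0, 0))
  ex2 <- experiment_from_counts(m2)
  expect_equal(unname(enrichment_ratio(ex2, "antigen_pos", "v")), 2)
  # ER 2 in rep1, ER 0 in rep2 -> mean 1
  m3 <- counts_mat(v = c(10, 40, 0, 0, 0, 0, 10, 10, 0, 0, 0, 0),
                   w = c(90, 60, 0, 0, 0, 0, 90, 90, 0, 0, 0, 0))
  ex3 <- experiment_from_counts(m3)
  expect_equal(unname(enrichment_ratio(ex3, "antigen_pos", "v")), 1)
  # missing from all inputs: NA without pseudocount, finite with it
  m4 <- counts_mat(v = c(0, 40, 0, 0, 0, 0, 0, 40, 0, 0, 0, 0),
                   w = c(90, 60, 0, 0, 0, 0, 90, 60, 0, 0, 0, 0))
  ex4 <- experiment_from_counts(m4)
  expect_true(is.na(unname(enrichment_ratio(ex4, "antigen_pos", "v"))))
  expect_true(is.finite(unname(enrichment_ratio(ex4, "antigen_pos", "v",
                                                pseudocount = 0.5))))
})

test_that("depth scaling leaves enrichment of proportionally sampled variants at 0", {
  m <- counts_mat(v = c(10, 100, 0, 0, 0, 0, 10, 100, 0, 0, 0, 0),
                  w = c(30, 300, 0, 0, 0, 0, 30, 300, 0, 0, 0, 0))
  ex <- experiment_from_counts(m)
  er <- enrichment_ratio(ex, "antigen_pos")
  expect_equal(unname(er), c(0, 0))
})

test_that("site_enrichment_matrix equals a direct counting oracle", {
  design <- tiny_design()
  set.seed(5)
  a <- sample_library_variants(design, 25)
  set.seed(6)
  b <- sample_library_variants(design, 20)
  m <- site_enrichment_matrix(a, b, design)
  idx <- c(2, 5, 8)
  for (i in seq_along(idx)) {
    for (r in AA_ALPHABET) {
      fa <- mean(substring(a, idx[i], idx[i]) == r)
      fb <- mean(substring(b, idx[i], idx[i]) == r)
      expected <- if (fa > 0 && fb > 0) log2(fa / fb) else NA_real_
      expect_equal(m[i, r], expected, info = paste("site", idx[i], "residue", r))
    }
  }
  # equal frequency -> 0; 50% vs 25% -> 1
  aa <- c("ACDEFGHIKL", "ACDEFGHIKL", "ASDEFGHIKL", "ASDEFGHIKL")
  bb <- c("ACDEFGHIKL", "ACDEFGHIKL", "ACDEFGHIKL", "ASDEFGHIKL")
  m2 <- site_enrichment_matrix(aa, bb, design)
  expect_equal(m2["T2", "S"], 1)   # 0.5 vs 0.25
  mm <- site_enrichment_matrix(aa, aa, design)
  expect_equal(mm["T2", "C"], 0)
})

test_that("master dataset selection is evenly stratified and prioritizes antigen positives", {
  set.seed(8)
  n <- 400
  lab <- data.frame(
    id = sprintf("v%03d", 1:n),
    sequence = sprintf("v%03d", 1:n),
    antigen_label = sample(c("positive", "negative"), n, TRUE, prob = c(0.25, 0.75)),
    specificity_label = rep(c("positive", "negative"), each = n / 2),
    frequency = round(runif(n), 3),
    stringsAsFactors = FALSE
  )
  sel <- select_master_dataset(lab, 200)
  expect_equal(as.integer(table(sel$specificity_label)), c(100L, 100L))
  # every antigen positive in a stratum is retained while the stratum can hold them
  for (s in c("positive", "negative")) {
    pool <- lab[lab$specificity_label == s, ]
    n_pos <- sum(pool$antigen_label == "positive")
    kept_pos <- sum(sel$specificity_label == s & sel$antigen_label == "positive")
    expect_equal(kept_pos, min(n_pos, 100L))
  }
  # remaining slots filled by descending frequency
  for (s in c("positive", "negative")) {
    pool <- lab[lab$specificity_label == s & lab$antigen_label == "negative", ]
    kept <- sel[sel$specificity_label == s & sel$antigen_label == "negative", ]
    top <- pool[order(-pool$frequency, pool$id), ][seq_len(nrow(kept)), "id"]
    expect_setequal(kept$id, top)
  }
  # deterministic across reruns
  expect_identical(sel, select_master_dataset(lab[sample(n), ], 200))
  expect_error(select_master_dataset(lab, 2 * n + 10), "stratum")
  expect_error(select_master_dataset(lab, 3), "even")
})
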