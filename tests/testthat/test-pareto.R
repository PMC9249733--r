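pp <- function(aff, ns, id = sprintf("p%03d", seq_along(aff))) {
  data.frame(id = id, affinity_metric = aff, nonspec_metric = ns,
             stringsAsFactors = FALSE)
}

oracle_front <- function(points) {
  dom <- vapply(seq_len(nrow(points)), function(i) {
    any(points$affinity_metric >= points$affinity_metric[i] &
          points$nonspec_metric <= points$nonspec_metric[i] &
          (points$affinity_metric > points$affinity_metric[i] |
             points$nonspec_metric < points$nonspec_metric[i]))
  }, logical(1))
  points$id[!dom]
}

test_that("pareto_front returns exactly the non-dominated points", {
  pts <- pp(c(1, 2, 0), c(1, 2, 3))
  f <- pareto_front(pts)
  expect_setequal(f$id, c("p001", "p002"))  # (0,3) dominated by (1,1)
  expect_equal(nrow(pareto_front(pp(5, 5))), 1L)
  # strictly increasing affinity/nonspec curve: mutual non-domination
  curve <- pp(1:10, 1:10)
  expect_setequal(pareto_front(curve)$id, curve$id)
  # duplicates of a frontier point are all retained
  dup <- pp(c(1, 1, 0), c(0, 0, 1), id = c("a", "b", "c"))
  expect_setequal(pareto_front(dup)$id, c("a", "b"))
  expect_error(pareto_front(pp(numeric(0), numeric(0))), "non-empty")
  expect_error(pareto_front(pp(c(1, NA), c(1, 2))), "non-finite")
})

test_that("pareto_front matches the quadratic dominance oracle on random clouds", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- 300
    pts <- pp(round(rnorm(n), 2), round(rnorm(n), 2))  # rounding forces ties
    expect_setequal(pareto_front(pts)$id, oracle_front(pts))
  }
})

test_that("pareto_front is idempotent and ignores dominated additions", {
  set.seed(9)
  pts <- pp(rnorm(50), rnorm(50))
  f <- pareto_front(pts)
  expect_setequal(pareto_front(f)$id, f$id)
  dominated <- pp(min(pts$affinity_metric) - 1, max(pts$nonspec_metric) + 1, "dom")
  expect_setequal(pareto_front(rbind(pts, dominated))$id, f$id)
})

test_that("near_frontier ranks by z-scored distance to the frontier", {
  set.seed(17)
  pts <- pp(rnorm(80), rnorm(80))
  f <- pareto_front(pts)
  expect_setequal(near_frontier(pts, nrow(f))$id, f$id)
  expect_setequal(near_frontier(pts, 80)$id, pts$id)
  k <- nrow(f) + 5
  nf <- near_frontier(pts, k)
  expect_equal(nrow(nf), k)
  # exhaustive-oracle check of the distance ranking
  z <- scale(cbind(pts$affinity_metric, pts$nonspec_metric))
  zf <- z[pts$id %in% f$id, , drop = FALSE]
  rest <- pts$id[!pts$id %in% f$id]
  d <- vapply(which(!pts$id %in% f$id), function(i) {
    min(sqrt(rowSums(sweep(zf, 2, z[i, ])^2)))
  }, numeric(1))
  expected_extra <- rest[order(d, rest)][1:5]
  expect_setequal(setdiff(nf$id, f$id), expected_extra)
})

test_that("blosum62 is the standard symmetric matrix", {
  expect_equal(blosum62("D", "E"), 2L)   # conservative, passes >= 0
  expect_equal(blosum62("W", "G"), -2L)  # fails the filter
  for (a in AA_ALPHABET) for (b in AA_ALPHABET) {
    expect_identical(blosum62(a, b), blosum62(b, a))
  }
  expect_error(blosum62("B", "A"), "non-canonical")
  # independent cross-check against the matrix shipped with Biostrings
  ref <- local({
    e <- new.env()
    suppressWarnings(utils::data("BLOSUM62", package = "Biostrings", envir = e))
    e$BLOSUM62
  })
  for (a in c("A", "D", "K", "W", "Y")) {
    for (b in AA_ALPHABET) expect_equal(blosum62(a, b), unname(ref[a, b]))
  }
})

scan_setup <- function() {
  set.seed(23)
  seqs <- sample_library_variants(tiny_design(), 30)
  enc <- feature_encoder("physchem")
  X <- encode_features(enc, seqs)
  y <- rep(c("negative", "positive"), 15)
  list(enc = enc, aff = fit_lda(X, y), ns = fit_lda(X, rev(y)), seqs = seqs)
}

test_that("single-mutant scan counts follow the closed form and the blosum filter", {
  su <- scan_setup()
  bases <- data.frame(id = "base1", sequence = su$seqs[1], stringsAsFactors = FALSE)
  regions <- list(R = 3:5)  # three sites, parents D, E, F (no cysteine parents)
  cand <- scan_single_mutants(bases, regions, su$enc, su$aff, su$ns,
                              blosum_min = NULL)
  expect_equal(nrow(cand), 3 * 18)  # 20 - parent - Cys per site
  parents <- strsplit(su$seqs[1], "")[[1]][3:5]
  closed_form <- sum(20 - 1 - vapply(parents, function(p) {
    length(setdiff("C", p))
  }, numeric(1)))
  expect_equal(nrow(cand), closed_form)
  filtered <- scan_single_mutants(bases, regions, su$enc, su$aff, su$ns,
                                  blosum_min = 0)
  expect_true(all(filtered$blosum62 >= 0))
  expect_equal(nrow(filtered), sum(cand$blosum62 >= 0))
  expect_equal(nrow(scan_single_mutants(bases, list(), su$enc, su$aff, su$ns)), 0L)
  # candidates never propose the parent residue or cysteine
  expect_true(all(cand$proposed != cand$parent))
  expect_true(all(cand$proposed != "C"))
  # scored into finite property metrics
  expect_true(all(is.finite(filtered$affinity_metric)))
  expect_true(all(is.finite(filtered$nonspec_metric)))
})

test_that("one-hot encoders are rejected for the mutational scan", {
  su <- scan_setup()
  oh <- feature_encoder("onehot", sequences = su$seqs)
  bases <- data.frame(id = "b", sequence = su$seqs[1])
  expect_error(scan_single_mutants(bases, list(R = 3:4), oh, su$aff, su$ns),
               "unsupported encoder")
})

test_that("select_designs prefers frontier-beating candidates and is deterministic", {
  ref <- pp(c(0, 1, 2), c(0, 1, 2), id = c("r1", "r2", "r3"))
  cands <- pp(c(3, 0.5, 0.5), c(1, 0.9, 1.5), id = c("beats", "mid", "dominated"))
  sel1 <- select_designs(cands, 1, ref)
  expect_equal(sel1$id, "beats")  # dominates-the-frontier candidate goes first
  expect_true(sel1$beyond_frontier)
  sel <- select_designs(cands, 3, ref)
  expect_equal(nrow(sel), 3L)
  expect_false(sel$beyond_frontier[sel$id == "dominated"])
  expect_identical(select_designs(cands, 3, ref), sel)  # rerun oracle
  expect_error(select_designs(cands, 0, ref), "positive")
})
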