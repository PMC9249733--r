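# Pareto-frontier identification in the (affinity up, non-specific binding
# down) property plane, near-frontier ranking, and design of novel single
# mutants under a BLOSUM62 conservation filter.
#
# Orientation convention, fixed package-wide: affinity_metric is maximized and
# nonspec_metric (higher = more non-specific binding = worse) is minimized.

check_points <- function(points) {
  need <- c("id", "affinity_metric", "nonspec_metric")
  if (!all(need %in% names(points))) {
    stop("points need columns: ", paste(need, collapse = ", "))
  }
  if (nrow(points) == 0L) stop("points must be non-empty")
  if (any(!is.finite(points$affinity_metric)) || any(!is.finite(points$nonspec_metric))) {
    stop("non-finite metric in points")
  }
  points
}

#' Pareto frontier of property points
#'
#' Returns all non-dominated points: `p` dominates `q` when
#' `p$affinity_metric >= q$affinity_metric` and
#' `p$nonspec_metric <= q$nonspec_metric` with at least one strict
#' inequality. Duplicates of a frontier point are all retained. Implemented
#' as a single sweep over points sorted by decreasing affinity.
#'
#' @param points Data.frame with columns `id`, `affinity_metric`,
#'   `nonspec_metric` (and anything else, carried through).
#' @return The non-dominated subset, with a logical `on_frontier` column
#'   added for convenience when re-joining.
#' @export
pareto_front <- function(points) {
  points <- check_points(points)
  aff <- points$affinity_metric
  ns <- points$nonspec_metric
  dominated <- logical(nrow(points))
  ord <- order(-aff, ns)
  best_ns_strictly_above <- Inf   # min nonspec among points with strictly larger affinity
  i <- 1L
  while (i <= length(ord)) {
    # process the block of equal affinity together
    j <- i
    while (j < length(ord) && aff[ord[j + 1L]] == aff[ord[i]]) j <- j + 1L
    block <- ord[i:j]
    min_ns_block <- min(ns[block])
    dominated[block] <- (ns[block] >= best_ns_strictly_above) | (ns[block] > min_ns_block)
    best_ns_strictly_above <- min(best_ns_strictly_above, min_ns_block)
    i <- j + 1L
  }
  out <- points[!dominated, , drop = FALSE]
  out$on_frontier <- TRUE
  rownames(out) <- NULL
  out
}

zscore_cols <- function(m) {
  mu <- colMeans(m)
  s <- apply(m, 2, stats::sd)
  s[s == 0] <- 1
  sweep(sweep(m, 2, mu), 2, s, "/")
}

#' Points at or near the Pareto frontier
#'
#' The frontier itself plus the non-frontier points closest to it, up to `k`
#' points in total. Distance is Euclidean in z-scored metric space to the
#' nearest frontier point; ties break by variant id.
#'
#' @param points Data.frame of property points (see [pareto_front()]).
#' @param k Maximum total number of points to return.
#' @return Subset of `points` with an `on_frontier` logical column.
#' @export
near_frontier <- function(points, k) {
  stopifnot(k >= 1)
  points <- check_points(points)
  front <- pareto_front(points)
  Z <- zscore_cols(cbind(points$affinity_metric, points$nonspec_metric))
  rownames(Z) <- points$id
  is_front <- points$id %in% front$id
  points$on_frontier <- is_front
  if (sum(is_front) >= k) {
    out <- points[is_front, , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  Zf <- Z[is_front, , drop = FALSE]
  rest <- which(!is_front)
  if (length(rest) > 0L) {
    d <- vapply(rest, function(i) {
      min(sqrt((Zf[, 1] - Z[i, 1])^2 + (Zf[, 2] - Z[i, 2])^2))
    }, numeric(1))
    ord <- rest[order(d, points$id[rest])]
    pick <- ord[seq_len(min(k - sum(is_front), length(ord)))]
  } else {
    pick <- integer(0)
  }
  out <- points[sort(c(which(is_front), pick)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enumerate and score novel single mutants
#'
#' For each base variant, each position in the given regions, and each
#' residue other than the current one (cysteine excluded by default), emits a
#' candidate with its BLOSUM62 substitution score, drops candidates below
#' `blosum_min` when the filter is on, and scores the survivors with the
#' trained affinity and non-specificity models. One-hot encoders cannot
#' represent novel residues and are rejected up front.
#'
#' @param bases Data.frame with `id` and `sequence` columns (the clones to
#'   mutate).
#' @param regions Named list of integer position vectors (1-based), e.g.
#'   `design$region_map[c("HCDR2", "HCDR3")]`.
#' @param encoder A [feature_encoder()] of kind `"physchem"` or
#'   `"embedding"`.
#' @param affinity_model,nonspec_model Trained `projection_model`s on that
#'   encoder's features.
#' @param blosum_min Minimum BLOSUM62 score to keep (default 0, the
#'   conservative-substitution filter); `NULL` disables the filter.
#' @param exclude Residues never proposed (default cysteine).
#' @return Data.frame of candidates: base id, position, parent/proposed
#'   residue, blosum62 score, mutant sequence, affinity_metric,
#'   nonspec_metric, provenance = "designed".
#' @export
scan_single_mutants <- function(bases, regions, encoder, affinity_model,
                                nonspec_model, blosum_min = 0,
                                exclude = "C") {
  stopifnot(inherits(encoder, "ab_encoder"))
  if (encoder$kind == "onehot") {
    stop("unsupported encoder: a one-hot model cannot score residues ",
         "absent from its fitting set; use physchem or embedding features")
  }
  stopifnot(is.list(regions), all(c("id", "sequence") %in% names(bases)))
  cand <- list()
  for (b in seq_len(nrow(bases))) {
    seq0 <- bases$sequence[b]
    ch <- strsplit(seq0, "")[[1]]
    for (pos in sort(unique(unlist(regions)))) {
      if (pos < 1 || pos > length(ch)) stop("region position out of sequence bounds: ", pos)
      parent <- ch[pos]
      for (r in setdiff(AA_ALPHABET, c(parent, exclude))) {
        sc <- blosum62(parent, r)
        if (!is.null(blosum_min) && sc < blosum_min) next
        mut <- ch
        mut[pos] <- r
        cand[[length(cand) + 1L]] <- data.frame(
          base_id = bases$id[b], position = pos, parent = parent,
          proposed = r, blosum62 = sc,
          sequence = paste(mut, collapse = ""),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(cand) == 0L) {
    return(data.frame(base_id = character(0), position = integer(0),
                      parent = character(0), proposed = character(0),
                      blosum62 = integer(0), sequence = character(0),
                      id = character(0), affinity_metric = numeric(0),
                      nonspec_metric = numeric(0), provenance = character(0)))
  }
  out <- do.call(rbind, cand)
  out$id <- paste0(out$base_id, ":", out$parent, out$position, out$proposed)
  Xc <- encode_features(encoder, out$sequence)
  out$affinity_metric <- project(affinity_model, Xc)
  out$nonspec_metric <- project(nonspec_model, Xc)
  out$provenance <- "designed"
  rownames(out) <- NULL
  out
}

#' Select design candidates along and beyond a reference frontier
#'
#' Prioritizes candidates that are non-dominated against the library
#' frontier, then spreads the selection across the property plane by greedy
#' max-min distance in z-scored metric space (z-scoring uses the pooled
#' reference + candidate points). Deterministic: ties break by candidate id.
#'
#' @param candidates Data.frame of scored candidates (see
#'   [scan_single_mutants()]).
#' @param n Number of designs to return (>= 1).
#' @param reference_front Data.frame of library frontier points
#'   ([pareto_front()] output).
#' @return Up to `n` rows of `candidates`, with a `beyond_frontier` logical.
#' @export
select_designs <- function(candidates, n, reference_front) {
  if (n <= 0) stop("n must be positive")
  candidates <- check_points(candidates)
  ref <- check_points(reference_front)
  # a candidate is beyond the frontier if no reference point dominates it
  dominated_by_ref <- vapply(seq_len(nrow(candidates)), function(i) {
    any(ref$affinity_metric >= candidates$affinity_metric[i] &
          ref$nonspec_metric <= candidates$nonspec_metric[i] &
          (ref$affinity_metric > candidates$affinity_metric[i] |
             ref$nonspec_metric < candidates$nonspec_metric[i]))
  }, logical(1))
  candidates$beyond_frontier <- !dominated_by_ref
  all_pts <- rbind(
    cbind(ref$affinity_metric, ref$nonspec_metric),
    cbind(candidates$affinity_metric, candidates$nonspec_metric))
  Z <- zscore_cols(all_pts)
  Zc <- Z[-seq_len(nrow(ref)), , drop = FALSE]
  ord <- order(-candidates$beyond_frontier, -candidates$affinity_metric,
               candidates$id)
  picked <- ord[1L]
  avail <- setdiff(ord, picked)
  while (length(picked) < min(n, nrow(candidates)) && length(avail) > 0L) {
    dmin <- vapply(avail, function(i) {
      min(sqrt((Zc[picked, 1] - Zc[i, 1])^2 + (Zc[picked, 2] - Zc[i, 2])^2))
    }, numeric(1))
    # prefer non-dominated candidates, then the most spread-out one
    key <- order(-candidates$beyond_frontier[avail], -dmin, candidates$id[avail])
    nxt <- avail[key[1L]]
    picked <- c(picked, nxt)
    avail <- setdiff(avail, nxt)
  }
  out <- candidates[picked, , drop = FALSE]
  rownames(out) <- NULL
  out
}
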