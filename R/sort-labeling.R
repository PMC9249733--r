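# Label assignment from sorted-library deep sequencing: presence/absence
# rules over the 12-sample count tables, occurrence frequencies, log2
# enrichment ratios, residue-level enrichment maps, and the stratified
# master-dataset selection.

SELECTIONS <- c("input", "antigen_pos", "psr_pos", "psr_neg", "ova_pos", "ova_neg")

#' Construct a sort experiment from a long count table
#'
#' @param counts Data.frame with columns `sample_id`, `replicate` (integer),
#'   `selection` (one of input, antigen_pos, psr_pos, psr_neg, ova_pos,
#'   ova_neg), `sequence_id`, `count`. One row per (sample, variant) with
#'   count > 0; zeros may be omitted.
#' @param sequences Optional named character vector mapping `sequence_id` to
#'   the amino-acid sequence; carried along for downstream encoding.
#' @param samples Optional data.frame (`sample_id`, `replicate`, `selection`)
#'   declaring the full sample set, so samples in which no variant was
#'   recovered are still represented; derived from `counts` when omitted.
#' @return An object of class `sort_experiment`.
#' @export
sort_experiment <- function(counts, sequences = NULL, samples = NULL) {
  need <- c("sample_id", "replicate", "selection", "sequence_id", "count")
  if (!all(need %in% names(counts))) {
    stop("counts must have columns: ", paste(need, collapse = ", "))
  }
  counts$replicate <- as.integer(counts$replicate)
  counts$count <- as.numeric(counts$count)
  if (any(counts$count < 0)) stop("negative read counts")
  if (any(!counts$selection %in% SELECTIONS)) {
    stop("unknown selection; expected one of ", paste(SELECTIONS, collapse = ", "))
  }
  if (is.null(samples)) {
    samples <- unique(counts[, c("sample_id", "replicate", "selection")])
  } else {
    samples <- unique(samples[, c("sample_id", "replicate", "selection")])
    samples$replicate <- as.integer(samples$replicate)
    if (!all(counts$sample_id %in% samples$sample_id)) {
      stop("counts reference sample_ids missing from the samples table")
    }
  }
  key <- paste(samples$selection, samples$replicate)
  if (anyDuplicated(key)) stop("more than one sample per (replicate, selection) pair")
  if (!any(samples$selection == "input")) stop("at least one input sample required")
  counts <- counts[counts$count > 0, , drop = FALSE]
  totals <- tapply(counts$count, counts$sample_id, sum)
  samples$total_reads <- as.numeric(totals[samples$sample_id])
  samples$total_reads[is.na(samples$total_reads)] <- 0
  structure(list(counts = counts, samples = samples, sequences = sequences),
            class = "sort_experiment")
}

#' @export
print.sort_experiment <- function(x, ...) {
  cat(sprintf("<sort_experiment: %d samples, %d variants, %s reads>\n",
              nrow(x$samples), length(experiment_variants(x)),
              format(sum(x$samples$total_reads), big.mark = ",")))
  invisible(x)
}

#' All variant ids observed anywhere in an experiment
#' @param experiment A [sort_experiment()].
#' @return Character vector of variant ids.
#' @export
experiment_variants <- function(experiment) {
  sort(unique(experiment$counts$sequence_id))
}

sample_ids_for <- function(experiment, selection, replicate = NULL) {
  s <- experiment$samples
  keep <- s$selection %in% selection
  if (!is.null(replicate)) keep <- keep & s$replicate %in% replicate
  s$sample_id[keep]
}

# variants x samples presence (count > 0) matrix
presence_matrix <- function(experiment, variants = experiment_variants(experiment),
                            sample_ids = experiment$samples$sample_id) {
  m <- matrix(FALSE, nrow = length(variants), ncol = length(sample_ids),
              dimnames = list(variants, sample_ids))
  cc <- experiment$counts
  cc <- cc[cc$sequence_id %in% variants & cc$sample_id %in% sample_ids, ]
  m[cbind(cc$sequence_id, cc$sample_id)] <- TRUE
  m
}

#' Assign antigen-binding labels
#'
#' A variant is labeled `positive` when present (count > 0) in both replicate
#' antigen-positive samples, `discarded` when present in exactly one, and
#' `negative` when present in neither but present in an input sample.
#' Variants absent from all three groups get `NA`.
#'
#' @param experiment A [sort_experiment()] with antigen_pos samples in both
#'   replicates and at least one input sample.
#' @param variants Variant ids to label (default: all observed).
#' @return Named character vector: `positive`, `negative`, `discarded`, or NA.
#' @export
assign_antigen_label <- function(experiment, variants = experiment_variants(experiment)) {
  ag <- sample_ids_for(experiment, "antigen_pos")
  if (length(ag) < 2L) stop("an antigen_pos sample is required in each replicate")
  inp <- sample_ids_for(experiment, "input")
  pm_ag <- presence_matrix(experiment, variants, ag)
  pm_in <- presence_matrix(experiment, variants, inp)
  n_ag <- rowSums(pm_ag)
  in_input <- rowSums(pm_in) > 0
  out <- rep(NA_character_, length(variants))
  out[n_ag == length(ag)] <- "positive"
  out[n_ag > 0 & n_ag < length(ag)] <- "discarded"
  out[n_ag == 0 & in_input] <- "negative"
  names(out) <- variants
  out
}

#' Assign specificity (non-specific binding) labels
#'
#' Over the four non-specific-binding positive samples (PSR and ovalbumin,
#' two replicates each) and the four negative samples: `positive` when present
#' in at least three of the four positive samples and none of the negatives;
#' `negative` when present in at least three of the four negatives and none of
#' the positives; otherwise `unlabeled`.
#'
#' @inheritParams assign_antigen_label
#' @return Named character vector: `positive`, `negative`, or `unlabeled`.
#' @export
assign_specificity_label <- function(experiment,
                                     variants = experiment_variants(experiment)) {
  pos <- sample_ids_for(experiment, c("psr_pos", "ova_pos"))
  neg <- sample_ids_for(experiment, c("psr_neg", "ova_neg"))
  if (length(pos) != 4L || length(neg) != 4L) {
    stop("expected 4 non-specific-binding positive and 4 negative samples")
  }
  n_pos <- rowSums(presence_matrix(experiment, variants, pos))
  n_neg <- rowSums(presence_matrix(experiment, variants, neg))
  out <- rep("unlabeled", length(variants))
  out[n_pos >= 3 & n_neg == 0] <- "positive"
  out[n_neg >= 3 & n_pos == 0] <- "negative"
  names(out) <- variants
  out
}

#' Occurrence frequency or relative abundance
#'
#' In `"occurrence"` mode, the fraction of the given samples in which each
#' variant is present (count > 0). In `"abundance"` mode, the per-sample
#' relative read abundance `count / total_reads` (a variants x samples
#' matrix), the quantity enrichment ratios are built from.
#'
#' @param experiment A [sort_experiment()].
#' @param variants Variant ids (default: all observed).
#' @param sample_ids Sample subset (default: all samples).
#' @param mode `"occurrence"` or `"abundance"`.
#' @return Named numeric vector (occurrence) or matrix (abundance).
#' @export
occurrence_frequency <- function(experiment,
                                 variants = experiment_variants(experiment),
                                 sample_ids = experiment$samples$sample_id,
                                 mode = c("occurrence", "abundance")) {
  mode <- match.arg(mode)
  if (length(sample_ids) == 0L) stop("empty sample subset")
  if (mode == "occurrence") {
    return(rowMeans(presence_matrix(experiment, variants, sample_ids)))
  }
  m <- matrix(0, nrow = length(variants), ncol = length(sample_ids),
              dimnames = list(variants, sample_ids))
  cc <- experiment$counts
  cc <- cc[cc$sequence_id %in% variants & cc$sample_id %in% sample_ids, ]
  m[cbind(cc$sequence_id, cc$sample_id)] <- cc$count
  totals <- experiment$samples$total_reads[match(sample_ids, experiment$samples$sample_id)]
  sweep(m, 2, ifelse(totals > 0, totals, 1), "/")
}

#' Replicate-averaged log2 enrichment ratio
#'
#' Per replicate, `log2(f_out / f_in)` of relative read abundances for the
#' given output selection versus the input; the replicate values are then
#' averaged over replicates where the ratio is defined. When a variant is
#' absent from the input (or output) of every replicate the value is `NA`
#' unless a pseudocount is configured, in which case `pseudocount` reads are
#' added to each count and its sample total.
#'
#' @param experiment A [sort_experiment()].
#' @param output_selection One of the non-input selections.
#' @param variants Variant ids (default: all observed).
#' @param pseudocount Reads added to numerator and denominator counts
#'   (default 0 = off; 0.5 is the conventional choice).
#' @return Named numeric vector (NA where undefined).
#' @export
enrichment_ratio <- function(experiment, output_selection,
                             variants = experiment_variants(experiment),
                             pseudocount = 0) {
  stopifnot(output_selection %in% setdiff(SELECTIONS, "input"))
  reps <- sort(unique(experiment$samples$replicate))
  ers <- matrix(NA_real_, nrow = length(variants), ncol = length(reps),
                dimnames = list(variants, reps))
  for (j in seq_along(reps)) {
    out_id <- sample_ids_for(experiment, output_selection, reps[j])
    in_id <- sample_ids_for(experiment, "input", reps[j])
    if (length(out_id) != 1L || length(in_id) != 1L) next
    cnt <- function(sid) {
      cc <- experiment$counts[experiment$counts$sample_id == sid, ]
      v <- cc$count[match(variants, cc$sequence_id)]
      v[is.na(v)] <- 0
      tot <- experiment$samples$total_reads[experiment$samples$sample_id == sid]
      (v + pseudocount) / (tot + pseudocount)
    }
    f_out <- cnt(out_id)
    f_in <- cnt(in_id)
    ok <- f_out > 0 & f_in > 0
    ers[ok, j] <- log2(f_out[ok] / f_in[ok])
  }
  out <- rowMeans(ers, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}

#' Site-by-residue log2 frequency-ratio matrix between two variant classes
#'
#' For each mutagenized site and residue, the log2 ratio of the residue's
#' frequency at that site among class-A sequences to its frequency among
#' class-B sequences. Residues never observed at a site in either class are
#' `NA` ("unavailable"); a zero denominator is also `NA` unless a
#' pseudocount is configured (added to both class counts, with the class
#' size inflated by `20 * pseudocount`).
#'
#' @param seqs_a,seqs_b Character vectors of equal-length sequences, the two
#'   classes being contrasted (e.g. high- vs low-affinity labels).
#' @param design A [library_design()]; rows of the result are its sites.
#' @param pseudocount Non-negative count added to the residue tallies.
#' @return Numeric matrix, sites x 20 residues, with site labels as rownames.
#' @export
site_enrichment_matrix <- function(seqs_a, seqs_b, design, pseudocount = 0) {
  if (length(seqs_a) == 0L || length(seqs_b) == 0L) stop("both classes must be non-empty")
  idx <- design_site_indices(design)
  labs <- vapply(design$sites, function(s) s$label, character(1))
  m <- matrix(NA_real_, nrow = length(idx), ncol = length(AA_ALPHABET),
              dimnames = list(labs, AA_ALPHABET))
  for (i in seq_along(idx)) {
    ra <- substring(seqs_a, idx[i], idx[i])
    rb <- substring(seqs_b, idx[i], idx[i])
    for (r in AA_ALPHABET) {
      ca <- sum(ra == r)
      cb <- sum(rb == r)
      if (ca == 0 && cb == 0 && pseudocount == 0) next  # never sampled
      fa <- (ca + pseudocount) / (length(ra) + 20 * pseudocount)
      fb <- (cb + pseudocount) / (length(rb) + 20 * pseudocount)
      if (fa > 0 && fb > 0) m[i, r] <- log2(fa / fb)
    }
  }
  m
}

#' Label every observed variant in an experiment
#'
#' Convenience wrapper producing one row per variant with antigen and
#' specificity labels, the cross-sample occurrence frequency, and the
#' replicate-averaged antigen-selection enrichment ratio.
#'
#' @param experiment A [sort_experiment()].
#' @param pseudocount Passed to [enrichment_ratio()].
#' @return Data.frame with columns `id`, `sequence` (NA if the experiment
#'   carries no sequence map), `antigen_label`, `specificity_label`,
#'   `frequency`, `enrichment_antigen`.
#' @export
label_experiment <- function(experiment, pseudocount = 0) {
  v <- experiment_variants(experiment)
  data.frame(
    id = v,
    sequence = if (!is.null(experiment$sequences)) unname(experiment$sequences[v]) else NA_character_,
    antigen_label = unname(assign_antigen_label(experiment, v)),
    specificity_label = unname(assign_specificity_label(experiment, v)),
    frequency = unname(occurrence_frequency(experiment, v)),
    enrichment_antigen = unname(enrichment_ratio(experiment, "antigen_pos", v,
                                                 pseudocount = pseudocount)),
    stringsAsFactors = FALSE
  )
}

#' Select the stratified master dataset
#'
#' Keeps `n` variants split evenly between specificity-positive and
#' specificity-negative strata. Within each stratum, antigen-positive variants
#' are taken first (they are the scarcer label), then remaining slots are
#' filled in order of descending occurrence frequency; ties break by
#' (frequency descending, sequence id lexicographic), so the selection is
#' deterministic.
#'
#' @param labeled Data.frame as produced by [label_experiment()]; rows with a
#'   discarded/NA antigen label or an unlabeled specificity label are dropped
#'   before selection.
#' @param n Even total size (default 4000).
#' @return The selected subset of `labeled` (n rows).
#' @export
select_master_dataset <- function(labeled, n = 4000) {
  if (n %% 2 != 0) stop("n must be even")
  el <- labeled[labeled$antigen_label %in% c("positive", "negative") &
                  labeled$specificity_label %in% c("positive", "negative"), ]
  half <- n / 2
  take <- function(stratum) {
    s <- el[el$specificity_label == stratum, ]
    if (nrow(s) < half) {
      stop("stratum '", stratum, "' has only ", nrow(s),
           " eligible variants; need ", half)
    }
    s <- s[order(s$antigen_label != "positive", -s$frequency, s$id), ]
    s[seq_len(half), ]
  }
  out <- rbind(take("positive"), take("negative"))
  rownames(out) <- NULL
  out
}
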