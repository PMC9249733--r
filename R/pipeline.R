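# End-to-end pipeline orchestration and the deposited-file CSV dialects.
# The R functions are the interface; each stage reads the previous stage's
# outputs, and every run writes a manifest with the seed, configuration, and
# output digests so results are reproducible.

PIPELINE_STAGES <- c("simulate", "label", "encode", "train", "evaluate",
                     "pareto", "scan")

#' Run the analysis pipeline end to end
#'
#' Runs the requested stages in their canonical order
#' (simulate, label, encode, train, evaluate, pareto, scan), each consuming
#' the previous stage's in-memory artifacts, and writes CSV outputs plus a
#' JSON manifest to `out_dir`. Unknown stage names fail before any work.
#'
#' @param stages Character vector, subset of the stage names above.
#' @param out_dir Output directory.
#' @param seed Integer seed driving every stochastic stage.
#' @param design A [library_design()] (default [default_library_design()]).
#' @param config A [sort_config()] for the simulate stage (its seed is
#'   overridden by `seed`).
#' @param encoder_kind Feature family for encode/train (default "onehot").
#' @param master_n Master-dataset size for the label stage; `NULL` keeps all
#'   labeled variants (the synthetic default, where strata are unbalanced).
#' @param holdout_fraction Fraction of labeled variants held out of training
#'   for the evaluate stage (default 0.2).
#' @param near_k Size of the near-frontier set exported by the pareto stage;
#'   `NULL` uses twice the frontier size.
#' @param scan_n Number of novel designs exported by the scan stage.
#' @return A list of artifacts (labeled data, models, evaluation, frontier,
#'   designs, manifest path), invisibly.
#' @export
run_pipeline <- function(stages = PIPELINE_STAGES, out_dir = tempdir(),
                         seed = 7L, design = default_library_design(),
                         config = NULL, encoder_kind = "onehot",
                         master_n = NULL, holdout_fraction = 0.2,
                         near_k = NULL, scan_n = 10L) {
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stop("unknown stage name(s): ", paste(bad, collapse = ", "))
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- list(seed = seed)
  outputs <- character(0)

  if ("simulate" %in% stages) {
    truth <- make_truth(design, seed = seed)
    cfg <- config %||% sort_config()
    cfg$seed <- as.integer(seed)
    art$sim <- simulate_sort(design, truth, cfg)
    paths <- write_fixture(art$sim, out_dir)
    outputs <- c(outputs, paths)
  }
  if ("label" %in% stages) {
    if (is.null(art$sim)) stop("missing upstream artifact: label needs simulate output")
    labeled <- label_experiment(art$sim$experiment)
    if (!is.null(master_n)) labeled <- select_master_dataset(labeled, master_n)
    art$labeled <- labeled
    p <- file.path(out_dir, "labeled.csv")
    write_emi_csv(labeled, p)
    outputs <- c(outputs, labeled = p)
  }
  if ("encode" %in% stages || "train" %in% stages) {
    if (is.null(art$labeled)) stop("missing upstream artifact: encode needs label output")
    lab <- art$labeled
    train_df <- lab[lab$antigen_label %in% c("positive", "negative") &
                      lab$specificity_label %in% c("positive", "negative"), ]
    art$train_df <- train_df
    art$encoder <- feature_encoder(encoder_kind, sequences = train_df$sequence)
    art$X <- encode_features(art$encoder, train_df$sequence)
  }
  if ("train" %in% stages) {
    art$affinity_model <- fit_lda(art$X, art$train_df$antigen_label)
    art$nonspec_model <- fit_lda(art$X, art$train_df$specificity_label)
  }
  if ("evaluate" %in% stages) {
    if (is.null(art$affinity_model)) stop("missing upstream artifact: evaluate needs train output")
    cv_aff <- cross_validate(art$X, art$train_df$antigen_label, "lda", seed = seed)
    cv_ns <- cross_validate(art$X, art$train_df$specificity_label, "lda", seed = seed)
    art$evaluation <- rbind(cbind(property = "affinity", cv_aff$report),
                            cbind(property = "nonspec", cv_ns$report))
    p <- file.path(out_dir, "cv_report.csv")
    utils::write.csv(art$evaluation, p, row.names = FALSE)
    outputs <- c(outputs, cv_report = p)
  }
  if ("pareto" %in% stages) {
    if (is.null(art$affinity_model)) stop("missing upstream artifact: pareto needs train output")
    pts <- data.frame(id = art$train_df$id,
                      affinity_metric = project(art$affinity_model, art$X),
                      nonspec_metric = project(art$nonspec_model, art$X),
                      provenance = "library", stringsAsFactors = FALSE)
    art$points <- pts
    art$frontier <- pareto_front(pts)
    k <- near_k %||% (2L * nrow(art$frontier))
    art$near <- near_frontier(pts, k)
    p <- file.path(out_dir, "frontier.csv")
    utils::write.csv(merge(pts, art$frontier[, c("id", "on_frontier")],
                           by = "id", all.x = TRUE), p, row.names = FALSE)
    outputs <- c(outputs, frontier = p)
  }
  if ("scan" %in% stages) {
    if (is.null(art$frontier)) stop("missing upstream artifact: scan needs pareto output")
    if (encoder_kind == "onehot") {
      # novel mutations need features defined outside the library; refit on
      # physchem features and rebuild the reference frontier in that
      # projection space (projections from different models are not on a
      # common scale)
      scan_enc <- feature_encoder("physchem")
      Xp <- encode_features(scan_enc, art$train_df$sequence)
      aff_m <- fit_lda(Xp, art$train_df$antigen_label)
      ns_m <- fit_lda(Xp, art$train_df$specificity_label)
      ref_front <- pareto_front(data.frame(
        id = art$train_df$id,
        affinity_metric = project(aff_m, Xp),
        nonspec_metric = project(ns_m, Xp), stringsAsFactors = FALSE))
    } else {
      scan_enc <- art$encoder
      aff_m <- art$affinity_model
      ns_m <- art$nonspec_model
      ref_front <- art$frontier
    }
    base_ids <- art$near$id[order(-art$near$affinity_metric)][1]
    bases <- art$train_df[art$train_df$id %in% base_ids, c("id", "sequence")]
    regions <- design$region_map[c("HCDR2", "HCDR3")]
    cands <- scan_single_mutants(bases, regions, scan_enc, aff_m, ns_m)
    art$designs <- select_designs(cands, scan_n, ref_front)
    p <- file.path(out_dir, "designs.csv")
    utils::write.csv(art$designs, p, row.names = FALSE)
    outputs <- c(outputs, designs = p)
  }
  manifest <- list(
    command = "run_pipeline", stages = stages, seed = seed,
    encoder_kind = encoder_kind,
    package_version = as.character(utils::packageVersion("abpareto")),
    outputs = as.list(vapply(outputs, function(f) {
      unname(tools::md5sum(f))
    }, character(1))))
  mp <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  art$manifest <- mp
  invisible(art)
}

#' Write / read labeled datasets in the deposited-file CSV dialect
#'
#' One row per variant with the amino-acid sequence and 1/0 antigen and
#' specificity labels (1 = positive). `read_emi_csv` rejects rows whose
#' sequence carries gaps or non-canonical residues (logged via warning) and
#' errors on non-binary label columns.
#'
#' @param labeled Data.frame with `sequence`, `antigen_label`,
#'   `specificity_label` (either "positive"/"negative"/... strings or 1/0).
#' @param path CSV path.
#' @return `path` (write); a data.frame with columns `sequence`,
#'   `antigen_label`, `specificity_label` coded 1/0 plus the label strings
#'   (read).
#' @export
write_emi_csv <- function(labeled, path) {
  to01 <- function(v) {
    if (is.numeric(v)) return(v)
    ifelse(v == "positive", 1L, ifelse(v == "negative", 0L, NA_integer_))
  }
  out <- data.frame(sequence = labeled$sequence,
                    antigen_label = to01(labeled$antigen_label),
                    specificity_label = to01(labeled$specificity_label))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_emi_csv
#' @export
read_emi_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sequence", "antigen_label", "specificity_label")
  if (!all(need %in% names(df))) {
    stop("missing columns in ", path, "; need ", paste(need, collapse = ", "))
  }
  for (col in need[-1]) {
    v <- df[[col]]
    if (!all(is.na(v) | v %in% c(0, 1))) stop("non-binary labels in column ", col)
  }
  chars <- strsplit(toupper(df$sequence), "", fixed = TRUE)
  bad <- vapply(chars, function(ch) any(!ch %in% AA_ALPHABET), logical(1))
  if (any(bad)) {
    warning(sum(bad), " row(s) with gaps or unidentified residues rejected")
    df <- df[!bad, , drop = FALSE]
  }
  df$antigen_str <- ifelse(df$antigen_label == 1, "positive", "negative")
  df$specificity_str <- ifelse(df$specificity_label == 1, "positive", "negative")
  rownames(df) <- NULL
  df
}

#' Read a binding-measurements table
#'
#' A CSV with a `sequence` (or `id`) column and one or more numeric
#' measurement columns (e.g. normalized antigen and ovalbumin binding for
#' individually characterized clones), used to correlate model projections
#' with experimental measurements in replication mode.
#'
#' @param path CSV path.
#' @return Data.frame; measurement columns are numeric.
#' @export
read_binding_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!any(c("sequence", "id") %in% names(df))) {
    stop("binding table needs a 'sequence' or 'id' column: ", path)
  }
  meas <- setdiff(names(df), c("sequence", "id"))
  if (length(meas) == 0L) stop("binding table has no measurement columns")
  for (m in meas) {
    df[[m]] <- as.numeric(df[[m]])
  }
  df
}
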