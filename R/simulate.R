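# Ground-truth-known simulator for the sort-and-sequence study design: a
# combinatorial CDR library over a synthetic parent VH, correlated latent
# affinity / non-specific-binding landscapes, quantile sort gates, and
# multinomial sequencing counts in duplicate (12 samples).

# Synthetic 115-residue VH-like parent (a generic human VH3 framework
# scaffold; NOT the study antibody, whose sequence is not public in print).
SYNTHETIC_PARENT_VH <- paste0(
  "EVQLLESGGGLVQPGGSLRLSCAASGFTFSSYYMSWVRQAPGKGLEWVSR",
  "ISPRRGGSTYYADSVKGRFTISRDNSKNTLYLQMNSLRAEDTAVAYWAKA",
  "GYDYSPYGYWGQGTL")

#' Default combinatorial library design
#'
#' Eight mutagenized sites on a synthetic 115-residue VH parent — one in
#' HCDR1, four in HCDR2, three in HCDR3 — each sampling the parent residue
#' plus five alternatives (6^8 = 1,679,616 theoretical variants, ~1.7e6).
#' Site labels follow the Kabat-style display convention.
#'
#' @return A [library_design()].
#' @export
default_library_design <- function() {
  sites <- list(
    site_spec(33, c("Y", "A", "D", "S", "T", "V"), "H33"),
    site_spec(50, c("R", "A", "D", "G", "Q", "S"), "H50"),
    site_spec(54, c("R", "A", "E", "G", "N", "S"), "H54"),
    site_spec(55, c("R", "D", "G", "K", "Q", "T"), "H55"),
    site_spec(56, c("G", "A", "D", "N", "S", "T"), "H56"),
    site_spec(95, c("A", "D", "E", "G", "S", "V"), "H95"),
    site_spec(97, c("W", "A", "F", "G", "S", "Y"), "H97"),
    site_spec(102, c("Y", "A", "D", "E", "S", "V"), "H102")
  )
  library_design(
    vh_sequence(SYNTHETIC_PARENT_VH, id = "parent"),
    sites,
    region_map = list(HCDR1 = 31:35, HCDR2 = 50:65, HCDR3 = 95:102)
  )
}

#' Draw a ground-truth effect model for a library design
#'
#' Per site and non-parent residue, an (affinity, non-specificity) effect
#' pair is drawn from a bivariate normal with the configured correlation, so
#' that affinity-raising residues tend to also raise non-specific binding —
#' the tradeoff structure the sorted libraries exhibit. Parent residues have
#' effect zero at every site (the parent is the reference), and a variant's
#' latent property is the sum of its site effects plus N(0, noise_sd) noise.
#'
#' @param design A [library_design()].
#' @param effect_sd Standard deviation of per-residue effects (default 1).
#' @param effect_correlation Correlation between the affinity and
#'   non-specificity effect of a residue, in `[-1, 1]` (default 0.6).
#' @param noise_sd Variant-level latent noise (default 0.5).
#' @param display_noise_sd Per-sample display/measurement noise added to the
#'   gated signal (default 0.5).
#' @param seed Integer seed.
#' @return An object of class `truth_model` with an `effects` data.frame
#'   (site index, residue, affinity_effect, nonspec_effect).
#' @export
make_truth <- function(design, effect_sd = 1, effect_correlation = 0.6,
                       noise_sd = 0.5, display_noise_sd = 0.5, seed = 1L) {
  if (abs(effect_correlation) > 1) stop("|effect_correlation| must be <= 1")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  rows <- list()
  for (s in design$sites) {
    parent_res <- substring(design$parent, s$index, s$index)
    for (r in s$allowed_residues) {
      if (r == parent_res) {
        eff <- c(0, 0)
      } else {
        z1 <- stats::rnorm(1)
        z2 <- stats::rnorm(1)
        eff <- effect_sd * c(z1, effect_correlation * z1 +
                               sqrt(1 - effect_correlation^2) * z2)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        site = s$index, residue = r,
        affinity_effect = eff[1], nonspec_effect = eff[2],
        stringsAsFactors = FALSE)
    }
  }
  structure(list(effects = do.call(rbind, rows),
                 effect_correlation = effect_correlation,
                 noise_sd = noise_sd, display_noise_sd = display_noise_sd,
                 seed = seed),
            class = "truth_model")
}

# additive latent values (no noise) for a set of sequences
truth_additive <- function(truth, design, sequences) {
  idx <- design_site_indices(design)
  aff <- numeric(length(sequences))
  ns <- numeric(length(sequences))
  eff <- truth$effects
  for (j in seq_along(idx)) {
    res <- substring(sequences, idx[j], idx[j])
    sub <- eff[eff$site == idx[j], ]
    k <- match(res, sub$residue)
    if (anyNA(k)) stop("sequence carries a residue outside the design at site ", idx[j])
    aff <- aff + sub$affinity_effect[k]
    ns <- ns + sub$nonspec_effect[k]
  }
  data.frame(affinity = aff, nonspec = ns)
}

#' Sort-gate configuration
#'
#' Defaults are the study conditions: antigen gates keep the top 50% of
#' antigen-positive cells; non-specific-binding gates keep the top 25% and
#' the bottom 10% of binders; sorting in duplicate; sequencing depth 1e5
#' reads per sample; log-normal initial variant abundances; a library sample
#' of 5,000 distinct variants (sparse sampling of the 1.7e6 design space).
#'
#' @param antigen_keep_top,nonspec_pos_keep_top,nonspec_neg_keep_bottom Gate
#'   quantile fractions in (0, 1).
#' @param depth Sequencing reads per sample (>= 0).
#' @param n_variants Number of distinct library variants to draw.
#' @param abundance_meanlog,abundance_sdlog Log-normal abundance parameters.
#' @param reagent_noise_sd Reagent-specific noise: the two pseudo-reagents
#'   (emulating PSR and ovalbumin) share the latent non-specificity plus an
#'   independent per-variant offset of this SD.
#' @param replicates Number of sort replicates (default 2).
#' @param seed Integer seed for the whole simulation.
#' @return A list of class `sort_config`.
#' @export
sort_config <- function(antigen_keep_top = 0.50, nonspec_pos_keep_top = 0.25,
                        nonspec_neg_keep_bottom = 0.10, depth = 1e5,
                        n_variants = 5000L, abundance_meanlog = 0,
                        abundance_sdlog = 1, reagent_noise_sd = 0.25,
                        replicates = 2L, seed = 7L) {
  q <- c(antigen_keep_top, nonspec_pos_keep_top, nonspec_neg_keep_bottom)
  if (any(q <= 0 | q >= 1)) stop("gate quantiles must lie in (0, 1)")
  if (depth < 0) stop("depth must be >= 0")
  structure(list(antigen_keep_top = antigen_keep_top,
                 nonspec_pos_keep_top = nonspec_pos_keep_top,
                 nonspec_neg_keep_bottom = nonspec_neg_keep_bottom,
                 depth = depth, n_variants = as.integer(n_variants),
                 abundance_meanlog = abundance_meanlog,
                 abundance_sdlog = abundance_sdlog,
                 reagent_noise_sd = reagent_noise_sd,
                 replicates = as.integer(replicates), seed = as.integer(seed)),
            class = "sort_config")
}

# abundance-weighted top/bottom gate: minimal set of cells covering the
# requested fraction of the sorted population
gate_keep <- function(signal, weights, fraction, side = c("top", "bottom")) {
  side <- match.arg(side)
  ord <- order(signal, decreasing = (side == "top"))
  cw <- cumsum(weights[ord]) / sum(weights)
  k <- which(cw >= fraction)[1]
  kept <- logical(length(signal))
  kept[ord[seq_len(k)]] <- TRUE
  kept
}

#' Simulate a 12-sample sort-and-sequence experiment
#'
#' Draws a variant library and log-normal abundances, computes latent
#' affinity and non-specificity per variant from the truth model (additive
#' site effects plus variant noise), applies abundance-weighted quantile
#' gates per sample with per-sample display noise, and draws multinomial
#' sequencing counts at the configured depth for the input, antigen-positive,
#' and the four non-specific-binding samples in each replicate.
#'
#' @param design A [library_design()].
#' @param truth A [make_truth()] model.
#' @param config A [sort_config()].
#' @return List with `experiment` (a [sort_experiment()]), `truth_table`
#'   (data.frame: id, sequence, latent_affinity, latent_nonspec, abundance),
#'   and the inputs, class `sort_simulation`.
#' @export
simulate_sort <- function(design, truth, config = sort_config()) {
  stopifnot(inherits(design, "library_design"), inherits(truth, "truth_model"),
            inherits(config, "sort_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  seqs <- sample_library_variants(design, config$n_variants)
  nv <- length(seqs)
  ids <- sprintf("v%05d", seq_len(nv))
  add <- truth_additive(truth, design, seqs)
  lat_aff <- add$affinity + stats::rnorm(nv, 0, truth$noise_sd)
  lat_ns <- add$nonspec + stats::rnorm(nv, 0, truth$noise_sd)
  abund <- stats::rlnorm(nv, config$abundance_meanlog, config$abundance_sdlog)
  # two pseudo-reagents share the latent non-specificity with reagent noise
  reagent <- list(psr = lat_ns + stats::rnorm(nv, 0, config$reagent_noise_sd),
                  ova = lat_ns + stats::rnorm(nv, 0, config$reagent_noise_sd))
  dn <- truth$display_noise_sd
  rows <- list()
  add_sample <- function(selection, rep_i, kept) {
    probs <- abund * kept
    sid <- paste0(selection, "_r", rep_i)
    if (config$depth > 0 && sum(probs) > 0) {
      cnt <- drop(stats::rmultinom(1, config$depth, probs))
      nz <- cnt > 0
      rows[[length(rows) + 1L]] <<- data.frame(
        sample_id = sid, replicate = rep_i, selection = selection,
        sequence_id = ids[nz], count = cnt[nz], stringsAsFactors = FALSE)
    } else {
      # valid degenerate sample: zero depth yields an empty count set
      rows[[length(rows) + 1L]] <<- data.frame(
        sample_id = sid, replicate = rep_i, selection = selection,
        sequence_id = ids[1], count = 0, stringsAsFactors = FALSE)
    }
  }
  for (r in seq_len(config$replicates)) {
    add_sample("input", r, rep(TRUE, nv))
    sig_ag <- lat_aff + stats::rnorm(nv, 0, dn)
    add_sample("antigen_pos", r, gate_keep(sig_ag, abund, config$antigen_keep_top, "top"))
    for (rg in names(reagent)) {
      sig_pos <- reagent[[rg]] + stats::rnorm(nv, 0, dn)
      sig_neg <- reagent[[rg]] + stats::rnorm(nv, 0, dn)
      add_sample(paste0(rg, "_pos"), r,
                 gate_keep(sig_pos, abund, config$nonspec_pos_keep_top, "top"))
      add_sample(paste0(rg, "_neg"), r,
                 gate_keep(sig_neg, abund, config$nonspec_neg_keep_bottom, "bottom"))
    }
  }
  counts <- do.call(rbind, rows)
  sequences <- stats::setNames(seqs, ids)
  experiment <- sort_experiment(counts, sequences = sequences)
  truth_table <- data.frame(id = ids, sequence = seqs,
                            latent_affinity = lat_aff, latent_nonspec = lat_ns,
                            abundance = abund, stringsAsFactors = FALSE)
  structure(list(experiment = experiment, truth_table = truth_table,
                 design = design, truth = truth, config = config),
            class = "sort_simulation")
}

#' Write a simulated experiment to plain-text fixture files
#'
#' Emits `counts.csv` (the 12-sample long count table), `sequences.csv`,
#' `truth.csv` (variant latents, used only by evaluation code — the labeling
#' and modeling stages read the counts alone), `design.yaml`, and
#' `manifest.json` recording the seeds and configuration, so the fixture can
#' be regenerated byte-identically.
#'
#' @param sim A [simulate_sort()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  stopifnot(inherits(sim, "sort_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.csv"),
             sequences = file.path(dir, "sequences.csv"),
             truth = file.path(dir, "truth.csv"),
             design = file.path(dir, "design.yaml"),
             manifest = file.path(dir, "manifest.json"))
  utils::write.csv(sim$experiment$counts, paths["counts"], row.names = FALSE)
  utils::write.csv(data.frame(id = names(sim$experiment$sequences),
                              sequence = unname(sim$experiment$sequences)),
                   paths["sequences"], row.names = FALSE)
  utils::write.csv(sim$truth_table, paths["truth"], row.names = FALSE)
  write_design_yaml(sim$design, paths["design"])
  manifest <- list(
    seed = sim$config$seed,
    truth_seed = sim$truth$seed,
    config = unclass(sim$config),
    truth_params = list(effect_correlation = sim$truth$effect_correlation,
                        noise_sd = sim$truth$noise_sd,
                        display_noise_sd = sim$truth$display_noise_sd),
    package_version = as.character(utils::packageVersion("abpareto")),
    files = as.list(basename(paths)))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Write / read a library design as YAML
#' @param design A [library_design()].
#' @param path YAML file path.
#' @return `path` (write) or a [library_design()] (read).
#' @export
write_design_yaml <- function(design, path) {
  obj <- list(
    parent = as.character(design$parent),
    parent_id = attr(design$parent, "id"),
    sites = lapply(design$sites, function(s) {
      list(index = s$index, label = s$label,
           allowed_residues = paste(s$allowed_residues, collapse = ""))
    }),
    region_map = lapply(design$region_map, function(r) as.integer(range(r)))
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_design_yaml
#' @export
read_design_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  sites <- lapply(obj$sites, function(s) {
    site_spec(s$index, strsplit(s$allowed_residues, "")[[1]], s$label)
  })
  rm_ <- if (length(obj$region_map)) {
    lapply(obj$region_map, function(r) seq(r[[1]], r[[2]]))
  } else NULL
  library_design(vh_sequence(obj$parent, id = obj$parent_id %||% "parent"),
                 sites, region_map = rm_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a fixture count table back into a sort experiment
#' @param dir Fixture directory written by [write_fixture()].
#' @return A [sort_experiment()].
#' @export
read_fixture_experiment <- function(dir) {
  counts <- utils::read.csv(file.path(dir, "counts.csv"), stringsAsFactors = FALSE)
  seqs <- utils::read.csv(file.path(dir, "sequences.csv"), stringsAsFactors = FALSE)
  sort_experiment(counts, sequences = stats::setNames(seqs$sequence, seqs$id))
}
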