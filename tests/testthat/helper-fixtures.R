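# Shared fixtures, all built in code.

# Small 10-residue design with three mutagenized sites.
tiny_design <- function() {
  library_design(
    vh_sequence("ACDEFGHIKL", id = "tiny-parent"),
    list(site_spec(2, c("C", "A", "S"), "T2"),
         site_spec(5, c("F", "Y", "W", "L"), "T5"),
         site_spec(8, c("I", "V", "L"), "T8")),
    region_map = list(R1 = 1:4, R2 = 5:10)
  )
}

# Build a sort_experiment from a presence/abundance matrix: rows = variants,
# columns = the 12 standard samples. Entries are read counts.
experiment_from_counts <- function(count_matrix, sequences = NULL) {
  sel <- c("input", "antigen_pos", "psr_pos", "psr_neg", "ova_pos", "ova_neg")
  samples <- expand.grid(selection = sel, replicate = 1:2,
                         stringsAsFactors = FALSE)
  samples$sample_id <- paste0(samples$selection, "_r", samples$replicate)
  stopifnot(ncol(count_matrix) == nrow(samples))
  colnames(count_matrix) <- samples$sample_id
  rows <- do.call(rbind, lapply(seq_len(nrow(samples)), function(j) {
    nz <- count_matrix[, j] > 0
    if (!any(nz)) return(NULL)
    data.frame(sample_id = samples$sample_id[j], replicate = samples$replicate[j],
               selection = samples$selection[j],
               sequence_id = rownames(count_matrix)[nz],
               count = count_matrix[nz, j], stringsAsFactors = FALSE)
  }))
  sort_experiment(rows, sequences = sequences, samples = samples)
}

# One shared default-condition simulation (seed 7), reused by several tests
# and the end-to-end acceptance block; built once per test run.
.sim_cache <- new.env(parent = emptyenv())
default_simulation <- function() {
  if (is.null(.sim_cache$sim)) {
    design <- default_library_design()
    truth <- make_truth(design, seed = 7)
    .sim_cache$sim <- simulate_sort(design, truth, sort_config(seed = 7))
    .sim_cache$labeled <- label_experiment(.sim_cache$sim$experiment)
  }
  list(sim = .sim_cache$sim, labeled = .sim_cache$labeled)
}

# Well-separated two-cluster toy set for classifier sanity checks.
toy_clusters <- function(n_per = 20, d = 3, gap = 10, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * d, 0, 0.1), n_per, d),
             matrix(rnorm(n_per * d, gap, 0.1), n_per, d))
  list(X = X, y = rep(c("negative", "positive"), each = n_per))
}
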