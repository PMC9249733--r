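# Feature encoders: position-wise one-hot vectors, the 26-descriptor
# physicochemical vector, and 64-unit recurrent-network (mLSTM) embeddings.
# All encoders are pure: given a fitted encoder state, encoding is
# deterministic and has no side effects.

#' Fit a position-wise one-hot encoder
#'
#' Per sequence position, one indicator column is created for each residue
#' observed at that position in the fitting set (data-driven categories).
#' Invariant positions therefore contribute a single always-one column, and
#' encoding an unseen residue at a position is an error: a one-hot model
#' cannot represent mutations outside the fitted library.
#'
#' @param sequences Character vector of equal-length sequences.
#' @return An object of class `onehot_encoder` holding the category sets.
#' @export
onehot_fit <- function(sequences) {
  sequences <- as.character(sequences)
  chars <- strsplit(sequences, "", fixed = TRUE)
  L <- unique(lengths(chars))
  if (length(L) != 1L) stop("sequences must be equal length")
  m <- matrix(unlist(chars), nrow = length(chars), byrow = TRUE)
  categories <- lapply(seq_len(L), function(j) sort(unique(m[, j])))
  structure(list(length = L, categories = categories,
                 encoder_id = "onehot"),
            class = "onehot_encoder")
}

#' Encode sequences with a fitted one-hot encoder
#'
#' @param encoder An [onehot_fit()] result.
#' @param sequences Character vector of sequences of the fitted length.
#' @return Numeric matrix, one row per sequence; each row sums to the
#'   sequence length. Column names are `p<position>.<residue>`.
#' @export
onehot_encode <- function(encoder, sequences) {
  stopifnot(inherits(encoder, "onehot_encoder"))
  sequences <- as.character(sequences)
  chars <- strsplit(sequences, "", fixed = TRUE)
  if (any(lengths(chars) != encoder$length)) {
    stop("sequence length differs from the fitted length ", encoder$length)
  }
  cols <- unlist(lapply(seq_len(encoder$length), function(j) {
    paste0("p", j, ".", encoder$categories[[j]])
  }))
  offs <- c(0L, cumsum(lengths(encoder$categories)))
  X <- matrix(0, nrow = length(sequences), ncol = length(cols),
              dimnames = list(names(sequences), cols))
  for (i in seq_along(sequences)) {
    ch <- chars[[i]]
    for (j in seq_len(encoder$length)) {
      k <- match(ch[j], encoder$categories[[j]])
      if (is.na(k)) {
        stop("unsupported encoder: residue '", ch[j], "' at position ", j,
             " was not observed in the one-hot fitting set")
      }
      X[i, offs[j] + k] <- 1
    }
  }
  X
}

net_charge_at_ph <- function(counts_pos, counts_neg, ph) {
  pos <- sum(counts_pos / (1 + 10^(ph - PKA_SET$positive[names(counts_pos)])))
  neg <- sum(counts_neg / (1 + 10^(PKA_SET$negative[names(counts_neg)] - ph)))
  pos - neg
}

#' Isoelectric point of a sequence
#'
#' Bisection on the Henderson-Hasselbalch net-charge function over pH 0-14
#' using the configured (Bjellqvist/ExPASy-style) pKa set, to a net-charge
#' tolerance of 1e-4. Both termini are counted.
#'
#' @param sequence Character scalar amino-acid sequence.
#' @return The pH at which the modeled net charge is zero.
#' @export
isoelectric_point <- function(sequence) {
  ch <- strsplit(as.character(sequence), "")[[1]]
  if (length(ch) == 0L) stop("empty sequence")
  counts_pos <- c(Nterm = 1, K = sum(ch == "K"), R = sum(ch == "R"), H = sum(ch == "H"))
  counts_neg <- c(Cterm = 1, D = sum(ch == "D"), E = sum(ch == "E"),
                  C = sum(ch == "C"), Y = sum(ch == "Y"))
  lo <- 0; hi <- 14
  repeat {
    mid <- (lo + hi) / 2
    q <- net_charge_at_ph(counts_pos, counts_neg, mid)
    if (abs(q) < 1e-4 || (hi - lo) < 1e-10) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
}

#' Physicochemical descriptor vector (26 features)
#'
#' Features 1-20: counts of each canonical residue in alphabetical one-letter
#' order; 21-24: counts of hydrophobic (A,I,L,F,V), amphipathic (W,Y,M),
#' polar (Q,N,S,T,C,M), and charged (K,R,D,E,H) residues (methionine belongs
#' to two sets by design); 25: isoelectric point; 26: mean Kyte-Doolittle
#' hydropathy.
#'
#' @param sequences Character vector of sequences (any lengths).
#' @return Numeric matrix, one row per sequence, 26 named columns.
#' @export
physchem_encode <- function(sequences) {
  sequences <- as.character(sequences)
  if (any(nchar(sequences) == 0L)) stop("empty sequence")
  assert_residues(sequences)
  out <- t(vapply(sequences, function(s) {
    ch <- strsplit(s, "")[[1]]
    counts <- vapply(AA_ALPHABET, function(a) sum(ch == a), numeric(1))
    classes <- vapply(AA_CLASS_SETS, function(set) sum(ch %in% set), numeric(1))
    c(counts, classes,
      pI = isoelectric_point(s),
      hydropathy = mean(KD_HYDROPATHY[ch]))
  }, numeric(26)))
  colnames(out) <- c(paste0("n_", AA_ALPHABET), names(AA_CLASS_SETS),
                     "pI", "kd_hydropathy")
  rownames(out) <- names(sequences)
  out
}

## ---- 64-unit recurrent (mLSTM) embedder -----------------------------------

#' Initialize (or load) mLSTM embedder weights
#'
#' The embedder is a single-layer multiplicative LSTM over one-hot residue
#' inputs whose mean hidden state is the sequence representation. Weights are
#' either drawn from a seeded normal initialization (for structural testing
#' and simulation work) or loaded from a JSON weight file produced by
#' [save_embedder_weights()] (e.g. converted pretrained weights).
#'
#' @param units Hidden-state size (default 64).
#' @param seed Integer seed for random initialization.
#' @param file Optional path to a JSON weight file; overrides random init.
#' @return An object of class `mlstm_weights`.
#' @export
mlstm_weights <- function(units = 64L, seed = 1L, file = NULL) {
  if (!is.null(file)) {
    w <- jsonlite::read_json(file, simplifyVector = TRUE)
    w <- lapply(w, as.matrix)
    dims_ok <- all(vapply(c("Wmx", "Wx"), function(k) ncol(w[[k]]) == 20L, logical(1))) &&
      nrow(w$Wmx) == nrow(w$Wmh) && nrow(w$Wx) == 4 * nrow(w$Wmx) &&
      ncol(w$Wm) == nrow(w$Wmx) && nrow(w$b) == 4 * nrow(w$Wmx)
    if (!dims_ok) stop("weight-file dimension mismatch: ", file)
    units <- nrow(w$Wmx)
    return(structure(c(w, list(units = units)), class = "mlstm_weights"))
  }
  units <- as.integer(units)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  rnd <- function(r, c) matrix(stats::rnorm(r * c, sd = 1 / sqrt(c)), r, c)
  structure(list(
    Wmx = rnd(units, 20L),       # multiplicative input path
    Wmh = rnd(units, units),     # multiplicative hidden path
    Wx = rnd(4L * units, 20L),   # gates (i, f, o, u) from input
    Wm = rnd(4L * units, units), # gates from the multiplicative state
    b = matrix(0, 4L * units, 1L),
    units = units
  ), class = "mlstm_weights")
}

#' Save embedder weights to a JSON file
#' @param weights An [mlstm_weights()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_embedder_weights <- function(weights, path) {
  w <- weights[c("Wmx", "Wmh", "Wx", "Wm", "b")]
  jsonlite::write_json(lapply(w, unclass), path, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Embed sequences with the recurrent embedder
#'
#' Runs the mLSTM over each sequence (one-hot residue inputs) and returns the
#' mean over positions of the hidden state: one row of `units` (default 64)
#' numeric features per sequence. Deterministic for fixed weights and
#' order-sensitive (permuting a sequence changes its embedding).
#'
#' @param sequences Character vector of sequences (lengths may differ).
#' @param weights An [mlstm_weights()] object.
#' @return Numeric matrix, sequences x units, columns `e1..e<units>`.
#' @export
embed_sequences <- function(sequences, weights) {
  stopifnot(inherits(weights, "mlstm_weights"))
  sequences <- as.character(sequences)
  assert_residues(sequences)
  u <- weights$units
  sigm <- function(z) 1 / (1 + exp(-z))
  # group by length so each group runs as batched matrix ops
  lens <- nchar(sequences)
  out <- matrix(0, length(sequences), u,
                dimnames = list(names(sequences), paste0("e", seq_len(u))))
  for (L in unique(lens)) {
    rows <- which(lens == L)
    chars <- strsplit(sequences[rows], "", fixed = TRUE)
    n <- length(rows)
    h <- matrix(0, u, n)
    cstate <- matrix(0, u, n)
    hsum <- matrix(0, u, n)
    for (t in seq_len(L)) {
      x <- matrix(0, 20L, n)
      x[cbind(match(vapply(chars, `[`, character(1), t), AA_ALPHABET), seq_len(n))] <- 1
      m <- (weights$Wmx %*% x) * (weights$Wmh %*% h)
      z <- weights$Wx %*% x + weights$Wm %*% m + matrix(weights$b, u * 4L, n)
      i <- sigm(z[seq_len(u), , drop = FALSE])
      f <- sigm(z[u + seq_len(u), , drop = FALSE])
      o <- sigm(z[2L * u + seq_len(u), , drop = FALSE])
      g <- tanh(z[3L * u + seq_len(u), , drop = FALSE])
      cstate <- f * cstate + i * g
      h <- o * tanh(cstate)
      hsum <- hsum + h
    }
    out[rows, ] <- t(hsum / L)
  }
  out
}

#' Build a reusable encoder object
#'
#' Uniform front end over the three feature families, so models can record
#' which encoder produced their training matrix and re-encode unseen
#' sequences identically.
#'
#' @param kind `"onehot"`, `"physchem"`, or `"embedding"`.
#' @param sequences Fitting set (required for one-hot).
#' @param weights [mlstm_weights()] for the embedding encoder (a seed-1
#'   random initialization by default).
#' @return An object of class `ab_encoder` with an `encode(sequences)` use
#'   via [encode_features()].
#' @export
feature_encoder <- function(kind = c("onehot", "physchem", "embedding"),
                            sequences = NULL, weights = NULL) {
  kind <- match.arg(kind)
  enc <- switch(kind,
    onehot = {
      if (is.null(sequences)) stop("one-hot encoder requires a fitting set")
      onehot_fit(sequences)
    },
    physchem = NULL,
    embedding = if (is.null(weights)) mlstm_weights() else weights
  )
  structure(list(kind = kind, state = enc, encoder_id = kind),
            class = "ab_encoder")
}

#' Encode sequences with an encoder object
#' @param encoder A [feature_encoder()].
#' @param sequences Character vector of sequences.
#' @return Numeric feature matrix, one row per sequence.
#' @export
encode_features <- function(encoder, sequences) {
  stopifnot(inherits(encoder, "ab_encoder"))
  switch(encoder$kind,
    onehot = onehot_encode(encoder$state, sequences),
    physchem = physchem_encode(sequences),
    embedding = embed_sequences(sequences, encoder$state)
  )
}
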