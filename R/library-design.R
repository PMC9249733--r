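# Sequence and library-design data model: parent VH sequence, mutagenized
# sites, variant/parent diffs, off-design rates, and sequence I/O.

assert_residues <- function(x, what = "sequence") {
  chars <- strsplit(x, "", fixed = TRUE)
  bad <- vapply(chars, function(ch) any(!ch %in% AA_ALPHABET), logical(1))
  if (any(bad)) {
    stop(what, " contains characters outside the canonical amino-acid ",
         "alphabet (ACDEFGHIKLMNPQRSTVWY): record(s) ",
         paste(which(bad), collapse = ", "))
  }
  invisible(x)
}

#' Construct a VH sequence record
#'
#' A validated amino-acid sequence over the 20-canonical-residue alphabet.
#' Gap characters and ambiguity codes (e.g. `X`) are rejected.
#'
#' @param residues Character scalar, the amino-acid sequence.
#' @param id Identifier; defaults to the sequence itself.
#' @return An object of class `vh_sequence` (a character scalar with an
#'   `id` attribute).
#' @export
vh_sequence <- function(residues, id = residues) {
  stopifnot(is.character(residues), length(residues) == 1L, nchar(residues) > 0L)
  assert_residues(residues)
  structure(residues, id = id, class = "vh_sequence")
}

#' @export
print.vh_sequence <- function(x, ...) {
  cat(sprintf("<vh_sequence %s: %d aa>\n%s\n", attr(x, "id"), nchar(x),
              unclass(x)))
  invisible(x)
}

#' Define a mutagenized site
#'
#' @param index 1-based position in the parent sequence.
#' @param allowed_residues Character vector of residues sampled at the site;
#'   must include the parent residue (checked by [library_design()]).
#' @param label Display label (e.g. Kabat-style "H33"); purely cosmetic.
#' @return A list of class `site_spec`.
#' @export
site_spec <- function(index, allowed_residues, label = paste0("S", index)) {
  stopifnot(length(index) == 1L, index >= 1L, length(allowed_residues) >= 1L)
  allowed_residues <- unique(toupper(allowed_residues))
  assert_residues(allowed_residues, "allowed_residues")
  structure(list(index = as.integer(index), label = label,
                 allowed_residues = allowed_residues),
            class = "site_spec")
}

#' Construct a combinatorial library design
#'
#' A parent sequence plus an ordered set of mutagenized sites, each with its
#' allowed residue set. Site indices must be strictly increasing and each
#' site's allowed set must contain the parent residue.
#'
#' @param parent A [vh_sequence()] (or character scalar, coerced).
#' @param sites List of [site_spec()] objects.
#' @param region_map Optional named list of integer index vectors (e.g.
#'   `list(HCDR2 = 50:58)`) used by the mutational scan.
#' @return An object of class `library_design`.
#' @export
library_design <- function(parent, sites, region_map = NULL) {
  if (!inherits(parent, "vh_sequence")) parent <- vh_sequence(parent)
  stopifnot(is.list(sites), length(sites) >= 1L)
  idx <- vapply(sites, function(s) s$index, integer(1))
  if (any(diff(idx) <= 0)) stop("site indices must be strictly increasing and unique")
  if (max(idx) > nchar(parent)) stop("site index exceeds parent length")
  pres <- substring(parent, idx, idx)
  ok <- mapply(function(s, p) p %in% s$allowed_residues, sites, pres)
  if (!all(ok)) {
    stop("parent residue missing from allowed set at site(s) ",
         paste(idx[!ok], collapse = ", "))
  }
  if (!is.null(region_map)) {
    stopifnot(is.list(region_map), !is.null(names(region_map)))
    if (any(unlist(region_map) > nchar(parent))) stop("region_map index exceeds parent length")
  }
  structure(list(parent = parent, sites = sites, region_map = region_map),
            class = "library_design")
}

#' @export
print.library_design <- function(x, ...) {
  cat(sprintf("<library_design: parent %d aa, %d sites, diversity %s>\n",
              nchar(x$parent), length(x$sites),
              format(theoretical_diversity(x), big.mark = ",")))
  for (s in x$sites) {
    cat(sprintf("  %s (pos %d): %s\n", s$label, s$index,
                paste(s$allowed_residues, collapse = "")))
  }
  invisible(x)
}

design_site_indices <- function(design) {
  vapply(design$sites, function(s) s$index, integer(1))
}

#' Theoretical diversity of a library design
#'
#' Product over sites of the allowed-residue set sizes: the number of distinct
#' protein sequences the combinatorial design can encode.
#'
#' @param design A [library_design()].
#' @return A numeric count (can exceed integer range for large designs).
#' @examples
#' # An 8-site design with 6 residues per site encodes 6^8 = 1,679,616
#' # variants, i.e. ~1.7e6.
#' @export
theoretical_diversity <- function(design) {
  stopifnot(inherits(design, "library_design"))
  prod(vapply(design$sites, function(s) length(s$allowed_residues), numeric(1)))
}

#' Mutations of a sequence relative to the design parent
#'
#' Positional diff against the parent; each difference is reported with its
#' site index, parent residue, observed residue, and whether the position is
#' one of the design's mutagenized sites.
#'
#' @param seq A [vh_sequence()] or character scalar, same length as the parent.
#' @param design A [library_design()].
#' @return A data.frame with columns `index`, `parent`, `observed`,
#'   `on_design` (logical), zero rows for the parent itself.
#' @export
mutations_from_parent <- function(seq, design) {
  stopifnot(inherits(design, "library_design"))
  s <- as.character(seq)
  p <- as.character(design$parent)
  if (nchar(s) != nchar(p)) {
    stop("malformed record: sequence length ", nchar(s),
         " differs from parent length ", nchar(p))
  }
  sc <- strsplit(s, "")[[1]]
  pc <- strsplit(p, "")[[1]]
  d <- which(sc != pc)
  data.frame(index = d, parent = pc[d], observed = sc[d],
             on_design = d %in% design_site_indices(design),
             stringsAsFactors = FALSE)
}

consensus_sequence <- function(sequences) {
  chars <- strsplit(sequences, "", fixed = TRUE)
  L <- unique(lengths(chars))
  if (length(L) != 1L) stop("sequences must be equal length for consensus")
  m <- matrix(unlist(chars), nrow = length(chars), byrow = TRUE)
  paste(apply(m, 2, function(col) names(which.max(table(col)))), collapse = "")
}

#' Fraction of sequences mutated outside the design sites
#'
#' For quality control: the fraction of sequences carrying at least one
#' mismatch to a reference at a position that was not intentionally
#' mutagenized. With `reference = "consensus"` the per-position majority
#' residue of the dataset is used, which recovers the parent when off-design
#' mutation rates are low.
#'
#' @param sequences Character vector of equal-length sequences.
#' @param design A [library_design()].
#' @param reference A reference sequence, or `"consensus"`.
#' @return Fraction in `[0, 1]`.
#' @export
off_design_fraction <- function(sequences, design, reference = "consensus") {
  sequences <- as.character(sequences)
  if (length(sequences) == 0L) stop("empty dataset")
  if (identical(reference, "consensus")) {
    reference <- consensus_sequence(sequences)
  } else {
    reference <- as.character(reference)
  }
  rc <- strsplit(reference, "")[[1]]
  off <- setdiff(seq_along(rc), design_site_indices(design))
  chars <- strsplit(sequences, "", fixed = TRUE)
  if (any(lengths(chars) != length(rc))) stop("sequences must match reference length")
  hits <- vapply(chars, function(ch) any(ch[off] != rc[off]), logical(1))
  mean(hits)
}

#' Enumerate or sample library members
#'
#' Draws `n` distinct variant sequences from the combinatorial design,
#' uniformly over the theoretical space, always including the parent.
#'
#' @param design A [library_design()].
#' @param n Number of distinct variants to draw (capped at the diversity).
#' @return Character vector of sequences (ids equal to sequences).
#' @export
sample_library_variants <- function(design, n) {
  div <- theoretical_diversity(design)
  n <- min(n, div)
  idx <- design_site_indices(design)
  sizes <- vapply(design$sites, function(s) length(s$allowed_residues), integer(1))
  pc <- strsplit(as.character(design$parent), "")[[1]]
  # draw residue-index tuples until n distinct; cheap because n << diversity
  seen <- character(0)
  out <- character(0)
  parent_seq <- as.character(design$parent)
  out <- parent_seq
  seen <- parent_seq
  while (length(out) < n) {
    k <- n - length(out)
    draws <- vapply(seq_len(k), function(i) {
      ch <- pc
      for (j in seq_along(idx)) {
        ch[idx[j]] <- sample(design$sites[[j]]$allowed_residues, 1L)
      }
      paste(ch, collapse = "")
    }, character(1))
    new <- setdiff(unique(draws), seen)
    out <- c(out, new)
    seen <- c(seen, new)
  }
  out[seq_len(n)]
}

#' Read sequences from FASTA or CSV
#'
#' Records with gaps or residues outside the canonical alphabet are discarded
#' and reported via a `discarded` attribute (and a warning), matching the
#' upstream filtering convention that unidentified residues are dropped.
#'
#' @param path File path.
#' @param format `"fasta"` or `"csv"` (CSV needs a `sequence` column; an `id`
#'   column is optional). Guessed from the extension by default.
#' @return Data.frame with columns `id`, `sequence`; attribute `discarded`
#'   holds the rejected records with reasons.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "fasta"
  }
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    df <- data.frame(id = names(set), sequence = as.character(set),
                     stringsAsFactors = FALSE, row.names = NULL)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!"sequence" %in% names(df)) stop("CSV must carry a 'sequence' column: ", path)
    if (!"id" %in% names(df)) df$id <- df$sequence
    df <- df[, c("id", "sequence")]
  }
  df$sequence <- toupper(df$sequence)
  chars <- strsplit(df$sequence, "", fixed = TRUE)
  bad <- vapply(chars, function(ch) any(!ch %in% AA_ALPHABET), logical(1))
  discarded <- df[bad, , drop = FALSE]
  if (nrow(discarded) > 0L) {
    discarded$reason <- "gap or unidentified residue"
    warning(nrow(discarded), " record(s) with gaps or unidentified residues discarded")
  }
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "discarded") <- discarded
  out
}

#' Write sequences to FASTA or CSV
#'
#' @param sequences Data.frame with `id` and `sequence` columns, or a
#'   character vector (ids taken from names or the sequences).
#' @param path Output path.
#' @param format `"fasta"` or `"csv"`; guessed from the extension by default.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(sequences, path, format = c("auto", "fasta", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "fasta"
  }
  if (is.character(sequences)) {
    ids <- if (!is.null(names(sequences))) names(sequences) else sequences
    sequences <- data.frame(id = ids, sequence = unname(sequences),
                            stringsAsFactors = FALSE)
  }
  assert_residues(sequences$sequence)
  if (format == "fasta") {
    set <- Biostrings::AAStringSet(sequences$sequence)
    names(set) <- sequences$id
    Biostrings::writeXStringSet(set, path)
  } else {
    utils::write.csv(sequences[, c("id", "sequence")], path, row.names = FALSE)
  }
  invisible(path)
}
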