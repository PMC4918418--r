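GAP <- "-"
MISSING <- "X"

new_aa_alignment <- function(ids, mat) {
  structure(list(ids = ids, seqs = mat,
                 n_sequences = nrow(mat), n_columns = ncol(mat)),
            class = "aa_alignment")
}

normalize_residues <- function(mat) {
  mat <- toupper(mat)
  mat[mat == "."] <- GAP
  mat[!(mat %in% c(AA_ALPHA, GAP))] <- MISSING
  mat
}

#' Read a protein multiple sequence alignment
#'
#' Reads FASTA (via seqinr) or Stockholm format into an `aa_alignment`.
#' Residues are uppercased, `.` is mapped to the gap symbol `-`, and any
#' character outside the 20 amino acids and the gap is treated as missing
#' (`X`). Stockholm insert-state lowercase columns are uppercased like any
#' other residue; multi-block (interleaved) Stockholm files are supported.
#'
#' @param path Path to the alignment file.
#' @param format `"fasta"` or `"stockholm"`.
#' @return An `aa_alignment`: list with `ids`, `seqs` (character matrix,
#'   sequences x columns), `n_sequences`, `n_columns`.
#' @export
read_alignment <- function(path, format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "fasta") {
    seqs <- seqinr::read.fasta(path, seqtype = "AA", set.attributes = FALSE)
    if (length(seqs) == 0) stop("empty alignment file: ", path)
    lens <- lengths(seqs)
    if (length(unique(lens)) != 1)
      stop("ragged alignment: sequence lengths differ (", path, ")")
    mat <- do.call(rbind, seqs)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^#", lines) & !grepl("^//", lines)]
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0) stop("empty alignment file: ", path)
    parts <- strsplit(lines, "[ \t]+")
    bad <- lengths(parts) != 2
    if (any(bad)) stop("malformed Stockholm sequence line: ", lines[bad][1])
    ids <- vapply(parts, `[`, character(1), 1)
    seqtxt <- vapply(parts, `[`, character(1), 2)
    # interleaved blocks: concatenate per id, preserving first-seen order
    uid <- unique(ids)
    joined <- vapply(uid, function(i)
      paste(seqtxt[ids == i], collapse = ""), character(1))
    lens <- nchar(joined)
    if (length(unique(lens)) != 1)
      stop("ragged alignment: sequence lengths differ (", path, ")")
    mat <- do.call(rbind, strsplit(joined, ""))
    rownames(mat) <- uid
  }
  mat <- normalize_residues(mat)
  new_aa_alignment(rownames(mat), unname(mat))
}

#' Write an alignment as FASTA
#'
#' @param aln An `aa_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "aa_alignment"))
  seqs <- lapply(seq_len(aln$n_sequences), function(i) aln$seqs[i, ])
  seqinr::write.fasta(seqs, names = aln$ids, file.out = path)
  invisible(path)
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat("aa_alignment:", x$n_sequences, "sequences x", x$n_columns, "columns\n")
  invisible(x)
}

#' Henikoff position-based sequence weights
#'
#' Position-based weighting: in each column, a residue occurring `s` times in
#' a column with `r` distinct residues contributes \eqn{1/(r s)} to its
#' sequence's weight; per-sequence weights are summed over columns and
#' normalised to sum to 1. Gaps and missing residues contribute nothing, and
#' all-gap columns are ignored.
#'
#' @param aln An `aa_alignment`.
#' @return Numeric vector of weights, one per sequence, summing to 1.
#' @examples
#' # single column A, A, B: weights proportional to (1/4, 1/4, 1/2)
#' @export
henikoff_weights <- function(aln) {
  stopifnot(inherits(aln, "aa_alignment"))
  w <- numeric(aln$n_sequences)
  any_col <- FALSE
  for (j in seq_len(aln$n_columns)) {
    col <- aln$seqs[, j]
    ok <- col %in% AA_ALPHA
    if (!any(ok)) next
    any_col <- TRUE
    counts <- table(col[ok])
    r <- length(counts)
    w[ok] <- w[ok] + 1 / (r * as.numeric(counts[col[ok]]))
  }
  if (!any_col) stop("degenerate alignment: no ungapped residues")
  w / sum(w)
}

#' Site-specific equilibrium frequency profiles from an alignment
#'
#' Estimates per-column amino acid frequency profiles with sequence weights,
#' applying the standard filtering rules: alignments must be larger than
#' `min_columns` sites with more than `min_sequences` sequences, and columns
#' whose weighted gap fraction exceeds `max_gap_fraction` are excluded.
#' Missing residues (`X`) are excluded from the frequency counts and do not
#' count as gaps.
#'
#' @param aln An `aa_alignment`.
#' @param weights Per-sequence weights (default [henikoff_weights()]).
#' @param min_columns Minimum alignment width; alignments not strictly larger
#'   are rejected (default 100).
#' @param min_sequences Minimum depth; alignments not strictly larger are
#'   rejected (default 100).
#' @param max_gap_fraction Columns with weighted gap fraction strictly greater
#'   than this are dropped (default 0.5).
#' @param pseudocount Mass added to every amino acid before renormalising
#'   (default 0: raw weighted frequencies).
#' @return Object of class `alignment_profiles`: list with `profiles`
#'   (n_kept x 20 matrix), `kept_columns` (0-based indices into the original
#'   alignment, matching the on-disk TSV convention), `weights`, `rejected`
#'   (NULL, or a reason string when the alignment fails the size gates, in
#'   which case `profiles` is empty), and `filters` (the thresholds applied).
#' @export
site_profiles <- function(aln, weights = NULL, min_columns = 100,
                          min_sequences = 100, max_gap_fraction = 0.5,
                          pseudocount = 0) {
  stopifnot(inherits(aln, "aa_alignment"))
  if (min_columns <= 0 || min_sequences <= 0)
    stop("size thresholds must be positive")
  if (is.null(weights)) weights <- henikoff_weights(aln)
  if (length(weights) != aln$n_sequences || any(weights < 0))
    stop("weights must be nonnegative, one per sequence")
  weights <- weights / sum(weights)
  filters <- list(min_columns = min_columns, min_sequences = min_sequences,
                  max_gap_fraction = max_gap_fraction,
                  pseudocount = pseudocount)
  reject <- function(reason)
    structure(list(profiles = matrix(numeric(0), 0, 20,
                                     dimnames = list(NULL, AA_ALPHA)),
                   kept_columns = integer(0), weights = weights,
                   rejected = reason, filters = filters),
              class = "alignment_profiles")
  if (aln$n_columns <= min_columns) return(reject("too few columns"))
  if (aln$n_sequences <= min_sequences) return(reject("too few sequences"))

  kept <- integer(0)
  prof <- list()
  for (j in seq_len(aln$n_columns)) {
    col <- aln$seqs[, j]
    gap_frac <- sum(weights[col == GAP])
    if (gap_frac > max_gap_fraction) next
    ok <- col %in% AA_ALPHA
    if (!any(ok)) next
    f <- vapply(AA_ALPHA, function(a) sum(weights[ok][col[ok] == a]),
                numeric(1))
    f <- f / sum(f)
    if (pseudocount > 0) {
      f <- f + pseudocount
      f <- f / sum(f)
    }
    kept <- c(kept, j - 1L)  # 0-based
    prof[[length(prof) + 1L]] <- f
  }
  P <- if (length(prof)) do.call(rbind, prof) else matrix(numeric(0), 0, 20)
  colnames(P) <- AA_ALPHA
  structure(list(profiles = P, kept_columns = kept, weights = weights,
                 rejected = NULL, filters = filters),
            class = "alignment_profiles")
}

#' @export
print.alignment_profiles <- function(x, ...) {
  if (!is.null(x$rejected)) {
    cat("alignment_profiles: rejected (", x$rejected, ")\n", sep = "")
  } else {
    cat("alignment_profiles:", nrow(x$profiles), "kept columns\n")
    cat(" mean effective amino acids:",
        format(mean(effective_n_amino_acids(x$profiles)), digits = 4), "\n")
  }
  invisible(x)
}

#' Per-site frequency scatter for an amino acid pair
#'
#' Extracts the per-site equilibrium frequencies of two amino acids (the raw
#' material of frequency-covariance estimates) together with their Pearson
#' correlation.
#'
#' @param profile_set An `alignment_profiles` object, or an n x 20 profile
#'   matrix.
#' @param aa_pair Character vector of two distinct one-letter codes, e.g.
#'   `c("I", "V")`.
#' @return A data.frame with columns `site`, `x`, `y` and attribute
#'   `correlation`.
#' @export
frequency_scatter <- function(profile_set, aa_pair) {
  if (inherits(profile_set, "alignment_profiles")) {
    P <- profile_set$profiles
    site <- profile_set$kept_columns
  } else {
    P <- profiles_matrix(profile_set)
    site <- seq_len(nrow(P)) - 1L
  }
  if (length(aa_pair) != 2 || aa_pair[1] == aa_pair[2] ||
      !all(aa_pair %in% AA_ALPHA))
    stop("aa_pair must be two distinct one-letter amino acid codes")
  if (nrow(P) < 3) stop("correlation undefined with fewer than 3 sites")
  df <- data.frame(site = site, x = P[, aa_pair[1]], y = P[, aa_pair[2]])
  attr(df, "correlation") <- stats::cor(df$x, df$y)
  df
}
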