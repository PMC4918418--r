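#' Read a PAML-style amino acid substitution model file
#'
#' Parses a PAML `.dat` file: 190 lower-triangle exchangeabilities (rows for
#' amino acids 2..20 in the PAML order A R N D C Q E G H I L K M F P S T W Y V)
#' followed by 20 equilibrium frequencies. Trailing free text is ignored.
#' The returned matrices are reordered to this package's alphabetical
#' one-letter ordering.
#'
#' @param path Path to the `.dat` file.
#' @return List with `exchangeability` (symmetric 20x20, zero diagonal),
#'   `frequencies` (20-vector summing to 1), both in alphabetical amino acid
#'   order, and `path`.
#' @examples
#' wag <- read_paml_dat(system.file("extdata", "wag.dat", package = "mutselhet"))
#' effective_n_amino_acids(wag$frequencies)
#' @export
read_paml_dat <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  txt <- readLines(path, warn = FALSE)
  toks <- unlist(strsplit(paste(txt, collapse = " "), "[ \t]+"))
  toks <- toks[nzchar(toks)]
  num <- suppressWarnings(as.numeric(toks))
  # numbers appear before any trailing commentary; stop at first non-number
  if (any(is.na(num))) num <- num[seq_len(which(is.na(num))[1] - 1)]
  if (length(num) < 210)
    stop("not a PAML dat file (found ", length(num), " leading numbers, need 210)")
  num <- num[1:210]
  S <- matrix(0, 20, 20, dimnames = list(AA_PAML, AA_PAML))
  k <- 1
  for (i in 2:20) for (j in 1:(i - 1)) {
    S[i, j] <- S[j, i] <- num[k]
    k <- k + 1
  }
  f <- num[191:210]
  names(f) <- AA_PAML
  if (any(f < 0) || abs(sum(f) - 1) > 1e-3)
    stop("frequency block does not sum to 1")
  f <- f / sum(f)
  list(exchangeability = S[AA_ALPHA, AA_ALPHA],
       frequencies = f[AA_ALPHA],
       path = path)
}

#' Write a 20x20 symmetric matrix in PAML lower-triangle format
#'
#' @param S Symmetric 20x20 matrix in alphabetical amino acid order.
#' @param path Output path.
#' @param frequencies Optional 20-vector (alphabetical order) appended as the
#'   PAML frequency row.
#' @return `path`, invisibly.
#' @export
write_paml_dat <- function(S, path, frequencies = NULL) {
  if (!is.matrix(S) || any(dim(S) != 20)) stop("S must be 20x20")
  if (max(abs(S - t(S))) > 1e-8) stop("S must be symmetric")
  dimnames(S) <- list(AA_ALPHA, AA_ALPHA)
  Sp <- S[AA_PAML, AA_PAML]
  con <- file(path, "w")
  on.exit(close(con))
  for (i in 2:20)
    writeLines(paste(formatC(Sp[i, 1:(i - 1)], format = "g", digits = 8),
                     collapse = " "), con)
  if (!is.null(frequencies)) {
    names(frequencies) <- AA_ALPHA
    writeLines("", con)
    writeLines(paste(formatC(frequencies[AA_PAML], format = "g", digits = 8),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Paths of the bundled standard-model fixtures
#'
#' The five published amino acid replacement models bundled with the package
#' as PAML-style `.dat` files: WAG, JTT, LG, Dayhoff, and BLOSUM62-derived
#' frequencies/exchangeabilities.
#'
#' @return Named character vector of file paths.
#' @export
standard_model_files <- function() {
  files <- c(WAG = "wag.dat", JTT = "jtt.dat", LG = "lg.dat",
             Dayhoff = "dayhoff.dat", BLOSUM62 = "blosum62.dat")
  vapply(files, function(f)
    system.file("extdata", f, package = "mutselhet", mustWork = TRUE),
    character(1))
}

#' Write/read a site rate matrix or profile as TSV
#'
#' Tab-separated text with a header row of one-letter amino acid codes;
#' profiles are written one row per site with a leading `site` column.
#'
#' @param x 20x20 matrix, or an n x 20 matrix of profiles.
#' @param path Output path.
#' @param site Optional site indices for profile rows.
#' @return `path` invisibly (writers); matrix (readers).
#' @export
write_aa_tsv <- function(x, path, site = NULL) {
  x <- as.matrix(x)
  if (ncol(x) != 20) stop("need 20 amino acid columns")
  colnames(x) <- AA_ALPHA
  df <- as.data.frame(x)
  if (!is.null(site)) df <- cbind(site = site, df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_aa_tsv
#' @export
read_aa_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  site <- NULL
  if ("site" %in% names(df)) {
    site <- df$site
    df$site <- NULL
  }
  m <- as.matrix(df)
  if (ncol(m) != 20 || !all(colnames(m) == AA_ALPHA))
    stop("expected 20 amino acid columns in alphabetical order")
  if (!is.null(site)) rownames(m) <- site
  m
}

#' Read CAT-style mixture classes from TSV
#'
#' Expects a TSV with a `weight` column and 20 amino acid frequency columns
#' (one-letter codes), one row per class.
#'
#' @param path Path to the class file.
#' @return List with `profiles` (K x 20 matrix, rows renormalised to 1) and
#'   `weights` (K-vector summing to 1).
#' @export
read_mixture_classes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  if (!"weight" %in% names(df)) stop("mixture class file needs a 'weight' column")
  w <- df$weight
  df$weight <- NULL
  if (!all(AA_ALPHA %in% names(df)))
    stop("mixture class file needs all 20 amino acid columns")
  P <- as.matrix(df[, AA_ALPHA])
  if (any(P < 0) || any(w < 0)) stop("negative entries in mixture class file")
  P <- P / rowSums(P)
  list(profiles = P, weights = w / sum(w))
}
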