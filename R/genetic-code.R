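# Amino acids, alphabetical by one-letter code: the internal ordering used in
# every matrix and vector in this package.
AA_ALPHA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# PAML file ordering, used only for .dat interchange.
AA_PAML <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
             "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

NUC <- c("A", "C", "G", "T")

#' Standard genetic code table
#'
#' Builds the table of 61 sense codons of the standard nuclear genetic code,
#' the codon to amino acid map, and the codon degeneracy \eqn{d_X} of each
#' amino acid (number of sense codons encoding it, so that
#' \eqn{\sum_X d_X = 61}).
#'
#' @param code_id Identifier of the genetic code. Only `"standard"` is
#'   supported.
#' @return An object of class `genetic_code`: a list with elements
#'   `codons` (character vector of 61 sense codons), `codon_to_aa` (named
#'   character vector mapping codon to one-letter amino acid), `degeneracy`
#'   (named integer vector \eqn{d_X} over the 20 amino acids in alphabetical
#'   one-letter order), and `stop_codons`.
#' @examples
#' gc <- genetic_code()
#' gc$degeneracy[["L"]]  # 6
#' sum(gc$degeneracy)    # 61
#' @export
genetic_code <- function(code_id = "standard") {
  if (!identical(code_id, "standard"))
    stop("unsupported genetic code: ", code_id)
  base3 <- expand.grid(p3 = NUC, p2 = NUC, p1 = NUC, stringsAsFactors = FALSE)
  codons <- paste0(base3$p1, base3$p2, base3$p3)
  # Translate via Biostrings-free hard table: row = first base, block layout.
  aa <- vapply(codons, translate_codon, character(1))
  stops <- codons[aa == "*"]
  sense <- codons[aa != "*"]
  map <- aa[aa != "*"]
  names(map) <- sense
  deg <- table(factor(map, levels = AA_ALPHA))
  structure(list(codons = sense,
                 codon_to_aa = map,
                 degeneracy = stats::setNames(as.integer(deg), AA_ALPHA),
                 stop_codons = stops),
            class = "genetic_code")
}

# One codon -> one-letter amino acid ('*' for stop), standard nuclear code.
translate_codon <- function(codon) {
  tab <- c(
    TTT = "F", TTC = "F", TTA = "L", TTG = "L",
    CTT = "L", CTC = "L", CTA = "L", CTG = "L",
    ATT = "I", ATC = "I", ATA = "I", ATG = "M",
    GTT = "V", GTC = "V", GTA = "V", GTG = "V",
    TCT = "S", TCC = "S", TCA = "S", TCG = "S",
    CCT = "P", CCC = "P", CCA = "P", CCG = "P",
    ACT = "T", ACC = "T", ACA = "T", ACG = "T",
    GCT = "A", GCC = "A", GCA = "A", GCG = "A",
    TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
    CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
    AAT = "N", AAC = "N", AAA = "K", AAG = "K",
    GAT = "D", GAC = "D", GAA = "E", GAG = "E",
    TGT = "C", TGC = "C", TGA = "*", TGG = "W",
    CGT = "R", CGC = "R", CGA = "R", CGG = "R",
    AGT = "S", AGC = "S", AGA = "R", AGG = "R",
    GGT = "G", GGC = "G", GGA = "G", GGG = "G")
  unname(tab[codon])
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Standard genetic code:", length(x$codons), "sense codons,",
      length(x$stop_codons), "stop codons\n")
  cat("Degeneracy d_X:\n")
  print(x$degeneracy)
  invisible(x)
}

#' Kimura two-parameter (K80) nucleotide exchange rates
#'
#' Per-pair nucleotide mutation rates under the K80 model: transversions at
#' rate 1 (this normalisation defines the neutral time unit) and transitions
#' (A<->G, C<->T) at rate `kappa`.
#'
#' @param kappa Transition/transversion rate ratio, > 0.
#' @return A symmetric 4x4 matrix of rates over A, C, G, T with zero diagonal.
#' @examples
#' k80_rates(2)["A", "G"]  # 2
#' @export
k80_rates <- function(kappa) {
  if (!is.numeric(kappa) || length(kappa) != 1L || !is.finite(kappa) || kappa <= 0)
    stop("kappa must be a single positive number")
  m <- matrix(1, 4, 4, dimnames = list(NUC, NUC))
  diag(m) <- 0
  m["A", "G"] <- m["G", "A"] <- kappa
  m["C", "T"] <- m["T", "C"] <- kappa
  m
}

# All single-nucleotide neighbours of a codon, with the per-site nucleotide
# rates applied. Returns data.frame(to, rate).
codon_neighbours <- function(codon, nuc_rates) {
  from <- strsplit(codon, "")[[1]]
  out_to <- character(9)
  out_rate <- numeric(9)
  k <- 0L
  for (pos in 1:3) {
    for (b in NUC[NUC != from[pos]]) {
      k <- k + 1L
      nb <- from
      nb[pos] <- b
      out_to[k] <- paste(nb, collapse = "")
      out_rate[k] <- nuc_rates[from[pos], b]
    }
  }
  data.frame(to = out_to, rate = out_rate, stringsAsFactors = FALSE)
}

#' Codon-averaged amino acid mutation model
#'
#' Averages a nucleotide mutation process over the codons encoding each amino
#' acid to obtain the amino-acid-level mutation rates \eqn{v_{XY}}, the
#' genetic-code/codon-usage weights \eqn{\lambda_X}, and the symmetric part
#' \eqn{v^S_{XY} = v_{XY} \lambda_X}. With uniform codon usage
#' \eqn{\lambda_X = d_X / 61}. Amino acid pairs not connected by any
#' single-nucleotide codon change have \eqn{v_{XY} = 0}.
#'
#' Under codon usage bias the codon-level mutation rates are taken as
#' \eqn{\mu(c, c')\sqrt{w_{c'}/w_c}}, the flux-symmetric process with
#' stationary distribution \eqn{w}; this is the minimal modification of the
#' nucleotide process that makes the aggregated amino acid model reversible,
#' and it leaves the rates untouched under uniform usage.
#'
#' Reversibility of the mutation process at the amino acid level holds by
#' construction: \eqn{v_{XY}\lambda_X = v_{YX}\lambda_Y = v^S_{XY}}.
#'
#' @param kappa Transition/transversion ratio for the K80 nucleotide model.
#' @param codon_weights Optional positive weights over the 61 sense codons
#'   (named by codon or in the order of `genetic_code()$codons`); default
#'   uniform usage.
#' @param code A `genetic_code` object; default the standard code.
#' @param nuc_rates Optional symmetric 4x4 nucleotide rate matrix over
#'   A, C, G, T overriding the K80 construction (for non-K80 or rescaled
#'   mutation processes).
#' @return An object of class `mutation_model`: list with `kappa`, `v`
#'   (20x20 matrix \eqn{v_{XY}}), `lambda` (\eqn{\lambda_X}, sums to 1), `vS`
#'   (symmetric \eqn{v^S_{XY}}), `nuc_rates`, `code`, and `accessible`
#'   (logical 20x20, TRUE where a single-nucleotide codon change connects the
#'   pair).
#' @examples
#' mm <- mutation_model(kappa = 2)
#' all.equal(mm$lambda, genetic_code()$degeneracy / 61,
#'           check.attributes = FALSE)
#' max(abs(mm$v * mm$lambda - t(mm$v * mm$lambda)))  # ~0: reversibility
#' @export
mutation_model <- function(kappa = 2, codon_weights = NULL,
                           code = genetic_code(), nuc_rates = NULL) {
  if (is.null(nuc_rates)) {
    nuc_rates <- k80_rates(kappa)
  } else {
    if (!is.matrix(nuc_rates) || any(dim(nuc_rates) != 4) ||
        max(abs(nuc_rates - t(nuc_rates))) > 1e-12 || any(nuc_rates < 0))
      stop("nuc_rates must be a symmetric nonnegative 4x4 matrix")
    dimnames(nuc_rates) <- list(NUC, NUC)
  }
  n_codon <- length(code$codons)
  if (is.null(codon_weights)) {
    w <- rep(1 / n_codon, n_codon)
    names(w) <- code$codons
  } else {
    if (length(codon_weights) != n_codon)
      stop("codon_weights must have length ", n_codon)
    if (any(!is.finite(codon_weights)) || any(codon_weights <= 0))
      stop("codon_weights must be positive and finite")
    w <- codon_weights
    if (!is.null(names(w))) {
      if (!setequal(names(w), code$codons)) stop("codon_weights names must be the sense codons")
      w <- w[code$codons]
    } else names(w) <- code$codons
    w <- w / sum(w)
  }

  # Codon-level mutation rates: mu(c, c') sqrt(w_c' / w_c). The square-root
  # factor makes the codon process reversible with stationary distribution w
  # (flux w_c mu sqrt(w_c'/w_c) = mu sqrt(w_c w_c') is symmetric), which is
  # what amino-acid-level reversibility v_XY lambda_X = v_YX lambda_Y
  # requires under codon usage bias. Under uniform usage the factor is 1 and
  # the rates are the plain codon-averaged K80 rates.
  v <- matrix(0, 20, 20, dimnames = list(AA_ALPHA, AA_ALPHA))
  for (c1 in code$codons) {
    X <- code$codon_to_aa[[c1]]
    nb <- codon_neighbours(c1, nuc_rates)
    keep <- nb$to %in% code$codons
    for (i in which(keep)) {
      c2 <- nb$to[i]
      Y <- code$codon_to_aa[[c2]]
      if (Y != X)
        v[X, Y] <- v[X, Y] + w[[c1]] * nb$rate[i] * sqrt(w[[c2]] / w[[c1]])
    }
  }
  lambda <- vapply(AA_ALPHA, function(a)
    sum(w[code$codon_to_aa[code$codons] == a]), numeric(1))
  v <- v / lambda  # codon-averaged: divide by total weight of source codons
  vS <- v * lambda # vS_XY = v_XY * lambda_X
  vS <- (vS + t(vS)) / 2  # symmetrise away rounding; asymmetry is O(eps)
  structure(list(kappa = kappa, v = v, lambda = lambda, vS = vS,
                 nuc_rates = nuc_rates, code = code,
                 codon_weights = w,
                 accessible = v > 0),
            class = "mutation_model")
}

#' @export
print.mutation_model <- function(x, ...) {
  cat("Codon-averaged amino acid mutation model (K80, kappa =", x$kappa, ")\n")
  cat(" single-nucleotide-accessible amino acid pairs:",
      sum(x$accessible[upper.tri(x$accessible)] | t(x$accessible)[upper.tri(x$accessible)]),
      "of 190\n")
  cat(" lambda_X range:", format(range(x$lambda), digits = 3), "\n")
  invisible(x)
}
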