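#' Contact structure
#'
#' A coarse-grained protein fold: the set of residue pairs in spatial
#' contact. Pairs are unordered, 0-based, and must be non-adjacent in
#' sequence (\eqn{|i - j| \ge 2}).
#'
#' @param n_residues Number of residues.
#' @param contacts Two-column matrix of 0-based residue index pairs.
#' @return Object of class `contact_structure` with canonicalised (i < j,
#'   deduplicated) contacts.
#' @export
contact_structure <- function(n_residues, contacts) {
  contacts <- matrix(as.integer(contacts), ncol = 2)
  if (nrow(contacts) > 0) {
    if (any(contacts < 0) || any(contacts >= n_residues))
      stop("contact indices must lie in [0, n_residues)")
    contacts <- t(apply(contacts, 1, sort))
    if (any(contacts[, 2] - contacts[, 1] < 2))
      stop("contacts must satisfy |i - j| >= 2 (no self or neighbour contacts)")
    contacts <- unique(contacts)
  }
  structure(list(n_residues = as.integer(n_residues), contacts = contacts),
            class = "contact_structure")
}

#' @export
print.contact_structure <- function(x, ...) {
  cat("contact_structure:", x$n_residues, "residues,",
      nrow(x$contacts), "contacts\n")
  invisible(x)
}

#' Read/write contact maps
#'
#' Contact maps are stored as two-column TSV of 0-based residue index pairs
#' with a header line `n_residues=N`.
#'
#' @param path File path.
#' @param structure A `contact_structure` (writer).
#' @return A `contact_structure` (reader); `path` invisibly (writer).
#' @export
read_contact_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^\\s*n_residues\\s*=", lines, value = TRUE)
  if (length(hdr) != 1) stop("contact map needs one 'n_residues=N' header line")
  n <- as.integer(sub(".*=\\s*", "", hdr))
  body <- lines[!grepl("^\\s*(n_residues\\s*=|#|$)", lines)]
  if (length(body) == 0) return(contact_structure(n, matrix(integer(0), 0, 2)))
  m <- do.call(rbind, lapply(strsplit(body, "[ \t]+"), as.integer))
  contact_structure(n, m)
}

#' @rdname read_contact_map
#' @export
write_contact_map <- function(structure, path) {
  stopifnot(inherits(structure, "contact_structure"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("n_residues=", structure$n_residues), con)
  if (nrow(structure$contacts) > 0)
    writeLines(paste(structure$contacts[, 1], structure$contacts[, 2],
                     sep = "\t"), con)
  invisible(path)
}

#' Pairwise contact potential
#'
#' Returns a symmetric 20x20 table of contact energies (units of kT,
#' alphabetical amino acid order). The bundled `"synthetic"` potential is a
#' synthetic knowledge-based-style potential constructed from physicochemical
#' first principles — a hydrophobic-attraction term (product of min-max
#' normalised Kyte–Doolittle hydrophobicities), a charge-interaction term
#' (opposite charges attract, like charges repel), and a weak uniform
#' background attraction:
#' \deqn{e(X, Y) = -2\,h'_X h'_Y + 0.8\, c_X c_Y - 0.2.}
#' It is a stand-in with the qualitative structure of estimated statistical
#' potentials (hydrophobic residues drive compact-state stability,
#' electrostatics modulate it), not a published table.
#'
#' @param source `"synthetic"`, or a path to a 20x20 TSV (header row of
#'   one-letter codes) such as one written by [write_aa_tsv()].
#' @return Symmetric 20x20 numeric matrix.
#' @export
contact_potential <- function(source = "synthetic") {
  if (identical(source, "synthetic")) {
    kd <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4,
            H = -3.2, I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5,
            P = -1.6, Q = -3.5, R = -4.5, S = -0.8, T = -0.7, V = 4.2,
            W = -0.9, Y = -1.3)[AA_ALPHA]
    h <- (kd - min(kd)) / (max(kd) - min(kd))
    ch <- c(A = 0, C = 0, D = -1, E = -1, F = 0, G = 0, H = 0.5, I = 0,
            K = 1, L = 0, M = 0, N = 0, P = 0, Q = 0, R = 1, S = 0,
            T = 0, V = 0, W = 0, Y = 0)[AA_ALPHA]
    e <- -2 * outer(h, h) + 0.8 * outer(ch, ch) - 0.2
    dimnames(e) <- list(AA_ALPHA, AA_ALPHA)
    return(e)
  }
  m <- read_aa_tsv(source)
  if (nrow(m) != 20) stop("contact potential must be 20x20")
  rownames(m) <- AA_ALPHA
  if (max(abs(m - t(m))) > 1e-8) stop("contact potential must be symmetric")
  m
}

#' Stability model: potential, native fold, decoy ensemble
#'
#' Bundles everything needed to map an amino acid sequence to a folding free
#' energy and a fitness: the pairwise contact potential, the native contact
#' structure, an ensemble of alternative ("decoy") folds used to estimate the
#' free energy of the vastly larger ensemble of non-native conformations, and
#' the log-size of that ensemble.
#'
#' @param native A `contact_structure`.
#' @param decoys List of `contact_structure`s sharing `n_residues` with the
#'   native (at least 2, default ensembles have 55).
#' @param potential Symmetric 20x20 contact energy matrix
#'   (default [contact_potential()]).
#' @param log_n_unfolded Log of the number of alternative conformations the
#'   decoys represent; default \eqn{\ln 10^{160}}.
#' @param kT Energy scale; the internal unit (default 1).
#' @return Object of class `stability_model`.
#' @export
stability_model <- function(native, decoys, potential = contact_potential(),
                            log_n_unfolded = 160 * log(10), kT = 1) {
  stopifnot(inherits(native, "contact_structure"))
  if (length(decoys) < 2)
    stop("need at least 2 decoy structures to estimate the energy spread")
  for (d in decoys) {
    stopifnot(inherits(d, "contact_structure"))
    if (d$n_residues != native$n_residues)
      stop("decoys must share n_residues with the native structure")
  }
  if (max(abs(potential - t(potential))) > 1e-8)
    stop("potential must be symmetric")
  dimnames(potential) <- list(AA_ALPHA, AA_ALPHA)
  structure(list(native = native, decoys = decoys, potential = potential,
                 log_n_unfolded = log_n_unfolded, kT = kT),
            class = "stability_model")
}

#' @export
print.stability_model <- function(x, ...) {
  cat("stability_model:", x$native$n_residues, "residues,",
      nrow(x$native$contacts), "native contacts,",
      length(x$decoys), "decoys, ln N_unfolded =",
      format(x$log_n_unfolded, digits = 4), "\n")
  invisible(x)
}

# seq: integer vector of amino acid indices (1..20) or character vector.
seq_to_int <- function(seq) {
  if (is.character(seq)) {
    i <- match(seq, AA_ALPHA)
    if (any(is.na(i))) stop("unknown amino acid in sequence")
    return(i)
  }
  as.integer(seq)
}

#' Contact energy of a sequence on a structure
#'
#' \eqn{E = \sum_{(i,j) \in \mathrm{contacts}} e(A_i, A_j)}.
#'
#' @param seq Amino acid sequence: character vector of one-letter codes or
#'   integer indices (1..20, alphabetical).
#' @param structure A `contact_structure` with matching length.
#' @param potential Symmetric 20x20 energy matrix.
#' @return Scalar energy.
#' @export
contact_energy <- function(seq, structure, potential) {
  stopifnot(inherits(structure, "contact_structure"))
  a <- seq_to_int(seq)
  if (length(a) != structure$n_residues)
    stop("sequence length must equal n_residues")
  if (nrow(structure$contacts) == 0) return(0)
  sum(potential[cbind(a[structure$contacts[, 1] + 1L],
                      a[structure$contacts[, 2] + 1L])])
}

#' Folding free energy of a sequence
#'
#' \eqn{\Delta G = E_\mathrm{native} - G_\mathrm{alt}} where the free energy
#' of the non-native ensemble is estimated from the decoy energies by a
#' Gaussian (random-energy) approximation:
#' \deqn{G_\mathrm{alt} = -kT \ln Z_\mathrm{alt}, \quad
#'   \ln Z_\mathrm{alt} = \ln N_\mathrm{unfolded} - \mu_d/kT +
#'   \sigma_d^2 / (2 kT^2)}
#' with \eqn{\mu_d, \sigma_d} the mean and standard deviation of the
#' sequence's energies over the decoy ensemble.
#'
#' @inheritParams contact_energy
#' @param model A `stability_model`.
#' @return Scalar \eqn{\Delta G} (negative = stable native fold).
#' @export
folding_free_energy <- function(seq, model) {
  stopifnot(inherits(model, "stability_model"))
  a <- seq_to_int(seq)
  e_nat <- contact_energy(a, model$native, model$potential)
  e_dec <- vapply(model$decoys, function(d)
    contact_energy(a, d, model$potential), numeric(1))
  mu <- mean(e_dec)
  sg2 <- stats::var(e_dec)
  kT <- model$kT
  lnZ <- model$log_n_unfolded - mu / kT + sg2 / (2 * kT^2)
  e_nat + kT * lnZ
}

#' Fitness from folding free energy
#'
#' The probability of being folded at equilibrium:
#' \deqn{f = \frac{e^{-\Delta G / kT}}{1 + e^{-\Delta G / kT}}.}
#' Saturates stably at 0 and 1.
#'
#' @param dG Folding free energy (same units as kT).
#' @param kT Energy scale (default 1).
#' @return Fitness in (0, 1); 0.5 at \eqn{\Delta G = 0}.
#' @export
fold_fitness <- function(dG, kT = 1) {
  if (any(!is.finite(dG))) stop("dG must be finite")
  stats::plogis(-dG / kT)
}
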