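# Dirichlet sampler via gamma draws.
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Default physicochemical site classes
#'
#' Amino acid groupings used by the synthetic profile generator to mimic the
#' covariance structure of real site profiles: sites enriched for aliphatic /
#' hydrophobic residues, small residues, charged/polar residues, and
#' aromatics.
#'
#' @return Named list of one-letter-code character vectors.
#' @export
physicochemical_classes <- function() {
  list(aliphatic = c("I", "L", "V", "M"),
       small = c("A", "G", "S", "T", "C"),
       charged = c("D", "E", "K", "R", "Q", "N", "H"),
       aromatic = c("F", "Y", "W", "H"),
       polar_small = c("S", "T", "N", "D"),
       turn = c("P", "G", "N", "D", "S"))
}

#' Generate heterogeneous site profiles
#'
#' Draws site-specific equilibrium frequency profiles from a mixture of
#' physicochemically structured classes, emulating the spatial heterogeneity
#' of amino acid propensities across the columns of large protein family
#' alignments. Each site is assigned a class; its profile is drawn from a
#' Dirichlet distribution centred on the class propensity vector. Amino acids
#' outside the class keep a small base mass (`epsilon`) so the profiles stay
#' strictly positive.
#'
#' @param n_sites Number of sites (>= 2).
#' @param classes List of classes: character vectors of one-letter codes or
#'   numeric 20-vectors of propensities (default
#'   [physicochemical_classes()]).
#' @param class_weights Mixing weights, one per class (default uniform).
#' @param concentration Dirichlet concentration (sum of alphas); larger means
#'   profiles hug the class centre (default 50).
#' @param epsilon Base mass for out-of-class amino acids (default 1e-3).
#' @param seed Optional integer seed.
#' @return List with `profiles` (n_sites x 20 matrix), `class` (integer
#'   labels), and `centers` (K x 20 matrix of class propensity vectors).
#' @export
generate_profiles <- function(n_sites, classes = physicochemical_classes(),
                              class_weights = NULL, concentration = 50,
                              epsilon = 1e-3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_sites < 2) stop("n_sites must be at least 2")
  if (length(classes) == 0) stop("empty class set")
  if (concentration <= 0) stop("concentration must be positive")
  centers <- t(vapply(classes, function(cl) {
    if (is.character(cl)) {
      if (!all(cl %in% AA_ALPHA)) stop("unknown amino acid in class")
      p <- rep(epsilon, 20)
      names(p) <- AA_ALPHA
      p[cl] <- (1 - (20 - length(cl)) * epsilon) / length(cl)
    } else {
      if (length(cl) != 20 || any(cl < 0)) stop("numeric class must be a nonnegative 20-vector")
      p <- cl + epsilon
    }
    p / sum(p)
  }, numeric(20)))
  K <- nrow(centers)
  if (is.null(class_weights)) class_weights <- rep(1 / K, K)
  if (length(class_weights) != K || any(class_weights < 0))
    stop("class_weights must be nonnegative, one per class")
  class_weights <- class_weights / sum(class_weights)
  lab <- sample.int(K, n_sites, replace = TRUE, prob = class_weights)
  P <- t(vapply(lab, function(k) rdirichlet1(concentration * centers[k, ]),
                numeric(20)))
  colnames(P) <- AA_ALPHA
  colnames(centers) <- AA_ALPHA
  list(profiles = P, class = lab, centers = centers)
}

# Transition probability matrix exp(Q t) of a reversible site process via
# symmetric eigendecomposition.
site_transition_matrix <- function(pi, mutation, t) {
  Q <- f81_rates(pi, mutation)$Q
  sq <- sqrt(pi)
  Sym <- Q * outer(sq, 1 / sq)          # D^{1/2} Q D^{-1/2}, symmetric
  Sym <- (Sym + t(Sym)) / 2
  e <- eigen(Sym, symmetric = TRUE)
  P <- outer(1 / sq, sq) * (e$vectors %*% (exp(t * e$values) * t(e$vectors)))
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Evolve a synthetic alignment from site profiles
#'
#' Simulates phylogenetically related sequences: per site, an F81-style
#' process with rates \eqn{Q_{XY} = v^S_{XY}\pi_{L,Y}} (stationary at the
#' site's profile) is run down a star or balanced binary tree with the given
#' branch length. Root states are drawn from the site profiles, so the
#' alignment is stationary: its per-site frequencies converge to the input
#' profiles as sequences accumulate. Alignments are gap-free.
#'
#' @param profiles n_sites x 20 matrix (or list) of site profiles.
#' @param n_sequences Number of tip sequences (>= 2).
#' @param branch_length Expected substitutions per edge in the time units of
#'   the per-site process (>= 0; 0 yields identical sequences).
#' @param tree_shape `"star"` (tips independent given root) or `"balanced"`
#'   (complete binary tree, internal edges share `branch_length`).
#' @param mutation A `mutation_model`.
#' @param seed Optional integer seed.
#' @return An `aa_alignment` of `n_sequences` gap-free rows.
#' @export
evolve_alignment <- function(profiles, n_sequences, branch_length,
                             tree_shape = c("star", "balanced"),
                             mutation, seed = NULL) {
  tree_shape <- match.arg(tree_shape)
  stopifnot(inherits(mutation, "mutation_model"))
  if (!is.null(seed)) set.seed(seed)
  if (n_sequences < 2) stop("n_sequences must be at least 2")
  if (branch_length < 0) stop("branch_length must be nonnegative")
  P <- profiles_matrix(profiles)
  n_sites <- nrow(P)
  out <- matrix("", n_sequences, n_sites)
  for (L in seq_len(n_sites)) {
    pi <- as_profile(P[L, ], pseudocount = 1e-10)
    root <- sample.int(20, 1, prob = pi)
    if (branch_length == 0) {
      out[, L] <- AA_ALPHA[root]
      next
    }
    Ptrans <- site_transition_matrix(pi, mutation, branch_length)
    if (tree_shape == "star") {
      tips <- vapply(seq_len(n_sequences), function(s)
        sample.int(20, 1, prob = Ptrans[root, ]), integer(1))
    } else {
      depth <- ceiling(log2(n_sequences))
      states <- root
      for (d in seq_len(depth)) {
        states <- unlist(lapply(states, function(s)
          c(sample.int(20, 1, prob = Ptrans[s, ]),
            sample.int(20, 1, prob = Ptrans[s, ]))))
      }
      tips <- states[seq_len(n_sequences)]
    }
    out[, L] <- AA_ALPHA[tips]
  }
  new_aa_alignment(paste0("seq", seq_len(n_sequences)), out)
}

#' Generate a native structure and decoy ensemble
#'
#' Random contact maps standing in for a native protein fold and its ensemble
#' of alternative folds: the native and every decoy have identical contact
#' counts (so their energies are comparable), drawn uniformly from the pairs
#' with \eqn{|i - j| \ge 2}. Decoys are re-drawn if they coincide exactly with
#' the native map.
#'
#' @param n_residues Chain length.
#' @param contact_density Fraction of admissible pairs in contact, in (0, 1\];
#'   `round(density * n_admissible)` contacts are drawn.
#' @param n_decoys Ensemble size (default 55).
#' @param seed Optional integer seed.
#' @return List with `native` (a `contact_structure`) and `decoys` (list of
#'   `contact_structure`s).
#' @export
generate_structure <- function(n_residues, contact_density, n_decoys = 55,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pairs <- which(upper.tri(matrix(0, n_residues, n_residues)), arr.ind = TRUE)
  pairs <- pairs[pairs[, 2] - pairs[, 1] >= 2, , drop = FALSE]
  n_contacts <- round(contact_density * nrow(pairs))
  if (contact_density < 0 || n_contacts > nrow(pairs))
    stop("impossible contact density")
  draw <- function() {
    idx <- sample.int(nrow(pairs), n_contacts)
    contact_structure(n_residues, pairs[idx, , drop = FALSE] - 1L)
  }
  native <- draw()
  key <- function(s) paste(s$contacts[, 1], s$contacts[, 2], collapse = ";")
  nk <- key(native)
  decoys <- vector("list", n_decoys)
  for (d in seq_len(n_decoys)) {
    repeat {
      cand <- draw()
      if (n_contacts == 0 || key(cand) != nk) break
    }
    decoys[[d]] <- cand
  }
  list(native = native, decoys = decoys)
}
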