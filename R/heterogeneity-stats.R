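# Coerce a list of profiles / matrix to an n_sites x 20 matrix.
profiles_matrix <- function(profiles) {
  if (is.list(profiles)) profiles <- do.call(rbind, profiles)
  if (!is.matrix(profiles) || ncol(profiles) != 20)
    stop("profiles must be a list of 20-vectors or an n x 20 matrix")
  if (any(!is.finite(profiles)) || any(profiles < 0))
    stop("profiles must be nonnegative and finite")
  if (any(abs(rowSums(profiles) - 1) > 1e-6))
    stop("every profile must sum to 1")
  colnames(profiles) <- AA_ALPHA
  profiles
}

#' Site-averaged substitution model via frequency covariances
#'
#' Averages the per-site flux and equilibrium distribution of the F81-style
#' site processes \eqn{Q_{L,XY} = v^S_{XY}\pi_{L,Y}} over sites, giving the
#' standard-model rate matrix
#' \deqn{\hat Q_{XY} = v^S_{XY}\left(1 +
#'   \frac{\mathrm{Cov}(\pi_{L,X},\pi_{L,Y})}{\hat\pi_X\hat\pi_Y}\right)\hat\pi_Y}
#' with \eqn{\hat\pi_X = \langle \pi_{L,X}\rangle_L} and the covariance taken
#' over sites (population form, divisor = number of sites). The site-averaged
#' rate thus depends on the tendency of the two amino acids to be acceptable
#' at the same sites.
#'
#' @param profiles List of site profiles (20-vectors) or an n_sites x 20
#'   matrix, at least 2 sites.
#' @param mutation A `mutation_model` supplying \eqn{v^S_{XY}}.
#' @return Object of class `averaged_model`: list with `pihat` (20-vector),
#'   `cov` (20x20 covariance of site frequencies), `Qhat` (20x20 averaged rate
#'   matrix, rows sum to 0), and `S` (symmetric exchangeability including the
#'   \eqn{v^S} factor, \eqn{\hat Q_{XY} = S_{XY}\hat\pi_Y}). Negative rate
#'   entries (possible under extreme anticorrelation) are floored at 0 with a
#'   warning.
#' @export
average_model <- function(profiles, mutation) {
  stopifnot(inherits(mutation, "mutation_model"))
  P <- profiles_matrix(profiles)
  n <- nrow(P)
  if (n < 2) stop("need at least 2 site profiles to average (covariance undefined)")
  pihat <- colMeans(P)
  Pc <- sweep(P, 2, pihat)
  covP <- crossprod(Pc) / n  # population covariance over sites
  denom <- outer(pihat, pihat)
  corr_fac <- 1 + covP / denom
  S <- mutation$vS * corr_fac
  Qhat <- S * rep(pihat, each = 20)  # Qhat_XY = S_XY * pihat_Y
  if (any(Qhat < 0)) {
    warning(sum(Qhat < 0), " negative averaged rate entries floored at 0")
    Qhat[Qhat < 0] <- 0
    S[S < 0] <- 0
  }
  dimnames(Qhat) <- list(AA_ALPHA, AA_ALPHA)
  diag(Qhat) <- 0
  diag(Qhat) <- -rowSums(Qhat)
  structure(list(pihat = pihat, cov = covP, Qhat = Qhat, S = (S + t(S)) / 2),
            class = "averaged_model")
}

#' @export
print.averaged_model <- function(x, ...) {
  cat("averaged_model over sites: mean profile effective amino acids",
      format(effective_n_amino_acids(x$pihat), digits = 4), "\n")
  invisible(x)
}

#' Exchangeability matrix from site profiles
#'
#' The symmetric exchangeability implied by the covariance of site-specific
#' equilibrium frequencies, with the mutation term \eqn{v^S_{XY}} omitted (as
#' when comparing against empirical exchangeabilities estimated from
#' databases):
#' \deqn{S_{XY} = 1 + \mathrm{Cov}(\pi_{L,X}, \pi_{L,Y}) / (\hat\pi_X \hat\pi_Y).}
#'
#' @inheritParams average_model
#' @return 20x20 symmetric matrix. Rows/columns of amino acids never observed
#'   (\eqn{\hat\pi_X = 0}) are `NA`.
#' @export
exchangeability_from_profiles <- function(profiles) {
  P <- profiles_matrix(profiles)
  n <- nrow(P)
  if (n < 2) stop("need at least 2 site profiles (covariance undefined)")
  pihat <- colMeans(P)
  Pc <- sweep(P, 2, pihat)
  covP <- crossprod(Pc) / n
  S <- 1 + covP / outer(pihat, pihat)
  S[outer(pihat == 0, pihat == 0, "|")] <- NA_real_
  S <- (S + t(S)) / 2
  dimnames(S) <- list(AA_ALPHA, AA_ALPHA)
  S
}

#' Effective number of acceptable amino acids
#'
#' The exponential of the sequence entropy of a site profile,
#' \eqn{\Omega = \exp(-\sum_X \pi_X \ln \pi_X)}, with \eqn{0\ln 0 \equiv 0}.
#' Equals the number of amino acids that, if equally likely, would give the
#' same entropy: 1 for a fully conserved site, 20 for an unconstrained one.
#'
#' @param pi Site profile (nonnegative 20-vector summing to 1), or an
#'   n x 20 matrix of profiles.
#' @return Scalar (or vector, one per row) in \[1, 20\].
#' @examples
#' effective_n_amino_acids(rep(1/20, 20))            # 20
#' effective_n_amino_acids(c(1, rep(0, 19)))         # 1
#' @export
effective_n_amino_acids <- function(pi) {
  if (is.matrix(pi)) return(apply(pi, 1, effective_n_amino_acids))
  if (length(pi) != 20 || any(!is.finite(pi)) || any(pi < 0))
    stop("profile must be a nonnegative finite 20-vector")
  pl <- ifelse(pi > 0, pi * log(pi), 0)
  exp(-sum(pl))
}

#' Substitution rate relative to neutral
#'
#' The overall substitution rate of a site (or pooled) profile relative to the
#' neutral, mutation-limited rate:
#' \deqn{\omega = \frac{\sum_{\langle XY\rangle} \pi_X Q_{XY}}
#'   {\sum_{\langle XY\rangle} (d_X/61)\, v_{XY}}}
#' with \eqn{Q} from [rate_from_frequencies()] and the sums running over the
#' amino acid pairs connected by single-nucleotide codon changes (expanded as
#' ordered pairs consistently in numerator and denominator; the ratio is
#' invariant to that choice). Equals 1 when \eqn{\pi = \lambda} (the neutral
#' profile) and drops toward 0 as the profile concentrates.
#'
#' @inheritParams rate_from_frequencies
#' @return Nonnegative scalar \eqn{\omega}.
#' @export
relative_rate <- function(pi, mutation, pseudocount = 1e-10) {
  stopifnot(inherits(mutation, "mutation_model"))
  Q <- rate_from_frequencies(pi, mutation, pseudocount)
  acc <- mutation$accessible
  num <- sum((Q$stationary * Q$Q)[acc])
  den <- sum((mutation$lambda * mutation$v)[acc])  # = sum vS over ordered pairs
  num / den
}

#' Constraint statistics of a mixture of site classes
#'
#' For a CAT-style mixture of site classes, the effective number of acceptable
#' amino acids and the relative rate are reported as the class-weight averages
#' of the per-class statistics.
#'
#' @param class_profiles List of class profiles (20-vectors) or K x 20 matrix.
#' @param class_weights Nonnegative weights summing to 1, one per class.
#' @param mutation A `mutation_model`.
#' @param pseudocount Passed to [relative_rate()].
#' @return A one-row data.frame with columns `omega_eff` (mean \eqn{\Omega})
#'   and `rate_ratio` (mean \eqn{\omega}).
#' @export
mixture_statistics <- function(class_profiles, class_weights, mutation,
                               pseudocount = 1e-10) {
  P <- profiles_matrix(class_profiles)
  if (length(class_weights) != nrow(P))
    stop("class_weights length must match number of classes")
  if (any(class_weights < 0) || abs(sum(class_weights) - 1) > 1e-8)
    stop("class_weights must be nonnegative and sum to 1")
  om <- effective_n_amino_acids(P)
  rr <- apply(P, 1, relative_rate, mutation = mutation,
              pseudocount = pseudocount)
  data.frame(omega_eff = sum(class_weights * om),
             rate_ratio = sum(class_weights * rr))
}

#' Normalise a rate matrix to unit average rate
#'
#' Rescales a rate matrix so the expected number of substitutions per unit
#' time at stationarity is 1:
#' \eqn{\sum_X \pi_X \sum_{Y \ne X} Q_{XY} = 1}.
#'
#' @param Q A `site_rate_matrix`, or a plain 20x20 rate matrix together with
#'   `pi`.
#' @param pi Stationary profile (required when `Q` is a plain matrix).
#' @return Same type as the input, rescaled. Idempotent and invariant to
#'   input scaling.
#' @export
normalize_rate_matrix <- function(Q, pi = NULL) {
  if (inherits(Q, "site_rate_matrix")) {
    off <- Q$Q
    diag(off) <- 0
    r <- sum(Q$stationary * rowSums(off))
    if (r <= 0) stop("degenerate rate matrix: zero total rate")
    Q$Q <- Q$Q / r
    return(Q)
  }
  if (is.null(pi)) stop("pi required for a plain rate matrix")
  off <- Q
  diag(off) <- 0
  r <- sum(pi * rowSums(off))
  if (r <= 0) stop("degenerate rate matrix: zero total rate")
  Q / r
}
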