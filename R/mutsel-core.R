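#' Kimura fixation factor
#'
#' The factor by which selection scales the mutation rate in the diffusion
#' approximation: \eqn{S / (1 - e^{-S})} with \eqn{S = 4 N_e (m_Y - m_X)} the
#' population-scaled selection coefficient. Evaluated stably across the whole
#' real line: a series expansion is used for \eqn{|S| < 10^{-4}} (the
#' expression is 0/0 at neutrality) and `expm1` branches avoid overflow for
#' large \eqn{|S|}.
#'
#' @param S Population-scaled selection coefficient(s), finite numeric.
#' @return Nonnegative factor(s), same length as `S`. `fixation_factor(0)` is
#'   1 (neutral limit); the factor is strictly increasing in `S` and satisfies
#'   `fixation_factor(S) / fixation_factor(-S) == exp(S)`.
#' @examples
#' fixation_factor(0)        # 1
#' fixation_factor(3) / fixation_factor(-3)  # e^3
#' @export
fixation_factor <- function(S) {
  if (!is.numeric(S) || any(!is.finite(S)))
    stop("S must be finite numeric")
  out <- numeric(length(S))
  small <- abs(S) < 1e-4
  # S/(1-e^{-S}) = 1 + S/2 + S^2/12 - S^4/720 + ...
  out[small] <- 1 + S[small] / 2 + S[small]^2 / 12
  pos <- !small & S > 0
  out[pos] <- S[pos] / (-expm1(-S[pos]))
  neg <- !small & S < 0
  # S/(1-e^{-S}) = S e^S / (e^S - 1); stable for very negative S
  out[neg] <- S[neg] * exp(S[neg]) / expm1(S[neg])
  out
}

#' Site equilibrium amino acid distribution from fitnesses
#'
#' The stationary distribution of the site-specific mutation-selection
#' process: \eqn{\pi_X \propto \lambda_X e^{4 N_e m_X}}, where \eqn{m_X} is
#' the marginal Malthusian fitness of amino acid X at the site and
#' \eqn{\lambda_X} the genetic-code weight. Computed with max-shifted
#' exponentials so it never overflows.
#'
#' @param m Numeric 20-vector of marginal Malthusian fitnesses (alphabetical
#'   one-letter amino acid order).
#' @param Ne4 The population-scaled factor \eqn{4 N_e}; only the product
#'   \eqn{4 N_e m} matters.
#' @param mutation A `mutation_model` supplying \eqn{\lambda_X}.
#' @return A named 20-vector of equilibrium frequencies summing to 1.
#' @examples
#' mm <- mutation_model(kappa = 2)
#' p <- equilibrium_profile(rep(0, 20), Ne4 = 1000, mm)
#' all.equal(p, mm$lambda)  # selection-free limit: pi = lambda
#' @export
equilibrium_profile <- function(m, Ne4, mutation) {
  stopifnot(inherits(mutation, "mutation_model"))
  if (length(m) != 20 || any(!is.finite(m)))
    stop("m must be a finite 20-vector")
  s <- Ne4 * m
  w <- log(mutation$lambda) + s
  w <- exp(w - max(w))
  p <- w / sum(w)
  names(p) <- AA_ALPHA
  p
}

# Validate a site profile; optionally smooth zeros with a pseudocount.
as_profile <- function(pi, pseudocount = 0) {
  if (length(pi) != 20 || any(!is.finite(pi)) || any(pi < 0))
    stop("profile must be a nonnegative finite 20-vector")
  if (abs(sum(pi) - 1) > 1e-6) stop("profile must sum to 1")
  if (pseudocount > 0) pi <- pi + pseudocount
  pi <- pi / sum(pi)
  names(pi) <- AA_ALPHA
  pi
}

new_site_rate_matrix <- function(Q, pi) {
  dimnames(Q) <- list(AA_ALPHA, AA_ALPHA)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  structure(list(Q = Q, stationary = stats::setNames(pi, AA_ALPHA)),
            class = "site_rate_matrix")
}

#' Site substitution rate matrix from fitnesses
#'
#' The site-specific mutation-selection rate matrix
#' \eqn{Q_{XY} = v_{XY}\, S_{XY}/(1 - e^{-S_{XY}})} with
#' \eqn{S_{XY} = 4 N_e (m_Y - m_X)}.
#'
#' @inheritParams equilibrium_profile
#' @return A `site_rate_matrix`: list with 20x20 matrix `Q` (rows sum to 0)
#'   and its `stationary` profile. Satisfies detailed balance
#'   \eqn{\pi_X Q_{XY} = \pi_Y Q_{YX}}.
#' @export
rate_from_fitness <- function(m, Ne4, mutation) {
  stopifnot(inherits(mutation, "mutation_model"))
  if (length(m) != 20 || any(!is.finite(m)))
    stop("m must be a finite 20-vector")
  S <- Ne4 * outer(m, m, function(x, y) y - x)
  Q <- mutation$v * fixation_factor(S)
  new_site_rate_matrix(Q, equilibrium_profile(m, Ne4, mutation))
}

#' Site substitution rate matrix from equilibrium frequencies
#'
#' Re-expresses the mutation-selection rates in terms of the site's
#' equilibrium frequencies:
#' \deqn{Q_{XY} = v_{XY} \frac{\ln(\lambda_X \pi_Y / (\lambda_Y \pi_X))}
#'   {1 - \lambda_Y \pi_X / (\lambda_X \pi_Y)}}
#' which equals \eqn{v_{XY} S/(1-e^{-S})} with
#' \eqn{S = \ln(\lambda_X \pi_Y / (\lambda_Y \pi_X))}. When the frequency
#' ratio is 1 the stable neutral limit \eqn{Q_{XY} = v_{XY}} is returned.
#'
#' @param pi Site profile: nonnegative 20-vector summing to 1 (alphabetical
#'   amino acid order).
#' @param mutation A `mutation_model`.
#' @param pseudocount Smoothing mass added to every amino acid before
#'   renormalising when `pi` contains zeros (default 1e-10). Set to 0 to
#'   require strictly positive input.
#' @return A `site_rate_matrix` whose stationary distribution is (the
#'   smoothed) `pi`.
#' @examples
#' mm <- mutation_model(kappa = 2)
#' Q <- rate_from_frequencies(mm$lambda, mm)
#' max(abs(Q$Q[mm$accessible] - mm$v[mm$accessible]))  # ~0: neutral profile
#' @export
rate_from_frequencies <- function(pi, mutation, pseudocount = 1e-10) {
  stopifnot(inherits(mutation, "mutation_model"))
  pi <- as_profile(pi, pseudocount)
  if (any(pi <= 0))
    stop("pi must be strictly positive (use a pseudocount to smooth zeros)")
  lam <- mutation$lambda
  lp <- log(pi) - log(lam)
  S <- outer(lp, lp, function(x, y) y - x)  # S_XY = ln(lam_X pi_Y/(lam_Y pi_X))
  Q <- mutation$v * fixation_factor(S)
  new_site_rate_matrix(Q, pi)
}

#' F81-style rate matrix
#'
#' The exchangeability-times-frequency model with the symmetric part of the
#' mutation process as exchangeability: \eqn{Q_{XY} = v^S_{XY} \pi_Y}, an
#' amino acid analogue of the Felsenstein 1981 model with site-specific
#' frequencies and no physicochemical exchangeability term. It arises from
#' the frequency form of the mutation-selection rates by linearising each
#' logarithm (\eqn{\ln x \to x - 1}); this is a formal substitution that
#' preserves the stationary distribution and reversibility, not a numerical
#' approximation of the rates (the two parameterisations differ in their
#' pairwise time scales, which downstream normalisation absorbs).
#'
#' @inheritParams rate_from_frequencies
#' @return A `site_rate_matrix`. Its flux \eqn{\pi_X Q_{XY} =
#'   v^S_{XY}\pi_X\pi_Y} is symmetric.
#' @export
f81_rates <- function(pi, mutation, pseudocount = 0) {
  stopifnot(inherits(mutation, "mutation_model"))
  pi <- as_profile(pi, pseudocount)
  Q <- mutation$vS * rep(pi, each = 20)  # Q_XY = vS_XY * pi_Y
  new_site_rate_matrix(Q, pi)
}

#' Substitution flux of a site rate matrix
#'
#' \eqn{\Phi_{XY} = \pi_X Q_{XY}}: the expected number of X to Y substitutions
#' per unit time at stationarity. Symmetric for reversible processes.
#'
#' @param x A `site_rate_matrix`.
#' @return 20x20 matrix with zero diagonal.
#' @export
flux <- function(x) {
  stopifnot(inherits(x, "site_rate_matrix"))
  f <- x$stationary * x$Q
  diag(f) <- 0
  f
}

#' @export
print.site_rate_matrix <- function(x, ...) {
  off <- x$Q
  diag(off) <- 0
  rate <- sum(x$stationary * rowSums(off))
  cat("site_rate_matrix: 20x20, average rate", format(rate, digits = 4), "\n")
  cat(" stationary profile: effective amino acids",
      format(effective_n_amino_acids(x$stationary), digits = 4), "\n")
  invisible(x)
}
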