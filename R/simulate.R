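# Stable softplus: log(1 + e^x) without overflow.
softplus <- function(x) ifelse(x > 30, x + log1p(exp(-x)), log1p(exp(x)))

#' Instantaneous site-specific equilibrium profile
#'
#' For one site of a sequence evolving under stability selection, the
#' equilibrium distribution the site would reach if the rest of the sequence
#' stayed fixed: each candidate amino acid X is placed at the site, the
#' Malthusian fitness \eqn{m_X = \ln f} is computed from the folding free
#' energy, and the profile follows as
#' \eqn{\pi_X \propto \lambda_X e^{4 N_e m_X}}.
#'
#' @param seq Amino acid sequence (one-letter codes or integer indices).
#' @param site Site index (1-based).
#' @param model A `stability_model`.
#' @param mutation A `mutation_model` (supplies \eqn{\lambda_X}).
#' @param Ne4 Population-scaled factor \eqn{4 N_e}.
#' @return Named 20-vector summing to 1.
#' @export
instantaneous_site_profile <- function(seq, site, model, mutation, Ne4) {
  a <- seq_to_int(seq)
  stopifnot(site >= 1, site <= length(a))
  m <- vapply(1:20, function(b) {
    a2 <- a
    a2[site] <- b
    dG <- folding_free_energy(a2, model)
    -softplus(dG / model$kT)  # ln f
  }, numeric(1))
  equilibrium_profile(m, Ne4, mutation)
}

# Precompute codon machinery: neighbour targets and nucleotide rates.
codon_tables <- function(mutation) {
  code <- mutation$code
  n_codon <- length(code$codons)
  codon_index <- stats::setNames(seq_len(n_codon), code$codons)
  aa_of <- match(code$codon_to_aa[code$codons], AA_ALPHA)
  nb_target <- matrix(0L, n_codon, 9)
  nb_rate <- matrix(0, n_codon, 9)
  for (k in seq_len(n_codon)) {
    nb <- codon_neighbours(code$codons[k], mutation$nuc_rates)
    sense <- nb$to %in% code$codons
    nb_target[k, sense] <- codon_index[nb$to[sense]]
    nb_rate[k, ] <- nb$rate  # rate kept for all; stop targets masked by 0 index
  }
  list(codon_index = codon_index, aa_of = aa_of,
       nb_target = nb_target, nb_rate = nb_rate, codons = code$codons)
}

# Directed edge list (both directions) of a contact structure, 1-based.
edge_list <- function(structure) {
  cm <- structure$contacts
  if (nrow(cm) == 0) return(list(i = integer(0), j = integer(0)))
  list(i = c(cm[, 1], cm[, 2]) + 1L, j = c(cm[, 2], cm[, 1]) + 1L)
}

# Neighbour-residue interaction sums for every (site, candidate aa):
# R[i, b] = sum over structure-neighbours j of i of pot[b, a_j].
interaction_sums <- function(edges, a, pot, n) {
  if (length(edges$i) == 0) return(matrix(0, n, 20))
  counts <- tabulate((a[edges$j] - 1L) * n + edges$i, nbins = n * 20L)
  matrix(counts, n, 20) %*% pot
}

#' Simulate sequence evolution under stability selection
#'
#' Gillespie simulation of a codon sequence evolving under K80 nucleotide
#' mutation and selection for folding stability. Every single-nucleotide
#' neighbour of the current sequence (mutations to stop codons excluded) is
#' assigned rate = nucleotide mutation rate x Kimura fixation factor of
#' \eqn{4 N_e (m_Y - m_X)}, with Malthusian fitness \eqn{m = \ln f} and
#' \eqn{f} the folded probability of the mutant sequence. Time advances
#' exponentially with the total rate; substitutions are accepted in proportion
#' to their rates. The timing and nature of every substitution and the
#' instantaneous site-specific equilibrium frequencies are recorded.
#'
#' With `Ne4 = 0` selection is off and the process is pure mutation (the
#' neutral control).
#'
#' @param model A `stability_model`.
#' @param mutation A `mutation_model` (its `kappa` drives the nucleotide
#'   process; its \eqn{\lambda_X} the instantaneous profiles).
#' @param Ne4 Population-scaled factor \eqn{4 N_e} (default 1000).
#' @param duration Simulated time in neutral units (transversion rate = 1).
#'   May be `Inf` if `max_substitutions` is finite.
#' @param sample_interval Spacing of state samples at which per-site profiles,
#'   effective amino acid numbers, relative rates and \eqn{\Delta G} are
#'   recorded.
#' @param start_codons Optional character vector of sense codons (length =
#'   n_residues); default random sense codons.
#' @param max_substitutions Stop after this many substitution events
#'   (default `Inf`).
#' @param seed Optional integer seed; identical seed + configuration gives an
#'   identical trajectory.
#' @return Object of class `sf_trajectory`: list with
#'   \describe{
#'     \item{events}{data.frame (time, site, from_codon, to_codon, from_aa,
#'       to_aa), times strictly increasing.}
#'     \item{pi_resident}{(n_events + 1) x n_residues matrix: after each event
#'       (row 1 = initial state), the instantaneous equilibrium frequency of
#'       each site's resident amino acid.}
#'     \item{samples}{list with `time`, `profiles` (array samples x sites x
#'       20), `omega_eff`, `rate_ratio` (samples x sites), `dG`.}
#'     \item{config}{the simulation settings, including the seed.}
#'     \item{final_codons}{the end-state codon sequence.}
#'   }
#' @export
sf_simulate <- function(model, mutation, Ne4 = 1000, duration = Inf,
                        sample_interval = 1, start_codons = NULL,
                        max_substitutions = Inf, seed = NULL) {
  stopifnot(inherits(model, "stability_model"),
            inherits(mutation, "mutation_model"))
  if (!is.finite(duration) && !is.finite(max_substitutions))
    stop("either duration or max_substitutions must be finite")
  if (is.finite(duration) && duration <= 0) stop("duration must be positive")
  if (!is.null(seed)) set.seed(seed)
  n <- model$native$n_residues
  ct <- codon_tables(mutation)
  kT <- model$kT
  pot <- model$potential
  neutral <- (Ne4 == 0)

  if (is.null(start_codons)) {
    codons <- sample.int(length(ct$codons), n, replace = TRUE)
  } else {
    if (length(start_codons) != n) stop("start_codons must have length n_residues")
    codons <- ct$codon_index[start_codons]
    if (any(is.na(codons))) stop("start_codons must all be sense codons")
    codons <- unname(codons)
  }
  a <- ct$aa_of[codons]

  structs <- c(list(model$native), model$decoys)
  K <- length(model$decoys)
  edges <- lapply(structs, edge_list)
  E <- vapply(seq_along(structs), function(s) {
    cm <- structs[[s]]$contacts
    if (nrow(cm) == 0) return(0)
    sum(pot[cbind(a[cm[, 1] + 1L], a[cm[, 2] + 1L])])
  }, numeric(1))

  log_lambda <- log(mutation$lambda)
  site_seq <- seq_len(n)

  # per-event records
  ev_time <- numeric(0); ev_site <- integer(0)
  ev_fromc <- integer(0); ev_toc <- integer(0)
  pi_res <- list()

  # sample records
  s_time <- numeric(0); s_prof <- list(); s_dG <- numeric(0)
  next_sample <- 0  # sample at t = 0, sample_interval, 2*sample_interval, ...

  t_now <- 0
  n_events <- 0L

  repeat {
    # --- fitness landscape of all single-aa variants of the current sequence
    if (neutral) {
      m_mat <- matrix(0, n, 20)
      prof <- matrix(rep(mutation$lambda, each = n), n, 20)
    } else {
      R_list <- lapply(edges, interaction_sums, a = a, pot = pot, n = n)
      delta <- lapply(seq_along(R_list), function(s) {
        R <- R_list[[s]]
        R - R[cbind(site_seq, a)]
      })
      Enat <- E[1] + delta[[1]]
      mu <- Reduce(`+`, lapply(2:(K + 1), function(s) E[s] + delta[[s]])) / K
      m2 <- Reduce(`+`, lapply(2:(K + 1), function(s) (E[s] + delta[[s]])^2))
      sg2 <- pmax(0, (m2 - K * mu^2) / (K - 1))
      dG_mat <- Enat + kT * (model$log_n_unfolded - mu / kT + sg2 / (2 * kT^2))
      m_mat <- -softplus(dG_mat / kT)
      w <- Ne4 * m_mat + rep(log_lambda, each = n)
      w <- exp(w - apply(w, 1, max))
      prof <- w / rowSums(w)
    }
    pi_res[[n_events + 1L]] <- prof[cbind(site_seq, a)]

    # --- rates of all single-nucleotide moves
    targets <- ct$nb_target[codons, , drop = FALSE]   # n x 9 (0 = stop)
    mu_rate <- ct$nb_rate[codons, , drop = FALSE]
    valid <- which(targets > 0L)
    i_idx <- ((valid - 1L) %% n) + 1L
    tgt <- targets[valid]
    b <- ct$aa_of[tgt]
    S <- Ne4 * (m_mat[cbind(i_idx, b)] - m_mat[cbind(i_idx, a[i_idx])])
    rates <- mu_rate[valid] * fixation_factor(S)
    total <- sum(rates)
    if (total <= 0) stop("zero total rate: no accessible moves")

    dt <- stats::rexp(1, total)
    t_next <- t_now + dt
    t_stop <- min(duration, t_next)

    # samples fall in [t_now, t_stop): state is constant there
    while (next_sample <= t_stop && next_sample <= duration) {
      s_time <- c(s_time, next_sample)
      s_prof[[length(s_prof) + 1L]] <- prof
      s_dG <- c(s_dG, if (neutral)
        folding_free_energy(a, model) else
          E[1] + kT * (model$log_n_unfolded -
                         mean(E[2:(K + 1)]) / kT +
                         stats::var(E[2:(K + 1)]) / (2 * kT^2)))
      next_sample <- next_sample + sample_interval
    }

    if (t_next > duration || n_events >= max_substitutions) break

    # --- accept one substitution
    j <- sample.int(length(rates), 1, prob = rates)
    i <- i_idx[j]
    new_codon <- tgt[j]
    n_events <- n_events + 1L
    ev_time <- c(ev_time, t_next); ev_site <- c(ev_site, i)
    ev_fromc <- c(ev_fromc, codons[i]); ev_toc <- c(ev_toc, new_codon)
    b_new <- ct$aa_of[new_codon]
    if (b_new != a[i] && !neutral) {
      for (s in seq_along(structs)) {
        R <- R_list[[s]]
        E[s] <- E[s] + R[i, b_new] - R[i, a[i]]
      }
    }
    codons[i] <- new_codon
    a[i] <- b_new
    t_now <- t_next
  }

  events <- data.frame(
    time = ev_time, site = ev_site,
    from_codon = ct$codons[ev_fromc], to_codon = ct$codons[ev_toc],
    from_aa = AA_ALPHA[ct$aa_of[ev_fromc]], to_aa = AA_ALPHA[ct$aa_of[ev_toc]],
    stringsAsFactors = FALSE)

  ns <- length(s_time)
  prof_arr <- array(0, dim = c(ns, n, 20))
  for (q in seq_len(ns)) prof_arr[q, , ] <- s_prof[[q]]
  omega_eff <- if (ns) t(apply(prof_arr, 1, function(p)
    effective_n_amino_acids(matrix(p, n, 20)))) else matrix(0, 0, n)
  rr <- if (ns) t(vapply(seq_len(ns), function(q)
    vapply(seq_len(n), function(i)
      relative_rate(prof_arr[q, i, ], mutation), numeric(1)),
    numeric(n))) else matrix(0, 0, n)

  structure(list(
    events = events,
    pi_resident = do.call(rbind, pi_res),
    samples = list(time = s_time, profiles = prof_arr,
                   omega_eff = omega_eff, rate_ratio = rr, dG = s_dG),
    config = list(Ne4 = Ne4, duration = duration,
                  sample_interval = sample_interval, kappa = mutation$kappa,
                  n_residues = n, n_decoys = K,
                  log_n_unfolded = model$log_n_unfolded, seed = seed,
                  max_substitutions = max_substitutions),
    final_codons = ct$codons[codons]),
    class = "sf_trajectory")
}

#' @export
print.sf_trajectory <- function(x, ...) {
  cat("sf_trajectory:", nrow(x$events), "substitutions over time",
      format(max(c(0, x$events$time)), digits = 4),
      "(", x$config$n_residues, "residues, 4Ne =", x$config$Ne4, ")\n")
  cat(" samples:", length(x$samples$time), "\n")
  invisible(x)
}

#' @export
summary.sf_trajectory <- function(object, burn_in_time = 0, ...) {
  keep <- object$samples$time >= burn_in_time
  ev <- object$events[object$events$time >= burn_in_time, ]
  out <- list(
    n_substitutions = nrow(ev),
    n_nonsynonymous = sum(ev$from_aa != ev$to_aa),
    mean_dG = mean(object$samples$dG[keep]),
    mean_omega_eff = mean(object$samples$omega_eff[keep, ]),
    mean_rate_ratio = mean(object$samples$rate_ratio[keep, ]))
  class(out) <- "summary.sf_trajectory"
  out
}

#' @export
print.summary.sf_trajectory <- function(x, ...) {
  cat("substitutions:", x$n_substitutions,
      "(nonsynonymous:", x$n_nonsynonymous, ")\n")
  cat("mean dG:", format(x$mean_dG, digits = 4),
      " mean per-site effective amino acids:",
      format(x$mean_omega_eff, digits = 4),
      " mean relative rate:", format(x$mean_rate_ratio, digits = 4), "\n")
  invisible(x)
}

#' @export
plot.sf_trajectory <- function(x, site = 1, ...) {
  st <- x$samples$time
  graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  graphics::plot(st, x$samples$dG, type = "l", xlab = "time",
                 ylab = expression(Delta * G), ...)
  graphics::plot(st, x$samples$omega_eff[, site], type = "l", xlab = "time",
                 ylab = bquote(Omega ~ "site" ~ .(site)), ...)
  invisible(x)
}

#' Burn-in point of a trajectory
#'
#' Declares when the simulation has reached mutational drift-selection
#' balance. The default criterion is a fixed count of substitutions
#' (10 x n_residues); the `"trend"` criterion instead requires no significant
#' linear trend (at level `alpha`) in the \eqn{\Delta G} trace over the second
#' half of the sampled period and returns the half-way time point.
#'
#' @param trajectory An `sf_trajectory`.
#' @param criterion `"substitutions"` or `"trend"`.
#' @param n_substitutions Substitution count for the default criterion.
#' @param alpha Significance level for the trend test.
#' @return List with `time` (burn-in time point) and `converged` (logical).
#'   When the criterion cannot be satisfied, `converged` is `FALSE` and `time`
#'   is `NA` — never a silent success.
#' @export
burn_in <- function(trajectory, criterion = c("substitutions", "trend"),
                    n_substitutions = 10 * trajectory$config$n_residues,
                    alpha = 0.05) {
  stopifnot(inherits(trajectory, "sf_trajectory"))
  criterion <- match.arg(criterion)
  if (criterion == "substitutions") {
    if (nrow(trajectory$events) < n_substitutions)
      return(list(time = NA_real_, converged = FALSE))
    return(list(time = trajectory$events$time[n_substitutions],
                converged = TRUE))
  }
  st <- trajectory$samples$time
  if (length(st) < 10) return(list(time = NA_real_, converged = FALSE))
  half <- st >= stats::median(st)
  fit <- stats::lm(trajectory$samples$dG[half] ~ st[half])
  p <- summary(fit)$coefficients[2, 4]
  if (p < alpha) return(list(time = NA_real_, converged = FALSE))
  list(time = stats::median(st), converged = TRUE)
}

#' Spatial and temporal heterogeneity statistics of a trajectory
#'
#' Computes the three averaging levels of the constraint statistics from a
#' stability-selection run:
#' \describe{
#'   \item{SF}{instantaneous: one \eqn{(\Omega, \omega)} per site per sampled
#'     time point;}
#'   \item{SF-T}{temporal averaging removed: per site, \eqn{(\Omega, \omega)}
#'     of the time-averaged profile;}
#'   \item{SF-TS}{temporal and spatial averaging: a single
#'     \eqn{(\Omega, \omega)} of the site-and-time-averaged profile.}
#' }
#' Because the entropy is concave, each averaging step can only increase the
#' apparent number of acceptable amino acids.
#'
#' @param trajectory An `sf_trajectory` with at least 2 samples after
#'   `burn_in_time`.
#' @param mutation The `mutation_model` used for relative rates.
#' @param burn_in_time Samples at or before this time are discarded.
#' @return List with data.frames `SF` (sample, site, omega_eff, rate_ratio),
#'   `SF_T` (site, omega_eff, rate_ratio) and `SF_TS` (one row), plus
#'   `summary` (label, mean omega_eff, mean rate_ratio, and 16th/84th
#'   percentile columns).
#' @export
sf_statistics <- function(trajectory, mutation, burn_in_time = 0) {
  stopifnot(inherits(trajectory, "sf_trajectory"),
            inherits(mutation, "mutation_model"))
  keep <- which(trajectory$samples$time > burn_in_time)
  if (length(keep) < 2)
    stop("need at least 2 post-burn-in samples")
  n <- trajectory$config$n_residues
  prof <- trajectory$samples$profiles[keep, , , drop = FALSE]

  sf <- data.frame(
    sample = rep(keep, n),
    site = rep(seq_len(n), each = length(keep)),
    omega_eff = as.vector(trajectory$samples$omega_eff[keep, ]),
    rate_ratio = as.vector(trajectory$samples$rate_ratio[keep, ]))

  tavg <- apply(prof, c(2, 3), mean)   # n x 20, dwell-weighted (equal spacing)
  sft <- data.frame(
    site = seq_len(n),
    omega_eff = effective_n_amino_acids(tavg),
    rate_ratio = apply(tavg, 1, relative_rate, mutation = mutation))

  tsavg <- colMeans(tavg)
  sfts <- data.frame(
    omega_eff = effective_n_amino_acids(tsavg),
    rate_ratio = relative_rate(tsavg, mutation))

  q68 <- function(x) stats::quantile(x, c(0.16, 0.84), names = FALSE)
  summary_df <- data.frame(
    label = c("SF", "SF-T", "SF-TS"),
    omega_eff = c(mean(sf$omega_eff), mean(sft$omega_eff), sfts$omega_eff),
    rate_ratio = c(mean(sf$rate_ratio), mean(sft$rate_ratio), sfts$rate_ratio),
    omega_eff_q16 = c(q68(sf$omega_eff)[1], q68(sft$omega_eff)[1], NA),
    omega_eff_q84 = c(q68(sf$omega_eff)[2], q68(sft$omega_eff)[2], NA),
    rate_ratio_q16 = c(q68(sf$rate_ratio)[1], q68(sft$rate_ratio)[1], NA),
    rate_ratio_q84 = c(q68(sf$rate_ratio)[2], q68(sft$rate_ratio)[2], NA))

  list(SF = sf, SF_T = sft, SF_TS = sfts, summary = summary_df)
}

#' Evolutionary Stokes shift test
#'
#' After an amino acid fixes at a site, the rest of the protein gradually
#' adapts to it, raising the resident's instantaneous equilibrium frequency.
#' This function compares, for every nonsynonymous substitution after burn-in
#' whose residue stays resident for `lag_events` further substitutions
#' (anywhere in the protein), the resident's instantaneous frequency
#' immediately after fixation with its frequency `lag_events` substitutions
#' later, and applies a one-sided sign test for an increase.
#'
#' @param trajectory An `sf_trajectory`.
#' @param lag_events Number of subsequent substitution events defining "long
#'   after" (default: one expected substitution per site, i.e. n_residues).
#' @param burn_in_time Events at or before this time are ignored.
#' @return List with `n_pairs`, `n_increase`, `p_value` (one-sided sign
#'   test), `mean_shift` (mean frequency change), and the per-pair data.frame.
#' @export
stokes_shift_test <- function(trajectory, lag_events = NULL,
                              burn_in_time = 0) {
  stopifnot(inherits(trajectory, "sf_trajectory"))
  if (is.null(lag_events)) lag_events <- trajectory$config$n_residues
  ev <- trajectory$events
  n_ev <- nrow(ev)
  rows <- list()
  for (e in seq_len(n_ev)) {
    if (ev$time[e] <= burn_in_time) next
    if (ev$from_aa[e] == ev$to_aa[e]) next
    e2 <- e + lag_events
    if (e2 > n_ev) break
    i <- ev$site[e]
    window <- (e + 1):e2
    moved <- ev$site[window] == i & ev$from_aa[window] != ev$to_aa[window]
    if (any(moved)) next
    # pi_resident row e+1 = state just after event e
    rows[[length(rows) + 1L]] <- data.frame(
      event = e, site = i, aa = ev$to_aa[e],
      pi_after = trajectory$pi_resident[e + 1L, i],
      pi_later = trajectory$pi_resident[e2 + 1L, i])
  }
  if (length(rows) == 0)
    stop("no eligible substitution pairs; trajectory too short for lag")
  d <- do.call(rbind, rows)
  inc <- d$pi_later > d$pi_after
  dec <- d$pi_later < d$pi_after
  nz <- sum(inc) + sum(dec)
  p <- stats::binom.test(sum(inc), nz, alternative = "greater")$p.value
  list(n_pairs = nrow(d), n_increase = sum(inc), p_value = p,
       mean_shift = mean(d$pi_later - d$pi_after), pairs = d)
}

#' Write a trajectory as JSON lines
#'
#' One JSON object per line: substitution events
#' (`{"type":"event","time":...,"site":...,"from_codon":...,"to_codon":...}`,
#' sites 1-based) followed by state samples (time, dG, per-site omega_eff and
#' rate_ratio). A leading header line records the configuration and seed.
#'
#' @param trajectory An `sf_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_jsonl <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "sf_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(c(list(type = "header"), trajectory$config),
                              auto_unbox = TRUE, null = "null", digits = NA),
             con)
  ev <- trajectory$events
  for (e in seq_len(nrow(ev)))
    writeLines(jsonlite::toJSON(list(type = "event", time = ev$time[e],
                                     site = ev$site[e],
                                     from_codon = ev$from_codon[e],
                                     to_codon = ev$to_codon[e]),
                                auto_unbox = TRUE, digits = NA), con)
  s <- trajectory$samples
  for (q in seq_along(s$time))
    writeLines(jsonlite::toJSON(list(type = "sample", time = s$time[q],
                                     dG = s$dG[q],
                                     omega_eff = round(s$omega_eff[q, ], 6),
                                     rate_ratio = round(s$rate_ratio[q, ], 6)),
                                auto_unbox = TRUE, digits = NA), con)
  invisible(path)
}
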