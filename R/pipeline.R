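# Write a TSV with a commented header recording the seed/configuration.
write_run_tsv <- function(df, path, seed, extra = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# seed=", if (is.null(seed)) "NA" else seed,
                    if (!is.null(extra)) paste0(" ", extra) else ""), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Obtain site profiles either from an alignment file or from the synthetic
# generator; shared by the pipeline commands.
resolve_profiles <- function(alignment = NULL, format = "fasta",
                             n_sites = 500, seed = NULL,
                             profile_args = list(), site_args = list()) {
  if (!is.null(alignment)) {
    aln <- read_alignment(alignment, format)
    ps <- do.call(site_profiles, c(list(aln), site_args))
    if (!is.null(ps$rejected))
      stop("alignment rejected: ", ps$rejected)
    return(ps)
  }
  gp <- do.call(generate_profiles,
                c(list(n_sites = n_sites, seed = seed), profile_args))
  structure(list(profiles = gp$profiles,
                 kept_columns = seq_len(nrow(gp$profiles)) - 1L,
                 weights = NULL, rejected = NULL,
                 filters = list(synthetic = TRUE)),
            class = "alignment_profiles")
}

#' Frequency-covariance scatter analysis
#'
#' For chosen amino acid pairs, extracts the per-site equilibrium frequency
#' pairs (from an alignment or from synthetic profiles) and their Pearson
#' correlations — the raw material behind covariance-based exchangeabilities.
#' Physicochemically similar pairs (e.g. I-V) correlate positively across
#' sites; dissimilar pairs (e.g. L-S) do not.
#'
#' @param pairs List of 2-vectors of one-letter codes (default I-V and L-S).
#' @param alignment Optional path to an alignment file; when `NULL`, profiles
#'   are generated synthetically.
#' @param format Alignment format, `"fasta"` or `"stockholm"`.
#' @param n_sites Number of synthetic sites when no alignment is given.
#' @param seed Seed for the synthetic generator.
#' @param outdir Optional output directory: per-pair scatter TSVs and a
#'   correlation summary are written with the seed in a commented header.
#' @param ... Passed to [generate_profiles()] (synthetic route).
#' @return List with `scatter` (named list of per-pair data.frames) and
#'   `correlations` (data.frame pair, correlation).
#' @export
run_frequency_scatter <- function(pairs = list(c("I", "V"), c("L", "S")),
                                  alignment = NULL, format = "fasta",
                                  n_sites = 500, seed = 1, outdir = NULL,
                                  ...) {
  ps <- resolve_profiles(alignment, format, n_sites, seed,
                         profile_args = list(...))
  scatter <- lapply(pairs, function(p) frequency_scatter(ps, p))
  names(scatter) <- vapply(pairs, paste, character(1), collapse = "")
  cors <- data.frame(
    pair = names(scatter),
    correlation = vapply(scatter, attr, numeric(1), "correlation"))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(scatter))
      write_run_tsv(scatter[[nm]], file.path(outdir, paste0("scatter_", nm, ".tsv")), seed)
    write_run_tsv(cors, file.path(outdir, "scatter_correlations.tsv"), seed)
  }
  list(scatter = scatter, correlations = cors)
}

#' Exchangeability comparison against standard substitution models
#'
#' Computes the covariance-based exchangeability matrix from site profiles
#' (mutation term omitted), normalises it and each bundled standard model to
#' unit average substitution rate, and reports Pearson and Spearman
#' correlations between the off-diagonal exchangeabilities, restricted to
#' amino acid pairs connected by single-nucleotide codon changes.
#'
#' @inheritParams run_frequency_scatter
#' @param mutation A `mutation_model`, used only for the single-step pair
#'   restriction.
#' @param models Named paths to PAML .dat files (default
#'   [standard_model_files()]).
#' @param profiles Optional n x 20 profile matrix (or `alignment_profiles`
#'   object) used directly instead of the alignment/synthetic routes.
#' @return List with `S` (normalised profile-based exchangeability matrix)
#'   and `comparison` (data.frame model, pearson, spearman).
#' @export
run_exchangeability_comparison <- function(alignment = NULL, format = "fasta",
                                           n_sites = 500, seed = 1,
                                           mutation = mutation_model(kappa = 2),
                                           models = standard_model_files(),
                                           profiles = NULL,
                                           outdir = NULL, ...) {
  P <- if (!is.null(profiles)) {
    if (inherits(profiles, "alignment_profiles")) profiles$profiles else
      profiles_matrix(profiles)
  } else {
    resolve_profiles(alignment, format, n_sites, seed,
                     profile_args = list(...))$profiles
  }
  S <- exchangeability_from_profiles(P)
  pihat <- colMeans(P)
  acc <- mutation$accessible & upper.tri(mutation$accessible)
  # normalise both sides so the implied rate matrix Q = S pi_Y has unit rate
  norm_S <- function(S, pi) {
    Q <- S * rep(pi, each = 20)
    diag(Q) <- 0
    S / sum(pi * rowSums(Q))
  }
  Sn <- norm_S(S, pihat)
  comparison <- do.call(rbind, lapply(names(models), function(nm) {
    std <- read_paml_dat(models[[nm]])
    Sstd <- norm_S(std$exchangeability, std$frequencies)
    x <- Sn[acc]
    y <- Sstd[acc]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(data.frame(model = nm, pearson = NA_real_, spearman = NA_real_))
    data.frame(model = nm,
               pearson = stats::cor(x[ok], y[ok]),
               spearman = stats::cor(x[ok], y[ok], method = "spearman"))
  }))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_aa_tsv(Sn, file.path(outdir, "exchangeability.tsv"))
    write_run_tsv(comparison, file.path(outdir, "exchangeability_comparison.tsv"), seed)
  }
  list(S = Sn, comparison = comparison)
}

#' The constraint-rate plane
#'
#' Assembles \eqn{(\Omega, \omega)} points — effective number of acceptable
#' amino acids versus substitution rate relative to neutral — for any of:
#' the bundled standard substitution models, a CAT-style mixture class file,
#' site profiles (from an alignment or the synthetic generator), and a
#' stability-selection simulation (SF, SF-T, SF-TS averaging levels).
#' Per-site/per-sample sets carry 16th/84th percentile columns (a central 68%
#' interval).
#'
#' @param standard_models Named PAML .dat paths, or `NULL` to skip.
#' @param mixture_file Optional TSV of mixture classes
#'   (see [read_mixture_classes()]).
#' @param profiles Optional n x 20 matrix of site profiles (or an
#'   `alignment_profiles` object).
#' @param trajectory Optional `sf_trajectory`; its burn-in is determined with
#'   [burn_in()].
#' @param mutation A `mutation_model`.
#' @param pseudocount Smoothing for [relative_rate()] on empirical profiles.
#' @param seed Recorded in output headers.
#' @param outdir Optional output directory for the points TSV.
#' @return data.frame with columns label, omega_eff, rate_ratio,
#'   omega_eff_q16, omega_eff_q84, rate_ratio_q16, rate_ratio_q84.
#' @export
run_omega_plane <- function(standard_models = standard_model_files(),
                            mixture_file = NULL, profiles = NULL,
                            trajectory = NULL,
                            mutation = mutation_model(kappa = 2),
                            pseudocount = 1e-10, seed = 1, outdir = NULL) {
  q68 <- function(x) stats::quantile(x, c(0.16, 0.84), names = FALSE)
  row1 <- function(label, om, rr) {
    data.frame(label = label,
               omega_eff = mean(om), rate_ratio = mean(rr),
               omega_eff_q16 = if (length(om) > 1) q68(om)[1] else NA,
               omega_eff_q84 = if (length(om) > 1) q68(om)[2] else NA,
               rate_ratio_q16 = if (length(rr) > 1) q68(rr)[1] else NA,
               rate_ratio_q84 = if (length(rr) > 1) q68(rr)[2] else NA)
  }
  out <- list()
  for (nm in names(standard_models)) {
    std <- read_paml_dat(standard_models[[nm]])
    out[[length(out) + 1L]] <- row1(
      nm, effective_n_amino_acids(std$frequencies),
      relative_rate(std$frequencies, mutation, pseudocount))
  }
  if (!is.null(mixture_file)) {
    mx <- read_mixture_classes(mixture_file)
    ms <- mixture_statistics(mx$profiles, mx$weights, mutation, pseudocount)
    out[[length(out) + 1L]] <- row1(basename(mixture_file),
                                    ms$omega_eff, ms$rate_ratio)
  }
  if (!is.null(profiles)) {
    P <- if (inherits(profiles, "alignment_profiles")) profiles$profiles else
      profiles_matrix(profiles)
    om <- effective_n_amino_acids(P)
    rr <- apply(P, 1, relative_rate, mutation = mutation,
                pseudocount = pseudocount)
    out[[length(out) + 1L]] <- row1("profiles", om, rr)
  }
  if (!is.null(trajectory)) {
    bi <- burn_in(trajectory)
    if (!bi$converged) stop("trajectory not converged: burn-in criterion unmet")
    st <- sf_statistics(trajectory, mutation, burn_in_time = bi$time)
    out[[length(out) + 1L]] <- row1("SF", st$SF$omega_eff, st$SF$rate_ratio)
    out[[length(out) + 1L]] <- row1("SF-T", st$SF_T$omega_eff, st$SF_T$rate_ratio)
    out[[length(out) + 1L]] <- row1("SF-TS", st$SF_TS$omega_eff, st$SF_TS$rate_ratio)
  }
  res <- do.call(rbind, out)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_run_tsv(res, file.path(outdir, "omega_plane.tsv"), seed)
  }
  res
}

#' @export
plot.averaged_model <- function(x, reference = NULL, ...) {
  acc <- upper.tri(x$S)
  if (is.null(reference)) {
    graphics::plot(x$pihat, effective_n_amino_acids(x$pihat) + 0 * x$pihat,
                   xlab = "mean frequency", ylab = "", type = "h", ...)
  } else {
    graphics::plot(reference[acc], x$S[acc], log = "xy",
                   xlab = "reference exchangeability",
                   ylab = "profile-based exchangeability", ...)
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}
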