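# Shared fixtures, built in code.

mm2 <- mutation_model(kappa = 2)

# Random strictly positive profile.
random_profile <- function() {
  p <- rgamma(20, shape = 1)
  p / sum(p)
}

# Reduced stability-selection run shared by the simulator and acceptance
# tests: 50 residues, 10 decoys, drift-selection balance reached, several
# thousand post-burn-in substitutions. Built once per test session.
.sf_cache <- new.env(parent = emptyenv())

reduced_sf_run <- function() {
  if (!is.null(.sf_cache$traj)) return(.sf_cache$traj)
  st <- generate_structure(50, contact_density = 0.085, n_decoys = 10,
                           seed = 5)
  sm <- stability_model(st$native, st$decoys, log_n_unfolded = 0.9 * 50)
  traj <- sf_simulate(sm, mm2, Ne4 = 1000, duration = Inf,
                      max_substitutions = 4000, sample_interval = 0.05,
                      seed = 2)
  .sf_cache$traj <- traj
  traj
}

# Small FASTA fixture written to a temp file.
write_temp_fasta <- function(seqs, ids = paste0("s", seq_along(seqs))) {
  path <- tempfile(fileext = ".fasta")
  writeLines(unlist(Map(function(i, s) c(paste0(">", i), s), ids, seqs)), path)
  path
}
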