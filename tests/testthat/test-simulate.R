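small_system <- function(seed = 9, n = 12, decoys = 4) {
  st <- generate_structure(n, 0.12, n_decoys = decoys, seed = seed)
  stability_model(st$native, st$decoys, log_n_unfolded = 0.9 * n)
}

test_that("identical seed and configuration give identical trajectories", {
  sm <- small_system()
  t1 <- sf_simulate(sm, mm2, Ne4 = 500, duration = 0.5, sample_interval = 0.1,
                    seed = 42)
  t2 <- sf_simulate(sm, mm2, Ne4 = 500, duration = 0.5, sample_interval = 0.1,
                    seed = 42)
  expect_identical(t1$events, t2$events)
  expect_identical(t1$samples$profiles, t2$samples$profiles)
  expect_true(all(diff(t1$events$time) > 0))
  # consecutive codons differ in exactly one nucleotide
  nd <- mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
               t1$events$from_codon, t1$events$to_codon)
  expect_true(all(nd == 1))
})

test_that("neutral dynamics run at the mutation-limited rate", {
  sm <- small_system(seed = 11, n = 30)
  dur <- 10
  tr <- sf_simulate(sm, mm2, Ne4 = 0, duration = dur, sample_interval = 5,
                    seed = 7)
  n_ev <- nrow(tr$events)
  # exact neutral expectation: K80 rates are symmetric, so the sense-codon
  # chain is uniform at stationarity; expected total rate = n x mean over
  # codons of the rate mass toward sense neighbours
  gc <- genetic_code()
  r2 <- k80_rates(2)
  per_codon <- vapply(gc$codons, function(cod) {
    sp <- strsplit(cod, "")[[1]]
    tot <- 0
    for (pos in 1:3) for (b in setdiff(c("A", "C", "G", "T"), sp[pos])) {
      nb <- sp; nb[pos] <- b
      if (paste(nb, collapse = "") %in% gc$codons)
        tot <- tot + r2[sp[pos], b]
    }
    tot
  }, numeric(1))
  expected <- dur * 30 * mean(per_codon)
  expect_lt(abs(n_ev - expected), 3.5 * sqrt(expected))
  # relative rates are mutation-limited with selection off
  expect_equal(unique(as.vector(tr$samples$rate_ratio)), 1, tolerance = 1e-8)
  expect_equal(unique(as.vector(tr$samples$omega_eff)),
               effective_n_amino_acids(mm2$lambda), tolerance = 1e-8)
})

test_that("universally lethal replacements yield zero amino acid substitutions", {
  # potential with a unique optimum (all-alanine): every replacement breaks an
  # A-A contact, so with enormous 4Ne every nonsynonymous move has rate 0
  n <- 10
  pot <- matrix(0, 20, 20)
  pot[1, 1] <- -1  # alanine self-contact only
  ring <- cbind(0:(n - 3), 2:(n - 1))
  native <- contact_structure(n, ring)
  empty <- contact_structure(n, matrix(integer(0), 0, 2))
  sm <- stability_model(native, list(empty, empty), potential = pot,
                        log_n_unfolded = 2)
  tr <- sf_simulate(sm, mutation_model(kappa = 2), Ne4 = 1e6, duration = 2,
                    sample_interval = 1, seed = 3,
                    start_codons = rep("GCT", n))  # all alanine
  expect_equal(sum(tr$events$from_aa != tr$events$to_aa), 0)
  expect_gt(nrow(tr$events), 0)  # synonymous changes still occur
})

test_that("the simulator's internal profiles match the direct computation", {
  sm <- small_system(seed = 15)
  tr <- sf_simulate(sm, mm2, Ne4 = 800, duration = 0.05, sample_interval = 0.01,
                    seed = 5, start_codons = NULL)
  # the sample at t = 0 reflects the start state; instantaneous_site_profile
  # is the slow reference implementation of the vectorised internal path.
  # Recover start codons by rewinding the event list from the final state.
  gc <- genetic_code()
  codons <- tr$final_codons
  for (e in rev(seq_len(nrow(tr$events))))
    codons[tr$events$site[e]] <- tr$events$from_codon[e]
  seq0 <- unname(gc$codon_to_aa[codons])
  for (site in c(1, 5, 12)) {
    ref <- instantaneous_site_profile(seq0, site, sm, mm2, Ne4 = 800)
    expect_equal(unname(tr$samples$profiles[1, site, ]), unname(ref),
                 tolerance = 1e-9)
  }
})

test_that("sites without contacts have the neutral codon profile", {
  native <- contact_structure(9, rbind(c(0, 4), c(1, 6)))
  d1 <- contact_structure(9, rbind(c(0, 5), c(2, 7)))
  d2 <- contact_structure(9, rbind(c(1, 4), c(3, 6)))
  sm <- stability_model(native, list(d1, d2), log_n_unfolded = 5)
  # residue 9 (1-based) = index 8 has no contact in any structure
  p <- instantaneous_site_profile(rep("A", 9), 9, sm, mm2, Ne4 = 1000)
  expect_equal(p, mm2$lambda, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(sum(p), 1, tolerance = 1e-12)
})

test_that("burn-in criteria report convergence honestly", {
  tr <- reduced_sf_run()
  bi <- burn_in(tr)
  expect_true(bi$converged)
  expect_equal(bi$time, tr$events$time[10 * tr$config$n_residues])
  # not enough substitutions: explicit failure
  short <- tr
  short$events <- tr$events[1:10, ]
  expect_false(burn_in(short)$converged)
  expect_true(is.na(burn_in(short)$time))
  # white-noise dG trace: trend test accepts
  set.seed(20)
  fake <- structure(list(
    events = tr$events,
    samples = list(time = seq(0, 10, length.out = 200), dG = rnorm(200)),
    config = list(n_residues = 50)), class = "sf_trajectory")
  expect_true(burn_in(fake, criterion = "trend")$converged)
  # strongly trending trace: not converged
  fake$samples$dG <- seq(0, -20, length.out = 200) + rnorm(200, sd = 0.1)
  expect_false(burn_in(fake, criterion = "trend")$converged)
})

test_that("averaging heterogeneity away inflates the apparent amino acid count", {
  tr <- reduced_sf_run()
  bi <- burn_in(tr)
  st <- sf_statistics(tr, mm2, burn_in_time = bi$time)
  # per site: mean instantaneous effective count <= count of time-averaged
  # profile (entropy concavity)
  site_means <- tapply(st$SF$omega_eff, st$SF$site, mean)
  expect_true(all(site_means <= st$SF_T$omega_eff + 1e-8))
  # same argument across sites
  expect_lte(mean(st$SF_T$omega_eff), st$SF_TS$omega_eff + 1e-8)
  expect_error(sf_statistics(tr, mm2, burn_in_time = max(tr$samples$time)),
               "at least 2")
})

test_that("frozen profiles make SF and SF-T coincide", {
  # neutral run: instantaneous profiles are constant (= lambda)
  sm <- small_system(seed = 23, n = 10)
  tr <- sf_simulate(sm, mm2, Ne4 = 0, duration = 1, sample_interval = 0.2,
                    seed = 11)
  st <- sf_statistics(tr, mm2, burn_in_time = 0)
  site_means <- tapply(st$SF$omega_eff, st$SF$site, mean)
  expect_equal(unname(unclass(site_means)), st$SF_T$omega_eff,
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("trajectories serialise to JSON lines", {
  sm <- small_system(seed = 25)
  tr <- sf_simulate(sm, mm2, Ne4 = 500, duration = 0.3, sample_interval = 0.1,
                    seed = 13)
  tmp <- tempfile(fileext = ".jsonl")
  write_trajectory_jsonl(tr, tmp)
  lines <- readLines(tmp)
  expect_equal(length(lines),
               1 + nrow(tr$events) + length(tr$samples$time))
  hdr <- jsonlite::fromJSON(lines[1])
  expect_equal(hdr$type, "header")
  expect_equal(hdr$seed, 13)
  ev <- jsonlite::fromJSON(lines[2])
  expect_equal(ev$time, tr$events$time[1])
})
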