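test_that("site averaging reduces to F81 when profiles are identical", {
  P <- matrix(rep(random_profile(), 3), 3, 20, byrow = TRUE)
  am <- average_model(P, mm2)
  expect_lt(max(abs(am$cov)), 1e-15)
  off <- am$Qhat; diag(off) <- 0
  expect_equal(off, mm2$vS * rep(am$pihat, each = 20), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_error(average_model(P[1, , drop = FALSE], mm2), "at least 2")
})

test_that("covariance-form averaged rates equal brute-force flux averages", {
  set.seed(11)
  for (rep in 1:10) {
    n_sites <- sample(3:30, 1)
    P <- t(replicate(n_sites, random_profile()))
    am <- average_model(P, mm2)
    flux_sum <- matrix(0, 20, 20)
    for (L in seq_len(n_sites)) flux_sum <- flux_sum + flux(f81_rates(P[L, ], mm2))
    Qdirect <- (flux_sum / n_sites) / colMeans(P)
    diag(Qdirect) <- 0
    Qo <- am$Qhat; diag(Qo) <- 0
    expect_lt(max(abs(Qo - Qdirect)), 1e-10)
    # covariance rows sum to ~0 because frequencies sum to 1 at every site
    expect_lt(max(abs(rowSums(am$cov))), 1e-10)
    expect_equal(sum(am$pihat), 1, tolerance = 1e-12)
    expect_equal(am$S, t(am$S))
  }
})

test_that("anticorrelated residues get negative covariance", {
  # two near-delta sites: one isoleucine, one valine
  eps <- 1e-3
  pI <- rep(eps, 20); names(pI) <- names(mm2$lambda)
  pV <- pI
  pI["I"] <- 1 - 19 * eps
  pV["V"] <- 1 - 19 * eps
  am <- average_model(rbind(pI, pV), mm2)
  expect_lt(am$cov["I", "V"], 0)
})

test_that("exchangeabilities follow class co-membership", {
  P <- matrix(rep(rep(1 / 20, 20), 4), 4, 20, byrow = TRUE)
  S <- exchangeability_from_profiles(P)
  expect_equal(S[upper.tri(S)], rep(1, 190), tolerance = 1e-12)
  # block profiles: {I,V} sites vs {D,E} sites
  eps <- 1e-3
  base <- rep(eps, 20)
  names(base) <- names(mm2$lambda)
  iv <- base; iv[c("I", "V")] <- (1 - 18 * eps) / 2
  de <- base; de[c("D", "E")] <- (1 - 18 * eps) / 2
  P2 <- rbind(iv, iv, de, de)
  S2 <- exchangeability_from_profiles(P2)
  expect_gt(S2["I", "V"], S2["I", "D"])
  expect_equal(S2, t(S2))
})

test_that("effective number of amino acids spans its extremes", {
  expect_equal(effective_n_amino_acids(rep(1 / 20, 20)), 20)
  expect_equal(effective_n_amino_acids(c(1, rep(0, 19))), 1)
  # invariant to relabeling
  set.seed(5)
  p <- random_profile()
  expect_equal(effective_n_amino_acids(p),
               effective_n_amino_acids(sample(p)))
  # matrix input applies row-wise
  expect_length(effective_n_amino_acids(rbind(p, p)), 2)
})

test_that("relative rate is 1 at the neutral profile and vanishes when conserved", {
  expect_equal(relative_rate(mm2$lambda, mm2, pseudocount = 0), 1,
               tolerance = 1e-12)
  p <- rep(1e-6 / 19, 20); p[8] <- 1 - 1e-6
  p <- p / sum(p)
  expect_lt(relative_rate(p, mm2, pseudocount = 0), 1e-3)
  # invariant to uniform rescaling of the mutation process
  mm_scaled <- mutation_model(kappa = 2, nuc_rates = 5 * k80_rates(2))
  set.seed(9)
  pr <- random_profile()
  expect_equal(relative_rate(pr, mm2), relative_rate(pr, mm_scaled),
               tolerance = 1e-12)
})

test_that("mixture statistics average per-class values", {
  set.seed(13)
  p <- random_profile()
  one <- mixture_statistics(rbind(p), 1, mm2)
  expect_equal(one$omega_eff, effective_n_amino_acids(p))
  expect_equal(one$rate_ratio, relative_rate(p, mm2))
  # two delta classes
  d1 <- c(1, rep(0, 19)); d2 <- c(rep(0, 19), 1)
  two <- mixture_statistics(rbind(d1, d2), c(0.5, 0.5), mm2)
  expect_equal(two$omega_eff, 1)
  # Jensen: mixture mean effective size <= effective size of the pooled profile
  K <- 6
  P <- t(replicate(K, random_profile()))
  w <- rep(1 / K, K)
  mx <- mixture_statistics(P, w, mm2)
  pooled <- colSums(w * P)
  expect_lte(mx$omega_eff, effective_n_amino_acids(pooled))
  expect_error(mixture_statistics(P, c(0.5, 0.5), mm2), "length")
})

test_that("rate matrix normalisation fixes unit average rate", {
  set.seed(17)
  Q <- rate_from_frequencies(random_profile(), mm2, pseudocount = 0)
  Qn <- normalize_rate_matrix(Q)
  off <- Qn$Q; diag(off) <- 0
  expect_equal(sum(Qn$stationary * rowSums(off)), 1, tolerance = 1e-12)
  # idempotent and scale invariant
  expect_equal(normalize_rate_matrix(Qn)$Q, Qn$Q, tolerance = 1e-12)
  Q7 <- Q; Q7$Q <- 7 * Q$Q
  expect_equal(normalize_rate_matrix(Q7)$Q, Qn$Q, tolerance = 1e-12)
  zero <- Q; zero$Q <- Q$Q * 0
  expect_error(normalize_rate_matrix(zero), "degenerate")
})
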