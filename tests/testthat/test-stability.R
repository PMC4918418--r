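test_that("contact structures enforce their invariants", {
  cs <- contact_structure(10, rbind(c(0, 2), c(2, 0), c(5, 9)))
  expect_equal(nrow(cs$contacts), 2)  # duplicate (unordered) removed
  expect_true(all(cs$contacts[, 2] - cs$contacts[, 1] >= 2))
  expect_error(contact_structure(10, rbind(c(0, 1))), ">= 2")
  expect_error(contact_structure(10, rbind(c(3, 3))), ">= 2")
  expect_error(contact_structure(10, rbind(c(0, 10))), "lie in")
})

test_that("contact maps round-trip through TSV", {
  st <- generate_structure(30, 0.1, n_decoys = 2, seed = 3)
  tmp <- tempfile(fileext = ".tsv")
  write_contact_map(st$native, tmp)
  back <- read_contact_map(tmp)
  expect_equal(back$n_residues, 30)
  expect_equal(back$contacts, st$native$contacts)
  # empty map
  e <- contact_structure(5, matrix(integer(0), 0, 2))
  write_contact_map(e, tmp)
  expect_equal(nrow(read_contact_map(tmp)$contacts), 0)
})

test_that("synthetic contact potential is symmetric and hydrophobically ordered", {
  pot <- contact_potential()
  expect_equal(pot, t(pot))
  # strongest attraction between the most hydrophobic residues
  expect_lt(pot["I", "I"], pot["R", "R"] - 1)
  # like charges repel relative to opposite charges
  expect_gt(pot["K", "K"], pot["K", "D"])
  # bundled fixture holds the same numbers
  fix <- contact_potential(system.file("extdata",
                                       "contact_potential_synthetic.tsv",
                                       package = "mutselhet"))
  expect_equal(fix, pot, tolerance = 1e-5)
})

test_that("contact energy is the sum over contacting pairs", {
  pot <- contact_potential()
  e0 <- contact_structure(10, matrix(integer(0), 0, 2))
  expect_equal(contact_energy(rep("A", 10), e0, pot), 0)
  one <- contact_structure(10, rbind(c(2, 7)))
  s <- rep("A", 10); s[3] <- "I"; s[8] <- "V"
  expect_equal(contact_energy(s, one, pot), pot["I", "V"], ignore_attr = TRUE)
  st <- generate_structure(12, 0.2, n_decoys = 2, seed = 4)
  n_c <- nrow(st$native$contacts)
  expect_equal(contact_energy(rep("A", 12), st$native, pot),
               n_c * pot["A", "A"], ignore_attr = TRUE)
  expect_error(contact_energy(rep("A", 5), st$native, pot), "length")
})

test_that("folding free energy follows the random-energy closed form", {
  # degenerate ensemble: all decoys identical => sigma = 0
  native <- contact_structure(10, rbind(c(0, 5)))
  decoy <- contact_structure(10, rbind(c(1, 8)))
  pot <- contact_potential()
  sm <- stability_model(native, list(decoy, decoy), log_n_unfolded = log(100))
  s <- rep("L", 10)
  e_nat <- contact_energy(s, native, pot)
  mu <- contact_energy(s, decoy, pot)
  expect_equal(folding_free_energy(s, sm), e_nat - mu + log(100))
  # kT enters the closed form
  decoy2 <- contact_structure(10, rbind(c(2, 9)))
  sm2 <- stability_model(native, list(decoy, decoy2),
                         log_n_unfolded = log(100), kT = 2)
  e <- c(contact_energy(s, decoy, pot), contact_energy(s, decoy2, pot))
  expect_equal(folding_free_energy(s, sm2),
               e_nat + 2 * (log(100) - mean(e) / 2 + var(e) / 8))
  expect_error(stability_model(native, list(decoy)), "at least 2")
})

test_that("a well-designed native fold is stable", {
  # native contacts among hydrophobics, decoys among charged residues
  n <- 20
  nat_pairs <- cbind(0:7, 10:17)
  native <- contact_structure(n, nat_pairs)
  dec_pairs1 <- cbind(c(0, 1, 2, 3, 4, 5, 6, 7), c(2, 3, 4, 5, 6, 7, 8, 9))
  dec_pairs2 <- cbind(c(10, 11, 12, 13, 14, 15, 16, 17),
                      c(12, 13, 14, 15, 16, 17, 18, 19))
  sm <- stability_model(native,
                        list(contact_structure(n, dec_pairs1),
                             contact_structure(n, dec_pairs2)),
                        log_n_unfolded = log(4))
  s <- c(rep("K", 10), rep("E", 10))
  s[1:8] <- "I"; s[11:18] <- "L"  # hydrophobic across native contacts
  expect_lt(folding_free_energy(s, sm), 0)
})

test_that("fitness is the folded probability with stable saturation", {
  expect_equal(fold_fitness(0), 0.5)
  expect_equal(fold_fitness(-log(9)), 0.9)
  expect_equal(fold_fitness(1e6), 0)
  expect_equal(fold_fitness(-1e6), 1)
  dg <- seq(-10, 10, 0.5)
  expect_true(all(diff(fold_fitness(dg)) < 0))  # monotone decreasing in dG
  expect_error(fold_fitness(Inf), "finite")
})
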