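---
title: "Mutation-selection models, site heterogeneity, and stability-constrained simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutation-selection models, site heterogeneity, and stability-constrained simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutselhet)
```

## The model

Protein sites do not share one substitution process. Structural and
functional context gives every site its own amino acid propensities, and —
because those propensities are set by the residues at *other* sites — they
drift as the protein evolves. This package implements the mutation–selection
description of that situation and the statistics that relate it to standard
empirical substitution matrices.

**Mutation.** Nucleotide mutation follows the Kimura two-parameter (K80)
model: transversions at rate 1 (this normalisation defines the neutral time
unit), transitions at rate `kappa` (default 2). Averaging over the sense
codons of each amino acid gives the amino-acid-level mutation rates
$v_{XY}$, the code weights $\lambda_X$ ($d_X/61$ under uniform codon usage,
with $d_X$ the codon degeneracy), and the symmetric part
$v^S_{XY} = v_{XY}\lambda_X$. Amino acid pairs not connected by any
single-nucleotide codon change have $v_{XY}=0$, and all pair statistics in
the package restrict to the 75 accessible pairs: a continuous-time
single-nucleotide process cannot jump between the others.

**Selection.** With marginal Malthusian fitnesses $m_{X}$ at a site and
population-scaled coefficient $S = 4N_e(m_Y - m_X)$, the substitution rate is
$Q_{XY} = v_{XY}\, S/(1-e^{-S})$ and the stationary distribution is
$\pi_X \propto \lambda_X e^{4N_e m_X}$. Only the product $4 N_e m$ ever
enters, so the package treats `Ne4` as a single parameter. The rates can be
rewritten in the frequencies alone,
$S = \ln(\lambda_X \pi_Y / (\lambda_Y \pi_X))$, and the two constructions
(`rate_from_fitness`, `rate_from_frequencies`) agree entrywise to $10^{-14}$
in the test suite. Every generated matrix satisfies detailed balance:
deleterious changes in one direction are advantageous in the other, faster
than neutral — the opposite of what symmetric-exchangeability empirical
models assume at a single site.

**The F81 form.** Linearising each logarithm
($\ln(\lambda\pi) \to \lambda\pi - 1$) collapses the rates to
$Q_{XY} = v^S_{XY}\pi_Y$: the classic exchangeability-times-frequency model
with the mutation symmetric part as exchangeability. We document this as a
*formal substitution*, not an asymptotic approximation: the linearisation is
applied to products $\lambda_X\pi_Y \ll 1$, so the resulting rates differ
from the exact ones by pair-dependent scale factors even at the neutral
profile (our tests verify the substitution identity exactly, and the package
normalises rate matrices to unit average rate whenever scales are compared).
The F81 form is what makes the site-averaging algebra closed.

**Site averaging.** Averaging per-site flux and frequencies over sites under
the F81 form gives
$\hat Q_{XY} = v^S_{XY}\,(1 + \mathrm{Cov}(\pi_{L,X},\pi_{L,Y})/(\hat\pi_X\hat\pi_Y))\,\hat\pi_Y$:
the apparent exchangeability of a pair is governed by the covariance of
their site propensities. `average_model` uses the population covariance
(divisor $N$) because the average is over the given sites, not an inference;
the brute-force flux average agrees to $10^{-17}$. The covariance
denominator is $\hat\pi_X\hat\pi_Y$ — the flux-averaging derivation forces
it, and the oracle test is the arbiter. Extreme anticorrelation can push an
averaged rate below zero; such entries are floored at zero with a warning,
since they are smoothing artifacts of near-delta profiles.

**Constraint statistics.** `effective_n_amino_acids` is
$\Omega = \exp(-\sum \pi \ln \pi)$ (with $0\ln 0 = 0$): the number of equally
likely amino acids with the same entropy. `relative_rate` is
$\omega = \sum \pi_X Q_{XY} / \sum (d_X/61)\, v_{XY}$ over accessible pairs —
the ratio is the same whether the sums run over ordered or unordered pairs,
applied consistently, and equals 1 at the neutral profile
$\pi = \lambda$.

## Parameters that matter

| parameter | default | units / meaning |
|---|---|---|
| `kappa` | 2 | transition/transversion ratio of the K80 model |
| `Ne4` | 1000 | population-scaled selection, $4N_e$ (dimensionless) |
| `pseudocount` | 1e-10 | smoothing mass for zero frequencies before Eq.-3-style logs |
| `min_columns`, `min_sequences` | 100, 100 | alignment size gates (strictly larger required) |
| `max_gap_fraction` | 0.5 | columns with weighted gap fraction strictly above are dropped |
| `contact_density` | 0.085 | fraction of admissible pairs in contact (~4 contacts/residue) |
| `log_n_unfolded` | $\ln 10^{160}$ | log-size of the non-native ensemble (see below) |
| `sample_interval` | run-specific | spacing of instantaneous-state samples |

Codon usage bias enters through a reversible codon-level mutation process
$\mu(c,c')\sqrt{w_{c'}/w_c}$ with stationary distribution $w$. A plain
symmetric nucleotide rate cannot satisfy the amino-acid-level reversibility
requirement $v_{XY}\lambda_X = v_{YX}\lambda_Y$ under non-uniform usage; the
square-root factor is the minimal correction and vanishes under uniform
usage, where $\lambda_X = d_X/61$ exactly.

## Alignment profiles

`site_profiles` estimates per-column equilibrium frequencies with Henikoff
position-based weights (each residue contributes $1/(rs)$; gaps and
ambiguous residues contribute nothing). The filtering rules follow standard
practice for large family alignments: only alignments strictly larger than
100 columns with strictly more than 100 sequences are used, and columns with
weighted gap fraction strictly greater than 0.5 are discarded. Ambiguous
residues (`X`) are treated as missing, not as gaps and not as a 21st state.
Kept-column indices are stored 0-based, matching the on-disk TSV and
contact-map conventions.

## The synthetic-data generator

The generator supplies everything the analyses need in the absence of
curated family alignments and solved structures:

- **Profiles** are drawn from a Dirichlet mixture over physicochemical
  classes (aliphatic, small, charged/polar, aromatic, turn-forming);
  out-of-class amino acids keep base mass $10^{-3}$, since real weighted
  profiles are sparse but rarely exactly zero. Concentration 50 gives
  realistic within-class spread. This reproduces the qualitative covariance
  structure of family alignments (isoleucine–valine positively correlated
  across sites, leucine–serine not), which is all the exchangeability
  analysis consumes. It does *not* emulate alignment biases, gap structure,
  or non-stationary composition; passing tests say nothing about those.
- **Alignments** evolve each site down a star or balanced tree under the
  site's F81 process, so per-site frequencies are stationary at the input
  profiles by construction; sequences are phylogenetically redundant, as in
  real families. Indels are not simulated.
- **Structures** are uniform random contact maps with $|i-j|\ge 2$; the
  native and its decoys share one contact count so their contact energies
  are comparable. Random maps preserve the random-energy statistics of the
  decoy ensemble; they do not have protein-like contact-order or secondary
  structure.

## The stability simulator

`sf_simulate` runs an exact Gillespie simulation of a codon sequence: every
single-nucleotide neighbour (stops excluded) gets rate = nucleotide rate
times the fixation factor of $4N_e\,\Delta \ln f$, where
$f = e^{-\Delta G/kT}/(1+e^{-\Delta G/kT})$ is the folded probability.
$\Delta G$ is the native contact energy minus a Gaussian (random-energy)
estimate of the non-native free energy from the decoy energies:
$\ln Z_{\mathrm{alt}} = \ln N_{\mathrm{unf}} - \mu_d/kT + \sigma_d^2/(2kT^2)$.
The Gaussian estimator is this package's own construction for the
alternative-ensemble free energy; contact energies come from a **synthetic**
pairwise potential (hydrophobicity-product attraction, charge term, weak
background attraction; `contact_potential()` and the bundled
`contact_potential_synthetic.tsv`) — a stand-in with the qualitative
structure of knowledge-based potentials, clearly labelled as such.

**Choosing `log_n_unfolded`.** The conventional ensemble size $10^{160}$ for
a 300-residue chain corresponds to ~1.23 units of conformational entropy per
residue. At the reduced scale used throughout (50 residues, 10 decoys) that
value leaves the synthetic system unable to reach $\Delta G < 0$ at all:
every sequence is "unfolded", the fitness gradient never saturates, and the
walk freezes at a local optimum. We therefore calibrated the per-residue
entropy once, to $0.9\,n_{\mathrm{residues}}$, so that adapted sequences
equilibrate at $\Delta G \approx -5$ to $-10\,kT$ — the range typical of
real proteins — and a genuine drift–selection balance exists at
$4N_e = 1000$ ($\Delta G$ fluctuates with standard deviation $\approx 0.9\,kT$
instead of freezing). Problem sizes for the bundled analyses: 50 residues,
100 native contacts, 10 decoys, 4000 substitutions (burn-in = 10
substitutions per residue, leaving 3500), sampling every 0.05 neutral time
units.

**Burn-in** defaults to a fixed substitution count ($10 n$); the alternative
trend criterion fits a linear model to the second half of the $\Delta G$
trace and accepts only when no significant slope remains — failure is
reported explicitly, never silently.

**SF / SF-T / SF-TS.** From the sampled instantaneous profiles,
`sf_statistics` reports $(\Omega,\omega)$ per site per sample (SF), per site
for the time-averaged profile (SF-T; samples are equally spaced, so the
plain mean is the dwell-time average), and for the site-and-time average
(SF-TS). Entropy concavity forces mean SF $\le$ SF-T $\le$ SF-TS in $\Omega$,
and the simulations show the same ordering in $\omega$: ignoring temporal
and spatial heterogeneity progressively inflates both the apparent number
of acceptable amino acids and the apparent rate.

**Stokes shift.** `stokes_shift_test` compares each newly fixed residue's
instantaneous equilibrium frequency immediately after fixation with its
frequency `lag_events` substitutions later, keeping only residues still
resident through the window, and applies a one-sided sign test. "Long after"
is taken as one expected substitution per site (lag = $n_{\mathrm{residues}}$
events); the per-substitution entrenchment is small, so the test needs a few
thousand post-burn-in substitutions for power — the bundled run uses 4000.

## Numerical choices

- `fixation_factor` uses a series for $|S| < 10^{-4}$ (the expression is 0/0
  at neutrality) and `expm1` branches elsewhere; it never overflows.
- Equilibrium profiles use max-shifted exponentials.
- Zero frequencies are smoothed with a flag-controlled pseudocount
  (default $10^{-10}$) before the frequency-form rates.
- Matrices are stored in alphabetical one-letter amino acid order; PAML
  `.dat` interchange uses the PAML order. All randomised functions take an
  explicit seed and are bit-reproducible given one.
- The "68% credible" columns of the $(\Omega,\omega)$ tables are 16th/84th
  percentiles of the empirical distribution over sites (and samples).

## Scope and limitations

Likelihood inference on trees, CAT profile estimation, covarion-style rate
switching, and real database retrieval are out of scope. The mixture
machinery accepts user-supplied class files; the bundled
`mixture_classes_synthetic.tsv` is a synthetic stand-in, not published class
profiles. The simulator selects on stability only — no functional
constraints — and its decoy ensemble is far smaller than a real
conformational ensemble; quantitative placement of SF points in the
$(\Omega, \omega)$ plane therefore depends on the synthetic potential and
the calibrated ensemble entropy, and only the qualitative geometry
(SF below-left of SF-T, below-left of SF-TS; near-neutral standard-model
points) is asserted by the tests.
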