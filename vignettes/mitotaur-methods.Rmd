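---
title: "Models and methods behind mitotaur"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mitotaur}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitotaur)
```

`mitotaur` analyses complete taurine cattle mitogenomes: variant profiles
against the Bovine Reference Sequence (BRS, V00654 coordinates), haplogroup
classification, backbone-constrained parsimony trees, coalescence dating by
the ρ statistic and by clock-constrained maximum likelihood, and diversity
summaries, together with a calibrated simulator. This vignette records the
models, the tunable parameters, and the design decisions a maintainer or
reviewer would want spelled out.

## Variant representation

All variation is expressed relative to the reference in the branch-label
notation of the cattle mtDNA literature: `2536` (transition at np 2536),
`15953G` (transversion to G), `364+G` (insertion after np 364), `100d`
(deletion), suffix `h` (heteroplasmy), suffix `@` (back mutation, added by
tree annotation). Two conventions required a decision:

* **Indel normalization.** Homopolymer-tract length variants are ambiguous
  in placement; we left-align every indel (rotating inserted bases across
  identical reference bases), so an extra C anywhere in the C tract at
  np 222–229 is always labelled `221+C` and an extra A in the tract at
  np 1601–1606 becomes `1600+A`. The published convention only says such
  variants are "scored at" np 221/1600; left-alignment is our deterministic
  way of getting there, and it is what makes `filter_hypervariable()`
  reliable: it removes indels whose normalized position falls inside the
  tract windows (and the G insertion at np 364), while point substitutions
  anywhere — including inside the tracts — are kept.
* **Heteroplasmy.** Encoded on sequences as two-base IUPAC codes combining
  the reference base with one alternative. Three- and four-base codes are
  rejected rather than guessed at; `N` is treated as missing data and
  produces no call. A two-base code that does not include the reference
  base is an error, since the `h` notation presupposes the reference allele
  is one of the two.

One caveat is inherent to equal-length comparison: a genome carrying the
same number of inserted and deleted bases has the reference's length, and
`call_variants()` will then compare position-by-position instead of
aligning. Callers with such data should align externally and pass
`aligned_ref`.

## Haplogroup classification

A haplogroup configuration is a rooted tree of named nodes, each with its
own defining variants; a node's *full motif* is the union along the path
from the root (`founding_set()`). A profile is scored against every node as
`matched − λ·mismatched` over the full motif, with λ = 1 by default —
the symmetric penalty used by common mtDNA classifiers; raising λ
penalizes missing motif sites (e.g. back mutations at motif positions,
which by construction appear as absences) more strongly. Ties break to the
deepest node, then lexicographically, so a profile carrying a full parent
motif and nothing else is assigned to the parent, never arbitrarily to one
of its children.

The packaged configuration transcribes the published taurine topology
(PQT → P/QT, Q → Q1/Q2, T → T1'2'3/T5, the T1–T3 subclades, a zebu
haplogroup I placeholder). Its `verified` column is honest about content:
only the Q-diagnostic C→G transversion at np 15953 is anchored in the
literature text; the remaining defining motifs are synthetic placeholders
chosen at plausible coding-region positions. Classification correctness is
therefore always defined — and tested — relative to the configuration in
use, which is a plain TSV (or YAML) users are expected to replace with
curated motifs for real analyses.

## Parsimony trees and mutation annotation

`build_tree()` fixes the between-haplogroup structure to the configuration
backbone (branches carry each haplogroup's own defining variants) and
resolves structure within a haplogroup by greedy agglomeration on the
maximum-parsimony objective: the pair of subtrees sharing the most
non-founding mutations is merged first (ties: smallest shared position,
then label), the shared set moves onto the new internal branch, and merging
stops when nothing is shared — leaving the star topology that dominates
published cattle trees. Merging two subtrees sharing *s* mutations reduces
total tree length by exactly *s*, so agglomeration never increases length
and equals the star length only when no sharing exists. On
perfect-phylogeny-compatible data the greedy tree attains the exhaustive
minimum over all rooted multifurcating topologies (verified against a
Sankoff small-parsimony oracle for up to 5 tips); with conflicting
(recurrent) sharing the published trees themselves are ambiguous, and we
make the deterministic choice above rather than chase hand-curated
placements.

`annotate_recurrence()` flags a mutation *recurrent* when its
(position, kind, allele) occurs on two or more branches, and marks `@`
(back mutation) on a transition whose root-to-tip path already carries an
odd number of transitions at the same position — transitions are
self-inverse, so this is decidable from labels alone. A transversion that
happens to restore the reference cannot be recognized from its label
without the reference and is left unmarked; this mirrors the control-region
ambiguity acknowledged for the published trees. Annotation strips existing
marks first, so it is idempotent.

## Coalescence dating

**ρ statistic.** For a clade with n sampled haplotypes whose branches b
carry l~b~ mutations and subtend n~b~ samples,
ρ = Σ l~b~n~b~/n is the average mutational distance from the clade root and
σ = √(Σ l~b~n~b~²)/n its heuristic genealogy-based standard error — the
form obtained by treating branch counts as independent Poisson draws, so
Var(ρ) = Σ (n~b~/n)² l~b~. Both equal brute-force path sums on random
genealogies in the tests. Mutation counting follows the caller's filtering;
the dating convention (applied by `date_clade()`) is hypervariable sites
removed, coding region np 364–15791 only, heteroplasmies excluded.

**Clock.** Divergences convert to years at one mutation per 3,172 years
over the coding region (`clock_model()`), reported in ky. The published
age table also quotes a PQT age of 75.5 ± 10 ky used as a Bayesian
calibration point and a 6-year generation time; both belong to the Bayesian
skyline analysis, which is out of scope here, and the clock constant is the
only calibration the package applies. Report rounding is half-even to 2
decimals (ky) and 1 decimal (percentages); raw values are always retained
in the returned objects.

**Maximum likelihood.** `ml_divergence()` fits, by Felsenstein pruning, an
ultrametric (equal root-to-tip height) tree under HKY85 with equal-probability
discrete-gamma rate categories (32 by default; category rates are the exact
conditional means of Gamma(α, α), which average to 1 by construction).
Optimization is bounded quasi-Newton (L-BFGS-B) over log-transformed root
height, logit-transformed relative internal-node heights, log κ and log α,
initialized at κ = 2, α = 1 and half the mean pairwise mismatch fraction
for the height, with a convergence tolerance of about 1e-8 on the
log-likelihood; non-convergence is reported by warning and in the result,
never silently. The reported *molecular divergence* is the fitted per-site
root height times the coding-region length (15,791 − 364 + 1 = 15,428
sites), i.e. expected mutations from clade root to tip over the region —
the same scale as ρ, and converted to years with the same per-genome clock,
which is how the published age table treats it. The standard error is the
curvature (observed-information) SE of the height at the optimum, delta-method
transformed; whether the published table's ML uncertainty is exactly this
quantity is not stated, so the column is documented as curvature-based.
Equilibrium base frequencies default to the empirical alignment
frequencies. Degenerate inputs are handled explicitly: identical sequences
return divergence 0 with SE 0 (a boundary optimum), alignment columns with
anything but A/C/G/T are dropped, and an alignment with no usable columns
is an error. The pruning likelihood is tested for exact (1e-10) agreement
with exhaustive enumeration over internal states on small instances, and
the HKY transition matrices against an independent matrix exponential and
the Jukes–Cantor closed form.

## Diversity

Haplotype identity is equality of filtered variant profiles over the whole
molecule (control region included, as published haplotypes are). H is Nei's
unbiased gene diversity, computed in the integer-count form
(n² − Σc~i~²)/(n(n−1)) so the all-distinct case is exactly 1, with the
standard gene-diversity variance estimator for its SE (reported to 3
decimals by convention). For the survey composition of 31 all-distinct
haplotypes this gives H = 1.0 ± 0.008. M is the mean pairwise
symmetric-difference of variant sets within a haplogroup. Frequency tables
carry both the exact percentage (summing to 100) and its 1-decimal
half-even rounding; note 18/31 rounds to 58.1%.

## The simulator and what passing tests show

`sim_config()` defaults are the survey conditions the package is designed
around: 31 samples split 18/6/5/2 across T1/T2/T3/Q1, star within-haplogroup
genealogies, clade depths 15.57/13.64/12.53/19.29 ky (the published ρ-based
ages), the 1/3,172-years coding clock, HKY85 with κ = 20 and α = 0.5 over
32 categories, and a 5× control-region rate multiplier. κ and α are not
published for these data; κ = 20 reflects the strong transition bias of
published cattle mitogenome trees (branch labels are overwhelmingly
transitions) and α = 0.5 a typically strong mtDNA site-rate heterogeneity.
The control-region multiplier only affects realism — dating restricts to
the coding region — and 5× is a conventional order of magnitude for the
mtDNA control region.

Mutations are dropped per branch as Poisson with mean branch-years/3,172
over the coding region (gamma site rates are drawn once per clade and
average 1, so the clock is exact in expectation), placed ∝ site rate, with
the substituting base drawn from the HKY jump probabilities given the
current base. Recurrent and back mutations therefore arise naturally and
are left in place; heteroplasmy and indels are *not* simulated. Coalescent
modes scale standard Kingman waiting times so the expected root height
equals the clade age (for exponential growth, via a memoised Monte-Carlo
normalizing constant on an isolated RNG stream); a single seed determines
the entire dataset byte-for-byte.

What passing tests do show: the estimators are internally correct (oracle
equivalence), the pipeline recovers simulated truth (classification 100%,
ρ-ages unbiased within 2 SE over 200 star-clade replicates at 17.64 ky,
ML divergence within Monte-Carlo error), and the published worked examples
(clock conversions, percentages, shared-mutation arithmetic, H = 1.0 ±
0.008) are reproduced exactly. What they do not show: fidelity to features
the simulator omits — sequencing error, heteroplasmy calling, indel-rich
regions, non-star demography mixed within a clade, or the true (unpublished)
haplogroup motifs; and recomputing the published per-haplogroup age table
itself would require the underlying GenBank mitogenome set.

Problem sizes used by the test-suite property checks — 100 random
genealogies of up to 12 tips for ρ/σ, 4 taxa × 50 sites for the
enumeration oracle, 200 replicates of a 6-tip star clade for age recovery,
4 replicate 8-tip datasets for ML recovery — were chosen as the smallest
sizes at which the statistical assertions are sharp (e.g. the 200-replicate
mean has a standard error near 0.2 ky against a 2-SE acceptance band).

## Known limitations

* The haplogroup motif content shipped is a placeholder scaffold (see
  above); real analyses must supply curated motifs.
* `ml_divergence()` implements only the clock-constrained estimator; there
  is no unconstrained or relaxed-clock mode (Bayesian skyline analyses are
  deliberately out of scope).
* Back-mutation marking is label-based and so limited to transitions.
* Equal-length inputs with balanced indels bypass the internal aligner (see
  Variant representation).
* The circular genome is linearized at np 1; circularity matters only to
  the optional pairwise alignment step, and alignments spanning the origin
  are not special-cased.
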