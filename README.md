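# mitotaur

Population-genetic analysis of complete taurine cattle mitochondrial genomes
(mitogenomes, ~16.3 kb). Surveys of local cattle breeds use mitogenome
variation to date maternal lineages back to the Near-Eastern domestication of
*Bos taurus*: each mitogenome is reduced to its set of differences from the
Bovine Reference Sequence (BRS, GenBank V00654), assigned to a haplogroup of
the taurine mtDNA tree (P, Q with Q1/Q2, macro-haplogroup T with T1–T5 and
subclades), placed on a mutation-annotated parsimony tree, and the depth of
each clade is converted into a coalescence age with a molecular clock.
`mitotaur` implements that pipeline end to end for R users, plus a calibrated
simulator so every stage can be exercised and validated without external
sequence downloads.

## What it computes

* **Variant profiles** in the field's branch-label notation relative to the
  BRS coordinate system ("np", 1-based): a bare position is a transition
  (`16049`), a trailing base a transversion (`15953G`), `+X`/`d` an
  insertion/deletion (`364+G`, `100d`), `h` heteroplasmy. Calling from
  aligned or alignable FASTA, IUPAC-coded heteroplasmies, left-aligned
  indels, hypervariable-site filtering (the np 364 G insertion and the
  homopolymer tracts scored at np 221 and np 1600), coding-region
  restriction (np 364–15791).
* **Haplogroup classification** from an editable defining-motif
  configuration: each profile is scored against every node's full motif
  (`matched − λ·mismatched`), with deepest-node tie-breaking.
* **Parsimony mutation trees** constrained to the haplogroup backbone:
  profiles sharing non-founding mutations are joined greedily whenever that
  reduces total mutation count; recurrent mutations and back mutations
  (suffix `@`) are annotated; shared/private non-founding mutations between
  profiles are extracted for cross-population comparison.
* **Coalescence dating** two ways, both converted to years with the bovine
  coding-region clock of one mutation per 3,172 years:
  * the ρ statistic, ρ = Σ<sub>b</sub> l<sub>b</sub>n<sub>b</sub>/n (average
    mutational distance of a clade's haplotypes from the clade root), with
    the heuristic genealogy-based standard error
    σ = √(Σ<sub>b</sub> l<sub>b</sub>n<sub>b</sub>²)/n;
  * clock-constrained maximum likelihood under HKY85 with 32-category
    discrete-gamma rate heterogeneity (Felsenstein pruning), reporting the
    fitted root height scaled to the coding region, with a curvature-based
    standard error.
* **Diversity statistics**: Nei's unbiased haplotype diversity H with its
  sampling variance, within-haplogroup mean pairwise differences (M), and
  haplogroup frequency tables.
* **Simulation**: star or coalescent within-haplogroup genealogies, founder
  motifs, Poisson clock-rate mutations under HKY85+Γ with a hypermutable
  control region, and a truth manifest for parameter-recovery checks.

The packaged reference is a clearly-labelled *synthetic* stand-in for V00654
(same length, coordinate system and tract structure); supply the real BRS
FASTA via `load_reference(path)` for analyses of real data.

## Worked example

Simulate a 31-mitogenome survey with the package defaults (18/6/5/2 samples
across T1/T2/T3/Q1, star radiations at the published clade depths), then run
the analysis pipeline on it:

```r
library(mitotaur)

cfg <- sim_config(seed = 20151029)
ds  <- generate_dataset(cfg)
cls <- classify_profiles(ds$profiles, cfg$haplogroups)
summ <- diversity_summary(ds$profiles, cls)
cat(sprintf("n = %d mitogenomes, H = %g +/- %.3f\n", summ$n, summ$H, summ$se_H))
print(summ$by_haplogroup, digits = 3)
#> n = 31 mitogenomes, H = 1 +/- 0.008
#>   haplogroup  n  freq percent    M
#> 1         T1 18 58.06    58.1 12.4
#> 2         T2  6 19.35    19.4 14.3
#> 3         T3  5 16.13    16.1 13.2
#> 4         Q1  2  6.45     6.5 12.0
```

Every simulated mitogenome carries a distinct haplotype, so H is exactly 1
with Nei standard error 0.008; `percent` is the 1-decimal report rounding of
the exact `freq` column, and M is the mean pairwise difference within each
haplogroup. Dating the T1 clade by the ρ statistic:

```r
dq <- date_clade(ds$profiles[cls$haplogroup == "T1"], "T1", cfg$haplogroups)
dq$rho
#> <rho_estimate: rho = 4.778, sigma = 0.5152, n = 18>
dq$age
#> <age_estimate (rho): T = 15.16 ky, dT = 1.63 ky>
```

ρ = 4.78 mutations of average depth converts to 15.16 ± 1.63 ky under the
1/3,172-years clock — within sampling error of the simulated truth of
15.57 ky. `age_table()` lays such estimates out in the conventional report
format, alongside `ml_divergence()` fits where sequences are available, and
`write_tree_newick()`/`write_branch_table()` export the annotated parsimony
tree.

A thin command-line wrapper for the simulator ships at
`inst/scripts/simulate_dataset.R`
(`Rscript simulate_dataset.R --config cfg.yaml --seed 7 --out dir/`).

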