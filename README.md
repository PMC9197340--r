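# clonarch

Clonal architecture of immunoglobulin heavy-chain (IgH) repertoires in
B-cell precursor acute lymphoblastic leukemia (BCP-ALL).

High-throughput sequencing of the rearranged IgH locus reads out the clonal
composition of a diagnostic leukemia sample: every unique V(D)J junction is
a clonotypic barcode. Because leukemic blasts keep rearranging — in
particular by **VH replacement**, which swaps the V segment of an existing
VDJ join while retaining its D-J core — one ancestral rearrangement often
appears as a family of clonotypes with different V segments and N1 inserts
but a shared **D-N2-J stem**. `clonarch` reconstructs that structure and
tests whether the resulting clonal-complexity indicators are associated
with clinical covariates. It is aimed at hematology/immunogenomics groups
analysing AIRR-format IgH sequencing of leukemic marrow.

## The method

For each sample, with clonotype read fractions `f_i`:

1. **Index clones**: clonotypes with `f_i >= 5%` (inclusive; configurable).
2. **Foster clones**: index clones are grouped when they share a stem —
   same J gene, identical N2, and a contiguous D-region overlap
   `>= ceil(0.5 * min(|D_a|, |D_b|))` (longest common substring; when a
   rearrangement has no D, the J-anchored common suffix of the V-J inserts
   is used at the same fraction). Groups are connected components of this
   relation; each stands for one ancestral rearrangement.
3. **Evolved clones**: every clonotype, regardless of frequency, matching a
   group's stem under the relaxed predicate (N2 identity dropped) joins
   that group; multi-matches go to the largest D overlap.
4. **Indicators** per patient: `n_foster` (number of groups) and
   `max_evolved` (largest per-group evolved count, foster clone included),
   plus `n_index` and `total_evolved`.
5. **Associations**: indicators vs covariates with tie-corrected Spearman
   (age, WBC, ordinal EORTC risk) or Kruskal-Wallis (sex, NCI risk, CNS
   status, genetic type), two-sided at 0.05, pairwise deletion of missing.

A ground-truth simulator (`generate_germline_pool()`,
`simulate_leukemic_repertoire()`, `simulate_cohort()`) builds leukemic
repertoires with known architecture — 1-4 foster lineages, VH-replacement
evolved members, a stem-disjoint polyclonal background, multinomial read
sampling — so every stage is testable without external data. See the
vignette (`vignettes/clonal-architecture.Rmd`) for the modelling choices.

## Worked example

Simulate a patient with two foster lineages (6 and 3 evolved clones) over a
polyclonal background, then recover the architecture:

```r
library(clonarch)

ref <- generate_germline_pool(seed = 7)
sim <- simulate_leukemic_repertoire(ref, n_foster_lineages = 2,
                                    evolved_per_lineage = c(6, 3),
                                    background_clonotypes = 100,
                                    seed = 7, patient_id = "P001")
res <- run_architecture(sim$clonotypes, patient_id = "P001")
str(res$indicators)
#> List of 5
#>  $ patient_id   : chr "P001"
#>  $ n_index      : int 2
#>  $ n_foster     : int 2
#>  $ max_evolved  : int 6
#>  $ total_evolved: int 9
```

Two index clones (the two lineage founders, at 35% and 33% of reads) give
two foster groups; the larger lineage's 6 evolved clones set
`max_evolved`; 6 + 3 evolved clones in total. The first group's stem is the
founder's retained D, N2 and J gene:

```r
res$groups[[1]]$stem[c("d_call", "stem_seq", "n2", "j_gene")]
#> $d_call   [1] "D10"
#> $stem_seq [1] "CATCAATCGTTACT"
#> $n2       [1] "CT"
#> $j_gene   [1] "J3"
```

The headline association statistics of the reference cohort — 105 children
treated for BCP-ALL, shipped as contingency tables — can be recomputed
offline:

```r
rep <- reproduce_reference_tables()
#> foster vs EORTC risk:   rho = -0.263, p = 0.007  (n = 105)
#> foster vs genetic type: H = 6.88,     p = 0.032  (n = 101)
```

Patients in lower EORTC risk groups have more foster clones (negative rho),
and foster-clone count differs by genetic type; among t(12;21)/ETV6:RUNX1
patients only 7.4% have three or four foster clones, versus 25.6% with
hyperdiploidy and 17.1% with other genetic types.

For file-based work, `run_pipeline()` chains AIRR rearrangement TSVs,
covariate CSVs and report output (TSV/JSON/YAML); a thin command-line
wrapper lives at `inst/cli/clonarch.R` with subcommands `annotate`,
`architecture`, `simulate`, `run` and `reproduce`.

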