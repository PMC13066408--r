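# clonetraj

Clonal evolution and mutational trajectory analysis for T-cell
lymphoblastic neoplasia (T-ALL / T-LBL).

Targeted panel sequencing and SNP arrays see the same tumor from two
sides: small variants with allele frequencies and read depths, and
copy-number/LOH segments with BAF and logR. `clonetraj` integrates both
on the cancer cell fraction (CCF) scale, reconstructs each patient's
clone tree across longitudinal samples, and asks the cohort-level
questions that clone trees make answerable: which mutational events come
first, which ordered trajectories recur more often than label shuffling
explains, and whether the clonal position of *NOTCH1* — not merely its
presence — carries relapse risk. It is aimed at analysts of pediatric
and adult T-ALL/T-LBL cohorts; a synthetic-cohort generator with planted
clonal structure makes the whole pipeline testable without patient data.

## The models in brief

* **CCF integration.** For a small variant,
  `ccf = vaf * (rho*n_t + (1-rho)*n_n) / (m*rho)` with purity `rho`,
  local copy number `n_t` and multiplicity `m` (enumerated, smallest
  feasible). For a CNV carried by a fraction `f` of tumor cells the BAF
  relations are inverted in closed form, e.g. deletion
  `f = (1-2*BAF) / (rho*(1-BAF))`. Wilson intervals on VAF propagate to
  CCF intervals.
* **Clone trees.** Events are clustered by a binomial mixture on the raw
  read counts (EM, BIC-selected k); all rooted trees on the clusters are
  enumerated under the sum rule (children's CCFs cannot exceed the
  parent's at any timepoint) and filtered by allele-phasing constraints;
  selection is by minimal violation, then parsimony, with the number of
  co-optimal trees reported as ambiguity.
* **Trajectories.** Ordered label tuples (length 2–3) along strict
  ancestor chains, counted once per patient, filtered at 10% / 5%
  cohort frequency, tested against a within-patient label-shuffle null
  with Benjamini–Hochberg adjustment per subgroup and length class.
* **Nested levels.** The founding clone is level 1; cohort summaries
  weight event-class occurrences equally and patients by event count.
* **Relapse hazard.** Cox partial likelihood (Efron ties, Newton solver)
  on the NOTCH1-wild-type tumor fraction: largest clone CCF minus
  largest NOTCH1-carrying clone CCF, in percentage points.

Full derivations, defaults and design decisions are in the methods
vignette (`vignettes/clonal-trajectories.Rmd`).

## Worked example

Simulate a small cohort (10 patients per subgroup) and run the full
pipeline — CCF estimation, tree reconstruction, trajectories, landscape
statistics and the hazard model:

```r
library(clonetraj)

cfg <- pipeline_config(
  out_dir  = "demo_run",
  simulate = sim_config(n_per_subgroup = 10, seed = 42),
  n_perm   = 1000,
  seed     = 42
)
res <- run_pipeline(cfg)
#> [clonetraj] cohort: 40 patients, 154 calls, 115 segments
#> [clonetraj] trees: 40 reconstructed, 0 failed
#> [clonetraj] cox: HR 1.0252 per percentage point (1.0132-1.0373), p = 3.52e-05

subset(res$trajectories, subgroup == "pediatric T-ALL")[1:5,
       c("trajectory", "support", "frequency", "p_value", "p_adjusted")]
#>                trajectory support frequency    p_value p_adjusted
#>    KMT2D->dup_in_9p->USP7       1       0.1 0.01098901  0.1471861
#>    KMT2D->dup_in_9p->TP53       1       0.1 0.01398601  0.1471861
#>   KMT2D->LOH_in_9p->FBXW7       1       0.1 0.01698302  0.1471861
#>         LOH_in_9p->NOTCH1       5       0.5 0.02297702  0.7212787
#>  KMT2D->LOH_in_9p->NOTCH1       1       0.1 0.03096903  0.1948052

ped <- res$clinical$patient_id[res$clinical$subgroup == "pediatric T-ALL"]
trees <- res$trees[intersect(ped, names(res$trees))]
weighted_nested_level(trees, "tree")$value
#> [1] 3.162791
weighted_nested_level(trees, "event_class", "^(del|LOH)_in_9")$value
#> [1] 1.857143
```

Reading the output: `LOH_in_9p -> NOTCH1` appears in 50% of the
pediatric T-ALL trees — the generator plants a 10x ordering bias on that
pair in pediatric subgroups, mimicking chr9p lesions as founder events
with *NOTCH1* mutations arising in descendant clones. The chr9 del/LOH
nested level near 1.9 against a tree level above 3 says those lesions sit
far up the trees. The Cox fit recovers a hazard ratio close to the
planted 1.032 per percentage point of NOTCH1-wild-type fraction: each
additional percent of tumor cells without a *NOTCH1* mutation raises the
modeled relapse hazard by about 2.5% in this small run (at 10 patients
per subgroup the adjusted trajectory p-values are unsurprisingly
non-significant; the acceptance suite runs the powered versions).

Individual stages are ordinary functions — `read_variant_table()`,
`read_cnv_segments()`, `ccf_event_table()`, `reconstruct()`,
`trajectory_permutation_test()`, `fit_cox_ph()` — and can be used on real
variant/segment/clinical tables in the documented TSV or VCF formats.

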