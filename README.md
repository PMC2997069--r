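# chromclose

Chromatin-modification domains — ChIP-seq peak intervals for histone marks,
histone variants and DNA-binding factors — span kilobases; CpG methylation
is measured at single dinucleotides.  `chromclose` bridges the two scales
with a **closeness measure (CM)** and builds a full inference pipeline on
top of it, for epigenomics analysts who have per-feature domain calls (BED),
a CpG methylation table, and want to know which features associate with
methylation, how loci group into chromatin-signature modules, and which
feature pairs act together.

## The measure

For a CpG locus with midpoint *x* inside a merged domain [*s*, *e*) of
length *m* = *e* − *s* and centre *c* = (*s* + *e*)/2,

    CM = clamp(1 − 2·|x − c| / m,  0,  1)

and CM = 0 for a locus overlapping no domain of the feature (intervals are
0-based half-open; overlap means ≥ 1 bp).  The score is 1 at the domain
centre, falls linearly to 0 at the edge, and is normalized by domain length,
so it is comparable across domains and to methylation fractions.  Genomic
elements (promoters, CpG islands, repeats) enter the profile as binary
overlap indicators instead.

On the N × (f+1) profile of CM values plus methylation, the package
provides: OLS regression with t-test feature selection (p < 0.001),
10-fold cross-validated Pearson correlation and permutation empirical
p-values; homogeneity-based locus modules with value-swap randomization
controls; equal-frequency binarization and greedy BDeu Bayesian-network
structure learning with compelled/reversible (CPDAG) edge labelling, per
module and globally, with interaction tallies and random-data controls;
network topology metrics against edge-count-matched random graphs; and
partial-correlation validation of discovered pairs on independent
features × bins signal matrices.  A synthetic-data generator with planted
ground truth makes every stage testable offline.

## Worked example

```r
library(chromclose)

# the measure itself
d <- merge_domains(domain_set("chr1", c(1000, 4000), c(3000, 6000),
                              feature_name = "H3K4me3"))
closeness(genomic_interval("chr1", 1999, 2001), d)  # locus at domain centre
closeness(genomic_interval("chr1", 2499, 2501), d)  # halfway to the edge
closeness(genomic_interval("chr1", 9000, 9002), d)  # outside every domain

# synthetic dataset with five informative and five null features,
# then the feature-reduced model
ds  <- simulate_dataset(generator_config(seed = 1))
frm <- feature_reduced_model(ds$profile, seed = 1)
frm$reduced
```

Output:

```
[1] 1
[1] 0.5
[1] 0
cm_regression: 5 feature(s), residual df 4994
 feature coefficient std_error      t p
     f01      0.4902  0.003677 133.31 0
     f02     -0.3529  0.003821 -92.36 0
     f03      0.3398  0.003626  93.70 0
     f04      0.3001  0.003717  80.74 0
     f05     -0.2817  0.003627 -77.67 0
cross-validated Pcc: 0.9511
```

The selection recovered exactly the five planted features (the generator's
coefficients are 0.5, −0.4, 0.35, 0.3, −0.3; estimates are mildly attenuated
by the ~3% of loci whose methylation hit the [0,1] clamp), and the reduced
model predicts held-out methylation with Pcc ≈ 0.95 at noise sd 0.05.

Continue the pipeline end to end:

```r
run <- run_pipeline(pipeline_config(dataset = ds, seed = 1), "run1")
run$clustering          # homogeneity-based locus modules
run$tally               # pairwise interactions across module networks
```

A command-line front end with the same stages (simulate, profile, select,
cluster, bn, pcor, run) is at `inst/scripts/chromclose.R`.

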