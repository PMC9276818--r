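# twinbelief

Tools for quantifying the heritability of the cognitive and affective
processes behind belief formation, using the classical twin design.

## The problem

People form beliefs about personal risk ("how likely am I to be burgled?")
by combining prior expectations with new information, and these beliefs are
shaped by lower-level processes: how vividly an event can be imagined, how
negatively it is appraised, how well new information is learned and later
remembered. In a belief-updating task, a participant gives a first
probability estimate (the *prior*), sees the base rate of the event in a
demographically similar population (the *information*), gives a second
estimate (the *posterior*), and later rates a subset of the events on
vividness, negativity, familiarity and past experience and tries to recall
the presented base rates. Administering this task to monozygotic (MZ) and
same-sex dizygotic (DZ) twin pairs lets one ask how much of the individual
variation in each derived phenotype is genetic.

`twinbelief` implements the full analysis chain:

1. **Task phenotypes** — per trial, the *update* is `|second − first|`,
   signed positively when the change is toward the information (overshooting
   still counts as toward; trials with `first == information` are excluded);
   the *estimation error* is `|first − information|`. Per subject: the mean
   update, the *learning score* (the within-subject correlation of update
   with estimation error), the *memory score* (% of recall probes matching
   the presented information), the mean prior and the mean of each rating.
2. **Twin similarity** — for each phenotype, the partial correlation between
   the twin-A and twin-B vectors (controlling for between-twin differences
   of the other task factors and for pair-level age), recomputed under
   10,000 random A/B reassignments of each pair; the mean and the 2.5/97.5
   percentiles of that distribution are reported per zygosity. A larger MZ
   than DZ correlation, with separated percentile bands, indicates
   heritability.
3. **Biometric variance decomposition** — maximum-likelihood fit of the
   ACE family. For pair *j* with genetic relatedness *R<sub>j</sub>* (1 for
   MZ, ½ for DZ),

       y_ij = μ + x_ij'β + A_ij + C_j + E_ij
       Ω_j  = [ σ_A² + σ_C² + σ_E²     R_j σ_A² + σ_C²      ]
              [ R_j σ_A² + σ_C²        σ_A² + σ_C² + σ_E²   ]

   with the ADE variant replacing C by a dominance component D whose DZ
   covariance coefficient is ¼. Submodels (AE, CE, E) are compared by
   `AIC = −2LL + 2·ep` (ep counts the intercept plus variance components);
   DE is rejected as unidentified. Components are reported as percentages of
   the residual phenotypic variance with 95% profile-likelihood confidence
   intervals (deviance cutoff 3.841, boundary-aware).
4. **Synthetic cohorts** — a generator with known A/C/D/E ground truth
   (within-pair trait covariance `σ_A² + σ_C²` for MZ, `½σ_A² + σ_C²` for
   DZ, and the ADE analogues) and a minimal trial-level task model, so every
   stage is testable end to end without any data download.

## Worked example

```r
library(twinbelief)

study <- simulate_twin_study(twin_sim_config(seed = 1))  # 184 MZ + 80 DZ pairs
phen  <- subject_phenotypes(study$trials)
group_mean_tests(phen)
#>   phenotype      mean        sd        t  df             p   n
#> 1    update 4.2228028 3.1824563 30.48985 527 1.960513e-118 528
#> 2  learning 0.3950623 0.2439883 37.20605 527 1.506967e-149 528
```

Updates and learning scores are positive (t ≫ 0): subjects move their
estimates toward the information, and more so the larger their error.

```r
pairs <- pair_phenotypes(phen)
permutation_twin_correlation(pairs, "update", n_perm = 2000, seed = 1)
#> Permutation twin correlations: phenotype 'update'
#>   MZ: mean r = 0.403 (2.5%/97.5% = 0.376/0.421), 184 pairs, 2000 permutations
#>   DZ: mean r = 0.241 (2.5%/97.5% = 0.184/0.285), 80 pairs, 2000 permutations
```

MZ pairs are more alike than DZ pairs and the percentile bands do not
overlap — evidence of a genetic contribution to belief updating.

```r
sel <- model_selection(pairs, "vividness",
                       covariates = default_biometric_covariates("vividness"),
                       seed = 1)
sel
#> Biometric model comparison: phenotype 'vividness' (winner: AE)
#>  model     A         D     C      E  AIC minus2LL ep  df winner
#>     AE 30.52 0.000e+00  0.00  69.48 1497     1491  3 525   TRUE
#>     CE  0.00 0.000e+00 28.19  71.81 1497     1491  3 525  FALSE
#>    ACE 17.49 0.000e+00 12.46  70.05 1499     1491  4 524  FALSE
#>    ADE 30.52 3.987e-10  0.00  69.48 1499     1491  4 524  FALSE
#>     E  0.00 0.000e+00  0.00 100.00 1517     1513  2 526  FALSE
profile_ci(sel$fits[["AE"]])
#>   component estimate    lower    upper boundary_lower boundary_upper
#> 1         A 30.51991 18.17287 41.84430          FALSE          FALSE
#> 2         E 69.48009 58.15570 81.82713          FALSE          FALSE
```

The AE model wins: about 31% of the (covariate-adjusted) variance in
vividness is attributed to additive genetics (95% CI 18–42%), the rest to
unique environment. The cohort was simulated with a trait heritability of
35%, so the chain recovers the ground truth within its confidence interval.
Note how close the AE and CE deviances are — with 80 DZ pairs the design has
limited power to separate additive genetics from shared environment, which
is why the permutation bands and the confidence intervals matter more than
the point ranking.

`run_twin_pipeline(twin_run_config(...))` chains all stages into one seeded,
deterministic run that writes `phenotypes.csv`, `permutation.json`,
`biometric.csv` and a reconciling log.

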