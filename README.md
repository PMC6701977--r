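# cospectra

Comparative spectral decomposition of patient-matched tumor and normal
DNA copy-number profiles: the generalized singular value decomposition
(GSVD) and its third-order tensor extension, with the downstream
workflow that turns a tumor-exclusive component into segment genotype
calls, a patient classification, and a survival stratification.

The package is for computational biologists analyzing matched
tumor/normal copy-number datasets (WGS bins or microarray probes by
patients) who want an unsupervised separation of tumor-exclusive
alteration patterns from germline variation and experimental artifacts
(GC-content effects, sequencer batches), and a test of whether the
pattern stratifies overall survival.

## The method

Two matrices $D_1 \in \mathbb{R}^{K_1\times L}$ (tumor) and
$D_2 \in \mathbb{R}^{K_2\times L}$ (normal) share their patient axis
but not their bin axes. The GSVD factorizes both at once,

$$D_i = U_i \Sigma_i V^T, \qquad i = 1,2,$$

with orthonormal dataset-specific factors $U_i$, positive generalized
singular values $\sigma_{i,a}$, and a shared row-normalized $V^T$.
The angular distance
$\theta_a = \arctan(\sigma_{1,a}/\sigma_{2,a}) - \pi/4 \in (-\pi/4,\pi/4)$
measures how exclusively component $a$ belongs to the tumor dataset;
$P_{i,a}=\sigma_{i,a}^2/\sum_b\sigma_{i,b}^2$ measures its significance
within dataset $i$. The selected pattern is the most exclusive
significant component. For platform-matched profiles, two
$K_i \times L \times M$ tensors are decomposed via GSVDs of their mode
unfoldings into $D_i = R_i \times_a U_i \times_b V_x \times_c V_y$,
whose core-tensor ratios and angular distances provably collapse onto
the row-mode ones (and are tested to, numerically).

Downstream: segments are called amplified/unaltered/deleted by the
difference between segment and chromosome-arm medians in units of the
pattern's median absolute deviation; patients are classified by
Spearman correlation with the pattern (cutoff 0.35) and by their
superposition coefficient (0.35 scaled by the norm of the correlation
vector); Kaplan-Meier curves, log-rank tests and Cox models (Efron
ties, Harrell concordance) quantify the survival split. A synthetic
generator plants a known block pattern, shared variation, a GC
artifact, batch offsets and proportional-hazards outcomes, providing
ground truth for every step.

## Worked example

```r
library(cospectra)

res <- run_end_to_end(synthetic_config(seed = 7))
res$fit
#> <gsvd_fit> 100 components over 100 patients
#>   theta range: [-0.6955, 0.7204] rad

head(tidy(res$fit), 3)
#>   component sigma1 sigma2 ratio theta significance1 significance2
#> 1         1   91.8   5.98 15.4  0.720        0.133       0.000684
#> 2         2   63.0   6.06 10.4  0.689        0.0627      0.000702
#> 3         3   32.2  17.8   1.81 0.281        0.0164      0.00604
```

Component 1 is both the most tumor-exclusive ($\theta = 0.72$, near the
$\pi/4$ limit) and significant (13% of the tumor spectrum): it carries
the planted alteration pattern, while component 2 is the tumor
sequencer-batch artifact (its patient loadings separate the two
sequencers at MWW $P \approx 10^{-17}$); the shared germline-like and
GC components sit near $\theta = 0$ in the middle of the spectrum.
Classification and survival follow:

```r
res$segment_calls[, c("label", "n_probes", "delta_in_mads", "call")]
#>   label  n_probes delta_in_mads call
#> 1 block1      270         -1.01 deleted
#> 2 block2      150          1.34 amplified

str(res$summary[c("n_high_by_correlation", "high_set_overlap",
                  "km_median_high", "km_median_low", "logrank_p")])
#> $ n_high_by_correlation: int 20
#> $ high_set_overlap     : num 1
#> $ km_median_high       : num 7.09
#> $ km_median_low        : num 31.2
#> $ logrank_p            : num 0.00051

tidy(res$cox)
#>   term         hazard_ratio conf_low conf_high  p_value
#> 1 pattern_high         2.64     1.49      4.66 0.000822
```

The 20 pattern-high patients (exactly the planted carriers) show a
median survival of 7.1 months against 31.2 for the rest, a log-rank
$P = 5\times10^{-4}$ and a hazard ratio of 2.6 (true planted value 3,
inside the 95% CI). `autoplot(res$km)` draws the stratified curves and
`autoplot(res$fit)` the per-component angular distances.

A thin command-line wrapper over the same functions lives at
`inst/cli/cospec.R` (`simulate`, `gsvd`, `classify`, `survive`, `run`
subcommands).

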