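# otomix

Unconditional maximum-likelihood mixture models for mixed-stock analysis of
otolith chemistry, with the parametric-bootstrap machinery needed to know
how far to trust them.

## The problem

Fish that grew up in different nursery habitats carry habitat-specific
chemical fingerprints in their otoliths — here a panel of `J = 7`
standardized element:Ca ratios (Li, B, Mg, Rb, Sr, Y, Ba). A sample from a
mixed adult stock is modeled as a finite mixture of multivariate normal
sources,

    f(x) = Σₖ pₖ · g(x; μₖ, Σₖ),   k = 1…K

with three parameter groups: the number of contributing nursery sources
`K`, their baseline signatures `θₖ = (μₖ, Σₖ)`, and the mixing proportions
`pₖ` — the management-relevant estimand. Classical (conditional) mixture
analysis fixes `θₖ` from juvenile baseline samples and breaks when some
nurseries were never sampled. `otomix` implements the *unconditional*
alternative: an EM algorithm over the joint likelihood of labeled
nursery-source data and unlabeled mixed-stock data, so signatures of
sampled sources are refined by the mixture and signatures of unsampled
sources are estimated from it, for any number of sampled sources
`K_S = 0…K`. The number of sources can itself be estimated by BIC over a
ladder of fits, and a simulation framework quantifies bias (`BI`) and
uncertainty (`SE`) of all three parameter groups under controlled
incomplete-sampling and signature-separation scenarios.

## A worked example

Build a synthetic 4-source cohort whose centroids are separated by an
average squared Mahalanobis distance of 2.78 on the standardized scale,
sample 25 juveniles from three of the four sources, and a 100-fish mixed
stock with true proportions 0.1/0.2/0.3/0.4 randomly allocated to sources;
then fit the model with the fourth source unsampled:

```r
library(otomix)

baseline <- random_baseline(K = 4, J = 7, target_sep = 2.78, spread = 0.5, seed = 42)
nursery  <- draw_nursery_dataset(baseline, c("S1", "S2", "S3"), n_per_source = 25, seed = 101)
mixed    <- draw_mixed_dataset(baseline, m = c(0.1, 0.2, 0.3, 0.4), n_mixed = 100, seed = 102)

fit <- fit_mixture(nursery, mixed$table, K = 4, em_controls(seed = 103))
fit
#> Mixture fit: K = 4 (75 labeled + 100 mixed obs), loglik = -785.920
#>   converged after 28 iterations
#>  component  p_hat
#>         S1 0.1529
#>         S2 0.0910
#>         S3 0.3288
#>    novel-1 0.4273

round(mixed$truth$allocation, 2)
#>  S1  S2  S3  S4
#> 0.2 0.1 0.3 0.4
```

The three labeled components recover their true proportions to within a few
points, and the `novel-1` component — initialized by semi-supervised
K-means with the three known means held fixed — recovers the unsampled
source S4's 40% contribution as 0.427. Estimating the *number* of sources
is harder; the BIC ladder illustrates its documented pessimism:

```r
estimate_k(nursery, mixed$table, K_S = 3, K_max = 8, controls = em_controls(seed = 104))
#> Model selection by BIC: K_hat = 3 (delta = 244.35)
#>  K    loglik   q      BIC converged selected
#>  3 -841.6088 107 2235.850      TRUE     TRUE
#>  4 -785.9203 143 2310.405      TRUE    FALSE
#>  ...
```

With one source unsampled, BIC prefers the 3-component model: the selected
K is a lower bound on the true number of sources, not an estimate of it.
The simulation drivers under `analysis/` (run them in order,
`01_baselines.R` … `04_number_of_sources.R`) quantify exactly this, plus
the bias/uncertainty surfaces over sampling and separation scenarios,
writing their tables under `results/`.

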