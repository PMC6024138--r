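# ocdesign

Occupancy estimation for acoustic wildlife surveys whose automated species
classifications are wrong often enough to matter.

Passive acoustic recorders paired with classification software produce
visit-level detection data with **two** error processes: imperfect
detection (the species was present but no recording was classified to it)
and misidentification (a recording was classified to the species at a site
it does not occupy). A standard occupancy analysis handles only the first.
The usual remedies are to have an expert verify every detection before
fitting a standard model (**REMOVE**) — accurate but expensive — or to fit
the standard model to unverified data (**IGNORE**) — cheap but badly
positively biased. `ocdesign` implements a third option (**MODEL**): an
extended observation-confirmation (OC) occupancy model in which only a
configurable subset of visits is expert-confirmed, and the remaining
visits contribute their unverified detections with misidentification
modelled explicitly. The package is aimed at biostatisticians and
monitoring programs designing bat (or other taxa) acoustic surveys:
it answers "how much verification effort can we drop before occupancy
estimates degrade?"

## The model

Site occupancy is latent, `Z_i ~ Bernoulli(psi_i)`. During visit `j` to
site `i`, with probability `s1_ij` at least one recording is made and
correctly classified to the focal species, and with probability `s0_ij` at
least one recording is misclassified to it. An **unconfirmed** visit yields
only the ambiguous indicator `y_ij`, with

    Pr(y_ij = 1 | Z_i = 1) = p11_ij = s1_ij + s0_ij - s1_ij * s0_ij
    Pr(y_ij = 1 | Z_i = 0) = p10_ij = s0_ij

A **confirmed** visit yields a four-category outcome `nu_ij` from expert
review of the automatic classifications — 0 nothing to confirm, 1 all
overturned, 2 all verified, 3 mixed — with conditional multinomial
probabilities

    Z = 1:  { (1-s0)(1-s1),  s0 (1-s1),  s1 (1-s0),  s0 s1 }
    Z = 0:  { 1-s0,          s0,         0,          0     }

The likelihood mixes the two visit types within sites over the latent
state; covariates enter through logit links, by default
`logit(s_l) = b0_l + b1_l * log(K+1)` where `K` is the number of
auto-classified recordings during the visit (a call-quality proxy).
Fitting is by maximum likelihood (quasi-Newton, finite-difference Hessian,
±2 SE Wald intervals) with an explicit taxonomy of convergence failures.
A confirmation design `C(p, d)` confirms `d` visits (ambiguous detections
first) in a proportion `p` of sites; the simulator and study harness
compare REMOVE / IGNORE / MODEL across designs by bias, interval width,
coverage and convergence-failure counts on shared simulated datasets.

## Worked example

Simulate a widely distributed, average-detectability, easy-to-misidentify
species (the `HMH` scenario: `psi = 0.8`, detection coefficients
`(0, 1.6)`, misidentification coefficients `(-2.2, 1.5)`) over 84 sites
and 4 visits, keep expert confirmation for only 2 visits in half the
sites, and fit the OC model:

```r
library(ocdesign)

scenario <- defaultScenarios()$HMH
design   <- surveyDesign(nSites = 84, nVisits = 4)
survey   <- simulateUnambiguous(scenario, design, seed = 42)
partial  <- applyConfirmation(survey, confirmationDesign(0.5, 2), seed = 42)
partial
#> ocSurvey: 84 sites, 336 visits
#>   confirmed visits : 84 (25%)
#>   ambiguous detections: 296
#>   simulated; occupied sites: 69 of 84
#>   scenario: HMH

fitOC(partial, options = fitOptions(seed = 1))
#> ocFit [MODEL] status: converged
#>                 estimate     se   lower   upper
#> psi_(Intercept)   1.4948 0.3588  0.7772  2.2123
#> s1_(Intercept)   -0.0441 0.3205 -0.6850  0.5968
#> s1_logK           1.4315 0.3849  0.6617  2.2013
#> s0_(Intercept)   -1.9566 0.5122 -2.9811 -0.9322
#> s0_logK           1.5344 0.2575  1.0194  2.0494
#> psi-hat = 0.8168  (0.6851, 0.9013)
#> negative log-likelihood: 125.11139
```

With confirmation effort cut to a quarter of all visits, the occupancy
estimate `psi-hat = 0.817` still brackets the generating value 0.8 with an
interval of width ~0.22, and the detection and misidentification
coefficients are recovered near their generating values. The true number
of occupied sites in this draw was 69/84 = 0.82. `runStudy()` repeats this
comparison over hundreds of replicates, scenarios and confirmation designs
and summarizes bias, coverage and convergence failures;
`failureTable()` tabulates the failure counts.

A command-line interface wrapping the same functions ships in
`inst/cli/ocdesign.R` with subcommands `simulate`, `fit`, `study` and
`validate`; configuration is JSON and every run writes a manifest with the
seed needed to reproduce its outputs bit-for-bit.

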