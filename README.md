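# casteflow

Caste-structured loss/gain modelling of *Wolbachia* prevalence in
termite colonies.

## The problem

*Wolbachia* is a maternally inherited endosymbiont: every member of a
termite colony descends from the queen, so under pure vertical
transmission infection can only be *lost* along the developmental
sequence queen → larva → worker → white soldier → mature soldier.  A
PCR screen of 555 individuals from 15 *Cubitermes* colonies (four
cryptic species A–D; the full count table ships with the package) shows
white soldiers — the transitional molt stage fed pure saliva by
workers — at 74% infection, far above the workers (33%) they molt from.
`casteflow` is the analysis that quantifies how much horizontal gain,
and at which stage, is needed to explain that excess.

## The model

Stage-wise infection rates follow a discrete recursion with
per-transition loss probabilities `a(s,c)` and gain probabilities
`b(s,c)` (species `s`, stage `c`), in two variants:

* Eq. 1 (gain between stages): `I' = (1-a) I + b (1-I)`
* Eq. 2 (gain during the stage): `I' = (1-a) I (1-b) + b`

Starting from `I = 1` at the queen, the recursion is fitted to the
colony × stage infected counts by binomial maximum likelihood
(multi-start BFGS on the logit scale).  A 28-model grid crosses both
equations with loss/gain sharing patterns (`a(.,.)`, `a(s,.)`,
`a(.,c)`, `a(s,c)`; likewise for `b`), ranked by QAICc — AIC corrected
for overdispersion (`c-hat = 2.9`) and small effective sample size —
with Akaike weights.  The selected model is refined by zeroing
parameters whose Wald 95% CI covers 0 and tying parameters with
overlapping CIs, refitting after each action and keeping the QAICc-best
candidate.  Counterfactual trajectories with all gains forced to zero
isolate the loss process.

## Worked example

```r
library(casteflow)

data  <- table1_fixture()               # the embedded 15-colony screen
caste_summary_table(data)
#>          caste n_tested n_infected rate_pct ci_lower_pct ci_upper_pct letter
#>          larva      144         90    62.50           54           71      b
#>         worker      169         55    32.54           25           40      a
#>  white_soldier       77         57    74.03           64           84      c
#>        soldier      145         56    38.62           31           47      a

cells <- pool(data, "by_colony_stage")  # 54 binomial cells, stages 2-5

# refined structure: eq-2 recursion, one loss per species, one shared
# gain at the white-soldier stage
spec <- model_spec(2, "by_species", "by_stage",
                   zero_mask = data.frame(kind = "gain", species = NA,
                                          stage = c("larva", "worker",
                                                    "soldier")))
fit <- fit_model(spec, cells, compute_se = TRUE)
fit
#> caste_fit: eq2 a(s,.)/b(.,c)
#>   -lnL = 147.8824  K = 5  converged = TRUE
#>           parameter estimate     se
#>              a(A,.)   0.2245 0.0352
#>              a(B,.)   0.5224 0.0390
#>              a(C,.)   0.4410 0.0379
#>              a(D,.)   0.5592 0.1240
#>  b(.,white_soldier)   0.6435 0.0590
```

Per transition, species A loses the symbiont with probability 0.22 and
species B–D with 0.44–0.56, while an uninfected white soldier becomes
infected during that stage with probability 0.64 regardless of species.
Forcing that gain to zero collapses the expected white-soldier rate:

```r
sapply(c("A", "B", "C", "D"), function(sp)
  round(100 * counterfactual_no_gain(fit$params, sp, 2)$rate[4]))
#>  A  B  C  D
#> 47 11 17  9         # mean 21%, versus ~70% expected with the gain
```

The full pipeline — descriptives, grid, ranking, refinement,
trajectories — is one call
(`run_full_analysis("fixture", n_eff = 47)`), and the `analysis/`
directory holds the numbered scripts that generated everything under
`results/`:

```sh
Rscript analysis/01_descriptives.R        # rates, CIs, Wald letters
Rscript analysis/02_model_grid.R          # 28-model QAICc table
Rscript analysis/03_refine_trajectories.R # refinement + counterfactuals
Rscript analysis/04_recovery_simulation.R # synthetic-data validation
```

On the embedded data the grid selects model 27 (eq. 2, species-specific
loss, caste-specific gain; Akaike weight 0.35 at the `c-hat = 2.9`,
`n_eff = 47` preset), and the gain concentrates entirely at the white
soldier — the caste that receives pure saliva from workers, consistent
with trophallactic transmission.

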