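# istrack

Clonal tracking of long-term lymphoid progenitors (LtLP) from retroviral
vector integration sites (IS).

## The problem

In gene therapy with integrating vectors, each transduced progenitor and
all of its progeny carry the vector at one genomic coordinate — a
heritable clonal barcode. In patients who have lost their engineered
stem cells, vector-positive naive T (TN) and NK cells appearing years
later must descend from long-lived lymphoid-committed progenitors.
`istrack` turns longitudinal IS and TCR-repertoire tables from sorted
lymphocyte subsets into the quantities that characterise that progenitor
population:

- **IS hygiene and the abundance matrix** — cross-patient 10-fold
  collision (contamination) filter; IS × sample read-count matrix *M*
  with a relative-abundance view.
- **Clonal diversity** — Shannon *H = −Σ pᵢ ln pᵢ*, Simpson *D = Σ pᵢ²*,
  inverse Simpson, per sample and over time.
- **Sharing and recapture** — fractions of IS shared between naive,
  memory and NK compartments (optionally restricted to independently
  sequenced timepoints), longitudinal recapture fractions, and
  Pearson-correlation sharing networks.
- **Closed-population capture–recapture** — each timepoint is a capture
  occasion; Poisson log-linear models on capture-history counts
  (M0, Mt, and the Chao lower-bound heterogeneity variants Mh/Mth with
  η ≥ 0) give *N̂ = n_obs + exp(β̂0)*, the number of active clones
  including unseen ones, with delta-method SE. The reported model is the
  most conservative among those with lowest BIC.
- **TCR branch** — per-sample clonotype diversity, cross-subtype sharing
  networks, longitudinal clonotype recapture, and Hamming distance
  matrices over 50-bp CDR3-centred windows. Fresh TCRs on persistent IS
  is the fingerprint of ongoing thymic output from long-lived clones.
- **Proto-oncogene surveillance** — single-nearest-TSS gene assignment
  within 1 Mb, abundance classes at the 1%/10% thresholds for watched
  loci (LMO2, MECOM, CCND2), and clone trajectories against a 0.0001%
  sequencing noise floor.
- **A calibrated simulator** — `simulate_cohort()` generates IS/TCR
  tables with known ground truth (clone pool, heterogeneous output
  rates, bipotent T/NK clones, memory carryover, contamination), used to
  validate every estimator.

## Worked example

```r
library(istrack)

cohort <- simulate_cohort(sim_config(seed = 7))     # 2 patients x 3000 clones
flt    <- collision_filter(cohort$is_table, fold = 10)
m      <- build_matrix(flt$records)
m
#> abundance_matrix: 2960 IS x 30 samples, 615,348 total reads

head(diversity_timecourse(m, "TN")[, c("patient", "timepoint_months",
                                       "n_clones", "shannon")], 3)
#>   patient timepoint_months n_clones  shannon
#> 1      P1               60      395 5.645702
#> 2      P1              100      328 5.485857
#> 3      P1              140      245 5.185583

sharing_fraction(m, "TN", c("TSCM", "TCM", "TEM"))
#>   patient focal  comparators n_focal n_shared percent_shared
#> 1      P1    TN TSCM,TCM,TEM     842      312       37.05463
#> 2      P2    TN TSCM,TCM,TEM     874      287       32.83753

est <- estimate_ltlp(m, "TN")
est[, c("patient", "model", "N_hat", "SE", "BIC", "selected")]
#>   patient    model    N_hat       SE       BIC selected
#> 1      P1       M0 2366.222 173.3649  99.61076    FALSE
#> 2      P1       Mt 2325.770 169.4874  71.88962     TRUE
#> 3      P1  Mh_Chao 2464.299 201.2757 104.71424    FALSE
#> 4      P1 Mth_Chao 2425.164 196.8760  76.82661    FALSE
#> 5      P2       M0 2279.882 153.2469  85.94791    FALSE
#> 6      P2       Mt 2255.286 151.0274  72.28744     TRUE
#> 7      P2  Mh_Chao 2279.882 153.2469  85.94791    FALSE
#> 8      P2 Mth_Chao 2255.286 151.0274  72.28744    FALSE
```

Reading the output: each patient's 3000-clone pool yields ~850 observed
TN integration sites over three timepoints; TN Shannon diversity stays
high and flat (polyclonal, stable output); about a third of TN clones
reappear in memory subsets (ongoing differentiation); and the selected
capture–recapture fit estimates ~2300 active clones — a conservative
lower bound on the true 3000 under heterogeneous clone output (see the
methods vignette, `vignettes/clonal-tracking.Rmd`, on why these
estimators are lower bounds).

`run_pipeline(run_config(...))` executes the whole chain — from an IS
table or a simulation — and writes every stage artefact as TSV plus a
JSON run manifest.

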