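# meltrisk

Mixture toxic-risk screening of snow-melt and road-runoff contaminants.

Urban snow accumulates traffic-related chemicals (tire-wear transformation
products such as 6-PPD-quinone, vulcanization by-products, fuel and
antifreeze additives) alongside biocides, pesticides and compounds of human
consumption. When the snow melts, this mixture is released to sewers and
surface waters within days. `meltrisk` is for environmental chemists and
ecotoxicologists who have per-site concentration tables from such screening
campaigns and want to answer three questions:

1. **How risky is the mixture at each site?** Toxic units under
   concentration addition, per biological quality element (BQE: algae,
   crustaceans, fish), with chronic and acute threshold classification and
   ranked risk drivers.
2. **Which compounds in a treatment plant's influent actually come from the
   melt runoff?** Spearman rank correlation of daily influent concentrations
   with inlet flow.
3. **How well does the plant remove them?** Removal rates from cumulative
   influent/effluent loads over the melt period.

A synthetic-data module generates complete campaigns with known ground truth
(planted fingerprints, risk drivers, source classes and removal rates), so
the whole pipeline is testable end to end.

## The model

The toxic unit of compound *i* for BQE *b* in sample *s* is

```
TU_{s,b,i} = MEC_{s,i} / EC50_{b,i}
```

with the measured environmental concentration (MEC, stored in ng/L)
converted to mg/L exactly once. Mixture risk assumes concentration addition:

```
TUsum_{s,b} = Σ_i TU_{s,b,i}
```

summed over all detected (non-censored) compounds, using order-independent
compensated summation. Samples are prioritised against chronic TUsum
thresholds of 0.02 (algae), 0.001 (crustaceans) and 0.01 (fish), and an
acute threshold of 1 (configurable); exceedance is strict.

`EC50_{b,i}` follows a selection hierarchy: (1) the 5th percentile of all
experimental EC50 values available for that compound and BQE; else (2) a
baseline-toxicity (narcosis) QSAR prediction `log10 EC50 = a·logKow + b`,
capped at the compound's water solubility when the prediction exceeds it by
more than half a log10 unit (an effect cannot occur above saturation); else
(3) the compound is excluded and reported, never imputed.

In the treatment plant, compounds whose influent concentrations rise with
inlet flow (Spearman ρ > 0.5) are classified runoff-dominated; those diluted
by the extra flow (ρ < −0.5) have other dominant sources; |ρ| ≤ 0.5 is a
mixed pattern. Removal is `1 − L_eff/L_inf` from cumulative loads
(concentration × flow summed over days), binned as >80 %, 50–80 %, <50 %,
negative, or effluent-below-detection.

## Worked example

```r
library(meltrisk)

gen  <- generate_compound_library(n_compounds = 80, effect_data_coverage = 0.5, seed = 42)
snow <- generate_snow_samples(snow_scenario(seed = 42), gen$library, gen$effects)
risk <- assess_risk(snow$table, gen$library, effect_database(gen$effects))
risk
#> <risk_assessment>
#>   samples: 23
#>   algae      chronic exceedances: 23, acute: 23
#>   crustacean chronic exceedances: 23, acute: 23
#>   fish       chronic exceedances: 23, acute: 23

head(tidy(risk, "contributions"), 3)
#> # A tibble: 3 × 6
#>   sample_id     compound_id bqe      tu ec50_provenance  rank
#>   <chr>         <chr>       <chr> <dbl> <chr>           <int>
#> 1 background_01 C039        algae 2.84  predicted           1
#> 2 background_01 C004        algae 0.354 predicted           2
#> 3 background_01 C008        algae 0.227 experimental        3
```

23 synthetic sites (20 road, 3 background) all exceed the chronic and acute
thresholds for every organism group — the generator's log-uniform synthetic
EC50s make the toxicity of this particular mixture high. The contributions
table ranks compounds by toxic unit within each sample and BQE; `rank == 1`
is the site's dominant risk driver, and `autoplot(risk)` draws the stacked
per-site TU bars with minor contributors aggregated as "further compounds".

```r
ww  <- generate_wwtp_series(wwtp_scenario(seed = 42), gen$library)
att <- attribute_sources(ww$influent)
att
#> <source_attribution> cutoff |rho| > 0.5
#>   source_class             n
#> 1 diluted_other_source    27
#> 2 mixed                   23
#> 3 runoff_dominated        13

estimate_removal(ww$influent, ww$effluent,
                 compounds = unique(snow$table$compound_id))
#> <removal_result> 63 compounds, window 2021-02-17 to 2021-02-22
#>   bin                    n
#> 1 effluent_below_mdl    13
#> 2 high                  27
#> 3 low                    6
#> 4 medium                13
#> 5 negative               4
```

The attribution recovers exactly the planted 13 runoff-driven and 27
flow-diluted compounds; the removal bins match the planted per-compound
removal rates, including four compounds with apparent negative removal and
13 whose effluent concentrations fall below the detection limit.

A command-line wrapper with subcommands `simulate`, `risk`, `wwtp` and
`report` is installed at `inst/cli/meltrisk`; it reads a YAML configuration
and echoes it, with a log, into every output directory.

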