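# phasekin

Where an antioxidant sits inside an oil-in-water emulsion — dissolved in
the oil, in the water, or concentrated in the thin surfactant film between
them — largely decides how well it protects the oil from oxidation.
`phasekin` is an R package for food chemists and physical chemists working
on emulsion oxidation: it implements the pseudophase kinetic model that
turns bench measurements into partition constants, regional distributions
and effective interfacial concentrations, the assay reductions around it
(FRAP, DPPH EC₅₀, oxidative-stability induction times), and the
statistical layer that asks which compound properties actually predict
antioxidant efficiency.

## The model in brief

The emulsion is treated as three regions — oil (O), water (W),
interfacial (I) — with volume fractions Φ_O, Φ_W, Φ_I (Φ_I = surfactant
volume / emulsion volume). Effective concentrations are per litre of
region, and partitioning is described by

    P_OI = (AO_I)/(AO_O),   P_WI = (AO_I)/(AO_W)

For a compound occupying water + interface, the interfacial mole fraction
is `f_I = P_WI·Φ_I / (Φ_W + P_WI·Φ_I)` (symmetrically with Φ_O for
oil + interface) and `(AO_I) = f_I·[AO_T]/Φ_I`. The constants are
measured kinetically: a surface-confined arenediazonium probe reacts with
the antioxidant at `k_obs = k_I·(AO_I)`, so fitting k_obs across a series
of emulsifier fractions yields both the intrinsic interfacial rate
constant k_I and the partition constant. Downstream, Pearson screening
and probability-of-F stepwise regression (enter < 0.150, remove > 0.200)
relate the relative oxidative stability `(t_AO − t_C)/t_C` to the
interfacial concentration, the anodic peak potential E_pa, and the other
compound properties.

## Worked example

The package ships a measured property panel for five phenolic series
(tyrosol, hydroxytyrosol, 4-hydroxycinnamic, caffeic, dihydrocaffeic
acids and their C8/C16 esters) in 4:6 olive oil-in-water emulsions.
Distributions at an emulsifier fraction of 0.01 and the standard 0.24 mM
antioxidant load:

```r
library(phasekin)
comp <- emulsion_composition(0.4, 0.6, 0.01)
pd <- panel_distribution(phenolipid_panel(), comp, total_ao = 0.24e-3)
print(pd, digits = 3)
#>    compound     region_pair   p c_interface_mM enhancement f_interface
#> 1        HT water_interface  53           11.3        46.9       0.469
#> 2       HT8   oil_interface 296           21.1        88.1       0.881
#> 3      HT16   oil_interface  52           13.6        56.5       0.565
#> 4      HCA8   oil_interface  39           11.8        49.4       0.494
#> 5     HCA16   oil_interface  36           11.4        47.4       0.474
#> 6        CA water_interface 204           18.5        77.3       0.773
#> 7       CA8   oil_interface 502           22.2        92.6       0.926
#> 8      CA16   oil_interface 376           21.7        90.4       0.904
#> 9       DCA water_interface  58           11.8        49.2       0.492
#> 10     DCA8   oil_interface 368           21.6        90.2       0.902
#> 11    DCA16   oil_interface 220           20.3        84.6       0.846
```

Every compound is 47–93 times more concentrated at the interface than its
stoichiometric 0.24 mM — the central quantitative fact of interfacial
antioxidant chemistry. At a lower emulsifier fraction the film is thinner
and the effect stronger; octyl dihydrocaffeate at Φ_I = 0.005:

```r
distribution_two_region(partition_set(p_oi = 368),
                        emulsion_composition(0.4, 0.6, 0.005), 0.24e-3)
#> Antioxidant distribution at phi_interface = 0.005 ([AO_T] = 0.00024 M)
#>     region  fraction       conc_M
#>        oil 0.1785714 0.0001071429
#>      water 0.0000000 0.0000000000
#>  interface 0.8214286 0.0394285714
```

i.e. 82 % of the compound sits in the film at an effective ~39 mM.

A full synthetic study — traces to first-order fits to partition
constants to distributions to stability to stepwise selection — runs in
one call with known ground truth:

```r
run <- run_pipeline(scenario_spec(seed = 7))
run$partition_fits
#>  compound     region_pair     k_i  k_i_err      p   p_err k_i_true p_true
#>   ester16   oil_interface 0.60568 0.061998 174.22  64.871     0.60    215
#>    ester8   oil_interface 0.77004 0.063943 793.98 809.441     0.80    380
#>    parent water_interface 0.44918 0.039201  71.87  11.732     0.50     55
#>    weak16   oil_interface 0.03725 0.004594  40.69   8.863     0.04     36
#>     weak8   oil_interface 0.04817 0.003456  39.74   4.999     0.05     40
run$stepwise$predictors[1]
#> [1] "c_interface"
```

The interfacial concentration enters the stepwise model first — it is the
dominant planted predictor — and the standard errors honestly reflect how
weakly large partition constants are identified at realistic (±7–9 %)
rate noise: note `ester8`. The methods vignette
(`vignettes/pseudophase-partitioning.Rmd`) discusses both points.

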