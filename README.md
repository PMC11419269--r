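# trem2map

Tools for mapping ligand-binding surfaces on TREM2, the microglial
immunoreceptor whose point variants (R47H, R62H, D87N, T96K) modify
late-onset Alzheimer's disease risk. TREM2's V-type Ig ectodomain engages
apolipoprotein E, oligomeric amyloid-beta, TDP-43, complement C1q and
IL-34 through a handful of surfaces — a hydrophobic CDR-loop patch, an
electropositive *basic site*, and *site 2*. `trem2map` implements the
computational workflow for assigning ligands to surfaces:

* **Hydropathy-complementarity screen** — sequences are binarized by the
  sign of their Kyte–Doolittle index H(i) and a motif of length L is slid
  (forward and reversed) along a target, scoring each alignment by percent
  sign match and by the degree of complementary hydropathy

  C = Σᵢ |H(i) − H′(i)| / (9·L),  C ∈ [0, 1],

  with good hits (match > 75%, C > 0.5, both strict) clustered into
  candidate binding regions.
* **BLI kinetics** — 1:1 Langmuir sensorgram simulation
  (R(t) = R_eq(1 − e^(−k_obs t)), k_obs = k_on·c + k_off), double-reference
  subtraction, steady-state (R_eq = R_max·c/(c + K_D)) and global kinetic
  K_D fitting, biphasic-trace flagging, and fold-change-vs-WT reporting
  across the packaged 24-member variant panel with typed no-binding
  sentinels.
* **Competition binding** — sequential-association assays under a
  shared-site competitive model (dR_A/dt = k_on,A·c_A·(R_max − R_A − R_B)
  − k_off,A·R_A), percent decrease of the second association, and
  titration block curves.
* **Synthetic data** — seeded, bit-reproducible generators for sensorgram
  families, biphasic traces, competition traces, and sequence pairs with
  planted complementary windows, so the whole pipeline runs and is tested
  without any instrument data.

The human TREM2 (Q9NZC2) and IL-34 (Q6ZMJ4) precursor sequences and the
variant affinity panel ship with the package (`trem2map_extdata()`).

## Worked example

```r
library(trem2map)

trem2 <- read_fasta(trem2map_extdata("trem2_Q9NZC2.fasta"))[[1]]
il34  <- read_fasta(trem2map_extdata("il34_Q6ZMJ4.fasta"))[[1]]
res <- run_binding_site_screen(trem2, il34)
res$trem2_regions[, 1:4]
#>  sequence_id start end supporting_hits
#>        TREM2    48  85              17
#>        TREM2    92 130              16
```

Two candidate regions on TREM2: residues 48–85 (the central basic-site
strands plus all of CDR2) and 92–130 (the strand carrying site 2). The
reverse direction clusters five regions on IL-34. A sensorgram family
generated at the wild-type IL-34 affinity and refitted:

```r
fam <- make_sensorgram_family(16.5e-9, c(62.5, 125, 250, 500, 1000) * 1e-9,
                              noise_sd = 0.01, seed = 42)
fit_kinetics(fam)
#> <fit_result> model = one-to-one, converged = TRUE
#>   KD = 1.646e-08 M (se 3.9e-11)
#>   residual RMS = 0.0101 RU; biphasic = FALSE
```

The fitted K_D (16.46 nM) recovers the generating 16.5 nM to 0.2% under
1% noise. Variant effects come straight from the panel table:

```r
tab <- trem2_variant_table()
fold_change(tab$kd_il34[tab$variant == "R47H"],
            tab$kd_il34[tab$variant == "WT"])
#> R47H vs WT (IL-34): 4.84-fold affinity-decrease
```

A thin command-line wrapper for the screen lives in
`inst/scripts/trem2map-screen.R`; the methods vignette
(`vignettes/trem2-binding-surface-mapping.Rmd`) documents the models,
defaults and design decisions.

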