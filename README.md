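# nmrMetabotyping

Inflammation-aware metabolic phenotyping of plasma ^1^H-NMR profiles,
built for the prostate-cancer setting in which systemic inflammation —
read out through the glycoprotein NMR markers **GlycA** and **GlycB** —
tracks disease aggressiveness.  The package is aimed at NMR metabolomics
analysts who need a tested, reproducible pipeline from processed 1D
spectra to patient strata ("metabotypes") and their statistical
characterisation, without access to the original patient data: a
synthetic-spectrum generator with known ground truth makes every stage
verifiable end to end.

## What it computes

* **Spectral quantification.**  Each spectrum is calibrated to the
  α-glucose anomeric doublet at 5.24 ppm, then a 41-signal panel is
  quantified: resolvable metabolites by bounded Voigt-multiplet fits over
  a local linear baseline (Voigt profile
  V(x; σ, γ) = Re w(z) / (σ√2π), z = (x + iγ)/(σ√2), shared per-spectrum
  linewidths estimated from strong reference peaks); GlycA and GlycB by
  integration of 2.005–2.054 and 2.054–2.086 ppm above a shared
  local-baseline chord that removes the lipoprotein background; total
  protein amides by plain integration of 6–10 ppm.
* **Metabotype discovery.**  A KODAMA-style procedure learns sample
  proximities by iteratively maximising the cross-validated accuracy of a
  k-nearest-neighbour self-classification over randomised restarts; the
  co-classification matrix is embedded by metric MDS, clustered with Ward
  (D2) linkage, the cluster number k ∈ [2, 10] chosen by median
  silhouette, and clusters ordered I..k by clinical severity (share of
  very-high-risk/metastatic members, then median PSA).
* **Statistics.**  Wilcoxon rank-sum and Kruskal–Wallis tests, Fisher's
  exact test, Spearman correlation, Benjamini–Hochberg control at
  FDR < 10%, order-statistic median [95% CI] summaries, metabotype-vs-rest
  comparison tables and a clinical summary table.
* **Supervised validation.**  PLS-DA with double (nested) 10-fold
  cross-validation: inner folds select the component number, outer folds
  give unbiased accuracy, R² and Q².
* **Clinical data model.**  Patient records with censored PSA (">5000"),
  Gleason scores, clinical T stages, exact follow-up-day arithmetic and a
  simplified NCCN-style risk mapper.  A 14-patient patient-level table of
  the very-high-risk/inflammatory subgroup ships as a plain-text fixture
  (`clinicalFixturePath()`).

## Worked example

```r
library(nmrMetabotyping)

## a 4-metabotype synthetic cohort, 15 patients per group
coh  <- generateCohort(cohortConfig(seed = 42))
clin <- coh$clinical
clin$risk_group <- mapply(classifyRisk, clin$psa, clin$gleason_primary,
                          clin$gleason_secondary, clin$stage, clin$metastasis)

## unsupervised metabotype discovery (markers excluded from clustering)
mt <- discoverMetabotypes(coh$truth, clinical = clin, seed = 3)
mt
#> MetabotypeResult: 60 samples, k = 4
#>   I  II III  IV
#>  15  15  15  15

## characterise the inflammatory metabotype against the rest
cmp <- compareGroupVsRest(coh$truth, metabotypeLabels(mt), "IV")
head(cmp[, c("feature", "median_target", "median_rest", "direction", "p", "q")])
#>           feature median_target median_rest direction        p        q
#> 1           GlycA        14.547       9.582         1 3.18e-08 1.30e-06
#> 2      asparagine         0.762       0.991        -1 1.46e-07 2.98e-06
#> 3       glutamate         1.802       2.693        -1 3.03e-07 4.14e-06
#> 4      isoleucine         1.180       1.635        -1 1.14e-06 7.19e-06
#> 5          valine         1.906       2.715        -1 1.25e-06 7.19e-06
#> 6 hydroxybutyrate         1.784       1.366         1 1.48e-06 7.19e-06

## supervised check: IV vs rest by double cross-validated PLS-DA
y  <- factor(ifelse(metabotypeLabels(mt) == "IV", "IV", "rest"))
Xs <- scale(log1p(sweep(coh$truth, 2, apply(coh$truth, 2, median), "/")))
pls <- doubleCV(Xs, y, repeats = 5, seed = 7)
#> accuracy 1.000 [1.000, 1.000], R2 0.93, Q2 0.92, ncomp 1
```

The discovered metabotype IV shows exactly the planted inflammatory
portrait: GlycA up (direction +1), broad amino-acid reduction, ketone
bodies up — all at q far below the 10% FDR threshold — and is perfectly
separable by PLS-DA in this synthetic cohort.

On the shipped patient-level fixture:

```r
clinF <- loadClinicalCSV(clinicalFixturePath())
iv <- clinF[clinF$metabotype == "IV", ]
medianCI(iv$psa)$median
#> [1] 738        # ng/mL, the printed median PSA of that subgroup
```

## File formats

* Spectra: two-column TSV (`ppm`, `intensity`), header optional; files in
  NMR display order (descending ppm) are reversed on read.  A best-effort
  reader for processed Bruker 1D directories (`1r` + `procs`) is
  included.
* Clinical tables: CSV with columns `patient_id, collection_date,
  last_visit_date, psa, gleason_primary, gleason_secondary, stage`
  (optional: `death_date, ancestry, age, metastasis, metabotype,
  diabetes, hypertension, smoker`); dates `YYYY/MM/DD` or ISO; censored
  PSA written as `>5000`.
* Results: CSV tables plus a JSON summary (`runPipeline()` /
  `writeReport()`); a thin command-line wrapper lives at
  `inst/scripts/run_pipeline.R`.

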