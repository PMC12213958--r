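# smeloc

Simulation and source localization of ERP subsequent memory effects in
children's EEG, end to end and at desk scale.

During memory encoding, two ERP components predict whether a child will
later remember the *source* (context) of an item: an early frontal
positivity (P2, 120–250 ms) and a late slow wave (LSW, 1100–1500 ms).
Linking these scalp effects to their cortical generators requires a chain
of machinery — forward head modeling, montage registration, artifact-aware
preprocessing, per-subject component windows, an eLORETA inverse, ROI-level
current-density (CDR) scores, and group statistics with hemisphere-wise
FDR control. Each link is easy to get subtly wrong, and the participant
data such studies rest on are rarely public.

`smeloc` implements that chain as a tested R package and pairs it with a
synthetic multi-subject study generator whose ground truth is fully known,
so the whole pipeline can be validated without any external data: planted
effects must be recovered, null studies must stay null, and the forward and
inverse models must satisfy their analytic properties.

## What's inside

| Stage | Functions |
|---|---|
| Head & forward model | `make_head()`, `make_montage()`, `make_source_space()`, `dipole_potential()`, `compute_leadfield()`, `align_montage()` |
| Synthetic study | `make_roi_masks()`, `make_ground_truth()`, `study_design()`, `simulate_subject()`, `simulate_study()` |
| Preprocessing | `preproc_config()`, `detect_bad_channels()`, `interpolate_channels()`, `preprocess()` |
| Scalp ERP analysis | `collapsed_localizer()`, `locate_p2_window()`, `locate_lsw_window()`, `rebaseline()`, `cluster_means()`, `rm_anova_2x3x3()`, `emm_tukey_posthoc()` |
| Source inverse | `eloreta_weights()`, `make_inverse_operator()`, `apply_inverse_window()`, `cdr_scores()`, `roi_aggregate()` |
| Group inference | `paired_t()`, `bh_fdr()`, `build_stat_report()`, `format_stat_report()` |
| Orchestration | `pipeline_config()`, `run_stage()`, `run_all()` (plus a thin CLI at `inst/scripts/smeloc`) |

The core models, briefly. The head is a set of concentric homogeneous
shells (default brain/CSF/skull/scalp at 0.33/1.79/0.01/0.43 S/m); the
scalp potential of a current dipole is the per-degree Legendre series with
transfer coefficients from interface continuity, average-referenced into a
lead field **K** (μV per nA·m). The inverse is eLORETA — per-source 3×3
weights satisfying *W<sub>j</sub> = (K<sub>j</sub><sup>T</sup> M
K<sub>j</sub>)<sup>1/2</sup>*, *M = (K W<sup>−1</sup> K<sup>T</sup> +
αcH)<sup>+</sup>* — which localizes noiseless point sources exactly. CDR
scores are window-averaged norms of the reconstructed moment vectors;
condition contrasts (source correct − source incorrect) are paired t-tests
per ROI with Benjamini–Hochberg correction per hemisphere × mask family ×
component. Scalp amplitudes are tested with a 2×3×3 within-subject ANOVA
and Tukey-corrected estimated-marginal-mean contrasts.

## A worked example

Simulate a 12-subject study with the default planted effects (standardized
condition effect d = 0.8 in the left medial-temporal masks plus OFG for
P2, and in left EC/parahippocampal masks for LSW), run every stage, and
read the resulting statistics:

```r
library(smeloc)

cfg <- pipeline_config(out_dir = "demo", n_subjects = 12,
                       n_trials_per_condition = 40, master_seed = 11)
run_all(cfg)

tab <- read.table("demo/stats/stat_table.tsv", sep = "\t", header = TRUE)
subset(tab, significant,
       select = c(component, mask, mean_diff, t, df, p, q))
```

```
   component              mask mean_diff     t df         p         q
1         P2  left rostral PhG    0.9012 6.423 11 4.925e-05 7.965e-05
3         P2   left caudal PhG    0.8214 6.505 11 4.395e-05 7.965e-05
5         P2 left lateral PPHC    0.7446 6.052 11 8.290e-05 8.290e-05
9         P2           left EC    0.8512 6.146 11 7.244e-05 8.290e-05
11        P2           left TI    0.7872 6.578 11 3.983e-05 7.965e-05
18        P2               OFG    0.6866 5.872 11 1.074e-04 3.223e-04
19       LSW  left rostral PhG    0.2270 4.070 11 1.852e-03 3.704e-03
27       LSW           left EC    0.2154 4.781 11 5.702e-04 3.421e-03
   (further rows: the remaining planted masks and leakage neighbours)
```

Each row is one ROI × component contrast: `mean_diff` is the average
within-subject CDR difference (correct − incorrect, nA·m), `t`/`df`/`p`
the paired test, and `q` the BH-adjusted value within that ROI's
correction family; `significant` marks q < 0.05. With the default planted
truth, the significant list is dominated by the left-hemisphere planted
masks (plus their immediate neighbours — the expected spatial leakage of a
minimum-norm inverse), and no ROI shows a significant reversed effect.
`demo/erp/anova_P2.tsv` holds the scalp ANOVA — in this run the planted
frontal effect shows up as Condition F(1, 11) = 26.6, p = 3.1e-4 with a
strong Condition × Coronal interaction — and `demo/report/report.md`
summarizes recovery against the planted truth.

The numbers above come from the exact command shown; your output will
match it bit for bit given the same seed.

## Scope

The package validates the *pipeline*, not individual anatomy: heads are
spherical, ROI masks are synthetic patches carrying the study's ROI names
and correction structure, and the generator does not model ocular
physiology or real cortical geometry. See the methods vignette
(`vignettes/smeloc-methods.Rmd`) for the models, parameter defaults, and
the design decisions behind them.
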