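# aecnet

Band-specific resting-state connectomes from region-of-interest (ROI)
source time series, for researchers analysing electrophysiological
(MEG/EEG source-space) recordings: leakage-robust orthogonalized
amplitude-envelope correlation, proportional graph thresholding,
hemisphere-resolved resting-state-network community edge counts, and the
group/symptom statistics layered on top. A synthetic cohort generator
with planted ground truth makes the whole pipeline testable end to end
without access to patient recordings.

## The estimator

Source leakage — the instantaneous mixing of reconstructed sources caused
by the limited spatial resolution of the inverse solution — inflates
naive envelope correlation at zero lag. Before correlating envelopes, the
component of one analytic signal instantaneously in phase with the other
is removed:

    Y_perp_X(t,f) = Im( Y(t,f) X(t,f)* / |X(t,f)| ),     Env_X = |X|

For each ROI pair, the Pearson correlation between `Env(Y_perp_X)` and
`Env(X)` is computed in both orthogonalization directions over 30 s
sliding windows (stride 1/6 window), averaged per window, and reduced by
the median across windows. Thresholding the resulting matrix at the top
15% of connections gives a binary graph whose edges are counted within
and between the 14 hemisphere-resolved canonical networks (FPN, LM, SAL,
DAN, DMN, SMN, VN x L/R); groups are compared per measure with
pooled-variance t tests and symptom associations assessed with Spearman
rank correlations within the patient group.

## Worked example

The `analysis/` directory is a four-stage narrative workflow over the
package API (simulate, connectivity, graph, stats), writing its tables
under `results/`. Run from the repository root:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_connectivity.R
Rscript analysis/03_graph.R
Rscript analysis/04_stats.R
```

Stage 1 simulates a desk-scale cohort (60 ROIs, 120 s at 250 Hz, 8
controls + 8 patients) with envelope coupling planted in the left limbic
(LM) community at high beta, elevated in the patient group, and
depression scores (BDI-II, HAMD-17) that track each patient's planted
coupling. Typical output:

```
simulated 20 subjects (10 HC, 10 BD), 60 ROIs, 120 s @ 250 Hz
planted left-LM high-beta coupling: HC mean 0.060, BD mean 0.413
BD depression scores: BDI-II 36.2 +/- 8.6, HAMD-17 14.3 +/- 3.6
```

Stage 3 confirms proportional thresholding (every subject/band retains
265 edges at 15% density with 60 ROIs) and shows the planted effect in
the raw counts (left-LM intra mean 9.2 in patients vs 2.7 in controls);
stage 4 recovers it statistically:

```
15 of 210 measures significant at 5%, 2 at 1%
strongest group differences (t = HC - BD):
      band           measure         t            p
 high_beta        intra:LM_L -8.746945 6.719953e-08
     alpha  inter:FPN_R:VN_L -4.001316 8.373722e-04
```

Negative `t` means patients have more edges (the tables carry an explicit
`t_patient_minus_control` column); everything below the planted measure is
threshold noise at this cohort size. Within the patient group the planted
count correlates positively with the depression scores
(`results/stats/symptom_correlations.tsv`: rho = 0.52 for BDI-II,
0.45 for HAMD-17).

The same pipeline runs on real data by replacing stage 1: write each
subject's ROI time series with `write_timeseries()` (or the delimited-text
fallback `write_timeseries_tsv()`), supply a partition TSV
(`roi_label  network  hemisphere`) and a score table, and use
`run_config()` / `run_all()`.

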