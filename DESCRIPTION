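Package: netstab
Title: Test-Retest Stability of Resting-State fMRI Metrics in the Triple-Network Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for quantifying the intersession (test-retest) stability of
    voxel-wise resting-state fMRI measures - amplitude of low-frequency
    fluctuations (ALFF), fractional ALFF, regional homogeneity (ReHo,
    Kendall's coefficient of concordance), and degree centrality (DC) - and of
    region-of-interest functional connectivity across the default mode,
    central executive and salience networks. Provides temporal preprocessing
    (nuisance regression, framewise-displacement scrubbing, band-pass
    filtering), voxel-wise metric computation, 15-region network connectivity
    matrices with Fisher r-to-z transformation, Lin's concordance correlation
    coefficient with its accuracy/precision decomposition and asymptotic
    confidence intervals, Spearman internetwork stability with false
    discovery rate control, and a synthetic two-session BOLD generator with
    known ground-truth amplitude, connectivity and session fidelity so the
    whole pipeline can be exercised without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
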