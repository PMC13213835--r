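Package: gagmd
Title: Force-Field Comparison Analytics for Protein-Glycosaminoglycan MD Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for molecular-dynamics simulations of
    protein-glycosaminoglycan complexes. Builds proxy energy landscapes and
    disconnectivity graphs from potential-energy time series
    (Savitzky-Golay smoothing, alternating extrema, barrier trees),
    classifies pyranose ring puckering by Cremer-Pople coordinates and by a
    two-dihedral rule, computes glycosidic torsion series and heatmaps,
    RMSD/RMSF flexibility profiles with B-factor conversion and paired
    force-field comparison statistics (Pearson, Spearman, paired t, exact
    Wilcoxon signed-rank), and reconstructs potentials of mean force from
    umbrella-sampling windows by WHAM with dissociation free-energy
    extraction. Ships seedable synthetic-trajectory generators with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    bio3d,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    signal,
    withr,
    optparse
Config/testthat/edition: 3
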