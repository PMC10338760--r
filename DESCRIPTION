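Package: cavityqa
Title: Resection-Cavity Contour Visibility, Pre-Selection and Margin Expansion on CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality-assurance pipeline for CT-based auto-contouring of
    pediatric posterior-fossa resection cavities. Quantifies contour
    visibility as contrast and contrast-to-noise ratio over a GTV-anchored
    crop with bone exclusion, filters cohorts on visibility, continuity and
    posterior-fossa location, expands GTVs to anatomically constrained CTVs
    via spacing-aware Euclidean distance transforms, and evaluates predicted
    against reference contours with Dice, Hausdorff and mean surface
    distance, precision and recall. Ships a deterministic synthetic CT head
    phantom generator with programmable cavity contrast and noise so the
    full study design (two training arms crossed with two test sets) runs
    end-to-end without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
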