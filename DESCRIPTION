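Package: onhmorph
Title: Optic Nerve Head Rim and Lamina Cribrosa Morphometry from OCT B-Scan Boundaries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes neuroretinal rim and lamina cribrosa indices from segmented
    optic nerve head OCT B-scan boundary curves: horizontal rim width (HRW),
    minimum rim width in a horizontal section (MRW), their ratio (HMR), and the
    lamina cribrosa curvature index (LCCI), with the three-location/three-scan
    per-eye averaging protocol used in enhanced depth imaging studies of the
    optic nerve head. Includes a synthetic cohort generator for normal-tension
    glaucoma, central retinal artery occlusion and healthy fellow eyes; an
    eligibility screening and 1:1 caliper matching stage; and the study-style
    analysis plan (Shapiro-Wilk gated ANOVA or Kruskal-Wallis with Tukey or Dunn
    post-hoc patterns, interobserver ICC, and rim-width regressions).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
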