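Package: lactoburst
Title: Slow-Fast Analysis of Pseudo-Plateau Bursting in a Pituitary Lactotroph Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing pseudo-plateau bursting in a three-variable
    conductance-based pituitary lactotroph model as a canard-induced mixed
    mode oscillation.  Implements the one-fast/two-slow decomposition of the
    model: the critical manifold and its fold curves, the reduced and
    desingularized flows, ordinary and folded singularities with their
    spectral classification, the eigenvalue ratio mu and the rotation bound
    S_max, singular periodic orbits with the funnel-entry distance delta,
    one- and two-parameter scans of the folded saddle-node (type I and II),
    focus-node, fold-merge and delta = 0 boundaries, stiff integration of
    the full system with burst-feature extraction, the complementary
    two-fast/one-slow z-curve analysis, and a synthetic-trace generator for
    validating the feature extractor.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
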