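Package: cardiotwin
Title: Digital-Twin Personalization of Ventricular Tissue Conductivity from
    QRS Duration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building cardiac digital twins of the human ventricles
    and personalizing their tissue properties from the electrocardiogram.
    Builds idealized biventricular tetrahedral meshes with rule-based fibers,
    universal ventricular coordinates and AHA segmentation; maps cell radius
    (R), extracellular volume (ECV) and an extracellular conductivity factor
    (ECF) to monodomain conductivities; simulates ventricular activation with
    a reference monodomain solver using ten Tusscher-Panfilov 2006 membrane
    kinetics and with a calibrated anisotropic eikonal engine; fits R and ECF
    so that the simulated total activation time matches a target QRS duration
    under five-site endocardial pacing; measures septal conduction velocity
    under right-ventricular apical pacing; and generates synthetic paired
    pre/post aortic-valve-replacement cohorts with ground truth plus the
    accompanying nonparametric statistics (exact Wilcoxon signed-rank,
    Mann-Whitney and Spearman tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    data.table,
    igraph,
    jsonlite,
    methods,
    rlang,
    stats,
    tools,
    utils,
    xml2,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
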