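Package: shapemarkers
Title: Surface Shape Embedding and Biomarker Classification for Staging Neurodegeneration
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how cerebrospinal-fluid markers and the shapes of
    subcortical structures separate diagnostic groups along the Alzheimer's
    pathological cascade. Corresponded triangulated surfaces of the hippocampus
    and lateral ventricles are compared with a first-order (initial-momentum)
    approximation of the diffeomorphic metric distance, embedded with ISOMAP,
    and the resulting shape components, structure volumes and CSF markers
    (Abeta42, t-tau, p-tau) are fed to linear support-vector classifiers under a
    balanced-subsampling leave-one-out protocol, including prediction of MCI to
    AD conversion from a classifier trained on the normal and AD groups. A
    synthetic cohort generator with planted group effects makes every stage
    testable without access to restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, e1071, igraph, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'mesh-io.R'
    'mesh-geometry.R'
    'synthetic-cohort.R'
    'shape-metric.R'
    'embedding.R'
    'selection.R'
    'classify.R'
    'conversion.R'
    'defmap.R'
    'pipeline.R'
    'utils.R'
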