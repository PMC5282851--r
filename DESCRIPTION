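Package: ffpeQC
Title: Artifact-Aware Post-Processing of FFPE Amplicon Panel Sequencing
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quality control and post-processing of somatic variant calls
    from targeted amplicon panels applied to formalin-fixed paraffin-embedded
    (FFPE) tumour specimens. Characterises the deamination-driven mutation
    spectrum by allele-frequency bin, relates per-sample artifact burden to
    pre-normalization library concentration, derives concentration-informed
    per-sample allele-frequency reporting cutoffs, filters primer-footprint
    and recurrent-artifact calls, discriminates germline from somatic
    variants, reconstructs complex variants from read-backed phasing with
    protein-level reinterpretation, rescues indels suppressed by strand-bias
    filters near amplicon ends, and estimates gene-level copy number from
    amplicon coverage by bootstrap pseudo-controls. Includes a seeded
    synthetic-cohort generator emulating the statistical structure of FFPE
    panel data so the whole pipeline is testable without protected data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    MASS,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Sequencing, VariantDetection, QualityControl,
    CopyNumberVariation, Coverage
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'transcripts.R'
    'annotate.R'
    'utils.R'
    'io.R'
    'cnv.R'
    'ffpeQC-package.R'
    'panel.R'
    'postprocess.R'
    'qc.R'
    'simulate.R'
    'pipeline.R'
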