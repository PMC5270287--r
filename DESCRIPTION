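Package: pedexome
Title: Family-Based Exome Variant Prioritization with Dominant
    Segregation Filtering and Case-Control Validation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Prioritizes candidate disease variants from annotated
    whole-exome callsets of small pedigrees. Variants are first required
    to co-segregate with affection status under a dominant model
    (affected members heterozygous, unaffected members homozygous
    reference), then passed through a seven-stage annotation cascade
    (coding effect, predicted impact, SIFT/PolyPhen2 deleteriousness,
    PhyloP and PhastCons conservation, global and population-specific
    allele frequency) that splits survivors into common and rare tiers
    with per-stage survivor accounting. Candidate genes are ranked by
    cross-family overlap and annotated for proximity to linkage loci.
    A companion case-control module computes allele/genotype frequency
    tables and odds ratios with Woolf confidence intervals under
    allelic, dominant and recessive models, with Haldane-Anscombe
    zero-cell correction. A synthetic-data generator produces annotated
    multi-family callsets with planted causal variants and
    Hardy-Weinberg case-control cohorts so the full pipeline is
    testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    VariantAnnotation,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
biocViews: VariantAnnotation, Genetics, SNP, Sequencing, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'pedexome-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'filter-config.R'
    'filters.R'
    'segregation.R'
    'io-vcf.R'
    'io-ped.R'
    'io-tables.R'
    'discovery.R'
    'case-control.R'
    'hwe.R'
    'simulate.R'
    'pipeline.R'
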