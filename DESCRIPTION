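Package: tamscape
Title: Spatial Quantification of Tumor-Associated Macrophage Subsets in
    Brain Metastasis Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the spatial landscape of tumor-associated macrophage
    (TAM) subsets - microglia (MG), monocyte-derived macrophages (MDM) and
    border-associated macrophages (BAM) - in labeled tumor segmentation masks
    of brain-metastasis sections. Decomposes lesions into a 7-pixel periphery
    band, interior, intertumoral region and tumor-free area with exact
    Euclidean distance transforms; classifies cells from lineage-reporter
    marker combinations under four mouse-model rules; computes densities per
    0.01 mm2, composition fractions, MG/MDM ratios, proliferation and CD206
    co-expression fractions; implements a rectangular flow-cytometry gating
    hierarchy with FMO-subtracted median intensities; and provides the
    accompanying statistical layer (variance-stabilizing transforms, factorial
    ANOVA with post-hoc linear contrasts, two-stage Benjamini-Krieger-Yekutieli
    FDR, tie-aware Spearman and Mann-Whitney tests). A synthetic-data module
    generates sections, cell tables and flow-event tables with known ground
    truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
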