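Package: kmodule
Title: Co-Expression Network Modules with Distance Correlation and
    k-Module Refinement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds weighted gene co-expression networks from expression
    matrices using distance correlation or absolute Pearson correlation,
    selects a soft-thresholding power by scale-free topology fit, computes
    the topological overlap matrix, and detects modules by average-linkage
    hierarchical clustering with a tree-based dynamic cut.  Provides the
    k-module refinement algorithm, which iteratively reassigns each gene
    to the module to which it has the highest mean connectivity, and a
    k-eigengene comparator that reassigns genes by correlation with module
    eigengenes.  Includes cluster-validity metrics (silhouette, Dunn
    index), module preservation between independent sample splits via
    one-sided Fisher's exact tests computed in log space, and a synthetic
    expression-data generator with planted module structure for offline
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    cluster,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
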