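Package: gliopanel
Title: Discovery of Discriminatory Gene Panels for Diffuse Astrocytic Glioma Subtyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a gene-panel discovery pipeline for
    subtyping diffuse astrocytic gliomas (diffuse astrocytoma, anaplastic
    astrocytoma, glioblastoma) from log2 expression matrices: empirical-Bayes
    batch adjustment, CUR-leverage probe selection, pairwise differential
    expression with fold-change filtering, nonnegative matrix factorization
    consensus clustering, canonical (MANOVA) biplot, and linear discriminant
    validation. Ships a synthetic-cohort generator with known ground truth so
    the whole workflow is exercised end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, mclust
Suggests: testthat (>= 3.0.0), withr, MASS, limma, sva, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
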