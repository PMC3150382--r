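Package: hcsym
Title: Dendrogram Leaf Reordering by Bilateral Symmetric Distance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Seriation of hierarchical clustering dendrograms by node flipping.
    Implements HC-SYM, a leaf-ordering method that greedily pairs the most
    similar objects across the boundary of the left and right subtrees at
    selected internal nodes (minimising their bilateral symmetric distance) so
    that similar objects sit at cluster boundaries, together with supervised
    (seriation rate) and unsupervised (generalized anti-Robinson) evaluation
    of leaf orderings, an HC-PCA baseline that flips nodes against the first
    principal component, deterministic average-linkage clustering, Newick
    import/export, synthetic data generators, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
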