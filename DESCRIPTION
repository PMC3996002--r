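Package: FourRussiansRNA
Title: Four-Russians Accelerated Nussinov RNA Folding
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maximum non-crossing complementary base-pair matching for RNA
    sequences by the Nussinov dynamic program, together with a family of
    Four-Russians accelerated engines: the two-vector method with exhaustive
    difference-vector preprocessing, the Frid-Gusfield interleaved variant,
    partially and completely memoized hybrids, and a q-by-q tiled
    diagonal-wavefront engine with a verifiable tile-independence contract.
    All engines produce cell-identical dynamic-programming tables and
    support traceback to dot-bracket and connect-table (CT) formats, with
    instrumented operation counts for empirical work comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, Biostrings
Suggests: testthat (>= 3.0.0), jsonlite, withr
biocViews: Software, StructuralPrediction, RNA, FoldingAlgorithms
Config/testthat/edition: 3
RoxygenNote: 7.3.3
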