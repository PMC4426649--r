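Package: cliqueGO
Title: Ortholog-Clique-Based Gene Ontology Annotation Transfer
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
        role = c("aut", "cre"))
Description: Transfers Gene Ontology annotations to the genes of a target
        species from 1-to-1 ortholog cliques spanning multiple species.
        Orthologs are called by reciprocal best hits from BLAST tabular
        similarity files, separately for DNA and protein evidence, and
        intersected; the multipartite ortholog graph is mined for cliques
        of size three or more; cliques are validated by a GO-set-overlap
        statistic against a random-clique null; and candidate GO terms are
        scored by a phylogenetically weighted sum over clique members,
        thresholded, and refined against the GO DAG so that only terms at
        least as specific as the existing annotation are accepted. Seeded
        generators produce every input the pipeline consumes, so the whole
        tool is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, igraph, stats, utils
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
biocViews: GO, Annotation, GraphAndNetwork, Software
RoxygenNote: 7.3.3
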