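#' Build the multipartite ortholog graph
#'
#' One node per distinct gene, one undirected unit-weight edge per
#' ortholog pair; idempotent under duplicated pairs. Same-species pairs
#' are a hard error, preserving the multipartite invariant that a clique
#' can hold at most one gene per species.
#'
#' @param pairs data.frame with columns \code{species_a}, \code{gene_a},
#'   \code{species_b}, \code{gene_b} (see [canonicalPairs()]).
#' @return An [OrthologGraph-class].
#' @export
orthologGraph <- function(pairs) {
    need <- c("species_a", "gene_a", "species_b", "gene_b")
    stopifnot(all(need %in% names(pairs)))
    if (nrow(pairs) && any(pairs$species_a == pairs$species_b))
        stop("pair joins two genes of the same species", call. = FALSE)
    genes <- unique(data.frame(
        gene = c(pairs$gene_a, pairs$gene_b),
        species = c(pairs$species_a, pairs$species_b),
        stringsAsFactors = FALSE))
    dup <- genes$gene[duplicated(genes$gene)]
    if (length(dup))
        stop(sprintf("gene %s assigned to two species", dup[1L]),
             call. = FALSE)
    genes <- genes[order(genes$gene), , drop = FALSE]
    a <- pmin(pairs$gene_a, pairs$gene_b)
    b <- pmax(pairs$gene_a, pairs$gene_b)
    edges <- unique(data.frame(gene_a = a, gene_b = b,
                               stringsAsFactors = FALSE))
    edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
    rownames(genes) <- rownames(edges) <- NULL
    new("OrthologGraph", genes = genes, edges = edges)
}

#' @rdname OrthologGraph-accessors
#' @name OrthologGraph-accessors
#' @aliases orthoGenes,OrthologGraph-method orthoEdges,OrthologGraph-method
#' @param x an [OrthologGraph-class].
setMethod("orthoGenes", "OrthologGraph", function(x) x@genes)

#' @rdname OrthologGraph-accessors
setMethod("orthoEdges", "OrthologGraph", function(x) x@edges)

setMethod("show", "OrthologGraph", function(object) {
    cat(sprintf("OrthologGraph: %d genes over %d species, %d edges\n",
                nrow(object@genes), length(unique(object@genes$species)),
                nrow(object@edges)))
})

asIgraph <- function(graph) {
    igraph::graph_from_data_frame(graph@edges, directed = FALSE,
                                  vertices = graph@genes$gene)
}

#' Enumerate ortholog cliques
#'
#' Finds cliques of size at least \code{minSize} (default 3) in the
#' ortholog graph. By default only \emph{maximal} cliques are reported:
#' a non-maximal clique carries no annotation evidence its enclosing
#' clique lacks, and reporting all cliques inflates the output
#' combinatorially. \code{mode = "all"} reports every clique of
#' qualifying size. Output is deterministic: members sorted by species,
#' cliques ordered by size descending, then by the lexicographic gene
#' list.
#'
#' @param graph an [OrthologGraph-class].
#' @param minSize minimum clique size, at least 3.
#' @param mode \code{"maximal"} (default) or \code{"all"}.
#' @return List of cliques; each clique is a named character vector of
#'   gene ids, names being the species. The clique's OCL is its length.
#' @export
enumerateCliques <- function(graph, minSize = 3L,
                             mode = c("maximal", "all")) {
    mode <- match.arg(mode)
    stopifnot(minSize >= 3L)
    if (!nrow(graph@edges)) return(list())
    ig <- asIgraph(graph)
    raw <- if (mode == "maximal")
        igraph::max_cliques(ig, min = minSize)
    else igraph::cliques(ig, min = minSize)
    sp <- setNames(graph@genes$species, graph@genes$gene)
    cl <- lapply(raw, function(v) {
        g <- names(v)
        g <- g[order(sp[g])]
        setNames(g, sp[g])
    })
    key <- vapply(cl, function(x) paste(sort(x), collapse = "|"),
                  character(1))
    cl[order(-lengths(cl), key)]
}

#' Ortholog Clique Level per gene
#'
#' Maps each gene to the size of the largest clique containing it: the
#' number of species, including its own, in which it has pairwise
#' 1-to-1 orthologs. Genes in no clique are absent from the map.
#'
#' @param cliques list of cliques from [enumerateCliques()].
#' @return Named integer vector gene -> OCL.
#' @export
assignOCL <- function(cliques) {
    if (!length(cliques)) return(setNames(integer(0), character(0)))
    gene <- unlist(cliques, use.names = FALSE)
    size <- rep.int(lengths(cliques), lengths(cliques))
    ocl <- tapply(size, gene, max)
    setNames(as.integer(ocl), names(ocl))[order(names(ocl))]
}

#' Cliques as a long-format table
#'
#' One row per clique member: \code{clique_id}, \code{ocl},
#' \code{species}, \code{gene}. The inverse of [cliquesFromTable()].
#'
#' @param cliques list of cliques from [enumerateCliques()].
#' @return data.frame.
#' @export
cliqueTable <- function(cliques) {
    if (!length(cliques))
        return(data.frame(clique_id = integer(0), ocl = integer(0),
                          species = character(0), gene = character(0)))
    data.frame(
        clique_id = rep.int(seq_along(cliques), lengths(cliques)),
        ocl = rep.int(lengths(cliques), lengths(cliques)),
        species = unlist(lapply(cliques, names), use.names = FALSE),
        gene = unlist(cliques, use.names = FALSE),
        stringsAsFactors = FALSE)
}

#' @rdname cliqueTable
#' @param tab data.frame with columns \code{clique_id}, \code{species},
#'   \code{gene}.
#' @export
cliquesFromTable <- function(tab) {
    stopifnot(all(c("clique_id", "species", "gene") %in% names(tab)))
    lapply(split(tab, tab$clique_id),
           function(d) setNames(d$gene, d$species))
}

#' Write a graph in DIMACS edge format
#'
#' ASCII DIMACS as consumed by clique solvers: a \code{p edge N M}
#' header and one \code{e i j} line per edge, 1-based vertex indices.
#' The deterministic gene-to-index table (genes in lexicographic order)
#' is written alongside as \code{<path>.nodes.tsv}.
#'
#' @param graph a nonempty [OrthologGraph-class].
#' @param path output file path.
#' @return Invisibly, the gene-to-index data.frame.
#' @export
writeDimacs <- function(graph, path) {
    if (!nrow(graph@genes))
        stop("refusing to write DIMACS for an empty graph", call. = FALSE)
    idx <- setNames(seq_len(nrow(graph@genes)), graph@genes$gene)
    lines <- c(sprintf("p edge %d %d", nrow(graph@genes),
                       nrow(graph@edges)),
               sprintf("e %d %d", idx[graph@edges$gene_a],
                       idx[graph@edges$gene_b]))
    writeLines(lines, path)
    map <- data.frame(index = unname(idx), gene = names(idx),
                      species = graph@genes$species,
                      stringsAsFactors = FALSE)
    writeTSV(map, paste0(path, ".nodes.tsv"))
    invisible(map)
}
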