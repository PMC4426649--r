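#' @import methods
NULL

#' Gene Ontology DAG
#'
#' Parsed ontology: one row per term in \code{terms} (columns \code{id},
#' \code{name}, \code{namespace}, \code{obsolete}, \code{replaced_by}),
#' a named list \code{parents} mapping each term id to its parent ids
#' (\code{is_a} and \code{part_of} collapsed, see [readOBO()]), and one
#' root id per namespace in \code{roots}.
#'
#' Obsolete terms are retained, flagged and parentless, so that legacy
#' annotations referencing them can be detected rather than silently
#' dropped. Validity enforces GO id syntax, acyclicity over the
#' non-obsolete subgraph, namespace closure under parent links and
#' reachability of the namespace root from every live term.
#'
#' @slot terms data.frame of term records.
#' @slot parents named list, term id to character vector of parent ids.
#' @slot roots named character vector, namespace to root term id.
#' @seealso [readOBO()], [goAncestors()], [goDepth()]
#' @exportClass OntologyDAG
setClass("OntologyDAG",
    representation(terms = "data.frame", parents = "list",
                   roots = "character"))

validOntologyDAG <- function(object) {
    t <- object@terms
    msgs <- character(0)
    need <- c("id", "name", "namespace", "obsolete", "replaced_by")
    if (!all(need %in% names(t)))
        return(sprintf("terms must have columns %s",
                       paste(need, collapse = ", ")))
    if (anyDuplicated(t$id))
        msgs <- c(msgs, "duplicated term ids")
    bad <- t$id[!isGOId(t$id)]
    if (length(bad))
        msgs <- c(msgs, sprintf("malformed GO id: %s", bad[1L]))
    okns <- c("biological_process", "cellular_component",
              "molecular_function")
    if (!all(t$namespace %in% okns))
        msgs <- c(msgs, "unknown namespace")
    if (!setequal(names(object@parents), t$id))
        msgs <- c(msgs, "parents list must be keyed by every term id")
    ns <- setNames(t$namespace, t$id)
    obs <- setNames(t$obsolete, t$id)
    for (id in t$id) {
        p <- object@parents[[id]]
        if (id %in% p) {
            msgs <- c(msgs, sprintf("self-loop at %s", id)); break
        }
        if (obs[[id]] && length(p)) {
            msgs <- c(msgs, sprintf("obsolete term %s has parents", id))
            break
        }
        if (!all(p %in% t$id)) {
            msgs <- c(msgs, sprintf("dangling parent of %s", id)); break
        }
        if (length(p) && !all(ns[p] == ns[[id]])) {
            msgs <- c(msgs,
                      sprintf("parent of %s crosses namespaces", id))
            break
        }
    }
    if (!length(msgs)) {
        cyc <- findCycleMember(object@parents[!obs[names(object@parents)]])
        if (!is.na(cyc))
            msgs <- c(msgs, sprintf("cycle through %s", cyc))
    }
    if (!length(msgs)) {
        for (id in t$id[!t$obsolete]) {
            r <- object@roots[[ns[[id]]]]
            if (id != r && !(r %in% reachableAncestors(object@parents, id))) {
                msgs <- c(msgs,
                          sprintf("%s does not reach its namespace root", id))
                break
            }
        }
    }
    if (length(msgs)) msgs else TRUE
}
setValidity("OntologyDAG", validOntologyDAG)

## DFS cycle detection over a parent-link list; returns one member of a
## cycle, or NA if the graph is acyclic.
findCycleMember <- function(parents) {
    state <- new.env(parent = emptyenv())  # 1 = in stack, 2 = done
    visit <- function(id) {
        s <- state[[id]]
        if (!is.null(s)) return(if (s == 1L) id else NA_character_)
        state[[id]] <- 1L
        for (p in parents[[id]]) {
            if (!is.null(parents[[p]])) {
                hit <- visit(p)
                if (!is.na(hit)) return(hit)
            }
        }
        state[[id]] <- 2L
        NA_character_
    }
    for (id in names(parents)) {
        hit <- visit(id)
        if (!is.na(hit)) return(hit)
    }
    NA_character_
}

## Proper ancestors by breadth-first traversal of parent links.
reachableAncestors <- function(parents, id) {
    seen <- character(0)
    frontier <- parents[[id]]
    while (length(frontier)) {
        frontier <- setdiff(unique(frontier), seen)
        if (!length(frontier)) break
        seen <- c(seen, frontier)
        frontier <- unique(unlist(parents[frontier], use.names = FALSE))
    }
    seen
}

#' Multipartite ortholog graph
#'
#' Genes are nodes labelled with their species; each undirected edge is a
#' 1-to-1 ortholog pair. All edges carry weight 1. Validity enforces the
#' multipartite structure: no edge joins two genes of one species, no
#' self-loops, no duplicate edges, and every edge endpoint is a known
#' gene.
#'
#' @slot genes data.frame with columns \code{gene}, \code{species}.
#' @slot edges data.frame with columns \code{gene_a}, \code{gene_b},
#'   stored with \code{gene_a < gene_b} so symmetry is structural.
#' @seealso [orthologGraph()], [enumerateCliques()]
#' @exportClass OrthologGraph
setClass("OrthologGraph",
    representation(genes = "data.frame", edges = "data.frame"))

setValidity("OrthologGraph", function(object) {
    g <- object@genes; e <- object@edges
    if (!all(c("gene", "species") %in% names(g)))
        return("genes needs columns gene, species")
    if (!all(c("gene_a", "gene_b") %in% names(e)))
        return("edges needs columns gene_a, gene_b")
    if (anyDuplicated(g$gene)) return("duplicated gene node")
    if (nrow(e)) {
        if (any(e$gene_a == e$gene_b)) return("self-loop edge")
        if (any(e$gene_a > e$gene_b))
            return("edges must be stored with gene_a < gene_b")
        if (anyDuplicated(paste(e$gene_a, e$gene_b))) return("duplicate edge")
        sp <- setNames(g$species, g$gene)
        if (!all(e$gene_a %in% g$gene) || !all(e$gene_b %in% g$gene))
            return("edge endpoint not a known gene")
        if (any(sp[e$gene_a] == sp[e$gene_b]))
            return("edge joins two genes of the same species")
    }
    TRUE
})

#' Direct gene-to-GO annotation map
#'
#' Per-species map from gene id to its set of directly assigned GO term
#' ids (no ancestor propagation). Genes absent from the map are treated
#' as unannotated. Stored as a nested list: species, then gene, then a
#' character vector of GO ids.
#'
#' @slot annotations named list: species -> named list(gene -> character
#'   vector of GO ids).
#' @seealso [readAnnotations()], [termSet()], [goSetOverlap()]
#' @exportClass AnnotationMap
setClass("AnnotationMap", representation(annotations = "list"))

setValidity("AnnotationMap", function(object) {
    a <- object@annotations
    if (length(a) && is.null(names(a))) return("species must be named")
    for (sp in names(a)) {
        if (length(a[[sp]]) && is.null(names(a[[sp]])))
            return(sprintf("genes of %s must be named", sp))
        ids <- unlist(a[[sp]], use.names = FALSE)
        if (length(ids) && !all(isGOId(ids)))
            return(sprintf("malformed GO id under species %s", sp))
    }
    TRUE
})
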