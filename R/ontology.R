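#' Accessors for OntologyDAG
#'
#' \code{goTerms} returns the term table; \code{goRoots} the named vector
#' of namespace roots; \code{goParents} the direct parent ids of a term;
#' \code{goNamespace} and \code{isObsolete} per-term lookups.
#'
#' @param x an [OntologyDAG-class].
#' @param id a GO term id.
#' @param ... unused.
#' @return See details per accessor.
#' @name OntologyDAG-accessors
NULL

checkTermId <- function(x, id, allowObsolete = TRUE) {
    stopifnot(is.character(id), length(id) == 1L)
    hit <- match(id, x@terms$id)
    if (is.na(hit))
        stop(sprintf("unknown GO term id: %s", id), call. = FALSE)
    if (!allowObsolete && x@terms$obsolete[hit])
        stop(sprintf("GO term %s is obsolete", id), call. = FALSE)
    hit
}

#' @rdname OntologyDAG-accessors
#' @aliases goTerms,OntologyDAG-method
setMethod("goTerms", "OntologyDAG", function(x, ...) x@terms)

#' @rdname OntologyDAG-accessors
setMethod("goRoots", "OntologyDAG", function(x) x@roots)

#' @rdname OntologyDAG-accessors
setMethod("goParents", "OntologyDAG", function(x, id) {
    checkTermId(x, id)
    x@parents[[id]]
})

#' @rdname OntologyDAG-accessors
setMethod("goNamespace", "OntologyDAG", function(x, id) {
    x@terms$namespace[checkTermId(x, id)]
})

#' @rdname OntologyDAG-accessors
setMethod("isObsolete", "OntologyDAG", function(x, id) {
    x@terms$obsolete[checkTermId(x, id)]
})

setMethod("show", "OntologyDAG", function(object) {
    t <- object@terms
    cat(sprintf("OntologyDAG with %d terms (%d obsolete)\n",
                nrow(t), sum(t$obsolete)))
    for (ns in names(object@roots))
        cat(sprintf("  %s: root %s, %d terms\n", ns, object@roots[[ns]],
                    sum(t$namespace == ns & !t$obsolete)))
})

#' Proper ancestors of a GO term
#'
#' All terms reachable from \code{id} by following \code{is_a}/
#' \code{part_of} parent links, excluding \code{id} itself. The
#' namespace root returns the empty set. Errors on unknown or obsolete
#' ids (obsolete terms have no position in the live hierarchy).
#'
#' @param x an [OntologyDAG-class].
#' @param id a non-obsolete GO term id.
#' @return Character vector of ancestor term ids (possibly empty).
#' @examples
#' dag <- simulateOntology(depth = 2, branching = 2, seed = 1)
#' root <- goRoots(dag)[["biological_process"]]
#' goAncestors(dag, root)   # character(0)
#' @name goAncestors
#' @aliases goAncestors,OntologyDAG-method
#' @export goAncestors
setMethod("goAncestors", "OntologyDAG", function(x, id) {
    checkTermId(x, id, allowObsolete = FALSE)
    sort(reachableAncestors(x@parents, id))
})

#' Shortest path length from a GO term to its namespace root
#'
#' Number of edges on the shortest parent-path from \code{id} to the
#' root of its namespace; 0 for a root. Used for reporting the
#' specificity of accepted annotations; acceptance itself uses the
#' ancestor relation, not numeric depth.
#'
#' @inheritParams goAncestors
#' @return Non-negative integer.
#' @name goDepth
#' @aliases goDepth,OntologyDAG-method
#' @export goDepth
setMethod("goDepth", "OntologyDAG", function(x, id) {
    checkTermId(x, id, allowObsolete = FALSE)
    root <- x@roots[[x@terms$namespace[match(id, x@terms$id)]]]
    if (id == root) return(0L)
    depth <- 0L
    frontier <- id
    seen <- character(0)
    while (length(frontier)) {
        depth <- depth + 1L
        frontier <- setdiff(
            unique(unlist(x@parents[frontier], use.names = FALSE)), seen)
        if (root %in% frontier) return(depth)
        seen <- c(seen, frontier)
    }
    stop(sprintf("%s does not reach its namespace root", id), call. = FALSE)
})
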