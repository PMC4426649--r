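#' Read an OBO 1.2 ontology (go-basic dialect)
#'
#' Parses \code{[Term]} stanzas into an [OntologyDAG-class]. Both
#' \code{is_a} and \code{relationship: part_of} populate parent links;
#' go-basic releases guarantee acyclicity over the two, and the two are
#' not distinguished downstream. \code{is_obsolete: true} flags a term
#' obsolete (such terms keep no parents); \code{replaced_by} is recorded
#' so legacy annotations can be resolved on request. Roots are the
#' parentless non-obsolete term of each namespace.
#'
#' @param path path to an OBO 1.2 file, or a character vector of lines.
#' @return An [OntologyDAG-class].
#' @examples
#' obo <- c("format-version: 1.2", "",
#'   "[Term]", "id: GO:0008150", "name: biological_process",
#'   "namespace: biological_process", "",
#'   "[Term]", "id: GO:0009987", "name: cellular process",
#'   "namespace: biological_process", "is_a: GO:0008150 ! bp")
#' dag <- readOBO(obo)
#' goAncestors(dag, "GO:0009987")
#' @export
readOBO <- function(path) {
    lines <- if (length(path) == 1L && file.exists(path))
        readLines(path, warn = FALSE) else path
    starts <- grep("^\\[", lines)
    isTerm <- lines[starts] == "[Term]"
    ends <- c(starts[-1L] - 1L, length(lines))

    recs <- vector("list", sum(isTerm))
    k <- 0L
    for (i in seq_along(starts)) {
        if (!isTerm[i]) next
        body <- lines[seq(starts[i] + 1L, ends[i])]
        body <- body[nzchar(body) & !startsWith(body, "!")]
        key <- sub(":.*$", "", body)
        val <- sub("^[a-z_]+: *", "", body)
        val <- sub(" *!.*$", "", val)   # trailing comments
        id <- val[key == "id"][1L]
        if (is.na(id)) stop("[Term] stanza without id", call. = FALSE)
        ns <- val[key == "namespace"][1L]
        if (is.na(ns))
            stop(sprintf("term %s has no namespace", id), call. = FALSE)
        obsolete <- any(key == "is_obsolete" & val == "true")
        parents <- val[key == "is_a"]
        rel <- val[key == "relationship"]
        partof <- sub("^part_of +", "", rel[startsWith(rel, "part_of")])
        parents <- unique(c(parents, partof))
        k <- k + 1L
        recs[[k]] <- list(
            id = id,
            name = val[key == "name"][1L],
            namespace = ns,
            obsolete = obsolete,
            replaced_by = if (obsolete) val[key == "replaced_by"][1L]
                          else NA_character_,
            parents = if (obsolete) character(0) else parents)
    }
    recs <- recs[seq_len(k)]
    if (!k) stop("no [Term] stanzas found", call. = FALSE)

    terms <- data.frame(
        id = vapply(recs, `[[`, "", "id"),
        name = vapply(recs, `[[`, "", "name"),
        namespace = vapply(recs, `[[`, "", "namespace"),
        obsolete = vapply(recs, `[[`, FALSE, "obsolete"),
        replaced_by = vapply(recs, `[[`, "", "replaced_by"),
        stringsAsFactors = FALSE)
    parents <- setNames(lapply(recs, `[[`, "parents"), terms$id)

    dangling <- setdiff(unlist(parents, use.names = FALSE), terms$id)
    if (length(dangling))
        stop(sprintf("dangling parent id: %s", dangling[1L]), call. = FALSE)
    cyc <- findCycleMember(parents[!terms$obsolete])
    if (!is.na(cyc))
        stop(sprintf("cyclic is_a structure through %s", cyc),
             call. = FALSE)

    live <- terms[!terms$obsolete, ]
    nsplit <- split(live$id, live$namespace)
    roots <- vapply(nsplit, function(ids) {
        r <- ids[lengths(parents[ids]) == 0L]
        if (length(r) != 1L)
            stop(sprintf("expected one root per namespace, found %d",
                         length(r)), call. = FALSE)
        r
    }, character(1))

    new("OntologyDAG", terms = terms, parents = parents, roots = roots)
}

#' Serialize an OntologyDAG to OBO 1.2 text
#'
#' Emits deterministic go-basic style OBO that [readOBO()] round-trips:
#' terms sorted by id, parents sorted, obsolete terms flagged with their
#' replacement.
#'
#' @param dag an [OntologyDAG-class].
#' @param path optional file path; when omitted the lines are returned.
#' @return Invisibly (or visibly when \code{path} is missing) the OBO
#'   lines.
#' @export
writeOBO <- function(dag, path = NULL) {
    t <- dag@terms[order(dag@terms$id), ]
    out <- c("format-version: 1.2",
             "ontology: go  ! synthetic/derived, emitted by cliqueGO")
    for (i in seq_len(nrow(t))) {
        id <- t$id[i]
        out <- c(out, "", "[Term]",
                 paste0("id: ", id),
                 paste0("name: ", t$name[i]),
                 paste0("namespace: ", t$namespace[i]))
        for (p in sort(dag@parents[[id]]))
            out <- c(out, paste0("is_a: ", p))
        if (t$obsolete[i]) {
            out <- c(out, "is_obsolete: true")
            if (!is.na(t$replaced_by[i]))
                out <- c(out, paste0("replaced_by: ", t$replaced_by[i]))
        }
    }
    if (is.null(path)) return(out)
    writeLines(out, path)
    invisible(out)
}
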