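#' Construct an AnnotationMap
#'
#' @param x nested list species -> list(gene -> character vector of GO
#'   ids), or a data.frame with columns \code{species}, \code{gene},
#'   \code{go_id}. Duplicate (gene, term) rows collapse to one.
#' @return An [AnnotationMap-class].
#' @export
annotationMap <- function(x = list()) {
    if (is.data.frame(x)) {
        stopifnot(all(c("species", "gene", "go_id") %in% names(x)))
        bad <- which(!isGOId(x$go_id))
        if (length(bad))
            stop(sprintf("malformed GO id '%s' (row %d)",
                         x$go_id[bad[1L]], bad[1L]), call. = FALSE)
        x <- lapply(split(x, x$species), function(d)
            lapply(split(d$go_id, d$gene), function(v) sort(unique(v))))
    }
    new("AnnotationMap", annotations = x)
}

#' Direct GO term set of one gene
#'
#' Genes (or species) absent from the map have the empty set; no
#' ancestor propagation is applied.
#'
#' @param x an [AnnotationMap-class].
#' @param species species id.
#' @param gene gene id.
#' @return Character vector of GO ids, possibly empty.
#' @name termSet
#' @aliases termSet,AnnotationMap-method
#' @export termSet
setMethod("termSet", "AnnotationMap", function(x, species, gene) {
    s <- x@annotations[[species]]
    if (is.null(s)) return(character(0))
    v <- s[[gene]]
    if (is.null(v)) character(0) else v
})

#' @rdname AnnotationMap-accessors
#' @name AnnotationMap-accessors
#' @aliases annSpecies,AnnotationMap-method
#' @param x an [AnnotationMap-class].
#' @return \code{annSpecies}: character vector of species ids.
setMethod("annSpecies", "AnnotationMap", function(x) names(x@annotations))

setMethod("show", "AnnotationMap", function(object) {
    a <- object@annotations
    cat(sprintf("AnnotationMap: %d species, %d annotated genes, %d assignments\n",
                length(a), sum(lengths(a)),
                sum(vapply(a, function(s) sum(lengths(s)), 0))))
})

#' Read gene-to-GO annotations (TSV or GAF 2.x)
#'
#' TSV dialect: either three columns (species, gene, GO id) or two
#' columns (gene, GO id) with the species given explicitly; no header
#' required, comment lines starting with \code{#} skipped. GAF dialect:
#' standard 17-column Gene Association File, \code{!} comment lines
#' skipped, column 2 the object id and column 5 the GO id.
#'
#' @param path file path.
#' @param dialect \code{"tsv"} or \code{"gaf"}.
#' @param species species id; required for GAF and 2-column TSV.
#' @return An [AnnotationMap-class] (single species for GAF/2-column).
#' @export
readAnnotations <- function(path, dialect = c("tsv", "gaf"),
                            species = NULL) {
    dialect <- match.arg(dialect)
    lines <- readLines(path, warn = FALSE)
    if (dialect == "gaf") {
        lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
        if (is.null(species))
            stop("GAF input needs an explicit species id", call. = FALSE)
        parts <- strsplit(lines, "\t", fixed = TRUE)
        gene <- vapply(parts, `[`, "", 2L)
        go <- vapply(parts, `[`, "", 5L)
        bad <- which(!isGOId(go))
        if (length(bad))
            stop(sprintf("%s line %d: malformed GO id '%s'", path,
                         bad[1L], go[bad[1L]]), call. = FALSE)
        df <- data.frame(species = species, gene = gene, go_id = go,
                         stringsAsFactors = FALSE)
        return(annotationMap(df))
    }
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- unique(lengths(parts))
    if (length(parts) && length(nf) != 1L)
        stop(sprintf("%s: ragged TSV", path), call. = FALSE)
    if (!length(parts)) return(annotationMap())
    if (nf == 2L) {
        if (is.null(species))
            stop("2-column annotation TSV needs an explicit species id",
                 call. = FALSE)
        df <- data.frame(species = species,
                         gene = vapply(parts, `[`, "", 1L),
                         go_id = vapply(parts, `[`, "", 2L),
                         stringsAsFactors = FALSE)
    } else if (nf == 3L) {
        df <- data.frame(species = vapply(parts, `[`, "", 1L),
                         gene = vapply(parts, `[`, "", 2L),
                         go_id = vapply(parts, `[`, "", 3L),
                         stringsAsFactors = FALSE)
        ## tolerate a header row
        if (nrow(df) && df$go_id[1L] %in% c("go_id", "go", "GO"))
            df <- df[-1L, , drop = FALSE]
    } else stop(sprintf("%s: expected 2 or 3 columns", path),
                call. = FALSE)
    bad <- which(!isGOId(df$go_id))
    if (length(bad))
        stop(sprintf("%s line %d: malformed GO id '%s'", path, bad[1L],
                     df$go_id[bad[1L]]), call. = FALSE)
    annotationMap(df)
}

#' Merge annotation maps
#'
#' Union of per-gene term sets across maps (set semantics).
#'
#' @param ... [AnnotationMap-class] objects.
#' @return A single merged [AnnotationMap-class].
#' @export
mergeAnnotations <- function(...) {
    maps <- list(...)
    out <- list()
    for (m in maps) {
        for (sp in annSpecies(m)) {
            cur <- out[[sp]]
            add <- m@annotations[[sp]]
            if (is.null(cur)) { out[[sp]] <- add; next }
            for (g in names(add))
                cur[[g]] <- sort(unique(c(cur[[g]], add[[g]])))
            out[[sp]] <- cur
        }
    }
    annotationMap(out)
}

#' Flatten an AnnotationMap to a table
#'
#' @param ann an [AnnotationMap-class].
#' @return data.frame \code{species}, \code{gene}, \code{go_id}.
#' @export
annotationTable <- function(ann) {
    a <- ann@annotations
    rows <- lapply(names(a), function(sp) {
        g <- a[[sp]]
        if (!length(g))
            return(data.frame(species = character(0),
                              gene = character(0),
                              go_id = character(0)))
        data.frame(species = sp,
                   gene = rep.int(names(g), lengths(g)),
                   go_id = unlist(g, use.names = FALSE),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(species = character(0), gene = character(0),
                          go_id = character(0))
    out <- out[order(out$species, out$gene, out$go_id), , drop = FALSE]
    rownames(out) <- NULL
    out
}
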