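#' GO set overlap of a clique
#'
#' The fraction of the smallest member's direct GO term set that is
#' shared by every member, as a percentage:
#' \deqn{|S_1 \cap \dots \cap S_k| / \min_i |S_i| \times 100}
#' where \eqn{S_i} is the set of GO terms directly annotated to clique
#' member \eqn{i}. If any member is unannotated the minimum is zero and
#' the overlap is defined as 0: an unannotated member contributes no
#' supporting evidence, which matches the random-clique null being
#' dominated by zeros.
#'
#' @param clique named character vector (species -> gene), nonempty.
#' @param ann an [AnnotationMap-class].
#' @return Numeric percentage in [0, 100].
#' @examples
#' ann <- annotationMap(data.frame(
#'   species = rep(c("ath", "osa", "sbi"), c(2, 2, 3)),
#'   gene = rep(c("AT2G02170", "OS02G0116800", "SB04G001240"), c(2, 2, 3)),
#'   go_id = c("GO:0005886", "GO:0008150", "GO:0005886", "GO:0008150",
#'             "GO:0005886", "GO:0008150", "GO:0003677")))
#' clique <- c(ath = "AT2G02170", osa = "OS02G0116800", sbi = "SB04G001240")
#' goSetOverlap(clique, ann)  # 100
#' @export
goSetOverlap <- function(clique, ann) {
    stopifnot(length(clique) >= 1L, !is.null(names(clique)))
    sets <- mapply(function(sp, g) termSet(ann, sp, g),
                   names(clique), clique, SIMPLIFY = FALSE)
    sizes <- lengths(sets)
    if (any(sizes == 0L)) return(0)
    common <- Reduce(intersect, sets)
    length(common) / min(sizes) * 100
}

#' Overlap results for a list of cliques
#'
#' @param cliques list of cliques (named species -> gene vectors).
#' @param ann an [AnnotationMap-class].
#' @return data.frame \code{clique_id}, \code{ocl}, \code{overlap_pct}.
#' @export
overlapResults <- function(cliques, ann) {
    data.frame(
        clique_id = seq_along(cliques),
        ocl = as.integer(lengths(cliques)),
        overlap_pct = vapply(cliques, goSetOverlap, numeric(1),
                             ann = ann),
        stringsAsFactors = FALSE)
}

#' Random pseudo-cliques for the overlap null
#'
#' For each requested size k, draws the given number of pseudo-cliques:
#' a uniformly random subset of k distinct species, then one gene per
#' chosen species sampled uniformly from that species' full pool. Fully
#' reproducible under \code{seed}; the caller's RNG stream is left
#' untouched.
#'
#' @param speciesPools named list species -> character vector of genes.
#' @param sizeCounts named integer vector, clique size -> number of
#'   pseudo-cliques to draw.
#' @param seed integer seed.
#' @return List of pseudo-cliques (named species -> gene vectors).
#' @export
randomCliques <- function(speciesPools, sizeCounts, seed) {
    sizes <- as.integer(names(sizeCounts))
    stopifnot(!anyNA(sizes), all(sizeCounts >= 0))
    nonempty <- names(speciesPools)[lengths(speciesPools) > 0L]
    if (length(sizes) && max(sizes) > length(nonempty))
        stop(sprintf(
            "requested clique size %d exceeds the %d species with genes",
            max(sizes), length(nonempty)), call. = FALSE)
    withSeed(seed, {
        out <- list()
        for (j in seq_along(sizes)) {
            k <- sizes[j]
            for (i in seq_len(sizeCounts[j])) {
                sp <- sort(sample(nonempty, k))
                genes <- vapply(sp, function(s) {
                    pool <- speciesPools[[s]]
                    pool[sample.int(length(pool), 1L)]
                }, character(1))
                out[[length(out) + 1L]] <- genes
            }
        }
        out
    })
}

#' Histogram of overlap percentages per OCL
#'
#' Counts overlap values into bins given by \code{breaks}, one row per
#' clique size. Bins are right-closed (\code{(a, b]}) with the first
#' bin closed on both sides, so the partition of [0, 100] is exact and
#' non-overlapping by construction; unsorted or duplicated break points
#' are rejected.
#'
#' @param results data.frame from [overlapResults()].
#' @param breaks increasing numeric vector starting at 0 and ending at
#'   100; default ten bins of width 10.
#' @return Contingency table, rows = OCL, columns = bins.
#' @export
overlapHistogram <- function(results, breaks = seq(0, 100, by = 10)) {
    if (is.unsorted(breaks, strictly = TRUE))
        stop("breaks must be strictly increasing (overlapping bins)",
             call. = FALSE)
    if (breaks[1L] != 0 || breaks[length(breaks)] != 100)
        stop("breaks must span [0, 100]", call. = FALSE)
    ocl <- factor(results$ocl, levels = sort(unique(results$ocl)))
    bin <- cut(results$overlap_pct, breaks = breaks,
               include.lowest = TRUE, right = TRUE)
    table(ocl = ocl, bin = bin)
}
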