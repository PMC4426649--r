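#' Species phylogenetic group configuration
#'
#' Each species carries an integer group score encoding phylogenetic
#' proximity to the target species (1 = the target's own group, larger =
#' more distant); a clique member annotated with a term contributes the
#' reciprocal of its group score to that term's evidence. The target
#' species must be listed with group score 1.
#'
#' @param species character vector of species ids.
#' @param groupScore integer vector of scores >= 1, same length.
#' @param target the target species id.
#' @return data.frame \code{species}, \code{group_score}, \code{target}.
#' @export
speciesGroups <- function(species, groupScore, target) {
    stopifnot(length(species) == length(groupScore),
              !anyDuplicated(species), all(groupScore >= 1),
              target %in% species)
    if (groupScore[match(target, species)] != 1)
        stop("target species must have group score 1", call. = FALSE)
    data.frame(species = species,
               group_score = as.numeric(groupScore),
               target = species == target, stringsAsFactors = FALSE)
}

#' Default group scores for the ten plant species
#'
#' The bread-wheat study configuration: Triticum aestivum (target) and
#' T. urartu score 1; Aegilops tauschii and Hordeum vulgare 2;
#' Brachypodium distachyon 3; Oryza sativa 4; Sorghum bicolor and Zea
#' mays 5; Arabidopsis thaliana and Brassica rapa 6. Under it the
#' maximum attainable GO score for a size-10 clique is
#' 1 + 1 + 1/2 + 1/2 + 1/3 + 1/4 + 1/5 + 1/5 + 1/6 + 1/6 = 4.3166667.
#'
#' @return data.frame as from [speciesGroups()].
#' @examples
#' sum(1 / defaultPlantGroups()$group_score)  # 4.3166667
#' @export
defaultPlantGroups <- function() {
    speciesGroups(
        species = c("Triticum_aestivum", "Triticum_urartu",
                    "Aegilops_tauschii", "Hordeum_vulgare",
                    "Brachypodium_distachyon", "Oryza_sativa",
                    "Sorghum_bicolor", "Zea_mays",
                    "Arabidopsis_thaliana", "Brassica_rapa"),
        groupScore = c(1, 1, 2, 2, 3, 4, 5, 5, 6, 6),
        target = "Triticum_aestivum")
}

#' Read a species-group configuration file
#'
#' TSV with columns \code{species}, \code{group_score}, \code{target}
#' (logical or 0/1); exactly one target row.
#'
#' @param path file path.
#' @return data.frame as from [speciesGroups()].
#' @export
readSpeciesGroups <- function(path) {
    df <- readTSV(path)
    stopifnot(all(c("species", "group_score", "target") %in% names(df)))
    tgt <- df$species[as.logical(df$target)]
    if (length(tgt) != 1L)
        stop("species-group config needs exactly one target species",
             call. = FALSE)
    speciesGroups(df$species, df$group_score, tgt)
}

groupLookup <- function(groups, speciesNeeded) {
    missing <- setdiff(speciesNeeded, groups$species)
    if (length(missing))
        stop(sprintf("species missing from group config: %s",
                     paste(missing, collapse = ", ")), call. = FALSE)
    setNames(groups$group_score, groups$species)
}

#' Phylogenetically weighted GO score of a term on a clique
#'
#' \deqn{GO\_score(go, c) = \sum_{i \in c} \delta(go, i) / G_{score}(i)}
#' where \eqn{\delta(go, i)} is 1 iff species \eqn{i}'s clique gene
#' carries \code{go} among its direct annotations, else 0, and
#' \eqn{G_{score}(i)} is the species' phylogenetic group score. The
#' score is bounded by \eqn{\sum_{i \in c} 1 / G_{score}(i)}.
#'
#' @param go a GO term id.
#' @param clique named character vector (species -> gene).
#' @param ann an [AnnotationMap-class] of direct annotations.
#' @param groups group configuration from [speciesGroups()].
#' @return Numeric score.
#' @examples
#' groups <- defaultPlantGroups()
#' clique <- setNames(paste0(groups$species, "_G1"), groups$species)
#' ann <- annotationMap(data.frame(species = groups$species,
#'   gene = clique, go_id = "GO:0005886"))
#' goScore("GO:0005886", clique, ann, groups)  # 4.3166667
#' @export
goScore <- function(go, clique, ann, groups) {
    g <- groupLookup(groups, names(clique))
    carried <- mapply(function(sp, gene) go %in% termSet(ann, sp, gene),
                      names(clique), clique)
    sum(1 / g[names(clique)][carried])
}

#' Candidate GO terms for the target gene of a clique
#'
#' Step 1 of the enrichment procedure: the union of GO ids carried by
#' any clique member is proposed for the clique's target-species gene.
#' Terms already on the target gene are labelled \code{original} (they
#' are retained, not re-proposed); the rest are \code{candidate}.
#' Cliques without a target-species gene yield nothing.
#'
#' @inheritParams goScore
#' @param cliqueId identifier recorded in the output.
#' @return data.frame \code{gene}, \code{go_id}, \code{clique_id},
#'   \code{status}.
#' @export
candidateTerms <- function(clique, ann, groups, cliqueId = NA_integer_) {
    target <- groups$species[groups$target]
    empty <- data.frame(gene = character(0), go_id = character(0),
                        clique_id = integer(0), status = character(0),
                        stringsAsFactors = FALSE)
    if (!target %in% names(clique)) return(empty)
    tgtGene <- clique[[target]]
    original <- termSet(ann, target, tgtGene)
    all <- sort(unique(unlist(
        mapply(function(sp, g) termSet(ann, sp, g), names(clique),
               clique, SIMPLIFY = FALSE), use.names = FALSE)))
    if (!length(all)) return(empty)
    data.frame(gene = tgtGene, go_id = all, clique_id = cliqueId,
               status = ifelse(all %in% original, "original",
                               "candidate"),
               stringsAsFactors = FALSE)
}

#' Apply the GO-score threshold
#'
#' Candidates at or above the threshold (default \eqn{G_T = 0.5},
#' inclusive) keep status \code{candidate}; the rest become
#' \code{rejected-below-threshold}. Original terms always pass. The
#' 0.5 default makes a single annotation in a group-2 species (one of
#' the target's close relatives) sufficient evidence on its own, which
#' is why the comparison is inclusive by default; \code{strict = TRUE}
#' switches to a strict \code{>}.
#'
#' @param scored data.frame with columns \code{status},
#'   \code{go_score}.
#' @param threshold minimum score, default 0.5.
#' @param strict logical; strict rather than inclusive comparison.
#' @return The data.frame with statuses updated.
#' @export
thresholdFilter <- function(scored, threshold = 0.5, strict = FALSE) {
    stopifnot(threshold > 0)
    if (!nrow(scored)) return(scored)
    pass <- if (strict) scored$go_score > threshold
            else scored$go_score >= threshold
    drop <- scored$status == "candidate" & !pass
    scored$status[drop] <- "rejected-below-threshold"
    scored
}

#' Refine candidate terms against the GO DAG
#'
#' Step 3: a candidate adds information only if it is at least as
#' specific as the existing annotation, i.e. sits deeper in the DAG or
#' on a different path. Concretely a candidate \code{t} is
#' \code{accepted} iff it is not among the original terms and not a
#' proper ancestor of any original term; \code{t} in the originals is
#' \code{rejected-duplicate}; a proper ancestor of an original is
#' \code{rejected-ancestor-of-original}. A namespace root is accepted
#' iff the gene has no original term in that namespace (no placeholder
#' roots where annotation already exists along that sub-ontology).
#' Obsolete candidates are \code{flagged-obsolete}; with
#' \code{resolveObsolete} their \code{replaced_by} term (if any)
#' re-enters the candidate set and is refined in its place.
#'
#' @param candidates character vector of candidate GO ids.
#' @param original character vector of the gene's original GO ids.
#' @param dag an [OntologyDAG-class].
#' @param resolveObsolete replace obsolete candidates by their
#'   \code{replaced_by} term; default FALSE.
#' @return data.frame \code{go_id}, \code{status}, plus
#'   \code{resolved_from} when a replacement was followed. Output order
#'   is by \code{go_id}, independent of input order.
#' @export
refineByDag <- function(candidates, original, dag,
                        resolveObsolete = FALSE) {
    for (id in unique(c(candidates, original)))
        checkTermId(dag, id)
    out <- data.frame(go_id = character(0), status = character(0),
                      resolved_from = character(0),
                      stringsAsFactors = FALSE)
    addRow <- function(id, status, from = NA_character_)
        rbind(out, data.frame(go_id = id, status = status,
                              resolved_from = from,
                              stringsAsFactors = FALSE))
    liveOriginal <- original[!vapply(original, isObsolete, TRUE, x = dag)]
    origNs <- vapply(liveOriginal, goNamespace, "", x = dag)
    ancOfOriginal <- unique(unlist(lapply(liveOriginal, goAncestors,
                                          x = dag), use.names = FALSE))
    classify <- function(id, from = NA_character_) {
        if (isObsolete(dag, id)) {
            rep <- dag@terms$replaced_by[match(id, dag@terms$id)]
            out <<- addRow(id, "flagged-obsolete", from)
            if (resolveObsolete && !is.na(rep) && nzchar(rep) &&
                !rep %in% candidates)
                classify(rep, from = id)
            return(invisible(NULL))
        }
        status <-
            if (id %in% original) "rejected-duplicate"
            else if (id %in% goRoots(dag)) {
                if (goNamespace(dag, id) %in% origNs)
                    "rejected-ancestor-of-original" else "accepted"
            }
            else if (id %in% ancOfOriginal)
                "rejected-ancestor-of-original"
            else "accepted"
        out <<- addRow(id, status, from)
        invisible(NULL)
    }
    for (id in sort(unique(candidates))) classify(id)
    rownames(out) <- NULL
    out
}

#' Full 3-step enrichment of the target species
#'
#' Runs, per clique containing a target-species gene: candidate
#' generation, phylogenetically weighted scoring of every proposed and
#' original term, thresholding, and DAG refinement. When a gene belongs
#' to several cliques the per-clique assignments are unioned keeping,
#' for each (gene, term), the record with the maximum score. Candidate
#' terms unknown to the DAG are a hard error.
#'
#' @param cliques list of cliques from [enumerateCliques()].
#' @param ann an [AnnotationMap-class].
#' @param dag an [OntologyDAG-class].
#' @param groups group configuration, default [defaultPlantGroups()].
#' @param threshold minimum GO score, default 0.5.
#' @param strict strict rather than inclusive threshold.
#' @param resolveObsolete see [refineByDag()].
#' @return List with \code{assignments} (data.frame \code{gene},
#'   \code{go_id}, \code{clique_id}, \code{go_score}, \code{status})
#'   and \code{summary} (see Details).
#' @details The summary reports: \code{n_genes_enriched} (target genes
#'   with at least one accepted term), \code{n_newly_annotated}
#'   (previously unannotated genes gaining terms),
#'   \code{n_accepted} accepted assignments, \code{n_original} original
#'   assignments on clique-member target genes, \code{pct_increase} =
#'   accepted / original x 100, \code{mean_accepted_score},
#'   \code{accepted_path_lengths} (shortest-path depths of accepted
#'   terms), and \code{n_root_accepted}, reported both per assignment
#'   (\code{n_root_accepted}) and per gene
#'   (\code{n_genes_root_only}).
#' @export
enrichTarget <- function(cliques, ann, dag,
                         groups = defaultPlantGroups(),
                         threshold = 0.5, strict = FALSE,
                         resolveObsolete = FALSE) {
    target <- groups$species[groups$target]
    rows <- list()
    for (ci in seq_along(cliques)) {
        clique <- cliques[[ci]]
        cand <- candidateTerms(clique, ann, groups, cliqueId = ci)
        if (!nrow(cand)) next
        cand$go_score <- vapply(cand$go_id, goScore, numeric(1),
                                clique = clique, ann = ann,
                                groups = groups)
        cand <- thresholdFilter(cand, threshold, strict)
        tgtGene <- clique[[target]]
        original <- termSet(ann, target, tgtGene)
        pass <- cand$status == "candidate"
        if (any(pass)) {
            ref <- refineByDag(cand$go_id[pass], original, dag,
                               resolveObsolete)
            resolved <- ref[!is.na(ref$resolved_from) &
                            !ref$go_id %in% cand$go_id, , drop = FALSE]
            st <- setNames(ref$status, ref$go_id)
            hit <- !is.na(st[cand$go_id]) & pass
            cand$status[hit] <- unname(st[cand$go_id[hit]])
            if (nrow(resolved)) {
                extra <- data.frame(
                    gene = tgtGene, go_id = resolved$go_id,
                    clique_id = ci,
                    go_score = vapply(resolved$go_id, goScore,
                                      numeric(1), clique = clique,
                                      ann = ann, groups = groups),
                    status = resolved$status, stringsAsFactors = FALSE)
                cand <- rbind(cand, extra)
            }
        }
        rows[[length(rows) + 1L]] <- cand
    }
    assignments <- if (length(rows)) do.call(rbind, rows)
        else data.frame(gene = character(0), go_id = character(0),
                        clique_id = integer(0), go_score = numeric(0),
                        status = character(0), stringsAsFactors = FALSE)
    ## union across cliques: keep the maximum-score record per
    ## (gene, term); among equal scores prefer the stronger status
    rank <- c(original = 0L, accepted = 1L, `flagged-obsolete` = 2L,
              `rejected-duplicate` = 3L,
              `rejected-ancestor-of-original` = 4L,
              `rejected-below-threshold` = 5L, candidate = 6L)
    o <- order(assignments$gene, assignments$go_id,
               -assignments$go_score, rank[assignments$status],
               assignments$clique_id)
    assignments <- assignments[o, , drop = FALSE]
    keep <- !duplicated(paste0(assignments$gene, "\r",
                               assignments$go_id))
    assignments <- assignments[keep, , drop = FALSE]
    rownames(assignments) <- NULL

    acc <- assignments[assignments$status == "accepted", , drop = FALSE]
    orig <- assignments[assignments$status == "original", , drop = FALSE]
    hadAnnotation <- vapply(unique(assignments$gene), function(g)
        length(termSet(ann, target, g)) > 0L, logical(1))
    accDepth <- if (nrow(acc))
        vapply(acc$go_id, goDepth, integer(1), x = dag) else integer(0)
    isRoot <- acc$go_id %in% goRoots(dag)
    rootOnly <- if (nrow(acc))
        tapply(isRoot, acc$gene, all) else logical(0)
    summary <- list(
        n_genes_enriched = length(unique(acc$gene)),
        n_newly_annotated = sum(!hadAnnotation[unique(acc$gene)]),
        n_accepted = nrow(acc),
        n_original = nrow(orig),
        pct_increase = if (nrow(orig)) nrow(acc) / nrow(orig) * 100
                       else NA_real_,
        mean_accepted_score = if (nrow(acc)) mean(acc$go_score)
                              else NA_real_,
        accepted_path_lengths = unname(accDepth),
        n_root_accepted = sum(isRoot),
        n_genes_root_only = sum(rootOnly))
    list(assignments = assignments, summary = summary)
}

#' Histogram of GO scores, original vs new terms
#'
#' Separate seeded-bin counts for original-term scores and accepted
#' new-term scores. In any clique that contains the target gene an
#' original term's score includes the target's own contribution of 1
#' (group score 1), so original scores sit consistently above new-term
#' scores.
#'
#' @param assignments data.frame from [enrichTarget()].
#' @param breaks increasing numeric bin edges spanning all observed
#'   scores; default width-0.5 bins up to the ten-species maximum 4.5.
#' @return Contingency table, rows \code{original}/\code{new}.
#' @export
scoreHistogram <- function(assignments, breaks = seq(0, 4.5, by = 0.5)) {
    if (is.unsorted(breaks, strictly = TRUE))
        stop("breaks must be strictly increasing", call. = FALSE)
    sel <- assignments$status %in% c("original", "accepted")
    a <- assignments[sel, , drop = FALSE]
    grp <- factor(ifelse(a$status == "original", "original", "new"),
                  levels = c("original", "new"))
    bin <- cut(a$go_score, breaks = breaks, include.lowest = TRUE)
    table(status = grp, bin = bin)
}
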