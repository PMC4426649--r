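#' Synthetic scenario specification
#'
#' Describes a fully synthetic study: species and group scores, planted
#' 1-to-1 ortholog cliques, background genes, ontology shape, annotation
#' density and decoy-hit rate. The default mirrors the ten-plant study
#' shape: ten species under [defaultPlantGroups()] with one planted
#' clique at every size 3 through 10. All generators are pure functions
#' of (spec, seed), so identical calls give identical files.
#'
#' @param groups species-group configuration, see [speciesGroups()].
#' @param cliqueSizes integer sizes of the planted cliques; each must
#'   include the target species, so sizes are capped by the species
#'   count.
#' @param sharedTerms number of shared leaf GO terms planted on the
#'   non-target members of each clique (the transferable truth terms).
#' @param commonTerms number of additional leaf terms planted on every
#'   member, target included, of cliques with an annotated target;
#'   these drive the GO-set overlap of well-formed cliques above the
#'   random-clique null.
#' @param targetMode per planted clique, \code{"annotated"} (the target
#'   gene carries a parent of the first planted term) or
#'   \code{"unannotated"}; recycled along \code{cliqueSizes}.
#' @param backgroundGenes background genes per species.
#' @param depth,branching ontology shape per namespace.
#' @param annotationDensity fraction of background genes that carry
#'   random annotations.
#' @param decoyRate per planted gene, probability of an extra
#'   sub-threshold decoy hit.
#' @param seed mandatory integer seed.
#' @return A \code{ScenarioSpec} list.
#' @export
scenarioSpec <- function(groups = defaultPlantGroups(),
                         cliqueSizes = 3:10,
                         sharedTerms = 2L,
                         commonTerms = 2L,
                         targetMode = c("unannotated", "annotated"),
                         backgroundGenes = 20L,
                         depth = 3L, branching = 3L,
                         annotationDensity = 0.3,
                         decoyRate = 0.1,
                         seed) {
    if (missing(seed)) stop("seed is mandatory", call. = FALSE)
    stopifnot(all(cliqueSizes >= 3L),
              all(cliqueSizes <= nrow(groups)),
              all(targetMode %in% c("annotated", "unannotated")))
    structure(list(
        groups = groups,
        cliqueSizes = as.integer(cliqueSizes),
        sharedTerms = as.integer(sharedTerms),
        commonTerms = as.integer(commonTerms),
        targetMode = rep_len(targetMode, length(cliqueSizes)),
        backgroundGenes = as.integer(backgroundGenes),
        depth = as.integer(depth), branching = as.integer(branching),
        annotationDensity = annotationDensity,
        decoyRate = decoyRate,
        seed = as.integer(seed)), class = "ScenarioSpec")
}

#' Generate a synthetic three-namespace ontology
#'
#' Builds one rooted tree per GO namespace with the requested depth and
#' branching factor, then adds diamond edges (a second parent one level
#' up) to a fixed tenth of the eligible nodes, plus one obsolete term
#' per namespace carrying a \code{replaced_by} pointer to a live leaf.
#' Serializes via [writeOBO()] to OBO 1.2 that [readOBO()] round-trips.
#'
#' @param depth levels below each root, >= 1.
#' @param branching children per node, >= 1.
#' @param seed integer seed.
#' @return An [OntologyDAG-class].
#' @export
simulateOntology <- function(depth, branching, seed) {
    stopifnot(depth >= 1L, branching >= 1L)
    nss <- c("biological_process", "cellular_component",
             "molecular_function")
    withSeed(seed, {
        nextId <- 0L
        mk <- function() {
            nextId <<- nextId + 1L
            sprintf("GO:%07d", nextId)
        }
        ids <- character(0); name <- character(0); ns <- character(0)
        obsolete <- logical(0); replaced <- character(0)
        parents <- list()
        roots <- character(0)
        for (n in nss) {
            root <- mk()
            ids <- c(ids, root); name <- c(name, n); ns <- c(ns, n)
            obsolete <- c(obsolete, FALSE)
            replaced <- c(replaced, NA_character_)
            parents[[root]] <- character(0)
            roots[[n]] <- root
            levels <- list(root)
            for (d in seq_len(depth)) {
                prev <- levels[[d]]
                cur <- character(0)
                for (p in prev) for (b in seq_len(branching)) {
                    id <- mk()
                    ids <- c(ids, id)
                    name <- c(name, sprintf("%s term %s", n, id))
                    ns <- c(ns, n)
                    obsolete <- c(obsolete, FALSE)
                    replaced <- c(replaced, NA_character_)
                    parents[[id]] <- p
                    cur <- c(cur, id)
                }
                ## diamonds: a second parent from the grandparent level
                if (d >= 2L) {
                    extra <- cur[seq_along(cur) %% 10L == 0L]
                    for (id in extra) {
                        cand <- setdiff(prev, parents[[id]])
                        if (length(cand))
                            parents[[id]] <- c(parents[[id]],
                                cand[sample.int(length(cand), 1L)])
                    }
                }
                levels[[d + 1L]] <- cur
            }
            leafPool <- levels[[depth + 1L]]
            obsId <- mk()
            ids <- c(ids, obsId)
            name <- c(name, sprintf("%s obsolete term", n))
            ns <- c(ns, n)
            obsolete <- c(obsolete, TRUE)
            replaced <- c(replaced,
                          leafPool[sample.int(length(leafPool), 1L)])
            parents[[obsId]] <- character(0)
        }
        terms <- data.frame(id = ids, name = name, namespace = ns,
                            obsolete = obsolete, replaced_by = replaced,
                            stringsAsFactors = FALSE)
        new("OntologyDAG", terms = terms, parents = parents,
            roots = roots)
    })
}

## Leaf terms (live, childless) of a DAG, optionally per namespace.
goLeaves <- function(dag, namespace = NULL) {
    withParent <- unique(unlist(dag@parents, use.names = FALSE))
    t <- dag@terms
    live <- t$id[!t$obsolete]
    leaves <- setdiff(live, withParent)
    if (!is.null(namespace))
        leaves <- leaves[t$namespace[match(leaves, t$id)] == namespace]
    sort(leaves)
}

geneId <- function(species, n) sprintf("%s_G%04d", species, n)

#' Plant ortholog cliques and emit similarity tables
#'
#' For each planted clique the member genes are unique mutual best hits
#' in both the DNA and the protein tables (e-values drawn log-uniformly
#' in [1e-50, 1e-10], far below the 1e-5 cutoff). Decoy hits are either
#' sub-threshold (e-value in [1e-4, 1]) or significant but
#' non-reciprocal, so reciprocal-best-hit calling plus evidence
#' intersection recovers exactly the planted pair set. DNA tables carry
#' transcript ids (\code{GENE.T1}) to exercise the transcript-to-gene
#' lift.
#'
#' @param spec a [scenarioSpec()].
#' @return List: \code{truthPairs} (canonical pair table),
#'   \code{truthCliques} (list of named species -> gene vectors),
#'   \code{manifest} (data.frame naming the per-pair files),
#'   \code{tables} (named list keyed by the manifest's file names),
#'   \code{backgroundGenes} (named list species -> gene ids).
#' @export
plantOrthologs <- function(spec) {
    groups <- spec$groups
    species <- sort(groups$species)
    target <- groups$species[groups$target]
    withSeed(childSeed(spec$seed, 1L), {
        ## clique membership: the target plus its k-1 phylogenetically
        ## closest species (smallest group scores, ties by name), so a
        ## term shared by the non-target members always clears the 0.5
        ## evidence threshold
        byProximity <- groups$species[order(groups$group_score,
                                            groups$species)]
        byProximity <- setdiff(byProximity, target)
        cliques <- list()
        for (j in seq_along(spec$cliqueSizes)) {
            k <- spec$cliqueSizes[j]
            mem <- sort(c(target, byProximity[seq_len(k - 1L)]))
            cliques[[j]] <- setNames(geneId(mem, 1000L + j), mem)
        }
        background <- setNames(lapply(species, function(sp)
            geneId(sp, 2000L + seq_len(spec$backgroundGenes))), species)

        plantedE <- function(n) 10^stats::runif(n, -50, -10)
        decoyE <- function(n) 10^stats::runif(n, -4, 0)
        hitRow <- function(q, s, e, bit)
            data.frame(qseqid = q, sseqid = s, pident = 95, length = 400,
                       mismatch = 10, gapopen = 1, qstart = 1,
                       qend = 400, sstart = 1, send = 400,
                       evalue = e, bitscore = bit,
                       stringsAsFactors = FALSE)

        tables <- list()
        manifest <- list()
        pairsOut <- list()
        for (ia in seq_along(species)) for (ib in seq_along(species)) {
            if (ia >= ib) next
            A <- species[ia]; B <- species[ib]
            inClique <- Filter(function(cl)
                all(c(A, B) %in% names(cl)), cliques)
            for (st in c("dna", "protein")) {
                fwd <- list(); rev <- list()
                tx <- function(g) if (st == "dna") paste0(g, ".T1") else g
                for (cl in inClique) {
                    gA <- cl[[A]]; gB <- cl[[B]]
                    e <- plantedE(2L)
                    fwd[[length(fwd) + 1L]] <-
                        hitRow(tx(gA), tx(gB), e[1L], 500)
                    rev[[length(rev) + 1L]] <-
                        hitRow(tx(gB), tx(gA), e[2L], 500)
                    ## optional worse decoy from a planted gene
                    if (stats::runif(1) < spec$decoyRate &&
                        spec$backgroundGenes > 0L) {
                        bg <- sample(background[[B]], 1L)
                        fwd[[length(fwd) + 1L]] <-
                            hitRow(tx(gA), tx(bg), decoyE(1L), 40)
                    }
                    pairsOut[[length(pairsOut) + 1L]] <-
                        data.frame(species_a = A, gene_a = gA,
                                   species_b = B, gene_b = gB,
                                   evidence = "both",
                                   stringsAsFactors = FALSE)
                }
                ## background: sub-threshold mutual noise
                nbg <- min(spec$backgroundGenes, 5L)
                if (nbg) {
                    qa <- sample(background[[A]], nbg)
                    sb <- sample(background[[B]], nbg)
                    for (i in seq_len(nbg)) {
                        fwd[[length(fwd) + 1L]] <-
                            hitRow(tx(qa[i]), tx(sb[i]), decoyE(1L), 35)
                        rev[[length(rev) + 1L]] <-
                            hitRow(tx(sb[i]), tx(qa[i]), decoyE(1L), 35)
                    }
                }
                ## significant but non-reciprocal triple x -> y -> z
                if (spec$backgroundGenes >= 2L) {
                    xz <- sample(background[[A]], 2L)
                    y <- sample(background[[B]], 1L)
                    fwd[[length(fwd) + 1L]] <-
                        hitRow(tx(xz[1L]), tx(y), 1e-8, 120)
                    rev[[length(rev) + 1L]] <-
                        hitRow(tx(y), tx(xz[2L]), 1e-9, 130)
                }
                key <- sprintf("%s__%s.%s", A, B, st)
                emptyHits <- hitRow("x", "y", 1, 1)[0L, ]
                tables[[paste0(key, ".fwd.tsv")]] <-
                    if (length(fwd)) do.call(rbind, fwd) else emptyHits
                tables[[paste0(key, ".rev.tsv")]] <-
                    if (length(rev)) do.call(rbind, rev) else emptyHits
                manifest[[length(manifest) + 1L]] <- data.frame(
                    species_a = A, species_b = B, seqtype = st,
                    forward_file = paste0(key, ".fwd.tsv"),
                    reverse_file = paste0(key, ".rev.tsv"),
                    stringsAsFactors = FALSE)
            }
        }
        truthPairs <- unique(do.call(rbind, pairsOut))
        truthPairs <- truthPairs[order(truthPairs$species_a,
                                       truthPairs$species_b,
                                       truthPairs$gene_a), ]
        rownames(truthPairs) <- NULL
        list(truthPairs = truthPairs, truthCliques = cliques,
             manifest = do.call(rbind, manifest), tables = tables,
             backgroundGenes = background)
    })
}

#' Plant annotations with known transferable terms
#'
#' Each planted clique receives \code{sharedTerms} leaf terms on every
#' non-target member: these are the transferable truth terms, chosen as
#' leaves so DAG refinement accepts them. The target gene is annotated
#' according to the clique's mode: \code{"annotated"} gives it a parent
#' of the first planted term (so the planted leaf is strictly deeper),
#' \code{"unannotated"} leaves it empty. Background genes draw random
#' non-root terms at the requested density.
#'
#' @param spec a [scenarioSpec()].
#' @param dag an [OntologyDAG-class] (typically [simulateOntology()]).
#' @param planted result of [plantOrthologs()].
#' @return List: \code{ann} (an [AnnotationMap-class]) and
#'   \code{truthTransfers} (data.frame \code{clique_id}, \code{gene},
#'   \code{go_id}, \code{expected_score} for cliques holding a target
#'   gene).
#' @export
plantAnnotations <- function(spec, dag, planted) {
    groups <- spec$groups
    target <- groups$species[groups$target]
    leaves <- goLeaves(dag)
    if (spec$sharedTerms + spec$commonTerms > length(leaves))
        stop(sprintf("sharedTerms (%d) exceeds leaf count (%d)",
                     spec$sharedTerms, length(leaves)), call. = FALSE)
    g <- groupLookup(groups, groups$species)
    withSeed(childSeed(spec$seed, 2L), {
        rows <- list()
        truth <- list()
        for (j in seq_along(planted$truthCliques)) {
            cl <- planted$truthCliques[[j]]
            annotated <- spec$targetMode[j] == "annotated" &&
                target %in% names(cl)
            draw <- sample(leaves, spec$sharedTerms +
                                   if (annotated) spec$commonTerms
                                   else 0L)
            shared <- draw[seq_len(spec$sharedTerms)]
            common <- setdiff(draw, shared)
            nonTarget <- setdiff(names(cl), target)
            for (sp in nonTarget)
                rows[[length(rows) + 1L]] <- data.frame(
                    species = sp, gene = cl[[sp]],
                    go_id = c(shared, common),
                    stringsAsFactors = FALSE)
            if (target %in% names(cl)) {
                expected <- sum(1 / g[nonTarget])
                truth[[length(truth) + 1L]] <- data.frame(
                    clique_id = j, gene = cl[[target]], go_id = shared,
                    expected_score = expected, stringsAsFactors = FALSE)
                if (annotated) {
                    par <- goParents(dag, shared[1L])[1L]
                    rows[[length(rows) + 1L]] <- data.frame(
                        species = target, gene = cl[[target]],
                        go_id = c(par, common),
                        stringsAsFactors = FALSE)
                }
            }
        }
        nonRoot <- setdiff(dag@terms$id[!dag@terms$obsolete],
                           goRoots(dag))
        for (sp in names(planted$backgroundGenes))
            for (gene in planted$backgroundGenes[[sp]])
                if (stats::runif(1) < spec$annotationDensity)
                    rows[[length(rows) + 1L]] <- data.frame(
                        species = sp, gene = gene,
                        go_id = sample(nonRoot,
                                       sample.int(2L, 1L)),
                        stringsAsFactors = FALSE)
        df <- do.call(rbind, rows)
        truthTransfers <- if (length(truth)) do.call(rbind, truth)
            else data.frame(clique_id = integer(0), gene = character(0),
                            go_id = character(0),
                            expected_score = numeric(0))
        list(ann = annotationMap(df), truthTransfers = truthTransfers)
    })
}

#' Generate and optionally write a complete synthetic scenario
#'
#' Runs [simulateOntology()], [plantOrthologs()] and
#' [plantAnnotations()] under the spec's seed. With \code{dir} set, all
#' pipeline inputs are written as plain text: BLAST tabular files plus
#' \code{manifest.tsv}, \code{annotations.tsv}, \code{ontology.obo},
#' \code{groups.tsv}, and the truth tables \code{truth_pairs.tsv},
#' \code{truth_cliques.tsv}, \code{truth_transfers.tsv}.
#'
#' @param spec a [scenarioSpec()].
#' @param dir optional output directory (created if needed).
#' @return List: \code{dag}, \code{planted}, \code{ann},
#'   \code{truthTransfers}, plus \code{dir} when written.
#' @export
simulateScenario <- function(spec, dir = NULL) {
    dag <- simulateOntology(spec$depth, spec$branching,
                            childSeed(spec$seed, 0L))
    planted <- plantOrthologs(spec)
    annres <- plantAnnotations(spec, dag, planted)
    res <- list(dag = dag, planted = planted, ann = annres$ann,
                truthTransfers = annres$truthTransfers)
    if (!is.null(dir)) {
        dir.create(dir, recursive = TRUE, showWarnings = FALSE)
        for (fn in names(planted$tables)) {
            t <- planted$tables[[fn]]
            t$evalue <- sprintf("%.6e", t$evalue)
            write.table(t, file.path(dir, fn), sep = "\t",
                        quote = FALSE, row.names = FALSE,
                        col.names = FALSE)
        }
        cfg <- list(seed = spec$seed)
        writeTSV(planted$manifest, file.path(dir, "manifest.tsv"), cfg)
        writeTSV(annotationTable(annres$ann),
                 file.path(dir, "annotations.tsv"), cfg)
        writeOBO(dag, file.path(dir, "ontology.obo"))
        writeTSV(spec$groups, file.path(dir, "groups.tsv"), cfg)
        writeTSV(planted$truthPairs, file.path(dir, "truth_pairs.tsv"),
                 cfg)
        writeTSV(cliqueTable(planted$truthCliques),
                 file.path(dir, "truth_cliques.tsv"), cfg)
        writeTSV(annres$truthTransfers,
                 file.path(dir, "truth_transfers.tsv"), cfg)
        res$dir <- dir
    }
    res
}
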