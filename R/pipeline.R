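#' Run the pipeline end to end or stage by stage
#'
#' Thin orchestration over the module functions, mirroring the shell
#' subcommands: \code{simulate}, \code{rbbh}, \code{cliques},
#' \code{validate}, \code{enrich} and the full \code{all} chain. Every
#' output is plain TSV with a provenance comment header and
#' deterministic row order, so reruns are diff-clean. Missing inputs
#' raise condition class \code{cliqueGO_missing_input}, which the
#' command-line wrapper maps to exit status 2.
#'
#' @param subcommand one of \code{"simulate"}, \code{"rbbh"},
#'   \code{"cliques"}, \code{"validate"}, \code{"enrich"},
#'   \code{"all"}.
#' @param config named list of options. Recognised entries:
#'   \code{out} (output dir, required), \code{seed}, \code{manifest},
#'   \code{pairs}, \code{cliques}, \code{annotations}, \code{obo},
#'   \code{groupsFile}, \code{evalue} (default 1e-5), \code{minSize}
#'   (default 3), \code{threshold} (default 0.5), \code{strict},
#'   \code{resolveObsolete}, \code{allCliques}, \code{dimacs},
#'   \code{randomPerSize} (random-clique null draws per observed OCL).
#' @return Invisibly, a named list of written file paths.
#' @export
pipelineRun <- function(subcommand = c("all", "simulate", "rbbh",
                                       "cliques", "validate", "enrich"),
                        config = list()) {
    subcommand <- match.arg(subcommand)
    out <- config$out
    if (is.null(out)) stopMissing("config$out (output directory)")
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    cfg <- function(name, default = NULL) {
        v <- config[[name]]
        if (is.null(v)) default else v
    }
    needFile <- function(path, what) {
        if (is.null(path) || !file.exists(path)) stopMissing(what)
        path
    }
    written <- list()
    t0 <- proc.time()[["elapsed"]]
    stage <- function(name, n)
        message(sprintf("[%s] %s: %d records (%.1fs)", subcommand,
                        name, n, proc.time()[["elapsed"]] - t0))

    if (subcommand %in% c("simulate", "all")) {
        seed <- cfg("seed")
        if (is.null(seed)) stopMissing("seed")
        spec <- scenarioSpec(seed = seed)
        simDir <- if (subcommand == "all") file.path(out, "sim") else out
        sim <- simulateScenario(spec, dir = simDir)
        stage("simulate", nrow(sim$planted$truthPairs))
        written$sim <- simDir
        if (subcommand == "simulate") return(invisible(written))
        config$manifest <- file.path(simDir, "manifest.tsv")
        config$annotations <- file.path(simDir, "annotations.tsv")
        config$obo <- file.path(simDir, "ontology.obo")
        config$groupsFile <- file.path(simDir, "groups.tsv")
    }

    if (subcommand %in% c("rbbh", "all")) {
        manifest <- needFile(cfg("manifest"), "manifest TSV")
        pairs <- rbbhPipeline(manifest,
                              evalueCutoff = cfg("evalue", 1e-5),
                              dir = dirname(manifest))
        pairsPath <- file.path(out, "pairs.tsv")
        writeTSV(pairs, pairsPath,
                 list(evalue = cfg("evalue", 1e-5)))
        stage("rbbh", nrow(pairs))
        written$pairs <- pairsPath
        config$pairs <- pairsPath
    }

    if (subcommand %in% c("cliques", "all")) {
        pairsPath <- needFile(cfg("pairs"), "pairs TSV")
        graph <- orthologGraph(readTSV(pairsPath))
        mode <- if (isTRUE(cfg("allCliques"))) "all" else "maximal"
        cl <- enumerateCliques(graph, minSize = cfg("minSize", 3L),
                               mode = mode)
        clPath <- file.path(out, "cliques.tsv")
        writeTSV(cliqueTable(cl), clPath,
                 list(min_size = cfg("minSize", 3L), mode = mode))
        ocl <- assignOCL(cl)
        sp <- setNames(graph@genes$species, graph@genes$gene)
        writeTSV(data.frame(gene = names(ocl),
                            species = unname(sp[names(ocl)]),
                            ocl = unname(ocl)),
                 file.path(out, "ocl.tsv"))
        if (!is.null(cfg("dimacs")))
            writeDimacs(graph, cfg("dimacs"))
        stage("cliques", length(cl))
        written$cliques <- clPath
        config$cliques <- clPath
    }

    if (subcommand %in% c("validate", "all")) {
        clPath <- needFile(cfg("cliques"), "cliques TSV")
        annPath <- needFile(cfg("annotations"), "annotations TSV")
        cl <- cliquesFromTable(readTSV(clPath))
        ann <- readAnnotations(annPath)
        res <- overlapResults(cl, ann)
        ovPath <- file.path(out, "overlap.tsv")
        writeTSV(res, ovPath)
        hist <- overlapHistogram(res)
        writeTSV(as.data.frame(hist), file.path(out,
                                                "overlap_hist.tsv"))
        seed <- cfg("seed")
        if (!is.null(seed)) {
            pools <- lapply(ann@annotations, names)
            counts <- table(res$ocl)
            n <- rep.int(cfg("randomPerSize",
                             max(counts, 0L)), length(counts))
            rnd <- randomCliques(pools,
                                 setNames(n, names(counts)), seed)
            rres <- overlapResults(rnd, ann)
            writeTSV(rres, file.path(out, "overlap_random.tsv"),
                     list(seed = seed))
        }
        stage("validate", nrow(res))
        written$overlap <- ovPath
    }

    if (subcommand %in% c("enrich", "all")) {
        clPath <- needFile(cfg("cliques"), "cliques TSV")
        annPath <- needFile(cfg("annotations"), "annotations TSV")
        oboPath <- needFile(cfg("obo"), "OBO file")
        cl <- cliquesFromTable(readTSV(clPath))
        ann <- readAnnotations(annPath)
        dag <- readOBO(oboPath)
        groups <- if (!is.null(cfg("groupsFile")))
            readSpeciesGroups(needFile(cfg("groupsFile"),
                                       "species-group config"))
        else defaultPlantGroups()
        res <- enrichTarget(cl, ann, dag, groups,
                            threshold = cfg("threshold", 0.5),
                            strict = isTRUE(cfg("strict")),
                            resolveObsolete =
                                isTRUE(cfg("resolveObsolete")))
        a <- res$assignments
        a$go_score <- round(a$go_score, 2L)
        asgPath <- file.path(out, "assignments.tsv")
        writeTSV(a, asgPath, list(threshold = cfg("threshold", 0.5)))
        s <- res$summary
        writeTSV(data.frame(
            metric = c("n_genes_enriched", "n_newly_annotated",
                       "n_accepted", "n_original", "pct_increase",
                       "mean_accepted_score", "n_root_accepted",
                       "n_genes_root_only"),
            value = round(c(s$n_genes_enriched, s$n_newly_annotated,
                            s$n_accepted, s$n_original,
                            s$pct_increase, s$mean_accepted_score,
                            s$n_root_accepted,
                            s$n_genes_root_only), 4L)),
            file.path(out, "enrich_summary.tsv"))
        writeTSV(as.data.frame(scoreHistogram(res$assignments)),
                 file.path(out, "score_hist.tsv"))
        stage("enrich", nrow(a))
        written$assignments <- asgPath
    }
    invisible(written)
}

stopMissing <- function(what) {
    stop(structure(class = c("cliqueGO_missing_input", "error",
                             "condition"),
                   list(message = sprintf("missing input: %s", what),
                        call = NULL)))
}
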