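groups10 <- defaultPlantGroups()
target <- groups10$species[groups10$target]

test_that("GO score reproduces the printed worked values", {
    clique <- plantClique()
    allAnn <- annotationMap(data.frame(species = groups10$species,
                                       gene = clique[groups10$species],
                                       go_id = "GO:0000100"))
    s <- goScore("GO:0000100", clique, allAnn, groups10)
    expect_equal(s, 4.3166667, tolerance = 1e-7)
    expect_equal(round(s, 2), 4.32)
    ## only the H. vulgare (group 2) gene annotated: exactly 0.5
    hv <- annotationMap(data.frame(species = "Hordeum_vulgare",
                                   gene = clique[["Hordeum_vulgare"]],
                                   go_id = "GO:0000100"))
    expect_equal(goScore("GO:0000100", clique, hv, groups10), 0.5)
    ## unannotated term scores 0
    expect_equal(goScore("GO:0000999", clique, hv, groups10), 0)
    ## all members except the target: 4.3166667 - 1 = 3.3166667 ~ 3.32
    nonT <- setdiff(groups10$species, target)
    butT <- annotationMap(data.frame(species = nonT,
                                     gene = clique[nonT],
                                     go_id = "GO:0000100"))
    s9 <- goScore("GO:0000100", clique, butT, groups10)
    expect_equal(s9, 3.3166667, tolerance = 1e-7)
    expect_equal(round(s9, 2), 3.32)
    ## unknown species in the clique is an error
    bad <- c(clique, Mystery_species = "X_G1")
    expect_error(goScore("GO:0000100", bad, allAnn, groups10),
                 "missing from group config")
})

test_that("GO score is additive in annotated members and bounded", {
    clique <- plantClique()
    bound <- sum(1 / groups10$group_score)
    rows <- NULL
    acc <- 0
    for (i in seq_len(nrow(groups10))) {
        sp <- groups10$species[i]
        rows <- rbind(rows, data.frame(species = sp,
                                       gene = clique[[sp]],
                                       go_id = "GO:0000100"))
        s <- goScore("GO:0000100", clique, annotationMap(rows),
                     groups10)
        expect_equal(s, acc + 1 / groups10$group_score[i])
        expect_lte(s, bound + 1e-12)
        acc <- s
    }
    expect_equal(acc, 4.3166667, tolerance = 1e-7)
})

test_that("candidate terms come from any member; originals labelled", {
    clique <- c(setNames(c("TA_G1", "HV_G1", "BD_G1"),
                         c(target, "Hordeum_vulgare",
                           "Brachypodium_distachyon")))
    ann <- annFrom(list("Hordeum_vulgare", "HV_G1", "GO:0007568"))
    cand <- candidateTerms(clique, ann, groups10, cliqueId = 1L)
    expect_equal(cand$go_id, "GO:0007568")
    expect_equal(cand$status, "candidate")
    expect_equal(cand$gene, "TA_G1")
    ## only the target annotated: retained as original, no candidates
    annT <- annFrom(list(target, "TA_G1", "GO:0007568"))
    candT <- candidateTerms(clique, annT, groups10)
    expect_equal(candT$status, "original")
    ## no target gene in the clique: skipped
    noT <- clique[names(clique) != target]
    expect_equal(nrow(candidateTerms(noT, ann, groups10)), 0L)
})

test_that("threshold is inclusive by default, strict on request", {
    scored <- data.frame(gene = "g", go_id = sprintf("GO:%07d", 1:3),
                         clique_id = 1L,
                         go_score = c(0.5, 0.4999, 2),
                         status = "candidate")
    out <- thresholdFilter(scored)
    expect_equal(out$status,
                 c("candidate", "rejected-below-threshold",
                   "candidate"))
    strict <- thresholdFilter(scored, strict = TRUE)
    expect_equal(strict$status[1L], "rejected-below-threshold")
    ## originals always pass
    orig <- data.frame(gene = "g", go_id = "GO:0000009",
                       clique_id = 1L, go_score = 0.1,
                       status = "original")
    expect_equal(thresholdFilter(orig)$status, "original")
    expect_equal(nrow(thresholdFilter(scored[0L, ])), 0L)
})

test_that("DAG refinement implements the specificity rules", {
    dag <- chainDAG()   # GO:0000003 is_a GO:0000002 is_a GO:0000001
    ## deeper than the original: accepted
    r <- refineByDag("GO:0000003", original = "GO:0000002", dag)
    expect_equal(r$status, "accepted")
    ## ancestor of the original: rejected
    r2 <- refineByDag("GO:0000002", original = "GO:0000003", dag)
    expect_equal(r2$status, "rejected-ancestor-of-original")
    ## duplicate of an original
    r3 <- refineByDag("GO:0000002", original = "GO:0000002", dag)
    expect_equal(r3$status, "rejected-duplicate")
    ## root accepted only for genes with no original in that namespace
    r4 <- refineByDag("GO:0000001", original = character(0), dag)
    expect_equal(r4$status, "accepted")
    r5 <- refineByDag("GO:0000001", original = "GO:0000003", dag)
    expect_equal(r5$status, "rejected-ancestor-of-original")
    expect_error(refineByDag("GO:9999999", character(0), dag),
                 "unknown")
})

test_that("a root on a different path than the originals is accepted", {
    obo <- c("[Term]", "id: GO:0008150", "name: biological_process",
             "namespace: biological_process", "",
             "[Term]", "id: GO:0003674", "name: molecular_function",
             "namespace: molecular_function", "",
             "[Term]", "id: GO:0003677", "name: DNA binding",
             "namespace: molecular_function", "is_a: GO:0003674")
    dag <- readOBO(obo)
    ## gene annotated only in molecular_function: the bp root adds a path
    r <- refineByDag("GO:0008150", original = "GO:0003677", dag)
    expect_equal(r$status, "accepted")
    r2 <- refineByDag("GO:0003674", original = "GO:0003677", dag)
    expect_equal(r2$status, "rejected-ancestor-of-original")
})

test_that("obsolete candidates are flagged; replacements opt in", {
    obo <- c("[Term]", "id: GO:0000001", "name: root",
             "namespace: molecular_function", "",
             "[Term]", "id: GO:0016887", "name: ATPase activity",
             "namespace: molecular_function", "is_a: GO:0000001", "",
             "[Term]", "id: GO:0006200", "name: ATP catabolic process",
             "namespace: molecular_function", "is_obsolete: true",
             "replaced_by: GO:0016887")
    dag <- readOBO(obo)
    r <- refineByDag("GO:0006200", original = character(0), dag)
    expect_equal(r$status, "flagged-obsolete")
    r2 <- refineByDag("GO:0006200", original = character(0), dag,
                      resolveObsolete = TRUE)
    expect_equal(sort(r2$status), c("accepted", "flagged-obsolete"))
    expect_equal(r2$go_id[r2$status == "accepted"], "GO:0016887")
    expect_equal(r2$resolved_from[r2$status == "accepted"],
                 "GO:0006200")
})

test_that("refinement never accepts an ancestor of an original term", {
    for (seed in 1:20) {
        dag <- randomDAG(sample(10:50, 1L), seed + 900)
        ids <- goTerms(dag)$id
        original <- sample(ids, sample(1:3, 1L))
        candidates <- sample(ids, sample(2:8, 1L))
        r <- refineByDag(candidates, original, dag)
        acc <- r$go_id[r$status == "accepted"]
        expect_length(intersect(acc, original), 0L)
        for (o in original)
            expect_length(intersect(acc, goAncestors(dag, o)), 0L)
        ## invariant to candidate input order
        r2 <- refineByDag(rev(candidates), original, dag)
        expect_identical(r, r2)
    }
})

test_that("the hand-traced size-3 fixture enriches as computed", {
    ## target + two group-2 relatives; both relatives carry leaf t;
    ## the target's original term is t's parent.
    obo <- c("[Term]", "id: GO:0000001", "name: root",
             "namespace: biological_process", "",
             "[Term]", "id: GO:0000002", "name: parent",
             "namespace: biological_process", "is_a: GO:0000001", "",
             "[Term]", "id: GO:0000003", "name: t",
             "namespace: biological_process", "is_a: GO:0000002")
    dag <- readOBO(obo)
    clique <- setNames(c("TA_G1", "AT_G1", "HV_G1"),
                       c(target, "Aegilops_tauschii",
                         "Hordeum_vulgare"))
    ann <- annFrom(list("Aegilops_tauschii", "AT_G1", "GO:0000003"),
                   list("Hordeum_vulgare", "HV_G1", "GO:0000003"),
                   list(target, "TA_G1", "GO:0000002"))
    res <- enrichTarget(list(clique), ann, dag)
    a <- res$assignments
    ## t scores 1/2 + 1/2 = 1.0, passes 0.5, is deeper: accepted
    tRow <- a[a$go_id == "GO:0000003", ]
    expect_equal(tRow$status, "accepted")
    expect_equal(tRow$go_score, 1.0)
    ## the original parent term scores 1 (target's own contribution)
    pRow <- a[a$go_id == "GO:0000002", ]
    expect_equal(pRow$status, "original")
    expect_equal(pRow$go_score, 1.0)
    expect_equal(res$summary$n_genes_enriched, 1L)
    expect_equal(res$summary$n_newly_annotated, 0L)
    expect_equal(res$summary$n_accepted, 1L)
    expect_equal(res$summary$n_original, 1L)
    expect_equal(res$summary$pct_increase, 100)
    expect_equal(res$summary$accepted_path_lengths, 2L)
})

test_that("ancestor-only candidates leave the gene unenriched", {
    dag <- chainDAG()
    clique <- setNames(c("TA_G1", "HV_G1"),
                       c(target, "Hordeum_vulgare"))
    ann <- annFrom(list("Hordeum_vulgare", "HV_G1", "GO:0000002"),
                   list(target, "TA_G1", "GO:0000003"))
    res <- enrichTarget(list(clique), ann, dag)
    expect_equal(res$summary$n_accepted, 0L)
    expect_equal(res$summary$n_genes_enriched, 0L)
    expect_equal(
        res$assignments$status[res$assignments$go_id == "GO:0000002"],
        "rejected-ancestor-of-original")
})

test_that("unannotated targets are tallied as newly annotated", {
    dag <- chainDAG()
    clique <- setNames(c("TA_G1", "AT_G1", "HV_G1"),
                       c(target, "Aegilops_tauschii",
                         "Hordeum_vulgare"))
    ann <- annFrom(list("Aegilops_tauschii", "AT_G1", "GO:0000003"),
                   list("Hordeum_vulgare", "HV_G1", "GO:0000003"))
    res <- enrichTarget(list(clique), ann, dag)
    expect_equal(res$summary$n_accepted, 1L)
    expect_equal(res$summary$n_newly_annotated, 1L)
})

test_that("multi-clique genes keep the maximum score per term", {
    dag <- chainDAG()
    c1 <- setNames(c("TA_G1", "HV_G1"), c(target, "Hordeum_vulgare"))
    c2 <- setNames(c("TA_G1", "TU_G1", "AT_G1"),
                   c(target, "Triticum_urartu", "Aegilops_tauschii"))
    ann <- annFrom(list("Hordeum_vulgare", "HV_G1", "GO:0000003"),
                   list("Triticum_urartu", "TU_G1", "GO:0000003"),
                   list("Aegilops_tauschii", "AT_G1", "GO:0000003"))
    res <- enrichTarget(list(c1, c2), ann, dag)
    row <- res$assignments[res$assignments$go_id == "GO:0000003", ]
    expect_equal(nrow(row), 1L)
    ## clique 2 gives 1 + 1/2 = 1.5 > clique 1's 0.5
    expect_equal(row$go_score, 1.5)
    expect_equal(row$clique_id, 2L)
})

test_that("original scores in target cliques are at least 1", {
    sim <- simulateScenario(scenarioSpec(seed = 55,
                                         targetMode = "annotated"))
    res <- enrichTarget(sim$planted$truthCliques, sim$ann, sim$dag)
    orig <- res$assignments[res$assignments$status == "original", ]
    expect_gt(nrow(orig), 0L)
    expect_true(all(orig$go_score >= 1))
})

test_that("score histogram separates original from new terms", {
    a <- data.frame(gene = "g", go_id = sprintf("GO:%07d", 1:6),
                    clique_id = 1L,
                    go_score = c(1.0, 2.5, 4.3, 0.6, 0.6, 1.2),
                    status = c("original", "original", "original",
                               "accepted", "accepted", "accepted"))
    h <- scoreHistogram(a)
    expect_equal(unname(rowSums(h)), c(3L, 3L))
    expect_equal(unname(h["new", "(0.5,1]"]), 2L)
    expect_equal(unname(h["original", "(4,4.5]"]), 1L)
    expect_equal(sum(scoreHistogram(a[0L, ])), 0L)
})

test_that("enrichment output is deterministic across reruns", {
    sim <- simulateScenario(scenarioSpec(seed = 77))
    r1 <- enrichTarget(sim$planted$truthCliques, sim$ann, sim$dag)
    r2 <- enrichTarget(sim$planted$truthCliques, sim$ann, sim$dag)
    expect_identical(r1, r2)
})
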