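## Shared fixtures and independent brute-force oracles.

## --- tiny hand-built ontologies -------------------------------------

## chain: c -> b -> root (one namespace); plus minimal cc/mf if asked
chainDAG <- function() {
    terms <- data.frame(
        id = c("GO:0000001", "GO:0000002", "GO:0000003"),
        name = c("root", "b", "c"),
        namespace = "biological_process",
        obsolete = FALSE, replaced_by = NA_character_,
        stringsAsFactors = FALSE)
    parents <- list("GO:0000001" = character(0),
                    "GO:0000002" = "GO:0000001",
                    "GO:0000003" = "GO:0000002")
    new("OntologyDAG", terms = terms, parents = parents,
        roots = c(biological_process = "GO:0000001"))
}

## diamond: d -> {b, c} -> root, plus a long route d -> x -> y -> root
diamondDAG <- function(longRoute = FALSE) {
    ids <- c("GO:0000001", "GO:0000002", "GO:0000003", "GO:0000004")
    parents <- list("GO:0000001" = character(0),
                    "GO:0000002" = "GO:0000001",
                    "GO:0000003" = "GO:0000001",
                    "GO:0000004" = c("GO:0000002", "GO:0000003"))
    if (longRoute) {
        ids <- c(ids, "GO:0000005", "GO:0000006")
        parents[["GO:0000005"]] <- "GO:0000001"        # y
        parents[["GO:0000006"]] <- "GO:0000005"        # x
        parents[["GO:0000004"]] <- c(parents[["GO:0000004"]],
                                     "GO:0000006")
    }
    terms <- data.frame(id = ids, name = ids,
                        namespace = "biological_process",
                        obsolete = FALSE, replaced_by = NA_character_,
                        stringsAsFactors = FALSE)
    new("OntologyDAG", terms = terms, parents = parents,
        roots = c(biological_process = "GO:0000001"))
}

## random single-namespace DAG: term i > 1 draws parents among earlier
## terms, so the graph is acyclic and rooted by construction
randomDAG <- function(n, seed) {
    set.seed(seed)
    ids <- sprintf("GO:%07d", seq_len(n))
    parents <- list()
    parents[[ids[1L]]] <- character(0)
    for (i in 2L:n) {
        np <- sample.int(min(3L, i - 1L), 1L)
        parents[[ids[i]]] <- sample(ids[seq_len(i - 1L)], np)
    }
    terms <- data.frame(id = ids, name = ids,
                        namespace = "biological_process",
                        obsolete = FALSE, replaced_by = NA_character_,
                        stringsAsFactors = FALSE)
    new("OntologyDAG", terms = terms, parents = parents,
        roots = c(biological_process = ids[1L]))
}

## oracle: ancestors by naive recursive DFS (independent of the BFS in
## the package)
bfAncestors <- function(dag, id) {
    seen <- character(0)
    rec <- function(x) {
        for (p in dag@parents[[x]]) if (!p %in% seen) {
            seen <<- c(seen, p)
            rec(p)
        }
    }
    rec(id)
    sort(seen)
}

## oracle: shortest path to root by exhaustive path enumeration
bfDepth <- function(dag, id, root) {
    if (id == root) return(0L)
    best <- Inf
    rec <- function(x, d) {
        if (x == root) { best <<- min(best, d); return(invisible()) }
        for (p in dag@parents[[x]]) rec(p, d + 1L)
    }
    rec(id, 0L)
    as.integer(best)
}

## --- multipartite graphs and the exhaustive clique oracle -----------

randomMultipartite <- function(seed, maxNodes = 12L, p = 0.45) {
    set.seed(seed)
    nsp <- sample(3:5, 1L)
    per <- sample(1:3, nsp, replace = TRUE)
    while (sum(per) > maxNodes) per[which.max(per)] <-
        per[which.max(per)] - 1L
    species <- rep(sprintf("S%d", seq_len(nsp)), per)
    genes <- data.frame(gene = sprintf("%s_G%04d", species,
                                       seq_along(species)),
                        species = species, stringsAsFactors = FALSE)
    combos <- t(combn(nrow(genes), 2L))
    cross <- species[combos[, 1L]] != species[combos[, 2L]]
    pick <- cross & stats::runif(nrow(combos)) < p
    edges <- data.frame(
        gene_a = pmin(genes$gene[combos[pick, 1L]],
                      genes$gene[combos[pick, 2L]]),
        gene_b = pmax(genes$gene[combos[pick, 1L]],
                      genes$gene[combos[pick, 2L]]),
        stringsAsFactors = FALSE)
    pairs <- data.frame(species_a = genes$species[match(edges$gene_a,
                                                        genes$gene)],
                        gene_a = edges$gene_a,
                        species_b = genes$species[match(edges$gene_b,
                                                        genes$gene)],
                        gene_b = edges$gene_b,
                        stringsAsFactors = FALSE)
    orthologGraph(pairs)
}

## oracle: every clique of size >= minSize by exhaustive subset
## enumeration over the adjacency matrix; maximal filter by pairwise
## containment over the full clique list
bfCliques <- function(graph, minSize = 3L, maximal = TRUE) {
    genes <- orthoGenes(graph)$gene
    n <- length(genes)
    adj <- matrix(FALSE, n, n, dimnames = list(genes, genes))
    e <- orthoEdges(graph)
    adj[cbind(e$gene_a, e$gene_b)] <- TRUE
    adj[cbind(e$gene_b, e$gene_a)] <- TRUE
    found <- list()
    for (k in seq(minSize, n)) {
        if (k > n) break
        for (idx in utils::combn(n, k, simplify = FALSE)) {
            sub <- adj[idx, idx, drop = FALSE]
            if (all(sub[upper.tri(sub)]))
                found[[length(found) + 1L]] <- sort(genes[idx])
        }
    }
    if (maximal && length(found)) {
        keep <- vapply(found, function(cl)
            !any(vapply(found, function(other)
                length(other) > length(cl) && all(cl %in% other),
                logical(1))), logical(1))
        found <- found[keep]
    }
    found[order(vapply(found, paste, "", collapse = "|"))]
}

canonCliqueSet <- function(cliques)
    sort(unname(vapply(cliques, function(x) paste(sort(unname(x)),
                                                  collapse = "|"),
                       character(1))))

## small annotation map from species/gene/term triplets
annFrom <- function(...) {
    rows <- list(...)
    annotationMap(do.call(rbind, lapply(rows, function(r)
        data.frame(species = r[[1L]], gene = r[[2L]],
                   go_id = r[[3L]], stringsAsFactors = FALSE))))
}

## a toy clique over the default ten plant species, one gene each
plantClique <- function(groups = defaultPlantGroups()) {
    setNames(paste0(groups$species, "_G0001"), groups$species)
}
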