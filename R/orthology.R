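#' Read a BLAST tabular (outfmt 6) hit file
#'
#' Twelve tab-separated columns, no header: qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore. Rows with a
#' non-numeric e-value or bitscore are reported with their line number.
#'
#' @param path file path.
#' @return data.frame of hits with the standard column names.
#' @export
readBlastTab <- function(path) {
    cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
              "gapopen", "qstart", "qend", "sstart", "send",
              "evalue", "bitscore")
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (!length(lines))
        return(setNames(data.frame(character(0), character(0), numeric(0),
                                   integer(0), integer(0), integer(0),
                                   integer(0), integer(0), integer(0),
                                   integer(0), numeric(0), numeric(0),
                                   stringsAsFactors = FALSE), cols))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf < 12L))
        stop(sprintf("%s line %d: expected 12 tab-separated columns",
                     path, which(nf < 12L)[1L]), call. = FALSE)
    m <- do.call(rbind, lapply(parts, `[`, seq_len(12L)))
    ev <- suppressWarnings(as.numeric(m[, 11L]))
    bs <- suppressWarnings(as.numeric(m[, 12L]))
    if (anyNA(ev) || anyNA(bs))
        stop(sprintf("%s line %d: non-numeric evalue/bitscore",
                     path, which(is.na(ev) | is.na(bs))[1L]),
             call. = FALSE)
    data.frame(qseqid = m[, 1L], sseqid = m[, 2L],
               pident = as.numeric(m[, 3L]),
               length = as.integer(m[, 4L]),
               mismatch = as.integer(m[, 5L]),
               gapopen = as.integer(m[, 6L]),
               qstart = as.integer(m[, 7L]), qend = as.integer(m[, 8L]),
               sstart = as.integer(m[, 9L]), send = as.integer(m[, 10L]),
               evalue = ev, bitscore = bs, stringsAsFactors = FALSE)
}

#' Pick the longest transcript per gene
#'
#' Mirrors the pre-processing step in which only the longest transcript
#' of each gene enters the pairwise similarity searches. Ties break to
#' the lexicographically smallest transcript id, so the choice is
#' deterministic.
#'
#' @param transcripts data.frame with columns \code{gene},
#'   \code{transcript}, \code{length} (positive).
#' @return Named character vector: gene -> chosen transcript id.
#' @export
selectLongestTranscript <- function(transcripts) {
    stopifnot(all(c("gene", "transcript", "length") %in%
                  names(transcripts)))
    if (!nrow(transcripts)) return(setNames(character(0), character(0)))
    if (any(transcripts$length <= 0))
        stop("transcript lengths must be positive", call. = FALSE)
    empty <- tapply(transcripts$transcript, transcripts$gene, length) == 0L
    if (any(empty))
        stop(sprintf("gene %s has no transcripts",
                     names(empty)[empty][1L]), call. = FALSE)
    o <- order(transcripts$gene, -transcripts$length,
               transcripts$transcript)
    t <- transcripts[o, ]
    keep <- !duplicated(t$gene)
    setNames(t$transcript[keep], t$gene[keep])
}

#' Best hit per query under an e-value cutoff
#'
#' Hits with e-value above the cutoff are discarded (the cutoff is
#' inclusive: \code{evalue <= cutoff} survives). Multiple HSP rows for
#' one (query, subject) pair are collapsed to the best-bitscore row
#' first. Per query the single best subject is kept under the tie-break
#' cascade highest bitscore, then lowest e-value, then lexicographically
#' smallest subject id. Queries with no surviving hit are absent.
#'
#' @param hits data.frame as from [readBlastTab()].
#' @param evalueCutoff inclusive e-value threshold, default \code{1e-5}.
#' @return Named character vector: query -> best subject.
#' @export
bestHits <- function(hits, evalueCutoff = 1e-5) {
    stopifnot(evalueCutoff > 0)
    h <- hits[hits$evalue <= evalueCutoff, , drop = FALSE]
    if (!nrow(h)) return(setNames(character(0), character(0)))
    ## collapse HSPs: best bitscore (then lowest evalue) per (q, s)
    o <- order(h$qseqid, h$sseqid, -h$bitscore, h$evalue)
    h <- h[o, ]
    h <- h[!duplicated(paste0(h$qseqid, "\r", h$sseqid)), ]
    ## best subject per query
    o <- order(h$qseqid, -h$bitscore, h$evalue, h$sseqid)
    h <- h[o, ]
    h <- h[!duplicated(h$qseqid), ]
    setNames(h$sseqid, h$qseqid)
}

#' Reciprocal best hits between two species
#'
#' A pair (a, b) is kept iff b is a's best hit in the forward direction
#' and a is b's best hit in the reverse direction; the result is a
#' partial matching (each gene occurs at most once).
#'
#' @param forward named vector, A-query -> best B-subject.
#' @param reverse named vector, B-query -> best A-subject.
#' @return data.frame with columns \code{gene_a}, \code{gene_b}, sorted
#'   by \code{gene_a}.
#' @export
reciprocalBestHits <- function(forward, reverse) {
    a <- names(forward)
    keep <- !is.na(reverse[forward]) & reverse[forward] == a
    keep[is.na(keep)] <- FALSE
    out <- data.frame(gene_a = a[keep],
                      gene_b = unname(forward[keep]),
                      stringsAsFactors = FALSE)
    out[order(out$gene_a), , drop = FALSE]
}

#' Lift transcript-level pairs to gene level
#'
#' DNA reciprocal best hits are computed on transcripts; this maps both
#' columns through a transcript-to-gene table before evidence
#' intersection. Ids already at gene level pass through unchanged.
#'
#' @param pairs data.frame with \code{gene_a}, \code{gene_b}.
#' @param tx2gene named character vector transcript -> gene, or NULL for
#'   the default id scheme in which \code{GENE.Tk} lifts to \code{GENE}.
#' @return data.frame of gene-level pairs, duplicates collapsed.
#' @export
liftTranscripts <- function(pairs, tx2gene = NULL) {
    lift <- function(x) {
        if (is.null(tx2gene)) return(sub("\\.T[0-9]+$", "", x))
        y <- tx2gene[x]
        ifelse(is.na(y), x, unname(y))
    }
    out <- data.frame(gene_a = lift(pairs$gene_a),
                      gene_b = lift(pairs$gene_b),
                      stringsAsFactors = FALSE)
    out <- unique(out)
    out[order(out$gene_a), , drop = FALSE]
}

#' Intersect DNA and protein orthology evidence
#'
#' Only pairs supported by both the DNA and the protein reciprocal best
#' hits survive; disagreeing predictions are dismissed. The result is
#' symmetric in argument order and a subset of each input.
#'
#' @param dnaPairs,proteinPairs data.frames with \code{gene_a},
#'   \code{gene_b} (gene level).
#' @return data.frame \code{gene_a}, \code{gene_b}, \code{evidence}
#'   (always \code{"both"}).
#' @export
intersectEvidence <- function(dnaPairs, proteinPairs) {
    key <- function(p) paste0(p$gene_a, "\r", p$gene_b)
    keep <- dnaPairs[key(dnaPairs) %in% key(proteinPairs), , drop = FALSE]
    keep <- unique(keep)
    keep <- keep[order(keep$gene_a), , drop = FALSE]
    rownames(keep) <- NULL
    if (nrow(keep)) keep$evidence <- "both"
    else keep$evidence <- character(0)
    keep
}

#' Canonical cross-species ortholog pair table
#'
#' Attaches species labels and stores each pair with species in
#' lexicographic order, so downstream set operations need no orientation
#' logic. Within-species pairs are dropped with a warning.
#'
#' @param pairs data.frame \code{gene_a}, \code{gene_b} (plus optional
#'   \code{evidence}).
#' @param speciesA,speciesB species ids for the two columns.
#' @return data.frame \code{species_a}, \code{gene_a}, \code{species_b},
#'   \code{gene_b}, \code{evidence}.
#' @export
canonicalPairs <- function(pairs, speciesA, speciesB) {
    if (speciesA == speciesB) {
        warning("within-species pairs ignored")
        pairs <- pairs[0L, , drop = FALSE]
    }
    ev <- if ("evidence" %in% names(pairs)) pairs$evidence
          else rep("both", nrow(pairs))
    flip <- speciesA > speciesB
    n <- nrow(pairs)
    out <- data.frame(
        species_a = rep_len(if (flip) speciesB else speciesA, n),
        gene_a = if (flip) pairs$gene_b else pairs$gene_a,
        species_b = rep_len(if (flip) speciesA else speciesB, n),
        gene_b = if (flip) pairs$gene_a else pairs$gene_b,
        evidence = ev, stringsAsFactors = FALSE)
    out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

#' Run RBBH + evidence intersection over a manifest of hit files
#'
#' The manifest lists one row per directed species pair and sequence
#' type: columns \code{species_a}, \code{species_b}, \code{seqtype}
#' (\code{dna}/\code{protein}), \code{forward_file}, \code{reverse_file}.
#' DNA pairs are lifted to gene level (see [liftTranscripts()]) before
#' intersection with the protein pairs.
#'
#' @param manifest data.frame as above, or path to a TSV of it.
#' @param evalueCutoff inclusive e-value threshold, default \code{1e-5}.
#' @param tx2gene optional transcript-to-gene map for the DNA lift.
#' @param dir directory against which relative file paths resolve.
#' @return data.frame of canonical ortholog pairs across all species
#'   pairs (columns as [canonicalPairs()]).
#' @export
rbbhPipeline <- function(manifest, evalueCutoff = 1e-5, tx2gene = NULL,
                         dir = ".") {
    if (is.character(manifest)) manifest <- readTSV(manifest)
    need <- c("species_a", "species_b", "seqtype", "forward_file",
              "reverse_file")
    stopifnot(all(need %in% names(manifest)))
    resolve <- function(f)
        ifelse(file.exists(f), f, file.path(dir, f))
    pairKey <- paste(manifest$species_a, manifest$species_b)
    out <- list()
    for (k in unique(pairKey)) {
        rows <- manifest[pairKey == k, , drop = FALSE]
        bySeq <- list()
        for (st in c("dna", "protein")) {
            r <- rows[rows$seqtype == st, , drop = FALSE]
            if (nrow(r) != 1L)
                stop(sprintf("species pair %s needs exactly one %s row",
                             k, st), call. = FALSE)
            fwd <- bestHits(readBlastTab(resolve(r$forward_file)),
                            evalueCutoff)
            rev <- bestHits(readBlastTab(resolve(r$reverse_file)),
                            evalueCutoff)
            p <- reciprocalBestHits(fwd, rev)
            if (st == "dna") p <- liftTranscripts(p, tx2gene)
            bySeq[[st]] <- p
        }
        both <- intersectEvidence(bySeq$dna, bySeq$protein)
        out[[k]] <- canonicalPairs(both, rows$species_a[1L],
                                   rows$species_b[1L])
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
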