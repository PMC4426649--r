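#' @importFrom utils head read.delim write.table packageVersion
#' @importFrom stats setNames
NULL

## Run `expr` under a fixed RNG seed without disturbing the caller's RNG
## stream. R's RNG state is global, so the previous .Random.seed (if any)
## is restored on exit.
withSeed <- function(seed, expr) {
    stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
    env <- globalenv()
    had <- exists(".Random.seed", envir = env, inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
    on.exit({
        if (had) assign(".Random.seed", old, envir = env)
        else if (exists(".Random.seed", envir = env, inherits = FALSE))
            rm(".Random.seed", envir = env)
    })
    set.seed(as.integer(seed))
    expr
}

## Derive a distinct child seed from a user seed and a small stream index,
## kept inside 32-bit integer range.
childSeed <- function(seed, stream) {
    (as.numeric(seed) * 1021L + 7919L * stream) %% 2147483587
}

isGOId <- function(x) grepl("^GO:[0-9]{7}$", x)

## Comment header recording provenance, prepended to every TSV the
## pipeline writes so reruns are self-describing and diff-clean.
provenanceHeader <- function(config = list()) {
    ver <- tryCatch(as.character(packageVersion("cliqueGO")),
                    error = function(e) "unknown")
    kv <- if (length(config))
        paste(names(config), vapply(config, function(v)
            paste(as.character(v), collapse = ","), character(1)),
            sep = "=", collapse = " ")
    else ""
    c(sprintf("# cliqueGO %s", ver),
      if (nzchar(kv)) sprintf("# config: %s", kv))
}

writeTSV <- function(df, path, config = list()) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(provenanceHeader(config), con)
    write.table(df, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = TRUE)
    invisible(path)
}

readTSV <- function(path) {
    read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
               check.names = FALSE)
}
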