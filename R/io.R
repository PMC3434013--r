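# Readers and writers for the plain-text dialects the pipeline touches.
# All formats are TSV; comment lines start with "#" and runs of whitespace
# are accepted as delimiters (edge-list exports vary between sources).

readDataLines <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    lines <- readLines(path, warn = FALSE)
    keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
    list(lines = lines[keep], lineno = which(keep))
}

splitFields <- function(lines) strsplit(trimws(lines), "[\t ]+")

#' Read a protein-protein interaction edge list
#'
#' Parses a two-column (optionally three-column, with weights) tab- or
#' whitespace-delimited edge list into an [InteractionNetwork-class].
#' Duplicate edges (in either orientation) are collapsed, self-loops are
#' dropped, and the result is independent of line order.
#'
#' @param path path to the edge list.
#' @param weighted logical; read a third numeric weight column. Unweighted
#'   input gets weight 1.0 so all downstream formulas are written once in
#'   weighted form.
#' @param quiet suppress the parse summary message.
#' @return an [InteractionNetwork-class].
#' @export
#' @examples
#' f <- tempfile()
#' writeLines(c("A\tB", "B\tC"), f)
#' readPPIEdgelist(f)
readPPIEdgelist <- function(path, weighted = FALSE, quiet = FALSE) {
    dat <- readDataLines(path)
    if (length(dat$lines) == 0) stop("empty edge list: ", path, call. = FALSE)
    fields <- splitFields(dat$lines)
    need <- if (weighted) 3L else 2L
    bad <- which(lengths(fields) < need)
    if (length(bad) > 0)
        stop(sprintf("malformed line %d in %s: expected >= %d columns",
                     dat$lineno[bad[1]], path, need), call. = FALSE)
    from <- vapply(fields, `[`, character(1), 1L)
    to <- vapply(fields, `[`, character(1), 2L)
    weight <- if (weighted) {
        w <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3L)))
        if (anyNA(w))
            stop(sprintf("malformed line %d in %s: non-numeric weight",
                         dat$lineno[which(is.na(w))[1]], path), call. = FALSE)
        w
    } else rep(1, length(from))
    selfLoops <- sum(trimws(from) == trimws(to))
    net <- interactionNetwork(data.frame(from = from, to = to, weight = weight,
                                         stringsAsFactors = FALSE))
    dropped <- length(from) - numInteractions(net)
    if (!quiet)
        message(sprintf("read %d proteins, %d interactions from %s (%d input lines, %d dropped: %d self-loops, %d duplicates)",
                        numProteins(net), numInteractions(net), basename(path),
                        length(from), dropped, selfLoops, dropped - selfLoops))
    net
}

#' Write an interaction network as an edge list
#'
#' @param net an [InteractionNetwork-class].
#' @param path output path.
#' @param weighted include the weight column.
#' @return `path`, invisibly.
#' @export
writePPIEdgelist <- function(net, path, weighted = FALSE) {
    ed <- interactions(net)
    lines <- if (weighted) paste(ed$from, ed$to, format(ed$weight), sep = "\t")
             else paste(ed$from, ed$to, sep = "\t")
    iso <- setdiff(proteins(net), c(ed$from, ed$to))
    if (length(iso) > 0)
        lines <- c(lines, paste0("# isolated: ", paste(iso, collapse = ";")))
    writeLines(lines, path)
    invisible(path)
}

#' Read a time-course expression matrix
#'
#' Expects a header row `gene<TAB>t1...tk` and one row per gene. The token
#' `NA` (or an empty cell) marks a missing measurement; missing values are
#' treated downstream as never exceeding the activity threshold. Duplicate
#' gene rows keep the first occurrence with a warning.
#'
#' @param path path to the TSV file.
#' @param naToken string marking missing values (default "NA").
#' @return an [ExpressionSeries-class].
#' @export
readExpressionMatrix <- function(path, naToken = "NA") {
    dat <- readDataLines(path)
    if (length(dat$lines) < 2)
        stop("expression file needs a header and at least one gene row: ",
             path, call. = FALSE)
    header <- strsplit(dat$lines[1], "\t", fixed = TRUE)[[1]]
    k <- length(header) - 1L
    if (k < 1) stop("expression header must list at least one time point",
                    call. = FALSE)
    body <- strsplit(dat$lines[-1], "\t", fixed = TRUE)
    bad <- which(lengths(body) != k + 1L)
    if (length(bad) > 0)
        stop(sprintf("malformed line %d in %s: expected %d columns",
                     dat$lineno[-1][bad[1]], path, k + 1L), call. = FALSE)
    ids <- trimws(vapply(body, `[`, character(1), 1L))
    vals <- matrix(NA_real_, nrow = length(body), ncol = k)
    for (i in seq_along(body)) {
        cell <- trimws(body[[i]][-1])
        miss <- cell == naToken | cell == ""
        num <- suppressWarnings(as.numeric(cell))
        if (any(is.na(num) & !miss))
            stop(sprintf("non-numeric expression value on line %d in %s",
                         dat$lineno[-1][i], path), call. = FALSE)
        num[miss] <- NA_real_
        vals[i, ] <- num
    }
    if (anyDuplicated(ids)) {
        warning("duplicate gene IDs in ", basename(path),
                "; keeping the first occurrence", call. = FALSE)
        keep <- !duplicated(ids)
        ids <- ids[keep]; vals <- vals[keep, , drop = FALSE]
    }
    rownames(vals) <- ids
    colnames(vals) <- trimws(header[-1])
    expressionSeries(vals)
}

#' Write an expression series
#'
#' @param expr an [ExpressionSeries-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(expr, path) {
    v <- exprValues(expr)
    header <- paste(c("gene", colnames(v)), collapse = "\t")
    rows <- vapply(seq_len(nrow(v)), function(i)
        paste(c(rownames(v)[i], ifelse(is.na(v[i, ]), "NA",
                                       sprintf("%.15g", v[i, ]))),
              collapse = "\t"), character(1))
    writeLines(c(header, rows), path)
    invisible(path)
}

#' Read a complex catalogue
#'
#' One complex per line. Two dialects are accepted:
#' \itemize{
#'   \item `id<TAB>members` (gold-standard catalogues; members
#'     semicolon-separated),
#'   \item `id<TAB>frequency<TAB>times<TAB>members` (discovery output; times
#'     comma-separated TSN indices).
#' }
#' Duplicate members within a line are collapsed; duplicate complex IDs are
#' an error.
#'
#' @param path path to the TSV file.
#' @return a [ComplexCatalog-class].
#' @export
readComplexCatalog <- function(path) {
    dat <- readDataLines(path)
    if (length(dat$lines) == 0) stop("empty catalogue: ", path, call. = FALSE)
    body <- strsplit(dat$lines, "\t", fixed = TRUE)
    n <- lengths(body)
    if (any(n != 2 & n != 4))
        stop(sprintf("malformed line %d in %s: expected 2 or 4 columns",
                     dat$lineno[which(n != 2 & n != 4)[1]], path), call. = FALSE)
    ids <- trimws(vapply(body, `[`, character(1), 1L))
    if (anyDuplicated(ids))
        stop(sprintf("duplicate complex ID '%s' on line %d in %s",
                     ids[which(duplicated(ids))[1]],
                     dat$lineno[which(duplicated(ids))[1]], path), call. = FALSE)
    memCol <- ifelse(n == 2, 2L, 4L)
    memberStr <- trimws(mapply(`[`, body, memCol))
    membersList <- lapply(strsplit(memberStr, ";", fixed = TRUE),
                          function(m) unique(trimws(m[nzchar(trimws(m))])))
    empty <- which(lengths(membersList) == 0)
    if (length(empty) > 0)
        stop(sprintf("empty member list on line %d in %s",
                     dat$lineno[empty[1]], path), call. = FALSE)
    times <- lapply(seq_along(body), function(i) {
        if (n[i] == 2) return(integer(0))
        t <- trimws(body[[i]][3])
        if (!nzchar(t)) return(integer(0))
        as.integer(strsplit(t, ",", fixed = TRUE)[[1]])
    })
    freq <- vapply(seq_along(body), function(i) {
        if (n[i] == 2) return(0L)
        as.integer(body[[i]][2])
    }, integer(1))
    complexCatalog(ids, membersList, times, freq)
}

#' @describeIn writeClusters writes `id`, `frequency`, comma-separated
#'   `times` and semicolon-separated `members` (gold-standard catalogues
#'   without recorded times fall back to the two-column dialect). Entries
#'   are ordered by ID so the output is deterministic and round-trips
#'   through [readComplexCatalog()].
#' @export
setMethod("writeClusters", "ComplexCatalog", function(x, path, ...) {
    if (length(x) == 0) stop("refusing to write an empty catalogue", call. = FALSE)
    ord <- order(x@ids)
    hasTimes <- any(lengths(x@activeTimes) > 0)
    lines <- vapply(ord, function(i) {
        mem <- paste(sort(x@members[[i]]), collapse = ";")
        if (hasTimes)
            paste(x@ids[i], x@frequency[i],
                  paste(x@activeTimes[[i]], collapse = ","), mem, sep = "\t")
        else paste(x@ids[i], mem, sep = "\t")
    }, character(1))
    header <- if (hasTimes) "# id\tfrequency\ttimes\tmembers" else "# id\tmembers"
    writeLines(c(header, lines), path)
    invisible(path)
})

#' @describeIn writeClusters writes one module per line: `id`, modularity,
#'   number of complexes, semicolon-separated complex IDs and the
#'   semicolon-separated protein union.
#' @export
setMethod("writeClusters", "ModuleSet", function(x, path, ...) {
    if (length(x) == 0) stop("refusing to write an empty module set", call. = FALSE)
    ord <- order(x@ids)
    lines <- vapply(ord, function(i)
        paste(x@ids[i], format(x@modularity[i], digits = 10),
              length(x@complexIds[[i]]),
              paste(sort(x@complexIds[[i]]), collapse = ";"),
              paste(sort(x@proteins[[i]]), collapse = ";"), sep = "\t"),
        character(1))
    writeLines(c("# id\tmodularity\tn_complexes\tcomplexes\tproteins", lines),
               path)
    invisible(path)
})

#' Read a module file back as protein sets
#'
#' Parses the five-column module dialect written by
#' [writeClusters()] for [ModuleSet-class] objects and returns the protein
#' unions, which is what enrichment screening needs.
#'
#' @param path path to a `modules.tsv` file.
#' @return named list of character vectors (protein union per module ID).
#' @export
readModuleProteins <- function(path) {
    dat <- readDataLines(path)
    if (length(dat$lines) == 0) stop("empty module file: ", path, call. = FALSE)
    body <- strsplit(dat$lines, "\t", fixed = TRUE)
    bad <- which(lengths(body) != 5)
    if (length(bad) > 0)
        stop(sprintf("malformed line %d in %s: expected 5 columns",
                     dat$lineno[bad[1]], path), call. = FALSE)
    ids <- vapply(body, `[`, character(1), 1L)
    prots <- lapply(body, function(b)
        unique(trimws(strsplit(b[5], ";", fixed = TRUE)[[1]])))
    setNames(prots, ids)
}

#' Read a gene-to-term annotation map
#'
#' Two-column TSV `gene<TAB>term`, one annotation per line; the background
#' defaults to the set of annotated genes and may be widened with `extra`.
#'
#' @param path path to the TSV file.
#' @param extra additional (unannotated) genes to include in the background.
#' @return an [AnnotationMap-class].
#' @export
readAnnotationMap <- function(path, extra = character()) {
    dat <- readDataLines(path)
    if (length(dat$lines) == 0) stop("empty annotation map: ", path, call. = FALSE)
    fields <- splitFields(dat$lines)
    bad <- which(lengths(fields) < 2)
    if (length(bad) > 0)
        stop(sprintf("malformed line %d in %s: expected 2 columns",
                     dat$lineno[bad[1]], path), call. = FALSE)
    gene <- vapply(fields, `[`, character(1), 1L)
    term <- vapply(fields, `[`, character(1), 2L)
    annotationMap(split(term, gene),
                  background = unique(c(gene, trimws(as.character(extra)))))
}

#' Write an annotation map
#'
#' @param ann an [AnnotationMap-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAnnotationMap <- function(ann, path) {
    genes <- sort(names(ann@gene2terms))
    lines <- unlist(lapply(genes, function(g)
        paste(g, sort(ann@gene2terms[[g]]), sep = "\t")))
    writeLines(lines, path)
    invisible(path)
}
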