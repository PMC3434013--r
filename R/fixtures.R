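# Synthetic study generator: a static network with planted clique-like
# complexes and Erdos-Renyi background noise, plus a time-course expression
# matrix giving every planted complex a known contiguous activity window.
# Everything downstream of the readers can be exercised with these
# fixtures; no external downloads are required.

#' Describe a synthetic study
#'
#' Defaults describe the package's reference study conditions: 10 planted
#' complexes of sizes 4-8 (exact cliques), 100 background proteins,
#' background/noise edge probability 0.02, 30 time points with contiguous
#' activity windows of length 3-6, expression levels 1.0/0.3 straddling the
#' 0.7 activity threshold with +/-0.05 jitter, and 2 "process variant"
#' twins. A variant twin of a planted complex shares all members but one
#' (plus one new protein) and is active in the directly adjacent time
#' window; twins are what give the complex-complex network its edges, and
#' each original+twin pair shares a synthetic process annotation term.
#' Background proteins receive their own random activity windows so that
#' noise edges actually surface inside TSNs.
#'
#' @param nBackground number of background proteins (default 100).
#' @param nComplexes number of planted complexes (default 10).
#' @param sizeRange complex size range (default c(4, 8)).
#' @param intraEdgeP within-complex edge probability (default 1.0).
#' @param backgroundEdgeP noise edge probability (default 0.02).
#' @param k number of time points (default 30).
#' @param windows optional list of per-complex contiguous windows; drawn at
#'   random when omitted.
#' @param windowLength random window length range (default c(3, 6)).
#' @param exprHigh,exprLow in/out-of-window expression levels (defaults 1.0
#'   and 0.3).
#' @param jitter uniform jitter half-width (default 0.05); the jittered
#'   values never cross the threshold.
#' @param threshold activity threshold the fixture is designed around
#'   (default 0.7).
#' @param variantComplexes how many planted complexes get a variant twin
#'   (default 2).
#' @param seed RNG seed (default 1).
#' @return a [FixtureSpec-class].
#' @export
fixtureSpec <- function(nBackground = 100, nComplexes = 10,
                        sizeRange = c(4, 8), intraEdgeP = 1.0,
                        backgroundEdgeP = 0.02, k = 30, windows = list(),
                        windowLength = c(3, 6), exprHigh = 1.0,
                        exprLow = 0.3, jitter = 0.05, threshold = 0.7,
                        variantComplexes = 2, seed = 1) {
    methods::new("FixtureSpec",
                 nBackground = as.integer(nBackground),
                 nComplexes = as.integer(nComplexes),
                 sizeRange = as.integer(sizeRange),
                 intraEdgeP = as.numeric(intraEdgeP),
                 backgroundEdgeP = as.numeric(backgroundEdgeP),
                 k = as.integer(k), windows = windows,
                 windowLength = as.integer(windowLength),
                 exprHigh = as.numeric(exprHigh),
                 exprLow = as.numeric(exprLow),
                 jitter = as.numeric(jitter),
                 threshold = as.numeric(threshold),
                 variantComplexes = as.integer(variantComplexes),
                 seed = as.integer(seed))
}

.withSeed <- function(seed, expr) {
    hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (hadSeed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (hadSeed) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

# sample() that never falls into the 1:n trap for length-1 vectors
.sample1 <- function(x) if (length(x) == 1) x else sample(x, 1)

.randomWindow <- function(k, lenRange) {
    len <- .sample1(seq(min(lenRange[1], k), min(lenRange[2], k)))
    start <- .sample1(seq_len(k - len + 1))
    seq(start, start + len - 1)
}

#' Generate a synthetic study
#'
#' Builds the four inputs of the pipeline from a [fixtureSpec()]:
#' \itemize{
#'   \item the static [InteractionNetwork-class]: every planted complex is
#'     a clique with edge dropout `1 - intraEdgeP`; every other protein
#'     pair is a noise edge with probability `backgroundEdgeP`;
#'   \item the [ExpressionSeries-class]: each protein scores
#'     `exprHigh +/- jitter` inside its activity window(s) and
#'     `exprLow +/- jitter` outside (a protein in several complexes is
#'     active in the union of their windows); background proteins get their
#'     own random windows;
#'   \item the ground-truth [ComplexCatalog-class] recording members and
#'     activity windows of every planted complex (variants included);
#'   \item an [AnnotationMap-class] with one synthetic process term per
#'     planted group (an original and its variant twin share the term) and
#'     a catch-all term for background proteins; the background universe is
#'     all proteins.
#' }
#' Output is byte-identical for a fixed spec (the global RNG state is left
#' untouched).
#'
#' @param spec a [FixtureSpec-class].
#' @return list with elements `network`, `expression`, `truth`,
#'   `annotations`, and `spec`.
#' @export
#' @examples
#' fx <- generateFixture(fixtureSpec(nComplexes = 2, nBackground = 0,
#'     sizeRange = c(4, 4), backgroundEdgeP = 0, k = 6,
#'     windows = list(1:3, 4:6), variantComplexes = 0))
#' fx$truth
generateFixture <- function(spec) {
    stopifnot(methods::is(spec, "FixtureSpec"))
    methods::validObject(spec)
    .withSeed(spec@seed, {
        sizeChoices <- seq(spec@sizeRange[1], spec@sizeRange[2])
        sizes <- if (length(sizeChoices) == 1)
            rep(sizeChoices, spec@nComplexes)
        else sample(sizeChoices, spec@nComplexes, replace = TRUE)
        total <- sum(sizes)
        pool <- sprintf("P%03d", seq_len(total))
        memberIdx <- split(seq_len(total), rep(seq_len(spec@nComplexes), sizes))
        complexes <- lapply(memberIdx, function(i) pool[i])
        windows <- if (length(spec@windows) > 0) spec@windows
                   else lapply(seq_len(spec@nComplexes), function(i)
                       .randomWindow(spec@k, spec@windowLength))
        group <- seq_len(spec@nComplexes)

        # process-variant twins: same members minus one, plus one new
        # protein, active in the window directly adjacent to the original
        nextProt <- total
        if (spec@variantComplexes > 0) {
            for (i in seq_len(spec@variantComplexes)) {
                base <- complexes[[i]]
                nextProt <- nextProt + 1L
                newP <- sprintf("P%03d", nextProt)
                twin <- sort(c(base[-length(base)], newP))
                w <- windows[[i]]
                len <- length(w)
                afterLen <- min(len, spec@k - max(w))
                beforeLen <- min(len, min(w) - 1)
                twinWin <- if (afterLen >= 1)
                    seq(max(w) + 1, max(w) + afterLen)
                else if (beforeLen >= 1)
                    seq(min(w) - beforeLen, min(w) - 1)
                else stop("infeasible spec: no room for a variant window ",
                          "next to complex ", i, call. = FALSE)
                complexes <- c(complexes, list(twin))
                windows <- c(windows, list(twinWin))
                group <- c(group, i)
            }
        }
        nPlanted <- length(complexes)
        complexProteins <- sort(unique(unlist(complexes)))
        background <- if (spec@nBackground > 0)
            sprintf("B%03d", seq_len(spec@nBackground)) else character(0)
        allProteins <- c(complexProteins, background)

        # intra-complex edges (clique with dropout), then background noise
        # over every pair not inside a common complex
        edgeKeys <- new.env(parent = emptyenv())
        from <- character(0); to <- character(0)
        addEdge <- function(a, b) {
            key <- paste(min(a, b), max(a, b), sep = "\r")
            if (is.null(edgeKeys[[key]])) {
                edgeKeys[[key]] <- TRUE
                from <<- c(from, min(a, b)); to <<- c(to, max(a, b))
            }
        }
        inCommon <- new.env(parent = emptyenv())
        for (cm in complexes) {
            pr <- sort(cm)
            for (a in seq_len(length(pr) - 1))
                for (b in seq(a + 1, length(pr))) {
                    inCommon[[paste(pr[a], pr[b], sep = "\r")]] <- TRUE
                    if (runif(1) <= spec@intraEdgeP) addEdge(pr[a], pr[b])
                }
        }
        if (spec@backgroundEdgeP > 0 && length(allProteins) > 1) {
            np <- length(allProteins)
            for (a in seq_len(np - 1))
                for (b in seq(a + 1, np)) {
                    pa <- allProteins[a]; pb <- allProteins[b]
                    if (!is.null(inCommon[[paste(min(pa, pb), max(pa, pb),
                                                 sep = "\r")]])) next
                    if (runif(1) <= spec@backgroundEdgeP) addEdge(pa, pb)
                }
        }
        network <- interactionNetwork(
            data.frame(from = from, to = to, stringsAsFactors = FALSE),
            proteins = allProteins)

        # per-protein activity times: union of windows of owning complexes;
        # background proteins draw their own window
        activeAt <- setNames(vector("list", length(allProteins)), allProteins)
        for (i in seq_len(nPlanted))
            for (p in complexes[[i]])
                activeAt[[p]] <- union(activeAt[[p]], windows[[i]])
        for (p in background)
            activeAt[[p]] <- .randomWindow(spec@k, spec@windowLength)

        vals <- matrix(0, nrow = length(allProteins), ncol = spec@k,
                       dimnames = list(allProteins, paste0("t", seq_len(spec@k))))
        for (p in allProteins) {
            lev <- ifelse(seq_len(spec@k) %in% activeAt[[p]],
                          spec@exprHigh, spec@exprLow)
            vals[p, ] <- lev + runif(spec@k, -spec@jitter, spec@jitter)
        }
        expression <- expressionSeries(vals)

        truth <- complexCatalog(
            ids = sprintf("T%03d", seq_len(nPlanted)),
            members = complexes,
            activeTimes = lapply(windows, as.integer))

        gene2terms <- lapply(seq_len(nPlanted), function(i)
            sprintf("GO:P%03d", group[i]))
        ann <- list()
        for (i in seq_len(nPlanted))
            for (p in complexes[[i]])
                ann[[p]] <- union(ann[[p]], gene2terms[[i]])
        for (p in background) ann[[p]] <- "GO:BACKGROUND"
        annotations <- annotationMap(ann, background = allProteins)

        list(network = network, expression = expression, truth = truth,
             annotations = annotations, spec = spec)
    })
}

#' Write a generated fixture to disk
#'
#' Writes the four files in the package's text dialects: `ppi.tsv`,
#' `expression.tsv`, `truth.tsv`, `annotations.tsv`.
#'
#' @param fixture result of [generateFixture()].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
writeFixture <- function(fixture, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writePPIEdgelist(fixture$network, file.path(dir, "ppi.tsv"))
    writeExpressionMatrix(fixture$expression, file.path(dir, "expression.tsv"))
    writeClusters(fixture$truth, file.path(dir, "truth.tsv"))
    writeAnnotationMap(fixture$annotations, file.path(dir, "annotations.tsv"))
    invisible(dir)
}
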