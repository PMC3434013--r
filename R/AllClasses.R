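#' @import methods
#' @importFrom stats runif setNames phyper p.adjust
#' @importFrom utils head
NULL

#' InteractionNetwork: an undirected, weighted protein interaction graph
#'
#' Thin S4 wrapper around a simple undirected \pkg{igraph} object. Vertices
#' are protein identifiers; edges are physical interactions with a positive
#' weight (1.0 for unweighted input). Self-loops and duplicate edges are
#' removed at construction, so every downstream formula can assume a simple
#' graph.
#'
#' @slot graph an undirected simple \pkg{igraph} graph with a `weight` edge
#'   attribute; vertex names are the protein IDs.
#'
#' @seealso [interactionNetwork()], [readPPIEdgelist()]
#' @export
setClass("InteractionNetwork", slots = c(graph = "ANY"))

setValidity("InteractionNetwork", function(object) {
    g <- object@graph
    if (!inherits(g, "igraph"))
        return("'graph' must be an igraph object")
    if (igraph::is_directed(g))
        return("interaction graph must be undirected")
    if (igraph::any_loop(g))
        return("interaction graph must not contain self-loops")
    if (igraph::any_multiple(g))
        return("interaction graph must not contain duplicated edges")
    if (is.null(igraph::V(g)$name))
        return("vertices must be named by protein ID")
    if (anyDuplicated(igraph::V(g)$name))
        return("protein IDs must be unique")
    w <- igraph::E(g)$weight
    if (igraph::ecount(g) > 0 && (is.null(w) || any(!is.finite(w)) || any(w <= 0)))
        return("all edge weights must be finite and > 0")
    TRUE
})

#' Construct an InteractionNetwork from an edge table
#'
#' Canonicalises the input: trims whitespace from IDs, drops self-loops,
#' collapses duplicate edges regardless of endpoint order (keeping the
#' maximum weight, so the result is independent of row order), and sorts
#' vertices and edges so that two inputs describing the same network yield
#' identical objects.
#'
#' @param edges a data.frame with columns `from`, `to` and optionally
#'   `weight` (default 1.0).
#' @param proteins optional character vector of additional protein IDs to
#'   keep as isolated vertices.
#' @return an [InteractionNetwork-class] object.
#' @export
#' @examples
#' net <- interactionNetwork(data.frame(from = c("A", "B"), to = c("B", "C")))
#' numProteins(net)
interactionNetwork <- function(edges = data.frame(from = character(), to = character()),
                               proteins = character()) {
    stopifnot(is.data.frame(edges), all(c("from", "to") %in% names(edges)))
    from <- trimws(as.character(edges$from))
    to <- trimws(as.character(edges$to))
    weight <- if ("weight" %in% names(edges)) as.numeric(edges$weight) else rep(1, length(from))
    keep <- from != to
    from2 <- pmin(from[keep], to[keep])
    to2 <- pmax(from[keep], to[keep])
    weight <- weight[keep]
    key <- paste(from2, to2, sep = "\r")
    if (anyDuplicated(key)) {
        weight <- vapply(split(weight, key), max, numeric(1))
        pair <- strsplit(names(weight), "\r", fixed = TRUE)
        from2 <- vapply(pair, `[`, character(1), 1L)
        to2 <- vapply(pair, `[`, character(1), 2L)
    }
    ord <- order(from2, to2)
    from2 <- from2[ord]; to2 <- to2[ord]; weight <- weight[ord]
    verts <- sort(unique(c(from2, to2, trimws(as.character(proteins)))))
    g <- igraph::graph_from_data_frame(
        data.frame(from = from2, to = to2, weight = weight,
                   stringsAsFactors = FALSE),
        directed = FALSE, vertices = verts)
    methods::new("InteractionNetwork", graph = g)
}

#' ExpressionSeries: a gene-by-time expression matrix
#'
#' Holds time-course expression values, one row per gene and one ordered
#' column per time point. Missing measurements are stored as `NA` and are
#' treated downstream as "never above the activity threshold".
#'
#' @slot values numeric matrix; rownames are gene IDs, colnames the ordered
#'   time-point labels.
#' @seealso [expressionSeries()], [readExpressionMatrix()]
#' @export
setClass("ExpressionSeries", slots = c(values = "matrix"))

setValidity("ExpressionSeries", function(object) {
    v <- object@values
    if (!is.numeric(v)) return("expression values must be numeric")
    if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
        return("rows must carry unique gene IDs")
    if (ncol(v) < 1) return("at least one time point is required")
    if (is.null(colnames(v))) return("columns must carry time-point labels")
    TRUE
})

#' Construct an ExpressionSeries
#'
#' @param values numeric matrix with gene rownames and time-point colnames.
#' @return an [ExpressionSeries-class] object.
#' @export
expressionSeries <- function(values) {
    methods::new("ExpressionSeries", values = as.matrix(values))
}

#' TSNSeries: the dynamic PPI network
#'
#' An ordered series of time-sequenced subnetworks (TSNs). TSN i is the
#' subgraph of the static network induced on the proteins whose expression
#' at time i clears the activity threshold; isolated active proteins are
#' retained as degree-0 vertices.
#'
#' @slot source the static [InteractionNetwork-class].
#' @slot tsns list of k [InteractionNetwork-class] subnetworks.
#' @slot activeSets list of k character vectors of active proteins.
#' @slot threshold the activity threshold used (expression units).
#' @seealso [buildTSNSeries()]
#' @export
setClass("TSNSeries",
         slots = c(source = "InteractionNetwork", tsns = "list",
                   activeSets = "list", threshold = "numeric"))

setValidity("TSNSeries", function(object) {
    if (length(object@tsns) != length(object@activeSets))
        return("one active set is required per TSN")
    src <- proteins(object@source)
    for (i in seq_along(object@tsns)) {
        tsn <- object@tsns[[i]]
        if (!methods::is(tsn, "InteractionNetwork"))
            return("every TSN must be an InteractionNetwork")
        if (!all(proteins(tsn) %in% src))
            return("TSN vertices must be a subset of the static network")
        if (!setequal(proteins(tsn), object@activeSets[[i]]))
            return("TSN vertex set must equal its active set")
    }
    TRUE
})

#' ComplexCatalog: a deduplicated collection of protein complexes
#'
#' Each entry is a protein set together with the set of TSN indices in which
#' the exact set was found (empty for gold-standard catalogues) and its
#' frequency f_T, the number of TSNs containing it.
#'
#' @slot ids unique complex identifiers.
#' @slot members list of character vectors (non-empty, deduplicated, sorted).
#' @slot activeTimes list of integer vectors of TSN indices.
#' @slot frequency integer vector, `lengths(activeTimes)` when times are
#'   recorded.
#' @seealso [complexCatalog()], [discoverComplexes()], [readComplexCatalog()]
#' @export
setClass("ComplexCatalog",
         slots = c(ids = "character", members = "list",
                   activeTimes = "list", frequency = "integer"))

setValidity("ComplexCatalog", function(object) {
    n <- length(object@ids)
    if (length(object@members) != n || length(object@activeTimes) != n ||
        length(object@frequency) != n)
        return("slot lengths must agree")
    if (anyDuplicated(object@ids)) return("complex IDs must be unique")
    if (any(lengths(object@members) == 0)) return("member sets must be non-empty")
    if (any(vapply(object@members, anyDuplicated, integer(1)) > 0))
        return("member sets must not contain duplicates")
    if (any(object@frequency < 0)) return("frequencies must be non-negative")
    has <- lengths(object@activeTimes) > 0
    if (any(object@frequency[has] != lengths(object@activeTimes)[has]))
        return("frequency must equal the number of active times when recorded")
    TRUE
})

#' Construct a ComplexCatalog
#'
#' @param ids character vector of unique complex IDs.
#' @param members list of character vectors of member proteins.
#' @param activeTimes list of integer vectors of TSN indices (default: none
#'   recorded, as for gold-standard catalogues).
#' @param frequency integer vector; defaults to `lengths(activeTimes)`.
#' @return a [ComplexCatalog-class] object.
#' @export
#' @examples
#' complexCatalog("KC1", list(c("DIG1", "DIG2", "STE12")))
complexCatalog <- function(ids, members,
                           activeTimes = rep(list(integer(0)), length(ids)),
                           frequency = lengths(activeTimes)) {
    members <- lapply(members, function(m) sort(unique(trimws(as.character(m)))))
    activeTimes <- lapply(activeTimes, function(t) sort(unique(as.integer(t))))
    methods::new("ComplexCatalog", ids = as.character(ids), members = members,
                 activeTimes = activeTimes, frequency = as.integer(frequency))
}

#' AnnotationMap: gene-to-term functional annotations
#'
#' @slot gene2terms named list mapping each annotated gene to its character
#'   vector of term IDs.
#' @slot termDesc optional named character vector of term descriptions.
#' @slot background character vector of annotated genes (the enrichment
#'   universe).
#' @seealso [annotationMap()], [readAnnotationMap()], [enrichModules()]
#' @export
setClass("AnnotationMap",
         slots = c(gene2terms = "list", termDesc = "character",
                   background = "character"))

setValidity("AnnotationMap", function(object) {
    if (length(object@gene2terms) > 0 && is.null(names(object@gene2terms)))
        return("gene2terms must be named by gene")
    if (!all(names(object@gene2terms) %in% object@background))
        return("every annotated gene must appear in the background")
    if (any(lengths(object@gene2terms) == 0))
        return("term sets must be non-empty")
    TRUE
})

#' Construct an AnnotationMap
#'
#' @param gene2terms named list of term-ID vectors per gene.
#' @param background annotated-gene universe; defaults to the annotated genes.
#' @param termDesc optional named character vector of term descriptions.
#' @return an [AnnotationMap-class] object.
#' @export
annotationMap <- function(gene2terms, background = names(gene2terms),
                          termDesc = character()) {
    gene2terms <- lapply(gene2terms, function(t) sort(unique(as.character(t))))
    methods::new("AnnotationMap", gene2terms = gene2terms,
                 termDesc = termDesc, background = unique(as.character(background)))
}

#' CINGraph: the complex-complex interaction network
#'
#' A weighted graph whose vertices are catalogue complexes. An edge joins
#' two complexes that are temporally related (synchronous or adjacent) and
#' whose membership similarity is at least the construction threshold `th`;
#' the edge weight is the similarity.
#'
#' @slot graph undirected \pkg{igraph} with vertex attribute `frequency` and
#'   edge attribute `weight` (the similarity, in (0, 1]).
#' @slot th the similarity threshold used at construction.
#' @slot similarity which similarity variant was used
#'   ("squared", "literal" or "geometric").
#' @seealso [buildCIN()], [detectModules()]
#' @export
setClass("CINGraph",
         slots = c(graph = "ANY", th = "numeric", similarity = "character"))

setValidity("CINGraph", function(object) {
    g <- object@graph
    if (!inherits(g, "igraph")) return("'graph' must be an igraph object")
    if (igraph::any_loop(g)) return("the CIN must not contain self-loops")
    if (igraph::ecount(g) > 0) {
        w <- igraph::E(g)$weight
        if (any(w <= 0) || any(w > 1)) return("edge weights must lie in (0, 1]")
        if (any(w < object@th - 1e-12))
            return("every edge weight must be >= the construction threshold")
    }
    TRUE
})

#' ModuleSet: functional modules over a complex catalogue
#'
#' Each module is a set of catalogue complexes grown by greedy
#' modularity-gain extension on the CIN, together with the union of their
#' member proteins and the modularity of the module at termination.
#'
#' @slot ids module identifiers.
#' @slot complexIds list of character vectors of member complex IDs.
#' @slot proteins list of character vectors (union of member complexes).
#' @slot modularity numeric vector of terminal modularity values in \[0, 1\].
#' @slot belowMin logical; TRUE when the protein union is smaller than the
#'   requested minimum module size (such modules are kept so that the
#'   partition of the CIN vertex set is preserved, but flagged).
#' @slot trace list of data.frames recording each accepted extension step
#'   (added vertex and its modularity gain).
#' @seealso [detectModules()]
#' @export
setClass("ModuleSet",
         slots = c(ids = "character", complexIds = "list", proteins = "list",
                   modularity = "numeric", belowMin = "logical", trace = "list"))

setValidity("ModuleSet", function(object) {
    n <- length(object@ids)
    if (length(object@complexIds) != n || length(object@proteins) != n ||
        length(object@modularity) != n || length(object@belowMin) != n)
        return("slot lengths must agree")
    if (any(lengths(object@complexIds) == 0))
        return("modules must contain at least one complex")
    if (any(object@modularity < -1e-12 | object@modularity > 1 + 1e-12))
        return("modularity must lie in [0, 1]")
    TRUE
})

#' MatchResult: outcome of matching predicted against known complexes
#'
#' @slot osThreshold the overlap-score threshold used.
#' @slot tp,fp,fn the usual counts: `tp` predicted complexes matched by some
#'   known complex, `fp = #predicted - tp`, `fn` known complexes matched by
#'   no predicted complex.
#' @slot pairs data.frame of matched (predicted, known, os) pairs, one row
#'   per matched known complex, all with `os >= osThreshold`.
#' @slot bestMatches data.frame giving, for every known complex, its
#'   best-matching predicted complex with sizes, overlap and OS.
#' @seealso [matchComplexes()], [fMeasure()]
#' @export
setClass("MatchResult",
         slots = c(osThreshold = "numeric", tp = "integer", fp = "integer",
                   fn = "integer", pairs = "data.frame",
                   bestMatches = "data.frame"))

setValidity("MatchResult", function(object) {
    if (nrow(object@pairs) > 0 && any(object@pairs$os < object@osThreshold - 1e-12))
        return("every recorded pair must have OS >= the threshold")
    if (object@tp < 0 || object@fp < 0 || object@fn < 0)
        return("counts must be non-negative")
    TRUE
})

#' FixtureSpec: parameters of the synthetic data generator
#'
#' Describes a synthetic study: a static network with planted
#' clique-like complexes plus Erdos-Renyi background noise, and a
#' time-course expression matrix giving every planted complex a contiguous
#' activity window straddling the activity threshold.
#'
#' @slot nBackground number of background (non-complex) proteins.
#' @slot nComplexes number of planted complexes.
#' @slot sizeRange integer range of complex sizes.
#' @slot intraEdgeP within-complex edge probability (1.0 = exact cliques).
#' @slot backgroundEdgeP noise edge probability for all other pairs.
#' @slot k number of time points.
#' @slot windows optional list of per-complex contiguous time windows; when
#'   empty, windows are drawn at random.
#' @slot windowLength range of random window lengths.
#' @slot exprHigh,exprLow expression levels inside/outside a protein's
#'   activity window.
#' @slot jitter half-width of the uniform jitter added to expression values;
#'   never allowed to cross the threshold.
#' @slot threshold the activity threshold the fixture is designed around.
#' @slot variantComplexes number of planted complexes that receive a
#'   "process variant" twin (same members minus one, plus one new protein,
#'   active in the adjacent time window) - this is what gives the CIN its
#'   edges.
#' @slot seed RNG seed.
#' @seealso [fixtureSpec()], [generateFixture()]
#' @export
setClass("FixtureSpec",
         slots = c(nBackground = "integer", nComplexes = "integer",
                   sizeRange = "integer", intraEdgeP = "numeric",
                   backgroundEdgeP = "numeric", k = "integer",
                   windows = "list", windowLength = "integer",
                   exprHigh = "numeric", exprLow = "numeric",
                   jitter = "numeric", threshold = "numeric",
                   variantComplexes = "integer", seed = "integer"))

setValidity("FixtureSpec", function(object) {
    if (object@nComplexes < 1) return("at least one planted complex is required")
    if (length(object@sizeRange) != 2 || object@sizeRange[1] < 2 ||
        object@sizeRange[1] > object@sizeRange[2])
        return("sizeRange must be (min, max) with min >= 2")
    if (object@intraEdgeP < 0 || object@intraEdgeP > 1 ||
        object@backgroundEdgeP < 0 || object@backgroundEdgeP > 1)
        return("edge probabilities must lie in [0, 1]")
    if (object@k < 1) return("k must be >= 1")
    if (length(object@windows) > 0) {
        if (length(object@windows) != object@nComplexes)
            return("one window per planted complex is required")
        ok <- vapply(object@windows, function(w)
            length(w) > 0 && all(w >= 1 & w <= object@k) &&
                all(diff(sort(w)) == 1), logical(1))
        if (!all(ok)) return("windows must be contiguous subsets of 1..k")
    }
    if (!(object@exprLow + object@jitter < object@threshold &&
          object@threshold <= object@exprHigh - object@jitter))
        return("need exprLow + jitter < threshold <= exprHigh - jitter")
    if (object@variantComplexes < 0 || object@variantComplexes > object@nComplexes)
        return("variantComplexes must lie in 0..nComplexes")
    TRUE
})
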