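# Generics and accessors for the package's S4 containers.

#' Protein identifiers of a network
#' @param x an object holding proteins.
#' @return character vector of protein IDs.
#' @export
setGeneric("proteins", function(x) standardGeneric("proteins"))

#' @describeIn proteins vertices of an interaction network.
#' @export
setMethod("proteins", "InteractionNetwork", function(x) igraph::V(x@graph)$name)

#' Interaction table of a network
#' @param x an [InteractionNetwork-class].
#' @return data.frame with columns `from`, `to`, `weight`, endpoints in
#'   canonical (sorted) order.
#' @export
setGeneric("interactions", function(x) standardGeneric("interactions"))

#' @describeIn interactions edge list with weights.
#' @export
setMethod("interactions", "InteractionNetwork", function(x) {
    if (igraph::ecount(x@graph) == 0)
        return(data.frame(from = character(), to = character(),
                          weight = numeric()))
    ed <- igraph::as_data_frame(x@graph, what = "edges")
    data.frame(from = pmin(ed$from, ed$to), to = pmax(ed$from, ed$to),
               weight = ed$weight, stringsAsFactors = FALSE)
})

#' Number of proteins in a network
#' @param x an [InteractionNetwork-class].
#' @export
setGeneric("numProteins", function(x) standardGeneric("numProteins"))

#' @describeIn numProteins vertex count.
#' @export
setMethod("numProteins", "InteractionNetwork",
          function(x) as.integer(igraph::vcount(x@graph)))

#' Number of interactions in a network
#' @param x an [InteractionNetwork-class].
#' @export
setGeneric("numInteractions", function(x) standardGeneric("numInteractions"))

#' @describeIn numInteractions edge count.
#' @export
setMethod("numInteractions", "InteractionNetwork",
          function(x) as.integer(igraph::ecount(x@graph)))

#' Extract the underlying igraph object
#' @param x a graph-backed object.
#' @return the \pkg{igraph} graph.
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' @describeIn asIgraph underlying graph of an interaction network.
#' @export
setMethod("asIgraph", "InteractionNetwork", function(x) x@graph)

#' @describeIn asIgraph underlying graph of a complex-complex network.
#' @export
setMethod("asIgraph", "CINGraph", function(x) x@graph)

#' Gene identifiers of an expression series
#' @param x an [ExpressionSeries-class].
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' @describeIn genes row (gene) IDs.
#' @export
setMethod("genes", "ExpressionSeries", function(x) rownames(x@values))

#' Time-point labels of an expression series
#' @param x an [ExpressionSeries-class] or [TSNSeries-class].
#' @export
setGeneric("timePoints", function(x) standardGeneric("timePoints"))

#' @describeIn timePoints column labels.
#' @export
setMethod("timePoints", "ExpressionSeries", function(x) colnames(x@values))

#' Expression values
#' @param x an [ExpressionSeries-class].
#' @return the numeric gene-by-time matrix.
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @describeIn exprValues the matrix.
#' @export
setMethod("exprValues", "ExpressionSeries", function(x) x@values)

#' Active protein sets of a TSN series
#' @param x a [TSNSeries-class].
#' @return list of character vectors, one per time point.
#' @export
setGeneric("activeSets", function(x) standardGeneric("activeSets"))

#' @describeIn activeSets the per-time active sets.
#' @export
setMethod("activeSets", "TSNSeries", function(x) x@activeSets)

#' Complex identifiers
#' @param x a [ComplexCatalog-class] or [ModuleSet-class].
#' @export
setGeneric("ids", function(x) standardGeneric("ids"))

#' @describeIn ids catalogue entry IDs.
#' @export
setMethod("ids", "ComplexCatalog", function(x) x@ids)

#' @describeIn ids module IDs.
#' @export
setMethod("ids", "ModuleSet", function(x) x@ids)

#' Member protein sets
#' @param x a [ComplexCatalog-class].
#' @return named list of character vectors.
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' @describeIn members member sets keyed by complex ID.
#' @export
setMethod("members", "ComplexCatalog", function(x) setNames(x@members, x@ids))

#' Activity-time sets
#' @param x a [ComplexCatalog-class].
#' @return named list of integer vectors of TSN indices.
#' @export
setGeneric("activeTimes", function(x) standardGeneric("activeTimes"))

#' @describeIn activeTimes TSN indices per complex.
#' @export
setMethod("activeTimes", "ComplexCatalog", function(x) setNames(x@activeTimes, x@ids))

#' Complex frequencies f_T
#' @param x a [ComplexCatalog-class].
#' @return named integer vector: number of TSNs each complex appears in.
#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))

#' @describeIn frequencies frequency per complex.
#' @export
setMethod("frequencies", "ComplexCatalog", function(x) setNames(x@frequency, x@ids))

#' Module protein unions
#' @param x a [ModuleSet-class].
#' @return named list of character vectors.
#' @export
setGeneric("moduleProteins", function(x) standardGeneric("moduleProteins"))

#' @describeIn moduleProteins protein union per module.
#' @export
setMethod("moduleProteins", "ModuleSet", function(x) setNames(x@proteins, x@ids))

#' Module complex memberships
#' @param x a [ModuleSet-class].
#' @return named list of character vectors of complex IDs.
#' @export
setGeneric("moduleComplexes", function(x) standardGeneric("moduleComplexes"))

#' @describeIn moduleComplexes complex IDs per module.
#' @export
setMethod("moduleComplexes", "ModuleSet", function(x) setNames(x@complexIds, x@ids))

#' Module modularity values
#' @param x a [ModuleSet-class].
#' @return named numeric vector of terminal modularity values.
#' @export
setGeneric("moduleModularity", function(x) standardGeneric("moduleModularity"))

#' @describeIn moduleModularity modularity per module.
#' @export
setMethod("moduleModularity", "ModuleSet", function(x) setNames(x@modularity, x@ids))

#' Extension traces of a module set
#' @param x a [ModuleSet-class].
#' @return named list of data.frames with columns `vertex` and `gain`, one
#'   row per accepted extension step.
#' @export
setGeneric("extensionTrace", function(x) standardGeneric("extensionTrace"))

#' @describeIn extensionTrace accepted-step traces.
#' @export
setMethod("extensionTrace", "ModuleSet", function(x) setNames(x@trace, x@ids))

#' Write a catalogue or module set to a TSV file
#'
#' @param x a [ComplexCatalog-class] or [ModuleSet-class].
#' @param path output file path.
#' @param ... unused.
#' @return `path`, invisibly.
#' @export
setGeneric("writeClusters", function(x, path, ...) standardGeneric("writeClusters"))

## ---- length / subset / show -------------------------------------------

#' @export
#' @describeIn TSNSeries-class number of time points.
#' @param x a TSNSeries.
setMethod("length", "TSNSeries", function(x) length(x@tsns))

#' @export
#' @describeIn TSNSeries-class extract the i-th TSN.
#' @param i TSN index.
setMethod("[[", "TSNSeries", function(x, i) x@tsns[[i]])

#' @export
#' @describeIn ComplexCatalog-class number of complexes.
#' @param x a ComplexCatalog.
setMethod("length", "ComplexCatalog", function(x) length(x@ids))

#' @export
#' @describeIn ComplexCatalog-class subset by index or ID.
#' @param i index, logical or ID vector.
setMethod("[", "ComplexCatalog", function(x, i) {
    if (is.character(i)) i <- match(i, x@ids)
    complexCatalog(x@ids[i], x@members[i], x@activeTimes[i], x@frequency[i])
})

#' @export
#' @describeIn ModuleSet-class number of modules.
#' @param x a ModuleSet.
setMethod("length", "ModuleSet", function(x) length(x@ids))

#' Coerce a ComplexCatalog to a data.frame
#'
#' @param x a [ComplexCatalog-class].
#' @param ... unused.
#' @return data.frame with columns id, size, frequency, times, members
#'   (times comma-separated, members semicolon-separated).
#' @export
asCatalogFrame <- function(x, ...) {
    data.frame(id = x@ids, size = lengths(x@members), frequency = x@frequency,
               times = vapply(x@activeTimes, paste, character(1), collapse = ","),
               members = vapply(x@members, paste, character(1), collapse = ";"),
               stringsAsFactors = FALSE)
}

setMethod("show", "InteractionNetwork", function(object) {
    cat("InteractionNetwork:", numProteins(object), "proteins,",
        numInteractions(object), "interactions\n")
})

setMethod("show", "ExpressionSeries", function(object) {
    cat("ExpressionSeries:", nrow(object@values), "genes x",
        ncol(object@values), "time points;",
        sum(is.na(object@values)), "missing values\n")
})

setMethod("show", "TSNSeries", function(object) {
    sizes <- vapply(object@tsns, numProteins, integer(1))
    edges <- vapply(object@tsns, numInteractions, integer(1))
    cat("TSNSeries:", length(object), "time-sequenced subnetworks",
        sprintf("(threshold %g)\n", object@threshold))
    cat("  active proteins per TSN:", paste(sizes, collapse = " "), "\n")
    cat("  interactions per TSN:   ", paste(edges, collapse = " "), "\n")
})

setMethod("show", "ComplexCatalog", function(object) {
    cat("ComplexCatalog:", length(object), "complexes\n")
    if (length(object) > 0) {
        cat("  sizes:", paste(range(lengths(object@members)), collapse = "-"),
            " frequencies:", paste(range(object@frequency), collapse = "-"), "\n")
    }
})

setMethod("show", "CINGraph", function(object) {
    cat("CINGraph:", igraph::vcount(object@graph), "complexes,",
        igraph::ecount(object@graph), "edges",
        sprintf("(th = %g, similarity = %s)\n", object@th, object@similarity))
})

setMethod("show", "ModuleSet", function(object) {
    cat("ModuleSet:", length(object), "functional modules\n")
    if (length(object) > 0) {
        single <- sum(lengths(object@complexIds) == 1)
        cat(sprintf("  single-complex modules: %d (%.0f%%)\n", single,
                    100 * single / length(object)))
        cat("  protein-union sizes:",
            paste(range(lengths(object@proteins)), collapse = "-"), "\n")
    }
})

setMethod("show", "MatchResult", function(object) {
    cat(sprintf("MatchResult (OS >= %g): TP = %d, FP = %d, FN = %d\n",
                object@osThreshold, object@tp, object@fp, object@fn))
})

setMethod("show", "AnnotationMap", function(object) {
    cat("AnnotationMap:", length(object@gene2terms), "annotated genes,",
        length(unique(unlist(object@gene2terms))), "terms, background of",
        length(object@background), "\n")
})

setMethod("show", "FixtureSpec", function(object) {
    cat("FixtureSpec:", object@nComplexes, "planted complexes (sizes",
        paste(object@sizeRange, collapse = "-"), "),",
        object@nBackground, "background proteins,", object@k, "time points\n")
    cat(sprintf("  intraEdgeP = %g, backgroundEdgeP = %g, threshold = %g, seed = %d\n",
                object@intraEdgeP, object@backgroundEdgeP, object@threshold,
                object@seed))
})
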