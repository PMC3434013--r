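# Functional module discovery: temporal relations between complexes,
# the complex-complex interaction network (CIN), local modularity, and
# greedy modularity-gain seed extension ordered by complex frequency.

#' Membership similarity of two protein complexes
#'
#' The default ("squared") form is the squared-overlap ratio
#' \eqn{|C_i \cap C_j|^2 / (|C_i| \cdot |C_j|)}, the same convention as the
#' overlap score used for benchmarking: it is symmetric, equals 1 exactly
#' for identical sets and 0 exactly for disjoint ones. Two alternatives are
#' provided: `"literal"` (\eqn{|C_i \cap C_j| / (|C_i| \cdot |C_j|)}, which
#' cannot exceed 1/max(|Ci|,|Cj|) and therefore cannot reach moderate
#' thresholds for complexes of size >= 3) and `"geometric"`
#' (\eqn{|C_i \cap C_j| / \sqrt{|C_i| \cdot |C_j|}}).
#'
#' @param ci,cj non-empty character vectors of member proteins.
#' @param method one of `"squared"` (default), `"literal"`, `"geometric"`.
#' @return similarity in \[0, 1\].
#' @export
#' @examples
#' complexSimilarity(c("A", "B", "C"), c("A", "B", "C", "D"))  # 9/12
complexSimilarity <- function(ci, cj, method = c("squared", "literal", "geometric")) {
    method <- match.arg(method)
    ci <- unique(ci); cj <- unique(cj)
    if (length(ci) == 0 || length(cj) == 0)
        stop("complex member sets must be non-empty", call. = FALSE)
    ov <- length(intersect(ci, cj))
    switch(method,
           squared = ov^2 / (length(ci) * length(cj)),
           literal = ov / (length(ci) * length(cj)),
           geometric = ov / sqrt(length(ci) * length(cj)))
}

#' Temporal relation between two activity-time sets
#'
#' Two complexes are \emph{synchronous} when they function in at least one
#' common TSN, and \emph{adjacent} when (not synchronous but) some activity
#' time of one directly follows an activity time of the other. Otherwise
#' the relation is `"none"`. Time indices are linear by default; with
#' `cyclic = TRUE` (for periodic designs such as metabolic-cycle sampling)
#' times 1 and k also count as consecutive.
#'
#' @param ti,tj non-empty integer vectors of TSN indices.
#' @param cyclic treat the time axis as circular (default FALSE).
#' @param k number of time points, required when `cyclic = TRUE`.
#' @return one of `"synchronous"`, `"adjacent"`, `"none"`.
#' @export
#' @examples
#' temporalRelation(c(1, 2), c(2, 3))  # synchronous
#' temporalRelation(1, 2)              # adjacent
#' temporalRelation(1, 3)              # none
temporalRelation <- function(ti, tj, cyclic = FALSE, k = NULL) {
    ti <- as.integer(ti); tj <- as.integer(tj)
    if (length(ti) == 0 || length(tj) == 0)
        stop("activity-time sets must be non-empty", call. = FALSE)
    if (length(intersect(ti, tj)) > 0) return("synchronous")
    gaps <- abs(outer(ti, tj, "-"))
    if (cyclic) {
        if (is.null(k)) stop("'k' is required when cyclic = TRUE", call. = FALSE)
        gaps <- pmin(gaps, k - gaps)
    }
    if (any(gaps == 1)) return("adjacent")
    "none"
}

#' Build the complex-complex interaction network
#'
#' Vertices are the catalogue's complexes; an edge joins complexes i and j
#' exactly when they are temporally related (synchronous or adjacent, see
#' [temporalRelation()]) \emph{and} their membership similarity is at least
#' `th`. The edge weight is the similarity.
#'
#' @param catalog a [ComplexCatalog-class] whose entries have recorded
#'   activity times.
#' @param th similarity threshold in \[0, 1\] (default 0.5).
#' @param similarity similarity variant, see [complexSimilarity()].
#' @param cyclic treat the time axis as circular (default FALSE).
#' @return a [CINGraph-class].
#' @export
buildCIN <- function(catalog, th = 0.5,
                     similarity = c("squared", "literal", "geometric"),
                     cyclic = FALSE) {
    stopifnot(methods::is(catalog, "ComplexCatalog"), th >= 0, th <= 1)
    similarity <- match.arg(similarity)
    if (any(lengths(catalog@activeTimes) == 0))
        stop("every catalogue entry needs a non-empty activity-time set",
             call. = FALSE)
    m <- length(catalog)
    k <- if (m > 0) max(unlist(catalog@activeTimes)) else 1L
    from <- character(0); to <- character(0); w <- numeric(0)
    if (m > 1) {
        for (i in seq_len(m - 1)) {
            for (j in seq((i + 1), m)) {
                rel <- temporalRelation(catalog@activeTimes[[i]],
                                        catalog@activeTimes[[j]],
                                        cyclic = cyclic, k = k)
                if (rel == "none") next
                s <- complexSimilarity(catalog@members[[i]],
                                       catalog@members[[j]], method = similarity)
                if (s >= th && s > 0) {
                    from <- c(from, catalog@ids[i])
                    to <- c(to, catalog@ids[j])
                    w <- c(w, s)
                }
            }
        }
    }
    g <- igraph::graph_from_data_frame(
        data.frame(from = from, to = to, weight = w, stringsAsFactors = FALSE),
        directed = FALSE, vertices = catalog@ids)
    igraph::V(g)$frequency <- catalog@frequency[match(igraph::V(g)$name,
                                                      catalog@ids)]
    methods::new("CINGraph", graph = g, th = th, similarity = similarity)
}

# weighted adjacency lookup for a CIN: named list of named weight vectors
.cinAdj <- function(cin) {
    g <- asIgraph(cin)
    verts <- igraph::V(g)$name
    adj <- setNames(vector("list", length(verts)), verts)
    for (v in verts) adj[[v]] <- numeric(0)
    if (igraph::ecount(g) > 0) {
        ed <- igraph::as_data_frame(g, what = "edges")
        for (i in seq_len(nrow(ed))) {
            adj[[ed$from[i]]][ed$to[i]] <- ed$weight[i]
            adj[[ed$to[i]]][ed$from[i]] <- ed$weight[i]
        }
    }
    adj
}

#' Weighted in- and out-degree of a vertex relative to a cluster
#'
#' For a vertex v of a cluster K, the weighted in-degree is the total weight
#' of edges from v to the other members of K, and the weighted out-degree
#' the total weight of edges from v to the rest of the graph; they sum to
#' the vertex's weighted degree.
#'
#' @param cin a [CINGraph-class].
#' @param K character vector of cluster vertex IDs.
#' @param v a vertex ID; must belong to `K`.
#' @return named numeric vector `c(din = ..., dout = ...)`.
#' @export
weightedDegrees <- function(cin, K, v) {
    stopifnot(methods::is(cin, "CINGraph"))
    if (!v %in% K) stop("'v' must be a member of 'K'", call. = FALSE)
    adj <- .cinAdj(cin)
    if (!v %in% names(adj)) stop("unknown vertex: ", v, call. = FALSE)
    w <- adj[[v]]
    inK <- names(w) %in% setdiff(K, v)
    c(din = sum(w[inK]), dout = sum(w[!inK]))
}

.modularityFromAdj <- function(adj, K) {
    din <- 0; dout <- 0
    for (v in K) {
        w <- adj[[v]]
        if (length(w) == 0) next
        inK <- names(w) %in% K
        din <- din + sum(w[inK])
        dout <- dout + sum(w[!inK])
    }
    if (din + dout == 0) return(0)  # no incident edges at all
    din / (din + dout)
}

#' Local modularity of a vertex set
#'
#' \eqn{M_K = \sum_{v \in K} d^{in}_w(K,v) /
#'   (\sum_{v \in K} d^{in}_w(K,v) + \sum_{v \in K} d^{out}_w(K,v))}:
#' the fraction of the cluster's incident edge weight that stays inside the
#' cluster. It is 1 for a whole connected component and 0 for a single
#' vertex with neighbours; a vertex set with no incident edges at all is
#' assigned modularity 0 (the 0/0 guard that makes isolated vertices
#' singleton modules).
#'
#' @param cin a [CINGraph-class].
#' @param K non-empty character vector of vertex IDs.
#' @return modularity in \[0, 1\].
#' @export
cinModularity <- function(cin, K) {
    stopifnot(methods::is(cin, "CINGraph"), length(K) > 0)
    .modularityFromAdj(.cinAdj(cin), unique(K))
}

#' Modularity gain of adding a vertex to a cluster
#'
#' The exact difference \eqn{\delta_K M(v) = M_{K \cup \{v\}} - M_K}; both
#' modularities are evaluated from scratch, so there is no incremental
#' drift.
#'
#' @param cin a [CINGraph-class].
#' @param K character vector of cluster vertex IDs.
#' @param v candidate vertex, not in `K`.
#' @return the (possibly negative) gain.
#' @export
modularityGain <- function(cin, K, v) {
    stopifnot(methods::is(cin, "CINGraph"))
    if (v %in% K) stop("'v' is already a member of 'K'", call. = FALSE)
    adj <- .cinAdj(cin)
    .modularityFromAdj(adj, c(K, v)) - .modularityFromAdj(adj, K)
}

#' Detect functional modules by frequency-seeded modularity extension
#'
#' Vertices (complexes) are queued in non-increasing frequency order (ties:
#' higher CIN weighted degree first, then lexicographic ID). The head of
#' the queue seeds a singleton cluster K, which grows greedily: at each
#' step the unassigned neighbour of K with the largest positive modularity
#' gain (ties: larger total edge weight into K, then lexicographic ID) is
#' added, unless adding it would push the module's protein union above
#' `sMax`. When no neighbour offers a positive gain the module is emitted,
#' its vertices leave the queue, and the next seed is taken. The result is
#' a partition of the CIN vertex set; modules whose protein union is
#' smaller than `sMin` are kept (dropping them would orphan their
#' complexes) but flagged `belowMin`.
#'
#' @param cin a [CINGraph-class].
#' @param catalog the [ComplexCatalog-class] the CIN was built from (for
#'   protein unions).
#' @param sMin minimum module size in proteins (default 3).
#' @param sMax maximum module size in proteins (default `Inf`).
#' @return a [ModuleSet-class]; module IDs `FM0001`, ... in emission order.
#' @export
detectModules <- function(cin, catalog, sMin = 3, sMax = Inf) {
    stopifnot(methods::is(cin, "CINGraph"), methods::is(catalog, "ComplexCatalog"),
              sMin >= 1, sMax >= sMin)
    adj <- .cinAdj(cin)
    verts <- names(adj)
    if (!all(verts %in% catalog@ids))
        stop("the CIN contains complexes missing from the catalogue",
             call. = FALSE)
    mem <- members(catalog)
    freq <- frequencies(catalog)[verts]
    wdeg <- vapply(adj, function(w) if (length(w)) sum(w) else 0, numeric(1))
    queue <- verts[order(-freq, -wdeg, verts)]
    assigned <- character(0)

    modIds <- character(0); modComplexes <- list(); modProteins <- list()
    modM <- numeric(0); modTrace <- list()
    for (seed in queue) {
        if (seed %in% assigned) next
        K <- seed
        protUnion <- mem[[seed]]
        trace <- data.frame(vertex = character(0), gain = numeric(0),
                            stringsAsFactors = FALSE)
        repeat {
            nb <- setdiff(unique(unlist(lapply(K, function(v) names(adj[[v]])))),
                          c(K, assigned))
            if (length(nb) == 0) break
            # refuse candidates that would exceed the protein-size cap
            if (is.finite(sMax)) {
                fits <- vapply(nb, function(v)
                    length(union(protUnion, mem[[v]])) <= sMax, logical(1))
                nb <- nb[fits]
                if (length(nb) == 0) break
            }
            baseM <- .modularityFromAdj(adj, K)
            gains <- vapply(nb, function(v)
                .modularityFromAdj(adj, c(K, v)) - baseM, numeric(1))
            if (max(gains) <= 0) break
            toK <- vapply(nb, function(v) {
                w <- adj[[v]]; sum(w[names(w) %in% K])
            }, numeric(1))
            best <- nb[order(-gains, -toK, nb)][1]
            trace <- rbind(trace, data.frame(vertex = best, gain = gains[[best]],
                                             stringsAsFactors = FALSE))
            K <- c(K, best)
            protUnion <- union(protUnion, mem[[best]])
        }
        assigned <- c(assigned, K)
        modIds <- c(modIds, sprintf("FM%04d", length(modIds) + 1L))
        modComplexes <- c(modComplexes, list(sort(K)))
        modProteins <- c(modProteins, list(sort(protUnion)))
        modM <- c(modM, .modularityFromAdj(adj, K))
        modTrace <- c(modTrace, list(trace))
    }
    methods::new("ModuleSet", ids = modIds, complexIds = modComplexes,
                 proteins = modProteins, modularity = modM,
                 belowMin = lengths(modProteins) < sMin, trace = modTrace)
}
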