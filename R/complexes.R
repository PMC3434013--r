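# Protein complex discovery on TSNs: edge clustering values, hierarchical
# agglomeration with lambda-module locking, and catalogue assembly with
# activity times and frequencies. This is the core of the method and is
# implemented here from first principles.

# Adjacency as named weight vectors, keyed by vertex name.
.adjWeights <- function(net) {
    ed <- interactions(net)
    verts <- proteins(net)
    adj <- setNames(vector("list", length(verts)), verts)
    for (v in verts) adj[[v]] <- numeric(0)
    for (i in seq_len(nrow(ed))) {
        adj[[ed$from[i]]][ed$to[i]] <- ed$weight[i]
        adj[[ed$to[i]]][ed$from[i]] <- ed$weight[i]
    }
    adj
}

#' Edge clustering value (ECV)
#'
#' The clustering value of an edge (u, v) measures how embedded the edge is
#' among the shared neighbours of its endpoints:
#' \deqn{ECV(u,v) = \frac{\sum_{k \in I_{uv}} w(u,k) \cdot \sum_{k \in I_{uv}} w(v,k)}
#'                      {\sum_{s \in N_u} w(u,s) \cdot \sum_{t \in N_v} w(v,t)}}
#' with \eqn{I_{uv} = N_u \cap N_v}. It is symmetric, lies in \[0, 1\], and
#' is 0 exactly when the endpoints share no neighbour. On an unweighted
#' triangle every edge scores 1/4; on a 4-clique, 4/9.
#'
#' @param net an [InteractionNetwork-class].
#' @param u,v endpoint protein IDs; (u, v) must be an edge of `net`.
#' @return the ECV, a number in \[0, 1\].
#' @export
edgeClusteringValue <- function(net, u, v) {
    adj <- .adjWeights(net)
    if (!u %in% proteins(net) || !v %in% proteins(net) ||
        !v %in% names(adj[[u]]))
        stop(sprintf("(%s, %s) is not an edge of the network", u, v),
             call. = FALSE)
    .ecvOne(adj, u, v)
}

.ecvOne <- function(adj, u, v) {
    nu <- adj[[u]]; nv <- adj[[v]]
    common <- intersect(names(nu), names(nv))
    if (length(common) == 0) return(0)
    (sum(nu[common]) * sum(nv[common])) / (sum(nu) * sum(nv))
}

#' Edge clustering values for every edge of a network
#'
#' @param net an [InteractionNetwork-class].
#' @return data.frame with columns `from`, `to`, `weight`, `ecv`,
#'   endpoints in canonical order.
#' @export
edgeClusteringValues <- function(net) {
    ed <- interactions(net)
    if (nrow(ed) == 0) return(cbind(ed, ecv = numeric(0)))
    adj <- .adjWeights(net)
    ed$ecv <- vapply(seq_len(nrow(ed)),
                     function(i) .ecvOne(adj, ed$from[i], ed$to[i]),
                     numeric(1))
    ed
}

#' Cluster one network by ECV-ordered hierarchical agglomeration
#'
#' Every vertex starts as a singleton cluster. Edges are processed in
#' non-increasing order of their [edgeClusteringValue()] (ties broken by the
#' lexicographic order of the sorted endpoint pair, so the result is
#' deterministic across platforms); an edge whose endpoints lie in different
#' clusters merges them. Two safeguards keep genuinely distinct dense
#' regions apart:
#' \itemize{
#'   \item only edges with ECV > 0 drive agglomeration - an edge whose
#'     endpoints share no neighbour carries no evidence that they belong to
#'     the same complex;
#'   \item a cluster K is \emph{locked} once it is a lambda-module, i.e.
#'     \eqn{\sum_{v \in K} d^{in}_w(K,v) > \lambda \sum_{v \in K} d^{out}_w(K,v)}
#'     (degrees measured in the full network), and has at least `minSize`
#'     vertices; a merge between two locked clusters is rejected.
#' }
#' After the queue is exhausted, every cluster with at least `minSize`
#' vertices is emitted. Clusters are connected by construction (merges
#' happen only along edges) and pairwise disjoint.
#'
#' @param net an [InteractionNetwork-class] (one TSN); may be disconnected.
#' @param lambda positive tightness ratio (default 1.0, the recommended
#'   value): larger values require proportionally more internal than
#'   boundary weight before a cluster refuses further merging.
#' @param minSize minimum complex size s (default 3).
#' @return list of character vectors (sorted member sets), ordered by their
#'   first member; possibly empty.
#' @export
#' @examples
#' tri2 <- interactionNetwork(data.frame(
#'     from = c("A", "A", "B", "C", "D", "D", "E"),
#'     to   = c("B", "C", "C", "D", "E", "F", "F")))
#' hcpinCluster(tri2)  # the two triangles; the bridge C-D is never merged
hcpinCluster <- function(net, lambda = 1, minSize = 3) {
    stopifnot(methods::is(net, "InteractionNetwork"),
              is.numeric(lambda), lambda > 0, minSize >= 2)
    verts <- proteins(net)
    n <- length(verts)
    if (n == 0) return(list())
    ecv <- edgeClusteringValues(net)
    idx <- setNames(seq_len(n), verts)

    # neighbour lists in index space, for cross-cluster weight sums
    adjIdx <- vector("list", n)
    adjW <- vector("list", n)
    if (nrow(ecv) > 0) {
        for (i in seq_len(nrow(ecv))) {
            a <- idx[[ecv$from[i]]]; b <- idx[[ecv$to[i]]]; w <- ecv$weight[i]
            adjIdx[[a]] <- c(adjIdx[[a]], b); adjW[[a]] <- c(adjW[[a]], w)
            adjIdx[[b]] <- c(adjIdx[[b]], a); adjW[[b]] <- c(adjW[[b]], w)
        }
    }
    wdeg <- vapply(adjW, function(w) if (length(w)) sum(w) else 0, numeric(1))

    parent <- seq_len(n)
    find <- function(i) {
        while (parent[i] != i) {
            parent[i] <<- parent[parent[i]]
            i <- parent[i]
        }
        i
    }
    size <- rep(1L, n)          # cluster vertex count (at root)
    wtot <- wdeg                # sum over members of full weighted degree
    wint <- rep(0, n)           # sum of internal edge weights (each edge once)
    membersOf <- lapply(seq_len(n), identity)
    locked <- function(r)
        size[r] >= minSize && 2 * wint[r] > lambda * (wtot[r] - 2 * wint[r])

    if (nrow(ecv) > 0) {
        ord <- order(-ecv$ecv, ecv$from, ecv$to)
        for (e in ord) {
            if (ecv$ecv[e] <= 0) break  # zero-ECV edges never merge
            ru <- find(idx[[ecv$from[e]]]); rv <- find(idx[[ecv$to[e]]])
            if (ru == rv) next
            if (locked(ru) && locked(rv)) next
            if (size[ru] < size[rv]) { tmp <- ru; ru <- rv; rv <- tmp }
            # weight of all edges between the two clusters, via the smaller
            cross <- 0
            for (m in membersOf[[rv]]) {
                nb <- adjIdx[[m]]
                if (length(nb) == 0) next
                inOther <- vapply(nb, function(x) find(x) == ru, logical(1))
                cross <- cross + sum(adjW[[m]][inOther])
            }
            parent[rv] <- ru
            size[ru] <- size[ru] + size[rv]
            wtot[ru] <- wtot[ru] + wtot[rv]
            wint[ru] <- wint[ru] + wint[rv] + cross
            membersOf[[ru]] <- c(membersOf[[ru]], membersOf[[rv]])
            membersOf[rv] <- list(integer(0))
        }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    clusters <- split(verts, roots)
    clusters <- clusters[lengths(clusters) >= minSize]
    clusters <- lapply(clusters, sort)
    names(clusters) <- NULL
    clusters[order(vapply(clusters, `[`, character(1), 1L))]
}

#' Discover protein complexes across a TSN series
#'
#' Runs [hcpinCluster()] on every TSN and assembles the deduplicated
#' catalogue: identical protein sets found in several TSNs collapse into a
#' single entry whose activity-time set lists the TSN indices where the set
#' appeared and whose frequency f_T is the number of such TSNs. Sets
#' differing by even one protein are distinct entries. Catalogue IDs
#' (`C0001`, ...) are assigned in order of first appearance, so the result
#' is deterministic.
#'
#' @param series a [TSNSeries-class].
#' @param lambda tightness ratio passed to [hcpinCluster()] (default 1.0).
#' @param minSize minimum complex size s (default 3).
#' @return a [ComplexCatalog-class]; the attribute `"perTSN"` carries the
#'   number of complexes found in each TSN.
#' @export
discoverComplexes <- function(series, lambda = 1, minSize = 3) {
    stopifnot(methods::is(series, "TSNSeries"), length(series) > 0)
    seen <- new.env(parent = emptyenv())
    order_ <- character(0)
    perTSN <- integer(length(series))
    for (i in seq_len(length(series))) {
        clusters <- hcpinCluster(series[[i]], lambda = lambda, minSize = minSize)
        perTSN[i] <- length(clusters)
        for (cl in clusters) {
            key <- paste(cl, collapse = ";")
            if (is.null(seen[[key]])) {
                seen[[key]] <- list(members = cl, times = i)
                order_ <- c(order_, key)
            } else {
                seen[[key]]$times <- c(seen[[key]]$times, i)
            }
        }
    }
    n <- length(order_)
    cat <- complexCatalog(
        ids = sprintf("C%04d", seq_len(max(n, 0))),
        members = lapply(order_, function(k) seen[[k]]$members),
        activeTimes = lapply(order_, function(k) as.integer(seen[[k]]$times)))
    attr(cat, "perTSN") <- perTSN
    cat
}
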