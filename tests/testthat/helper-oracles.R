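# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately naive (explicit loops over neighbour sets / edges /
# enumerated draws) so they share no code with the implementation paths
# they check.

makeNet <- function(from, to, weight = NULL, proteins = character()) {
    d <- data.frame(from = from, to = to, stringsAsFactors = FALSE)
    if (!is.null(weight)) d$weight <- weight
    interactionNetwork(d, proteins = proteins)
}

# two unit-weight triangles joined by the bridge C-D
twoTriangles <- function() makeNet(
    c("A", "A", "B", "C", "D", "D", "E"),
    c("B", "C", "C", "D", "E", "F", "F"))

cliqueNet <- function(v) {
    pairs <- t(combn(v, 2))
    makeNet(pairs[, 1], pairs[, 2])
}

# a CIN with given unit/explicit weights, bypassing similarity construction
makeCIN <- function(from, to, weight = 1, vertices = NULL, th = 0) {
    if (is.null(vertices)) vertices <- sort(unique(c(from, to)))
    g <- igraph::graph_from_data_frame(
        data.frame(from = from, to = to,
                   weight = rep_len(weight, length(from)),
                   stringsAsFactors = FALSE),
        directed = FALSE, vertices = vertices)
    igraph::V(g)$frequency <- 1L
    methods::new("CINGraph", graph = g, th = th, similarity = "squared")
}

# ECV by explicit neighbour-set loops on an edge data.frame
ecvOracle <- function(edges, u, v) {
    nbr <- function(x) {
        sel <- edges$from == x | edges$to == x
        setdiff(unique(c(edges$from[sel], edges$to[sel])), x)
    }
    w <- function(a, b) {
        sel <- (edges$from == a & edges$to == b) | (edges$from == b & edges$to == a)
        edges$weight[sel][1]
    }
    nu <- nbr(u); nv <- nbr(v)
    common <- intersect(nu, nv)
    num1 <- 0; num2 <- 0
    for (k in common) { num1 <- num1 + w(u, k); num2 <- num2 + w(v, k) }
    den1 <- 0; den2 <- 0
    for (s in nu) den1 <- den1 + w(u, s)
    for (t in nv) den2 <- den2 + w(v, t)
    if (length(common) == 0) return(0)
    (num1 * num2) / (den1 * den2)
}

# local modularity by an explicit loop over the edge list
modularityOracle <- function(edges, K) {
    din <- 0; dout <- 0
    for (i in seq_len(nrow(edges))) {
        a <- edges$from[i]; b <- edges$to[i]; w <- edges$weight[i]
        if (a %in% K && b %in% K) din <- din + 2 * w
        else if (a %in% K || b %in% K) dout <- dout + w
    }
    if (din + dout == 0) return(0)
    din / (din + dout)
}

# upper-tail hypergeometric P(X >= x) by exhaustive enumeration of draws
hyperOracle <- function(x, termSize, background, drawn) {
    universe <- seq_len(background)
    inTerm <- universe <= termSize
    draws <- combn(background, drawn)
    hits <- apply(draws, 2, function(d) sum(inTerm[d]))
    mean(hits >= x)
}

# all graphs on n labelled vertices as edge data.frames (unit weights)
enumerateGraphs <- function(n, weights = NULL) {
    v <- LETTERS[seq_len(n)]
    pairs <- t(combn(v, 2))
    m <- nrow(pairs)
    lapply(seq_len(2^m) - 1L, function(mask) {
        sel <- bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0
        data.frame(from = pairs[sel, 1], to = pairs[sel, 2],
                   weight = if (is.null(weights)) rep(1, sum(sel))
                            else weights[sel],
                   stringsAsFactors = FALSE)
    })
}

randomGraph <- function(n, p = 0.5, weighted = TRUE) {
    v <- sprintf("V%02d", seq_len(n))
    pairs <- t(combn(v, 2))
    sel <- runif(nrow(pairs)) < p
    data.frame(from = pairs[sel, 1], to = pairs[sel, 2],
               weight = if (weighted) runif(sum(sel), 0.1, 1)
                        else rep(1, sum(sel)),
               stringsAsFactors = FALSE)
}
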