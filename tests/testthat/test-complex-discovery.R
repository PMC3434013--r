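test_that("edge clustering values match hand-derived cases", {
    tri <- cliqueNet(c("A", "B", "C"))
    expect_equal(edgeClusteringValue(tri, "A", "B"), 0.25)
    expect_equal(edgeClusteringValue(tri, "B", "A"), 0.25)  # symmetric

    k4 <- cliqueNet(LETTERS[1:4])
    expect_equal(edgeClusteringValue(k4, "A", "B"), 4 / 9)

    bridge <- makeNet(c("A", "B"), c("B", "C"))  # no common neighbour
    expect_equal(edgeClusteringValue(bridge, "A", "B"), 0)
    expect_error(edgeClusteringValue(bridge, "A", "C"), "not an edge")
})

test_that("ECV equals the explicit neighbour-set oracle on all 4-vertex graphs", {
    for (edges in enumerateGraphs(4)) {
        if (nrow(edges) == 0) next
        net <- makeNet(edges$from, edges$to)
        got <- edgeClusteringValues(net)
        for (i in seq_len(nrow(got))) {
            expect_equal(got$ecv[i],
                         ecvOracle(edges, got$from[i], got$to[i]),
                         tolerance = 1e-14)
        }
    }
})

test_that("ECV stays in [0,1] and matches the oracle on random weighted graphs", {
    set.seed(99)
    for (rep in 1:60) {
        edges <- randomGraph(sample(4:8, 1), p = 0.6)
        if (nrow(edges) == 0) next
        net <- makeNet(edges$from, edges$to, edges$weight)
        got <- edgeClusteringValues(net)
        expect_true(all(got$ecv >= 0 & got$ecv <= 1))
        for (i in seq_len(nrow(got)))
            expect_equal(got$ecv[i],
                         ecvOracle(interactions(net), got$from[i], got$to[i]),
                         tolerance = 1e-12)
    }
})

test_that("agglomeration separates bridged triangles and keeps cliques whole", {
    expect_equal(hcpinCluster(twoTriangles(), lambda = 1, minSize = 3),
                 list(c("A", "B", "C"), c("D", "E", "F")))
    expect_equal(hcpinCluster(cliqueNet(LETTERS[1:5]), lambda = 1, minSize = 3),
                 list(LETTERS[1:5]))
    # edgeless graph: no qualifying cluster
    expect_equal(hcpinCluster(makeNet(character(0), character(0),
                                      proteins = LETTERS[1:4])),
                 list())
})

test_that("clusters form a sub-partition: disjoint, connected, min size", {
    set.seed(7)
    for (rep in 1:25) {
        edges <- randomGraph(12, p = 0.3, weighted = (rep %% 2 == 0))
        if (nrow(edges) == 0) next
        net <- makeNet(edges$from, edges$to, edges$weight)
        cl <- hcpinCluster(net, lambda = 1, minSize = 3)
        all_ <- unlist(cl)
        expect_equal(anyDuplicated(all_), 0)
        expect_true(all(lengths(cl) >= 3))
        g <- asIgraph(net)
        for (k in cl) {
            sub <- igraph::induced_subgraph(g, k)
            expect_true(igraph::is_connected(sub))
        }
    }
})

test_that("identical protein sets collapse into one catalogue entry with activity times", {
    tri <- cliqueNet(c("A", "B", "C"))
    other <- cliqueNet(c("X", "Y", "Z"))
    empty <- makeNet(character(0), character(0), proteins = "A")
    m <- matrix(1, 1, 1, dimnames = list("A", "t"))
    series <- methods::new("TSNSeries",
        source = makeNet(c("A", "A", "B", "X", "X", "Y"),
                         c("B", "C", "C", "Y", "Z", "Z")),
        tsns = list(empty, tri, other, empty, tri, tri),
        activeSets = list("A", c("A", "B", "C"), c("X", "Y", "Z"),
                          "A", c("A", "B", "C"), c("A", "B", "C")),
        threshold = 0.7)
    catlg <- discoverComplexes(series)
    expect_equal(length(catlg), 2)
    expect_equal(unname(activeTimes(catlg)[[1]]), c(2L, 5L, 6L))
    expect_equal(unname(frequencies(catlg)), c(3L, 1L))
    # conservation: per-TSN cluster counts sum to total frequency
    expect_equal(sum(attr(catlg, "perTSN")), sum(frequencies(catlg)))
})

test_that("protein sets differing by one member stay distinct entries", {
    tri <- cliqueNet(c("A", "B", "C"))
    quad <- cliqueNet(c("A", "B", "C", "D"))
    series <- methods::new("TSNSeries",
        source = quad, tsns = list(tri, quad),
        activeSets = list(c("A", "B", "C"), c("A", "B", "C", "D")),
        threshold = 0.7)
    catlg <- discoverComplexes(series)
    expect_equal(length(catlg), 2)
    expect_equal(unname(frequencies(catlg)), c(1L, 1L))
})

test_that("frequency conservation holds on generated dynamic networks", {
    fx <- generateFixture(fixtureSpec(nComplexes = 5, nBackground = 40,
                                      k = 12, seed = 21))
    tsns <- buildTSNSeries(fx$network, fx$expression, 0.7, quiet = TRUE)
    catlg <- discoverComplexes(tsns)
    perTSN <- vapply(seq_len(length(tsns)),
                     function(i) length(hcpinCluster(tsns[[i]])), integer(1))
    expect_equal(sum(perTSN), sum(frequencies(catlg)))
    expect_equal(attr(catlg, "perTSN"), perTSN)
})
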