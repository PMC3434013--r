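test_that("complex similarity variants behave as documented", {
    s5 <- sprintf("P%d", 1:5)
    expect_equal(complexSimilarity(s5, s5), 1)
    expect_equal(complexSimilarity(c("A", "B"), c("C", "D")), 0)
    expect_equal(complexSimilarity(c("A", "B", "C"), c("A", "B", "C", "D")),
                 9 / 12)
    expect_equal(complexSimilarity(c("A", "B", "C"), c("A", "B", "C", "D"),
                                   method = "literal"), 3 / 12)
    expect_equal(complexSimilarity(c("A", "B", "C"), c("A", "B", "C", "D"),
                                   method = "geometric"), 3 / sqrt(12))
    expect_error(complexSimilarity(character(0), "A"), "non-empty")
})

test_that("temporal relations distinguish synchronous, adjacent and unrelated", {
    expect_equal(temporalRelation(c(1, 2), c(2, 3)), "synchronous")
    expect_equal(temporalRelation(1, 2), "adjacent")
    expect_equal(temporalRelation(1, 3), "none")
    expect_equal(temporalRelation(1, 30, cyclic = TRUE, k = 30), "adjacent")
    expect_error(temporalRelation(integer(0), 1), "non-empty")
})

test_that("CIN edges require both a temporal relation and sufficient similarity", {
    mem <- list(c("A", "B", "C"), c("A", "B", "C"), c("A", "B", "C", "D"))
    # identical complexes far apart in time: similarity 1, relation none
    cc <- complexCatalog(c("x", "y"), mem[c(1, 2)], list(1L, 5L))
    expect_equal(igraph::ecount(asIgraph(buildCIN(cc, th = 0.5))), 0)
    # similarity 0.75 at the same time: edge with that weight
    cc2 <- complexCatalog(c("x", "y"), mem[c(1, 3)], list(2L, 2L))
    g <- asIgraph(buildCIN(cc2, th = 0.5))
    expect_equal(igraph::ecount(g), 1)
    expect_equal(igraph::E(g)$weight, 0.75)
    # th = 1: only identical, temporally related pairs connect
    cc3 <- complexCatalog(c("x", "y", "z"), mem, list(1L, 2L, 2L))
    g3 <- asIgraph(buildCIN(cc3, th = 1))
    ed <- igraph::as_data_frame(g3)
    expect_equal(nrow(ed), 1)
    expect_setequal(c(ed$from, ed$to), c("x", "y"))
})

test_that("raising th never adds a CIN edge", {
    fx <- generateFixture(fixtureSpec(seed = 5))
    tsns <- buildTSNSeries(fx$network, fx$expression, 0.7, quiet = TRUE)
    catlg <- discoverComplexes(tsns)
    prev <- NULL
    for (th in seq(0.2, 1, by = 0.2)) {
        ed <- igraph::as_data_frame(asIgraph(buildCIN(catlg, th = th)))
        keys <- paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to))
        if (!is.null(prev)) expect_true(all(keys %in% prev))
        prev <- keys
    }
})

test_that("weighted in/out degrees split the weighted degree", {
    path <- makeCIN(c("a", "b"), c("b", "c"))
    expect_equal(weightedDegrees(path, c("a", "b"), "b"),
                 c(din = 1, dout = 1))
    expect_equal(weightedDegrees(path, c("a", "b", "c"), "b"),
                 c(din = 2, dout = 0))
    iso <- makeCIN("a", "b", vertices = c("a", "b", "z"))
    expect_equal(weightedDegrees(iso, "z", "z"), c(din = 0, dout = 0))
    expect_error(weightedDegrees(path, c("a", "b"), "c"), "member")
})

test_that("local modularity matches hand values and the 0/0 guard", {
    path <- makeCIN(c("a", "b"), c("b", "c"))
    expect_equal(cinModularity(path, c("a", "b")), 2 / 3)
    expect_equal(cinModularity(path, c("a", "b", "c")), 1)
    expect_equal(cinModularity(path, "b"), 0)
    iso <- makeCIN("a", "b", vertices = c("a", "b", "z"))
    expect_equal(cinModularity(iso, "z"), 0)  # no incident edges at all
})

test_that("modularity matches the edge-loop oracle on all 4-vertex graphs and subsets", {
    for (edges in enumerateGraphs(4)) {
        verts <- LETTERS[1:4]
        cin <- if (nrow(edges) == 0) makeCIN(character(0), character(0),
                                             vertices = verts)
               else makeCIN(edges$from, edges$to, vertices = verts)
        for (mask in seq_len(2^4 - 1)) {
            K <- verts[bitwAnd(mask, 2^(0:3)) > 0]
            expect_equal(cinModularity(cin, K), modularityOracle(edges, K),
                         tolerance = 1e-12)
        }
    }
})

test_that("modularity gain is the exact difference of modularities", {
    set.seed(31)
    for (rep in 1:40) {
        edges <- randomGraph(7, p = 0.4)
        if (nrow(edges) == 0) next
        verts <- sort(unique(c(edges$from, edges$to)))
        cin <- makeCIN(edges$from, edges$to, weight = edges$weight,
                       vertices = verts)
        K <- sample(verts, sample(seq_len(length(verts) - 1), 1))
        v <- sample(setdiff(verts, K), 1)
        expect_equal(modularityGain(cin, K, v),
                     modularityOracle(edges, c(K, v)) - modularityOracle(edges, K),
                     tolerance = 1e-12)
    }
    # hand cases: pendant triangle, single edge
    tri <- makeCIN(c("a", "a", "b", "c"), c("b", "c", "c", "d"))
    expect_equal(modularityGain(tri, c("a", "b"), "c"), 6 / 7 - 1 / 2)
    e1 <- makeCIN("a", "b")
    expect_equal(modularityGain(e1, "a", "b"), 1)
    expect_error(modularityGain(e1, c("a", "b"), "a"), "already")
    # a vertex whose edges all leave K ∪ {v} has negative gain
    star <- makeCIN(c("a", "c", "c"), c("b", "d", "e"))
    expect_lt(modularityGain(star, c("a", "b"), "c"), 0)
})

test_that("module extension partitions the CIN, seeded by frequency", {
    # two complex triads joined by one weak edge; distinct frequencies
    mem <- lapply(1:6, function(i) sprintf("P%d_%d", i, 1:4))
    freqs <- c(9L, 5L, 4L, 8L, 3L, 2L)
    catlg <- complexCatalog(sprintf("c%d", 1:6), mem,
                            activeTimes = lapply(freqs, seq_len))
    cin <- makeCIN(c("c1", "c1", "c2", "c4", "c4", "c5", "c3"),
                   c("c2", "c3", "c3", "c5", "c6", "c6", "c4"),
                   weight = c(1, 1, 1, 1, 1, 1, 0.1))
    mods <- detectModules(cin, catlg)
    expect_equal(length(mods), 2)
    expect_equal(moduleComplexes(mods)$FM0001, c("c1", "c2", "c3"))
    expect_equal(moduleComplexes(mods)$FM0002, c("c4", "c5", "c6"))
    # highest-frequency vertices seed the modules
    expect_equal(extensionTrace(mods)$FM0001$vertex[1] %in% c("c2", "c3"), TRUE)
    # partition of the vertex set
    expect_setequal(unlist(moduleComplexes(mods)), sprintf("c%d", 1:6))
    # protein unions match the catalogue
    expect_setequal(moduleProteins(mods)$FM0001, unlist(mem[1:3]))
})

test_that("an edgeless CIN yields single-complex modules", {
    catlg <- complexCatalog(c("a", "b"), list(c("P1", "P2", "P3"),
                                              c("Q1", "Q2", "Q3")),
                            list(1L, 3L))
    cin <- buildCIN(catlg, th = 0.5)
    mods <- detectModules(cin, catlg)
    expect_equal(length(mods), 2)
    expect_true(all(lengths(moduleComplexes(mods)) == 1))
    expect_equal(unname(moduleModularity(mods)), c(0, 0))
})

test_that("a fully cohesive component becomes a single module with modularity 1", {
    mem <- lapply(1:4, function(i) sprintf("P%d_%d", i, 1:3))
    catlg <- complexCatalog(sprintf("c%d", 1:4), mem,
                            activeTimes = lapply(c(4L, 3L, 2L, 1L), seq_len))
    pairs <- t(combn(sprintf("c%d", 1:4), 2))
    cin <- makeCIN(pairs[, 1], pairs[, 2])
    mods <- detectModules(cin, catlg, sMax = Inf)
    expect_equal(length(mods), 1)
    expect_equal(unname(moduleModularity(mods)), 1)
    expect_true(all(extensionTrace(mods)$FM0001$gain > 0))
})

test_that("sMax caps the module's protein union and belowMin is flagged", {
    mem <- list(sprintf("A%d", 1:4), sprintf("B%d", 1:4), c("A1", "C1"))
    catlg <- complexCatalog(c("a", "b", "c"), mem,
                            activeTimes = lapply(c(3L, 2L, 1L), seq_len))
    cin <- makeCIN(c("a", "a", "b"), c("b", "c", "c"))
    mods <- detectModules(cin, catlg, sMax = 6)
    # merging a with b (8 proteins) is refused; a+c fits (5 proteins)
    sizes <- lengths(moduleProteins(mods))
    expect_true(all(sizes <= 6))
    modsMin <- detectModules(cin, catlg, sMin = 100)
    expect_true(all(modsMin@belowMin))
})
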