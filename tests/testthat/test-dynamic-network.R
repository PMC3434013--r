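exprFromMatrix <- function(m) expressionSeries(m)

test_that("per-time activity filtering honours the threshold and missing rule", {
    m <- matrix(c(0.9, 0.5, NA, 0.8), 2, 2,
                dimnames = list(c("A", "B"), c("t1", "t2")))
    e <- exprFromMatrix(m)
    expect_equal(activeProteins(e, 1, 0.7), "A")
    expect_equal(activeProteins(e, 1, -Inf), c("A", "B"))  # vacuous filter
    # missing value excluded whatever the threshold
    expect_equal(activeProteins(e, 2, -Inf), "B")
    expect_equal(activeProteins(e, 1, 0.9), "A")  # boundary: >= keeps equality
    expect_error(activeProteins(e, 3, 0.7), "out of range")
    expect_error(activeProteins(e, 0, 0.7), "out of range")
})

test_that("TSNs are the subgraphs induced on active proteins", {
    tri <- makeNet(c("A", "A", "B"), c("B", "C", "C"))
    m <- matrix(c(1, 1, 1, 1, 1, 0.2), 3, 2,
                dimnames = list(c("A", "B", "C"), c("t1", "t2")))
    tsns <- buildTSNSeries(tri, exprFromMatrix(m), 0.7, quiet = TRUE)
    expect_equal(length(tsns), 2)
    expect_equal(numInteractions(tsns[[1]]), 3)   # full triangle
    expect_equal(numInteractions(tsns[[2]]), 1)   # only A-B
    expect_setequal(proteins(tsns[[2]]), c("A", "B"))

    # k = 1, all active: TSN equals the static network restricted to
    # measured genes
    m1 <- matrix(1, 3, 1, dimnames = list(c("A", "B", "C"), "t1"))
    t1 <- buildTSNSeries(tri, exprFromMatrix(m1), 0.7, quiet = TRUE)
    expect_identical(interactions(t1[[1]]), interactions(tri))

    # no overlap between network and expression -> nothing to build
    mX <- matrix(1, 1, 1, dimnames = list("Z", "t1"))
    expect_error(buildTSNSeries(tri, exprFromMatrix(mX), 0.7, quiet = TRUE),
                 "no overlap")
})

test_that("unmeasured proteins follow the configured policy", {
    net <- makeNet("A", "B", proteins = "C")   # C unmeasured
    m <- matrix(1, 2, 1, dimnames = list(c("A", "B"), "t1"))
    e <- exprFromMatrix(m)
    expect_false("C" %in% proteins(buildTSNSeries(net, e, 0.7,
                                                  quiet = TRUE)[[1]]))
    expect_true("C" %in% proteins(buildTSNSeries(net, e, 0.7,
                                                 unmeasured = "active",
                                                 quiet = TRUE)[[1]]))
})

test_that("lowering the threshold never removes TSN vertices or edges", {
    fx <- generateFixture(fixtureSpec(nComplexes = 4, nBackground = 30,
                                      k = 10, seed = 11))
    lo <- buildTSNSeries(fx$network, fx$expression, 0.4, quiet = TRUE)
    hi <- buildTSNSeries(fx$network, fx$expression, 0.7, quiet = TRUE)
    for (i in seq_len(length(hi))) {
        expect_true(all(proteins(hi[[i]]) %in% proteins(lo[[i]])))
        eh <- interactions(hi[[i]]); el <- interactions(lo[[i]])
        expect_true(all(paste(eh$from, eh$to) %in% paste(el$from, el$to)))
    }
})

test_that("every TSN is contained in the static network, with edge-union equality when all proteins are active", {
    fx <- generateFixture(fixtureSpec(nComplexes = 4, nBackground = 30,
                                      k = 10, seed = 12))
    tsns <- buildTSNSeries(fx$network, fx$expression, 0.7, quiet = TRUE)
    statEdges <- paste(interactions(fx$network)$from,
                       interactions(fx$network)$to)
    seen <- character(0)
    for (i in seq_len(length(tsns))) {
        ed <- interactions(tsns[[i]])
        keys <- paste(ed$from, ed$to)
        expect_true(all(keys %in% statEdges))
        expect_true(all(proteins(tsns[[i]]) %in% proteins(fx$network)))
        seen <- union(seen, keys)
    }
    expect_true(all(seen %in% statEdges))
    # threshold -Inf makes every protein active everywhere: union equality
    all_ <- buildTSNSeries(fx$network, fx$expression, -Inf, quiet = TRUE)
    ed1 <- interactions(all_[[1]])
    expect_setequal(paste(ed1$from, ed1$to), statEdges)
})

test_that("a planted complex's edges appear exactly inside its activity window", {
    fx <- generateFixture(fixtureSpec(nComplexes = 2, nBackground = 0,
                                      sizeRange = c(4, 4), backgroundEdgeP = 0,
                                      k = 6, windows = list(1:3, 4:6),
                                      variantComplexes = 0, seed = 3))
    tsns <- buildTSNSeries(fx$network, fx$expression, 0.7, quiet = TRUE)
    mem <- members(fx$truth)
    for (i in 1:6) {
        expected <- if (i <= 3) mem[[1]] else mem[[2]]
        expect_setequal(proteins(tsns[[i]]), expected)
        expect_equal(numInteractions(tsns[[i]]), choose(4, 2))
    }
})
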