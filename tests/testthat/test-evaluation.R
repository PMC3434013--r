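test_that("overlap scores match hand-derived benchmark cases", {
    dash <- c("ASK1", "DAD1", "DAD2", "DAD3", "DAD4", "DAM1", "DUO1",
              "SPC19", "SPC34")
    big <- c(dash[1:7], sprintf("X%02d", 1:29))     # 36 proteins, overlap 7
    expect_equal(overlapScore(big, dash), 49 / 324)
    small <- dash[1:7]                              # 7 proteins, overlap 7
    expect_equal(overlapScore(small, dash), 49 / 63)
    expect_equal(overlapScore(dash, dash), 1)
    expect_equal(overlapScore(small, dash), overlapScore(dash, small))
    expect_error(overlapScore(character(0), dash), "non-empty")
})

test_that("overlap score equals explicit set arithmetic on random pairs", {
    set.seed(17)
    pool <- sprintf("G%03d", 1:40)
    for (rep in 1:100) {
        a <- sample(pool, sample(1:15, 1))
        b <- sample(pool, sample(1:15, 1))
        expect_equal(overlapScore(a, b),
                     length(intersect(a, b))^2 / (length(a) * length(b)))
    }
})

test_that("matching counts TP/FP/FN at the OS threshold", {
    known <- complexCatalog(c("k1", "k2"),
                            list(c("A", "B", "D"), c("P", "Q", "R")))
    identicalPred <- complexCatalog(c("p1", "p2"),
                                    list(c("A", "B", "D"), c("P", "Q", "R")))
    m <- matchComplexes(identicalPred, known, 0.9)
    expect_equal(c(m@tp, m@fp, m@fn), c(2L, 0L, 0L))
    expect_equal(unname(fMeasure(m)), c(1, 1, 1))

    pred <- complexCatalog("p1", list(c("A", "B", "C")))
    m2 <- matchComplexes(pred, known["k1"], 0.5)   # OS = 4/9 < 0.5
    expect_equal(c(m2@tp, m2@fp, m2@fn), c(0L, 1L, 1L))
    expect_equal(unname(fMeasure(m2)["f"]), 0)
    expect_equal(nrow(m2@pairs), 0)

    expect_error(matchComplexes(pred, known, 0), "osThreshold")
})

test_that("f-measure combines the printed Sn/Sp definitions", {
    m <- methods::new("MatchResult", osThreshold = 0.2, tp = 2L, fp = 1L,
                      fn = 2L,
                      pairs = data.frame(), bestMatches = data.frame())
    fm <- fMeasure(m)
    expect_equal(unname(fm), c(0.5, 2 / 3, 4 / 7))
    # symmetric in Sn and Sp, bounded by twice the smaller one
    expect_equal(fm[["f"]], 2 * fm[["Sn"]] * fm[["Sp"]] / (fm[["Sn"]] + fm[["Sp"]]))
    expect_lte(fm[["f"]], 2 * min(fm[["Sn"]], fm[["Sp"]]))
    bad <- methods::new("MatchResult", osThreshold = 0.2, tp = 0L, fp = 0L,
                        fn = 3L, pairs = data.frame(),
                        bestMatches = data.frame())
    expect_error(fMeasure(bad), "Sp undefined")
})

test_that("matched-known counts never increase along a threshold sweep", {
    set.seed(23)
    pool <- sprintf("G%03d", 1:60)
    pred <- complexCatalog(sprintf("p%d", 1:12),
                           lapply(1:12, function(i) sample(pool, sample(3:8, 1))))
    known <- complexCatalog(sprintf("k%d", 1:8),
                            lapply(1:8, function(i) sample(pool, sample(3:8, 1))))
    sweep <- osThresholdSweep(pred, known, thresholds = seq(0.1, 1, 0.1))
    expect_true(all(diff(sweep$matchedKnown) <= 0))
    expect_true(all(diff(sweep$tp) <= 0))
})

test_that("frequency distributions report the headline fractions", {
    cc <- complexCatalog(sprintf("c%d", 1:4),
                         lapply(1:4, function(i) sprintf("P%d_%d", i, 1:3)),
                         activeTimes = list(1L, 2L, 3L, 1:4))
    fd <- frequencyDistribution(cc)
    expect_equal(fd$fractionSingle, 0.75)
    expect_equal(fd$fractionAboveThree, 0.25)
    expect_equal(sum(fd$counts), length(cc))
    allOnes <- complexCatalog(c("a", "b"), list("P1", "P2"),
                              list(1L, 2L))
    expect_equal(frequencyDistribution(allOnes)$fractionSingle, 1)
})

test_that("hypergeometric p-values match exhaustive enumeration on tiny backgrounds", {
    # term of size K in background N, module drawing n annotated genes,
    # observing x
    cases <- expand.grid(N = c(8, 10, 12), K = c(2, 4, 5), n = c(3, 5))
    for (i in seq_len(nrow(cases))) {
        N <- cases$N[i]; K <- cases$K[i]; n <- cases$n[i]
        genes <- sprintf("G%02d", 1:N)
        termGenes <- genes[1:K]
        module <- genes[seq(2, 1 + n)]   # overlap = |{2..K}| = K-1
        x <- length(intersect(module, termGenes))
        g2t <- c(setNames(rep(list("T1"), K), termGenes),
                 setNames(rep(list("T0"), N - K), genes[(K + 1):N]))
        ann <- annotationMap(g2t, background = genes)
        enr <- enrichModules(list(m1 = module), ann, cutoff = 0.001)
        p <- enr$rows$p[enr$rows$term == "T1"]
        expect_equal(p, hyperOracle(x, K, N, n), tolerance = 1e-12)
    }
})

test_that("enrichment handles degenerate terms and unannotatable modules", {
    genes <- sprintf("G%d", 1:10)
    g2t <- setNames(rep(list("ALL"), 10), genes)
    ann <- annotationMap(g2t, background = genes)
    enr <- enrichModules(list(m1 = genes[1:4]), ann)
    # a term covering the whole background is never enriched
    expect_equal(enr$rows$p[enr$rows$term == "ALL"], 1)
    expect_false(enr$summary$significant[1])
    # zero-overlap terms are not reported
    expect_false(any(enr$rows$overlap == 0))
    # unannotated module flagged, excluded from the denominator on request
    enr2 <- enrichModules(list(m1 = genes[1:4], m2 = c("Z1", "Z2")), ann,
                          dropUnannotatable = TRUE)
    expect_true(enr2$summary$unannotatable[2])
    expect_equal(attr(enr2$summary, "fractionSignificant"), 0)
})

test_that("p-value banding follows the reporting convention", {
    expect_equal(pValueBand(c(1e-20, 1e-12, 1e-7, 1e-4, 0.5, NA)),
                 c("<E-15", "E-15 to E-10", "E-10 to E-5", "E-5 to 0.001",
                   ">=0.001", NA))
})
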