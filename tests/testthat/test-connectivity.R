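test_that("the Poisson-binomial tail matches enumeration and closed forms", {
    expect_equal(binomialEnrichment(0, 10, 0.5), 1)
    expect_equal(binomialEnrichment(8, 8, 0.5), 0.5^8)
    expect_equal(binomialEnrichment(8, 10, 0.5), 56 / 1024)

    # equal probabilities reduce to the ordinary binomial tail
    for (p in c(0.2, 0.5, 0.8))
        expect_equal(binomialEnrichment(7, 12, p),
                     pbinom(6, 12, p, lower.tail = FALSE),
                     tolerance = 1e-14)

    # heterogeneous probabilities against 2^n exhaustive enumeration
    set.seed(30)
    for (rep in 1:3) {
        probs <- runif(12, 0.05, 0.95)
        k <- sample(0:12, 1)
        expect_equal(binomialEnrichment(k, 12, probs),
                     pbTailEnumeration(k, probs), tolerance = 1e-12)
    }

    expect_error(binomialEnrichment(5, 3, 0.5), "exceed")
    expect_error(binomialEnrichment(1, 3, c(0.5, 1, 0.5)),
                 "strictly inside")
})

test_that("concordance scoring reproduces counts, score and enrichment", {
    # 6 up-up, 2 down-down, 1 up-down, 1 down-up
    query <- makeCategorical(setNames(c(rep(1, 7), rep(-1, 3)),
                                      paste0("g", 1:10)))
    target <- makeCategorical(setNames(c(rep(1, 6), -1, 1, rep(-1, 2)),
                                       paste0("g", 1:10)))
    res <- concordanceScore(query, target)
    expect_identical(unname(res@counts),
                     c(6L, 2L, 1L, 1L))
    expect_equal(res@score, 0.6)
    expect_equal(res@enrichmentP, 56 / 1024)
    expect_identical(res@direction, "concordant")

    # identical and fully flipped targets hit the score bounds
    same <- concordanceScore(query, query)
    expect_equal(same@score, 1)
    flipped <- makeCategorical(-senses(query))
    anti <- concordanceScore(query, flipped)
    expect_equal(anti@score, -1)
    expect_identical(anti@direction, "discordant")
    expect_equal(anti@enrichmentP, 0.5^10)

    # empty overlap is flagged, not an error
    far <- makeCategorical(c(zz1 = 1L, zz2 = -1L))
    und <- concordanceScore(query, far)
    expect_false(und@defined)
    expect_identical(und@overlap, 0L)
})

test_that("concordance is antisymmetric under negation and symmetric in arguments", {
    set.seed(31)
    for (rep in 1:5) {
        q <- makeCategorical(setNames(sample(c(-1L, 1L), 20, TRUE),
                                      paste0("g", 1:20)))
        t <- makeCategorical(setNames(sample(c(-1L, 1L), 15, TRUE),
                                      paste0("g", 6:20)))
        a <- concordanceScore(q, t)
        b <- concordanceScore(q, makeCategorical(-senses(t)))
        expect_equal(b@score, -a@score)
        expect_identical(b@overlap, a@overlap)
        swapped <- concordanceScore(t, q)
        expect_equal(swapped@score, a@score)
        expect_identical(unname(swapped@counts[c("nUU", "nDD")]),
                         unname(a@counts[c("nUU", "nDD")]))
        expect_identical(unname(swapped@counts[c("nUD", "nDU")]),
                         unname(a@counts[c("nDU", "nUD")]))
    }
})

test_that("background frequencies re-weight the enrichment probability", {
    db <- list(
        makeDrugProfile(c(g1 = 1, g2 = 1, g3 = -1), "dA"),
        makeDrugProfile(c(g1 = 1, g2 = -1), "dB"),
        makeDrugProfile(c(g1 = 1, g3 = -1), "dC"))
    bg <- backgroundFrequencies(db)
    expect_identical(bg$gene, c("g1", "g2", "g3"))
    expect_equal(bg$pUp[1], (3 + 1) / (3 + 2))  # g1 up in all 3 profiles
    expect_equal(bg$pDown[3], (2 + 1) / (3 + 2))
    expect_true(all(bg$pUp > 0 & bg$pUp < 1))

    query <- makeCategorical(c(g1 = 1L, g3 = -1L))
    uni <- concordanceScore(query, db[[1]])
    wtd <- concordanceScore(query, db[[1]], background = bg)
    # matching on commonly regulated genes is less surprising under the
    # frequency-scaled background than under the uniform one
    expect_gt(wtd@enrichmentP, uni@enrichmentP)
})

test_that("regression Z agrees with the least-squares oracle", {
    # perfect proportionality pins Z at the positive cap
    a <- makeSignature(setNames(seq(-1, 1, length.out = 10),
                                paste0("g", 1:10)))
    b <- makeSignature(2 * profileValues(a))
    expect_equal(regressionZ(a, b), 8.2)

    # orthogonal vectors: slope 0, Z = 0
    x <- makeSignature(c(g1 = 1, g2 = -1, g3 = 1, g4 = -1))
    y <- makeSignature(c(g1 = 1, g2 = 1, g3 = -1, g4 = -1))
    expect_equal(regressionZ(x, y), 0)

    # fixed 20-gene vectors against the normal-equations oracle
    set.seed(32)
    va <- setNames(rnorm(20), paste0("g", 1:20))
    vb <- 0.6 * va + rnorm(20, 0, 0.8)
    z <- regressionZ(makeSignature(va), makeSignature(vb))
    oracle <- olsOracle(cbind(1, va), vb, 2)
    expect_equal(z, unname(oracle$z), tolerance = 1e-9)

    expect_error(regressionZ(x, makeSignature(c(g1 = 1, g2 = 2))),
                 "at least 4")
    flat <- makeSignature(setNames(rep(0.5, 4), paste0("g", 1:4)))
    expect_warning(zna <- regressionZ(flat, y), "undefined")
    expect_true(is.na(zna))
})

test_that("rank queries order reversers first under anticorrelate", {
    query <- makeCategorical(setNames(rep(c(1L, -1L), each = 10),
                                      paste0("g", 1:20)))
    exact <- makeDrugProfile(setNames(as.numeric(senses(query)) * 0.5,
                                      geneIds(query)), drug = "self")
    negated <- makeDrugProfile(-profileValues(exact), drug = "mirror")
    noise <- makeDrugProfile(setNames(c(0.5, -0.5, 0.5, -0.5, 0.5, -0.5),
                                      paste0("g", c(1, 2, 3, 11, 12, 13))),
                             drug = "noise")
    db <- list(self = exact, mirror = negated, noise = noise)

    anti <- rankQuery(query, db, "anticorrelate")
    expect_identical(anti$drug[1], "mirror")
    expect_equal(anti$score[1], -1)
    corr <- rankQuery(query, db, "correlate")
    expect_identical(corr$drug[1], "self")
    expect_identical(corr$drug[3], "mirror")

    # undefined-overlap profiles are placed last and flagged
    db$orphan <- makeDrugProfile(c(zz = 1), drug = "orphan")
    anti2 <- rankQuery(query, db, "anticorrelate")
    expect_identical(anti2$drug[4], "orphan")
    expect_false(anti2$defined[4])
})

test_that("KS enrichment statistic and Monte-Carlo null behave as derived", {
    # 5 hits at the very top of 100
    r <- ksEnrichment(1:5, 100, nPermutations = 200, seed = 40)
    expect_equal(r@D, 1 - 5 / 100)
    expect_equal(r@pMC, 1 / 201)

    # evenly spaced hits hug the diagonal
    even <- ksEnrichment(seq(10, 100, by = 10), 100,
                         nPermutations = 200, seed = 41)
    expect_lte(even@D, 0.01)

    expect_warning(all <- ksEnrichment(1:6, 6, nPermutations = 200,
                                       seed = 42), "all items")
    expect_equal(all@D, 0)

    expect_error(ksEnrichment(c(1, 1, 3), 10, seed = 1), "distinct")
    expect_error(ksEnrichment(c(0, 3), 10, seed = 1), "within")
    expect_error(ksEnrichment(1:2, 10, nPermutations = 10, seed = 1),
                 "100 permutations")
})

test_that("the Monte-Carlo p converges to the exhaustive placement fraction", {
    # universe 6, hits at ranks {1,2}: D = 2/3; of the C(6,2) = 15
    # placements only {1,2} reaches D >= 2/3, so the exact p is 1/15
    combos <- combn(6, 2)
    Dall <- apply(combos, 2, function(h)
        max(seq_along(h) / length(h) - sort(h) / 6))
    Dobs <- max(1:2 / 2 - c(1, 2) / 6)
    exact <- mean(Dall >= Dobs)
    expect_equal(exact, 1 / 15)

    r <- ksEnrichment(c(1, 2), 6, nPermutations = 10000, seed = 43)
    expect_equal(r@D, Dobs)
    mcSE <- sqrt(exact * (1 - exact) / 10000)
    expect_lt(abs(r@pMC - exact), 4 * mcSE + 2 / 10001)
})

test_that("anticorrelate queries enrich negated sub-profiles at top ranks", {
    set.seed(44)
    query <- makeCategorical(setNames(sample(c(-1L, 1L), 60, TRUE),
                                      paste0("g", 1:60)))
    qv <- as.numeric(senses(query)) * 0.5
    names(qv) <- geneIds(query)
    db <- list()
    for (i in 1:5) {
        sub <- sample(names(qv), 30)
        db[[sprintf("rev%02d", i)]] <-
            makeDrugProfile(-qv[sub], drug = sprintf("rev%02d", i))
    }
    for (i in 1:15) {
        vals <- setNames(sample(c(-0.5, 0.5), 30, TRUE),
                         sample(paste0("g", 1:60), 30))
        db[[sprintf("rnd%02d", i)]] <-
            makeDrugProfile(vals, drug = sprintf("rnd%02d", i))
    }
    ranked <- rankQuery(query, db, "anticorrelate")
    hitRanks <- ranked$rank[grepl("^rev", ranked$drug)]
    enr <- ksEnrichment(hitRanks, length(db), nPermutations = 2000,
                        seed = 45)
    expect_lt(enr@pMC, 0.01)
})
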