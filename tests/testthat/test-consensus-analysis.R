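test_that("hit selection requires repeated significant anti-correlation", {
    tab <- data.frame(
        drug = rep(c("dAll", "dOne", "dPos", "dTwo"), each = 5),
        signature = rep(paste0("sig", 1:5), 4),
        score = c(rep(-0.8, 5),                 # 5 significant anti
                  c(-0.8, 0.1, 0.2, 0.1, 0.3), # 1 significant anti
                  rep(0.8, 5),                 # significant positive only
                  c(-0.7, -0.6, 0.1, 0.2, 0.1)), # 2 significant anti
        enrichmentP = c(rep(0.001, 5),
                        c(0.001, 0.5, 0.5, 0.5, 0.5),
                        rep(0.001, 5),
                        c(0.01, 0.02, 0.5, 0.5, 0.5)),
        defined = TRUE, stringsAsFactors = FALSE)
    expect_identical(selectHits(tab), c("dAll", "dTwo"))
    expect_identical(selectHits(tab, minSignatures = 3), "dAll")
    expect_identical(selectHits(tab, alpha = 0.005), "dAll")

    # monotone: lowering alpha or raising minSignatures never adds drugs
    grids <- expand.grid(alpha = c(0.05, 0.02, 0.005),
                         minSig = c(1, 2, 3, 5))
    for (i in seq_len(nrow(grids) - 1)) {
        hi <- selectHits(tab, minSignatures = grids$minSig[i],
                         alpha = grids$alpha[i])
        lo <- selectHits(tab, minSignatures = grids$minSig[i] + 1,
                         alpha = grids$alpha[i] / 2)
        expect_true(all(lo %in% hi))
    }
})

test_that("connectivityTable feeds selectHits end to end", {
    query1 <- makeCategorical(setNames(rep(c(1L, -1L), 6),
                                       paste0("g", 1:12)))
    query2 <- makeCategorical(senses(query1))
    antiVals <- setNames(-as.numeric(senses(query1)) * 0.5,
                         geneIds(query1))
    anti <- makeDrugProfile(antiVals, "dAnti")
    tab <- connectivityTable(list(dAnti = anti),
                             list(q1 = query1, q2 = query2))
    expect_identical(nrow(tab), 2L)
    expect_true(all(tab$score == -1))
    expect_identical(selectHits(tab, minSignatures = 2, alpha = 0.05),
                     "dAnti")
})

test_that("sum-sense consensus applies the strict ratio threshold", {
    mk <- function(vals, d) makeDrugProfile(vals, drug = d)
    profiles <- list(
        p1 = mk(c(gUp = 0.5, gEdge = 0.5), "p1"),
        p2 = mk(c(gUp = 0.4, gEdge = 0.3), "p2"),
        p3 = mk(c(gUp = 0.7, gEdge = 0.2), "p3"),
        p4 = mk(c(gUp = 0.2, gEdge = -0.5), "p4"),
        p5 = mk(c(gUp = 0.3, gOther = 1), "p5"),
        p6 = mk(c(gUp = 0.6, gOther = -1), "p6"))
    cons <- sumSenseConsensus(profiles)
    # gUp: sense +1 in all 6 -> ratio 1
    expect_true("gUp" %in% geneIds(cons))
    expect_equal(unname(profileValues(cons)["gUp"]), 1)
    # gEdge: (+,+,+,-,0,0) -> ratio (3-1)/6 = 1/3, NOT > 1/3, dropped
    expect_false("gEdge" %in% geneIds(cons))
    # gOther: (+,-) cancels -> 0, dropped
    expect_false("gOther" %in% geneIds(cons))

    # invariant under reordering; antisymmetric under global sense flip
    shuffled <- sumSenseConsensus(profiles[c(4, 2, 6, 1, 3, 5)])
    expect_equal(profileValues(shuffled), profileValues(cons))
    flipped <- lapply(profiles, function(p) {
        p@values <- -p@values; p })
    consFlip <- sumSenseConsensus(flipped)
    expect_equal(profileValues(consFlip),
                 -profileValues(cons)[geneIds(consFlip)])

    expect_error(sumSenseConsensus(profiles[1]), ">= 2")
})

test_that("UPGMA reproduces the hand-traced merges and stays ultrametric", {
    # hand-executed average linkage on a 4-leaf distance matrix:
    # join (A,B) at height 2/2 = 1; d(AB,C) = (4+4)/2 = 4 -> height 2;
    # d(ABC,D) = (6+6+6)/3 = 6 -> height 3
    D <- matrix(c(0, 2, 4, 6,
                  2, 0, 4, 6,
                  4, 4, 0, 6,
                  6, 6, 6, 0), 4, 4,
                dimnames = list(LETTERS[1:4], LETTERS[1:4]))
    den <- upgmaFromDistance(D)
    expect_equal(den@heights, c(1, 2, 3))
    expect_identical(den@merge[1, ], c(-1L, -2L))     # A with B first
    expect_identical(sort(den@merge[2, ]), c(-3L, 1L)) # then C joins (A,B)
    expect_identical(sort(den@merge[3, ]), c(-4L, 2L)) # D last

    hc <- asHclust(den)
    expect_s3_class(hc, "hclust")
    expect_identical(hc$labels, LETTERS[1:4])

    nw <- tempfile(fileext = ".nwk")
    writeNewick(den, nw)
    tree <- ape::read.tree(nw)
    expect_setequal(tree$tip.label, LETTERS[1:4])
})

test_that("profile clustering merges identical profiles first", {
    vals <- setNames(c(0.5, -0.5, 0.5, -0.5, 0.5, -0.5), paste0("g", 1:6))
    profiles <- list(
        a = makeDrugProfile(vals, "a"),
        b = makeDrugProfile(vals, "b"),            # identical to a
        c = makeDrugProfile(-vals, "c"))           # fully opposed
    den <- upgmaCluster(profiles)
    expect_equal(den@heights[1], 0)               # identical pair first
    expect_identical(sort(den@merge[1, ]), c(-2L, -1L))
    expect_equal(den@heights[2], 1)               # distance 2 -> height 1
    expect_true(!is.unsorted(den@heights))

    # two profiles at sense distance d merge at height d/2
    two <- upgmaCluster(profiles[c("a", "c")])
    expect_equal(two@heights, 1)

    # a pair with no gene overlap gets the maximum distance, with warning
    profiles$d <- makeDrugProfile(c(zz = 1), "d")
    expect_warning(den2 <- upgmaCluster(profiles), "imputed")
    expect_true(validObject(den2))
})

test_that("within-set correlations exceed outside ones for a planted subset", {
    set.seed(50)
    shared <- setNames(rnorm(40), paste0("g", 1:40))
    profiles <- list()
    for (i in 1:4)   # correlated members: shared core plus small noise
        profiles[[sprintf("adc%d", i)]] <- makeDrugProfile(
            shared + rnorm(40, 0, 0.4), sprintf("adc%d", i))
    for (i in 1:4)   # unrelated profiles
        profiles[[sprintf("rnd%d", i)]] <- makeDrugProfile(
            setNames(rnorm(40), paste0("g", 1:40)), sprintf("rnd%d", i))
    sumry <- setCorrelationSummary(paste0("adc", 1:4), profiles)
    expect_equal(sumry$nWithinPairs, choose(4, 2))
    expect_equal(sumry$nOutsidePairs, choose(8, 2) - choose(4, 2))
    expect_gt(sumry$withinMeanZ, sumry$outsideMeanZ)

    # all-identical profiles collapse both means onto the Z cap
    same <- list(a = profiles[[1]], b = profiles[[1]], c = profiles[[1]])
    s2 <- setCorrelationSummary(c("a", "b"), same)
    expect_equal(s2$withinMeanZ, 8.2)
    expect_equal(s2$outsideMeanZ, 8.2)

    expect_error(setCorrelationSummary(names(profiles), profiles),
                 "strict subset")
    expect_warning(setCorrelationSummary("adc1", profiles), "singleton")
})

test_that("over-representation matches the hypergeometric closed form", {
    universe <- sprintf("g%04d", 1:1000)
    inSet <- universe[1:20]
    gs <- new("GeneSetCollection",
              sets = list(hit = inSet, miss = universe[900:940]),
              descriptions = c("planted", "disjoint"))
    res <- oraPathways(inSet, gs, universe, alpha = 0.5)
    expect_identical(res$set[1], "hit")
    # full overlap of a 20-gene set drawn as a 20-gene cohort
    oracle <- exp(lchoose(20, 20) + lchoose(980, 0) - lchoose(1000, 20))
    expect_equal(res$p[res$set == "hit"], oracle, tolerance = 1e-12)
    expect_false("miss" %in% res$set)

    expect_identical(nrow(oraPathways(character(0), gs, universe)), 0L)
    expect_error(oraPathways("nope", gs, universe), "subset")
})

test_that("random cohorts produce nominal false-positive rates before adjustment", {
    set.seed(51)
    universe <- sprintf("g%04d", 1:500)
    gs <- new("GeneSetCollection",
              sets = setNames(lapply(1:20, function(i)
                  sample(universe, 25)), sprintf("set%02d", 1:20)),
              descriptions = sprintf("random set %d", 1:20))
    falsePos <- 0
    nRep <- 30
    for (r in seq_len(nRep)) {
        cohort <- sample(universe, 40)
        res <- oraPathways(cohort, gs, universe, alpha = 1.1)
        falsePos <- falsePos + sum(res$p < 0.05)
    }
    rate <- falsePos / (nRep * 20)
    # hypergeometric discreteness keeps the realised rate at or below
    # nominal; allow a generous band around 0.05
    expect_lt(rate, 0.1)
})
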