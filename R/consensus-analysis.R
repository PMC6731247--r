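# Post-scoring analysis: hit selection, sum-sense gene cohorts, UPGMA
# clustering of compounds, within/between-set correlation summaries and
# gene-set over-representation.

#' Tabulate connectivity of a profile database against several signatures
#'
#' Convenience builder of the drug x signature score table consumed by
#' [selectHits()].
#'
#' @param db named list of \linkS4class{DrugProfile}s.
#' @param queries named list of \linkS4class{CategoricalSignature}s.
#' @param background passed to [concordanceScore()].
#' @return data.frame with columns `drug`, `signature`, `score`,
#'   `enrichmentP`, `overlap`, `defined`
#' @export
connectivityTable <- function(db, queries, background = "uniform") {
    drugs <- if (!is.null(names(db))) names(db)
             else vapply(db, function(p) p@drug, "")
    sigs <- names(queries)
    if (is.null(sigs)) sigs <- sprintf("signature%d", seq_along(queries))
    rows <- lapply(seq_along(queries), function(j) {
        res <- lapply(db, concordanceScore, query = queries[[j]],
                      background = background)
        data.frame(drug = drugs, signature = sigs[j],
                   score = vapply(res, function(r) r@score, 1),
                   enrichmentP = vapply(res, function(r) r@enrichmentP, 1),
                   overlap = vapply(res, function(r) r@overlap, 1L),
                   defined = vapply(res, function(r) r@defined, TRUE),
                   stringsAsFactors = FALSE, row.names = NULL)
    })
    do.call(rbind, rows)
}

#' Select hit compounds by repeated significant anti-correlation
#'
#' A drug is a hit when its significant anti-correlations — comparisons with
#' negative score, enrichment probability below `alpha` and a gene overlap
#' of at least `minOverlap` — number at least `minSignatures`. The overlap
#' floor guards against chance overlaps of a few genes, whose discrete
#' enrichment tail can reach nominal significance from a single lucky
#' sense pattern. Lowering `alpha` or raising `minSignatures` can only
#' shrink the hit set.
#'
#' @param scoreTable data.frame as from [connectivityTable()].
#' @param minSignatures minimum number of signatures (default 2).
#' @param alpha significance level on the enrichment probability
#'   (default 0.05).
#' @param minOverlap minimum gene overlap for a comparison to count
#'   (default 10; ignored if the table lacks an `overlap` column).
#' @return sorted character vector of hit drugs
#' @export
selectHits <- function(scoreTable, minSignatures = 2, alpha = 0.05,
                       minOverlap = 10) {
    needed <- c("drug", "signature", "score", "enrichmentP")
    if (!all(needed %in% colnames(scoreTable)))
        stop("score table must have columns ",
             paste(needed, collapse = ", "))
    defined <- if ("defined" %in% colnames(scoreTable))
        scoreTable$defined else !is.na(scoreTable$score)
    bigEnough <- if ("overlap" %in% colnames(scoreTable))
        scoreTable$overlap >= minOverlap else TRUE
    sig <- defined & bigEnough & scoreTable$score < 0 &
        scoreTable$enrichmentP < alpha
    counts <- table(scoreTable$drug[sig])
    sort(names(counts)[counts >= minSignatures])
}

#' Consistently regulated genes by sum-sense ratio
#'
#' Per gene, the ratio \eqn{(1/P) \sum_i \mathrm{sign}(g_i)} of regulation
#' senses over `P` profiles (0 where the gene is absent); genes with
#' `|ratio|` strictly above `minRatio` (default 1/3) form the consensus
#' cohort.
#'
#' @param profiles list of at least two \linkS4class{DrugProfile}s.
#' @param minRatio strict retention threshold (default 1/3).
#' @return a \linkS4class{SenseConsensus} over the selected genes
#' @export
sumSenseConsensus <- function(profiles, minRatio = 1 / 3) {
    if (length(profiles) < 2L) stop("need >= 2 profiles")
    P <- length(profiles)
    allGenes <- sort(unique(unlist(lapply(profiles, geneIds))))
    S <- matrix(0L, nrow = length(allGenes), ncol = P,
                dimnames = list(allGenes, names(profiles)))
    for (i in seq_len(P)) {
        si <- senses(profiles[[i]])
        S[names(si), i] <- si
    }
    ratio <- rowMeans(S)
    keep <- abs(ratio) > minRatio
    new("SenseConsensus", genes = allGenes[keep],
        ratios = unname(ratio[keep]),
        senseMatrix = S[keep, , drop = FALSE])
}

# Pairwise sense concordance distance between two profiles (1 - score);
# NA when the gene overlap is empty.
.senseDistance <- function(a, b) {
    sa <- senses(a); sa <- sa[sa != 0L]
    sb <- senses(b); sb <- sb[sb != 0L]
    common <- intersect(names(sa), names(sb))
    if (!length(common)) return(NA_real_)
    1 - mean(sa[common] * sb[common])
}

.pearsonDistance <- function(a, b) {
    va <- profileValues(a); vb <- profileValues(b)
    common <- intersect(names(va), names(vb))
    if (length(common) < 2L) return(NA_real_)
    x <- va[common]; y <- vb[common]
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    1 - cor(x, y)
}

#' UPGMA clustering of drug profiles
#'
#' Agglomerates profiles by average linkage (UPGMA) on a pairwise profile
#' distance: `1 - concordance score` over the sense overlap (default) or
#' `1 - Pearson correlation` of the values over the overlap. Node heights
#' are half the average inter-cluster distance at each merge (so two
#' profiles at distance d join at height d/2) and are non-decreasing — the
#' ultrametric property is asserted by the class validity on every run.
#' Pairs with no overlap get the maximum observed distance, with a warning.
#'
#' @param profiles named list of at least two \linkS4class{DrugProfile}s.
#' @param distance `"concordance"` or `"pearson"`.
#' @return a \linkS4class{Dendrogram}
#' @export
upgmaCluster <- function(profiles, distance = c("concordance", "pearson")) {
    distance <- match.arg(distance)
    n <- length(profiles)
    if (n < 2L) stop("need >= 2 profiles to cluster")
    labels <- if (!is.null(names(profiles))) names(profiles)
              else vapply(profiles, function(p) p@drug, "")
    labels <- make.unique(labels)
    fun <- if (distance == "concordance") .senseDistance
           else .pearsonDistance
    D <- matrix(0, n, n, dimnames = list(labels, labels))
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
        D[i, j] <- D[j, i] <- fun(profiles[[i]], profiles[[j]])
    }
    if (anyNA(D)) {
        warning("undefined pairwise distance(s) imputed as the maximum")
        D[is.na(D)] <- max(D, na.rm = TRUE)
    }
    upgmaFromDistance(D)
}

#' UPGMA tree from a precomputed distance matrix
#'
#' Average-linkage agglomeration of a symmetric distance matrix; merge
#' heights are half the average inter-cluster distance (node heights of the
#' ultrametric tree).
#'
#' @param D symmetric numeric distance matrix with labelled rows.
#' @return a \linkS4class{Dendrogram}
#' @export
upgmaFromDistance <- function(D) {
    if (is.null(rownames(D))) rownames(D) <- colnames(D) <-
        sprintf("leaf%d", seq_len(nrow(D)))
    hc <- hclust(as.dist(D), method = "average")
    new("Dendrogram", merge = hc$merge, heights = hc$height / 2,
        labels = rownames(D), order = as.integer(hc$order))
}

#' Convert a Dendrogram to hclust / export as Newick
#'
#' @param x a \linkS4class{Dendrogram}
#' @return `asHclust` returns a `stats::hclust` object (heights are node
#'   heights, i.e. half merge distances).
#' @export
asHclust <- function(x) {
    structure(list(merge = x@merge, height = x@heights, order = x@order,
                   labels = x@labels, method = "average",
                   call = match.call(), dist.method = "profile"),
              class = "hclust")
}

#' @rdname asHclust
#' @param path output file path for the Newick tree
#' @return `writeNewick` returns the path invisibly.
#' @export
writeNewick <- function(x, path) {
    ape::write.tree(ape::as.phylo(asHclust(x)), file = path)
    invisible(path)
}

#' Within- versus outside-set correlation summary
#'
#' Mean [regressionZ()] over all unordered pairs inside a member set versus
#' all remaining unordered pairs (pairs of a profile with itself are never
#' formed). Pairs with an undefined regression — zero variance or an
#' overlap below the 4 genes a slope test needs — are excluded from the
#' means.
#'
#' @param memberSet character vector of member drug names (a strict,
#'   non-empty subset of the profiles).
#' @param profiles named list of \linkS4class{DrugProfile}s.
#' @return list with `withinMeanZ`, `outsideMeanZ`, `nWithinPairs`,
#'   `nOutsidePairs`
#' @export
setCorrelationSummary <- function(memberSet, profiles) {
    nms <- names(profiles)
    if (is.null(nms)) stop("profiles must be named")
    if (!length(memberSet) || !all(memberSet %in% nms))
        stop("memberSet must be a non-empty subset of the profiles")
    if (length(memberSet) == length(profiles))
        stop("memberSet must be a strict subset")
    if (length(memberSet) == 1L)
        warning("singleton set: within-set mean undefined")
    pairs <- combn(nms, 2L)
    z <- apply(pairs, 2L, function(pr)
        tryCatch(suppressWarnings(regressionZ(profiles[[pr[1]]],
                                              profiles[[pr[2]]])),
                 error = function(e) NA_real_))
    within <- pairs[1, ] %in% memberSet & pairs[2, ] %in% memberSet
    list(withinMeanZ = if (any(within)) mean(z[within], na.rm = TRUE)
                       else NA_real_,
         outsideMeanZ = mean(z[!within], na.rm = TRUE),
         nWithinPairs = sum(within),
         nOutsidePairs = sum(!within))
}

#' Gene-set over-representation of a cohort
#'
#' Hypergeometric upper-tail p-value per set (overlap at least as large as
#' observed, given cohort and set sizes within the universe), adjusted by
#' Benjamini-Hochberg; sets with adjusted p below `alpha` are returned with
#' their overlap counts.
#'
#' @param cohort character gene set of interest (subset of `universe`).
#' @param collection a \linkS4class{GeneSetCollection}.
#' @param universe character background gene universe.
#' @param alpha FDR level (default 0.05).
#' @return data.frame with columns `set`, `description`, `overlap`,
#'   `setSize`, `cohortSize`, `p`, `padj`, ordered by p
#' @export
oraPathways <- function(cohort, collection, universe, alpha = 0.05) {
    if (!all(cohort %in% universe))
        stop("cohort must be a subset of the universe")
    empty <- data.frame(set = character(0), description = character(0),
                        overlap = integer(0), setSize = integer(0),
                        cohortSize = integer(0), p = numeric(0),
                        padj = numeric(0), stringsAsFactors = FALSE)
    if (!length(cohort) || !length(collection@sets)) return(empty)
    N <- length(universe)
    nC <- length(cohort)
    res <- lapply(seq_along(collection@sets), function(i) {
        members <- intersect(collection@sets[[i]], universe)
        K <- length(members)
        k <- length(intersect(cohort, members))
        p <- if (K == 0L) 1 else
            phyper(k - 1L, K, N - K, nC, lower.tail = FALSE)
        data.frame(set = names(collection@sets)[i],
                   description = collection@descriptions[i],
                   overlap = k, setSize = K, cohortSize = nC, p = p,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    out$padj <- p.adjust(out$p, method = "BH")
    out <- out[out$padj < alpha, , drop = FALSE]
    out[order(out$p), , drop = FALSE]
}
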