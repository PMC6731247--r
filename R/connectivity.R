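# Connectivity scoring: sense concordance with exact Poisson-binomial
# enrichment, regression Z between continuous profiles, database ranking,
# and KS running-sum rank enrichment with a Monte-Carlo null.

# Exact Poisson-binomial distribution by dynamic programming: f[j+1] is
# P(X = j) after all trials. O(n^2), exact to double precision.
.poissonBinomialDensity <- function(probs) {
    f <- 1
    for (p in probs)
        f <- c(f * (1 - p), 0) + c(0, f * p)
    f
}

#' Exact enrichment probability for non-identical Bernoulli trials
#'
#' Upper-tail probability `P(X >= matches)` of a Poisson-binomial variable
#' — the number of successes in independent trials with per-gene success
#' probabilities — computed exactly by dynamic programming. With equal
#' probabilities this reduces to the ordinary binomial tail. A per-gene
#' probability table (e.g. regulation frequencies across a profile
#' database, see [backgroundFrequencies()]) makes frequently regulated
#' genes cheap matches and rare ones informative.
#'
#' @param matches observed success count (`<= trials`).
#' @param trials number of trials.
#' @param probs success probability per trial, each strictly inside (0, 1);
#'   a scalar is recycled.
#' @return the tail probability, in (0, 1]
#' @export
binomialEnrichment <- function(matches, trials, probs) {
    if (matches > trials) stop("matches cannot exceed trials")
    if (matches < 0 || trials < 0) stop("counts must be non-negative")
    if (length(probs) == 1L) probs <- rep(probs, trials)
    if (length(probs) != trials)
        stop("need one probability per trial")
    if (any(probs <= 0) || any(probs >= 1))
        stop("probabilities must lie strictly inside (0, 1)")
    if (matches == 0) return(1)
    f <- .poissonBinomialDensity(probs)
    sum(f[seq.int(matches + 1L, trials + 1L)])
}

#' Per-gene regulation frequencies of a profile database
#'
#' Background probability table for [concordanceScore()]: for every gene,
#' the fraction of database profiles regulating it up and down, with
#' add-one (Laplace) smoothing so probabilities stay strictly inside
#' (0, 1).
#'
#' @param db list of \linkS4class{DrugProfile}s.
#' @param genes gene universe to tabulate (default: union over the db).
#' @return data.frame with columns `gene`, `pUp`, `pDown`
#' @export
backgroundFrequencies <- function(db, genes = NULL) {
    if (is.null(genes))
        genes <- sort(unique(unlist(lapply(db, geneIds))))
    P <- length(db)
    up <- setNames(numeric(length(genes)), genes)
    down <- up
    for (p in db) {
        s <- senses(p)
        up[names(s)[s > 0]] <- up[names(s)[s > 0]] + 1
        down[names(s)[s < 0]] <- down[names(s)[s < 0]] + 1
    }
    data.frame(gene = genes, pUp = unname((up + 1) / (P + 2)),
               pDown = unname((down + 1) / (P + 2)),
               stringsAsFactors = FALSE)
}

#' Sense concordance between a categorical query and a profile
#'
#' Over the gene overlap, counts sense agreements and disagreements
#' (up-up, down-down, up-down, down-up) and forms the concordance score
#' \deqn{(n_{\uparrow\uparrow} + n_{\downarrow\downarrow} -
#'        n_{\uparrow\downarrow} - n_{\downarrow\uparrow}) / n}
#' in [-1, 1]. The enrichment probability is the exact Poisson-binomial
#' tail ([binomialEnrichment()]) of the observed excess, evaluated in the
#' observed direction: the concordant count for non-negative scores, the
#' discordant count (with complemented probabilities) otherwise. An empty
#' overlap yields a result flagged undefined, not an error.
#'
#' @param query a \linkS4class{CategoricalSignature}.
#' @param target a \linkS4class{SignatureProfile},
#'   \linkS4class{DrugProfile} or \linkS4class{CategoricalSignature}.
#' @param background `"uniform"` (p = 0.5 per gene) or a data.frame from
#'   [backgroundFrequencies()].
#' @return a \linkS4class{ConnectivityResult}
#' @export
concordanceScore <- function(query, target, background = "uniform") {
    qs <- senses(query)
    ts <- senses(target)
    ts <- ts[ts != 0L]
    common <- intersect(names(qs), names(ts))
    n <- length(common)
    if (n == 0L)
        return(new("ConnectivityResult",
                   counts = setNames(integer(4),
                                     c("nUU", "nDD", "nUD", "nDU")),
                   score = NA_real_, enrichmentP = NA_real_,
                   direction = "undefined", overlap = 0L,
                   defined = FALSE))
    q <- qs[common]; t <- ts[common]
    counts <- c(nUU = sum(q > 0 & t > 0), nDD = sum(q < 0 & t < 0),
                nUD = sum(q > 0 & t < 0), nDU = sum(q < 0 & t > 0))
    score <- (counts["nUU"] + counts["nDD"] - counts["nUD"] -
              counts["nDU"]) / n
    pMatch <- if (identical(background, "uniform")) {
        rep(0.5, n)
    } else {
        idx <- match(common, background$gene)
        if (anyNA(idx))
            stop("background table missing gene(s): ",
                 paste(head(common[is.na(idx)], 3), collapse = ", "))
        ifelse(q > 0, background$pUp[idx], background$pDown[idx])
    }
    if (score >= 0) {
        direction <- "concordant"
        p <- binomialEnrichment(unname(counts["nUU"] + counts["nDD"]), n,
                                pMatch)
    } else {
        direction <- "discordant"
        p <- binomialEnrichment(unname(counts["nUD"] + counts["nDU"]), n,
                                1 - pMatch)
    }
    new("ConnectivityResult", counts = setNames(as.integer(counts),
            c("nUU", "nDD", "nUD", "nDU")),
        score = unname(score), enrichmentP = p, direction = direction,
        overlap = n, defined = TRUE)
}

#' Regression Z score between two continuous profiles
#'
#' Least-squares fit of `b` on `a` over their gene overlap; the two-sided
#' p-value of the slope's t statistic is converted to a Z via the
#' standard-normal quantile, signed by the slope and capped at +/- `zCap`.
#' A zero-variance side makes the regression undefined (`NA` with a
#' warning).
#'
#' @param a,b \linkS4class{SignatureProfile}s or
#'   \linkS4class{DrugProfile}s.
#' @param zCap cap on |Z| (default 8.2).
#' @return a single signed Z score (or `NA` if undefined)
#' @export
regressionZ <- function(a, b, zCap = .capZ) {
    va <- profileValues(a)
    vb <- profileValues(b)
    common <- intersect(names(va), names(vb))
    if (length(common) < 4L)
        stop("gene overlap must contain at least 4 genes")
    x <- va[common]; y <- vb[common]
    sxx <- sum((x - mean(x))^2)
    syy <- sum((y - mean(y))^2)
    if (sxx == 0 || syy == 0) {
        warning("zero-variance profile over the overlap: Z undefined")
        return(NA_real_)
    }
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    slope <- sxy / sxx
    df <- length(common) - 2L
    rss <- syy - slope * sxy
    rss <- max(rss, 0)
    se <- sqrt(rss / df / sxx)
    if (se == 0) {
        p <- 0
    } else {
        t <- slope / se
        p <- 2 * pt(-abs(t), df)
    }
    .signedZ(p, slope, cap = zCap)
}

#' Rank a profile database against a categorical query
#'
#' Scores every database profile with [concordanceScore()] and orders them
#' by score — ascending under `anticorrelate` (strongest reversers first),
#' descending under `correlate` — with ties broken by ascending enrichment
#' probability and finally lexicographically by drug name. Profiles whose
#' gene overlap with the query is below `minOverlap` carry too little
#' information for a meaningful sense comparison (a handful of chance
#' overlap genes can score exactly +/-1); they are placed last and flagged
#' `rankable = FALSE`, as are profiles with an undefined (empty-overlap)
#' score.
#'
#' @param query a \linkS4class{CategoricalSignature}.
#' @param db named list of \linkS4class{DrugProfile}s.
#' @param direction `"anticorrelate"` or `"correlate"`.
#' @param background passed to [concordanceScore()].
#' @param minOverlap minimum gene overlap for a profile to be ranked on its
#'   score (default 5).
#' @return data.frame with columns `drug`, `rank` (1-based), `score`,
#'   `enrichmentP`, `overlap`, `defined`, `rankable`; the full
#'   \linkS4class{ConnectivityResult} list is attached as attribute
#'   `"results"`.
#' @export
rankQuery <- function(query, db,
                      direction = c("anticorrelate", "correlate"),
                      background = "uniform", minOverlap = 5) {
    direction <- match.arg(direction)
    if (!length(db)) stop("profile database is empty")
    drugs <- if (!is.null(names(db))) names(db)
             else vapply(db, function(p) p@drug, "")
    results <- lapply(db, concordanceScore, query = query,
                      background = background)
    score <- vapply(results, function(r) r@score, 1)
    p <- vapply(results, function(r) r@enrichmentP, 1)
    defined <- vapply(results, function(r) r@defined, TRUE)
    overlap <- vapply(results, function(r) r@overlap, 1L)
    rankable <- defined & overlap >= minOverlap
    key <- if (direction == "anticorrelate") score else -score
    key[!rankable] <- Inf
    ord <- order(key, ifelse(rankable, p, Inf), drugs)
    out <- data.frame(drug = drugs[ord], rank = seq_along(ord),
                      score = score[ord], enrichmentP = p[ord],
                      overlap = overlap[ord], defined = defined[ord],
                      rankable = rankable[ord], stringsAsFactors = FALSE,
                      row.names = NULL)
    attr(out, "results") <- results[ord]
    out
}

#' KS running-sum rank enrichment with a Monte-Carlo null
#'
#' For a set of hit positions within a ranked universe, the statistic is
#' the maximal positive deviation of the cumulative hit fraction from the
#' zero-enrichment diagonal,
#' \deqn{D = \max_i \left( i/m - h_i/N \right)}
#' with sorted hit ranks `h`, `m` hits and universe size `N` (enrichment
#' toward high, i.e. early, ranks). Significance is the Monte-Carlo
#' probability that a uniformly random placement of `m` hits attains a
#' peak deviation at least `D`, with the add-one estimator
#' `(1 + #exceed)/(nPermutations + 1)` so it is never zero.
#'
#' @param hitRanks distinct integer ranks in `[1, universeSize]`.
#' @param universeSize size of the ranked universe.
#' @param nPermutations number of random placements (>= 100).
#' @param seed integer seed for the permutation stream.
#' @return an \linkS4class{EnrichmentResult}
#' @export
ksEnrichment <- function(hitRanks, universeSize, nPermutations = 1000,
                         seed) {
    if (missing(seed)) stop("a seed is required")
    if (anyDuplicated(hitRanks)) stop("hit ranks must be distinct")
    if (any(hitRanks < 1 | hitRanks > universeSize))
        stop("hit ranks must lie within [1, universeSize]")
    if (nPermutations < 100) stop("use at least 100 permutations")
    m <- length(hitRanks)
    if (m == universeSize)
        warning("all items are hits: D = 0 by construction")
    ii <- seq_len(m)
    D <- max(ii / m - sort(hitRanks) / universeSize)
    D <- max(D, 0)
    set.seed(seed)
    exceed <- 0L
    for (b in seq_len(nPermutations)) {
        h <- sort.int(sample.int(universeSize, m))
        if (max(ii / m - h / universeSize) >= D) exceed <- exceed + 1L
    }
    new("EnrichmentResult", D = D,
        pMC = (1 + exceed) / (nPermutations + 1),
        nPermutations = as.integer(nPermutations),
        seed = as.integer(seed))
}
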