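# Drug perturbation profiles: CMAP-style rank transforms with replicate
# aggregation and probe collapse, the cell-identity relative-rank profile,
# and plate-normalised treatment profiles (scaled fold or Z score).

#' CMAP-style scaled rank transform
#'
#' Maps per-feature expression-change ranks linearly onto [-1, 1]:
#' \deqn{v = 1 - 2 (R - R_{min}) / (R_{max} - R_{min})}
#' so the most upregulated feature (rank `R_min`) gets +1 and the most
#' downregulated (`R_max`) gets -1. Tied or non-contiguous ranks are first
#' resolved to a contiguous range by average ranking followed by a stable
#' re-rank.
#'
#' @param ranks named numeric/integer vector of ranks (1 = most
#'   upregulated).
#' @param drug,cellContext labels stored on the profile.
#' @return a \linkS4class{RankProfile}
#' @export
cmapRankTransform <- function(ranks, drug = "", cellContext = "") {
    if (length(ranks) < 2L)
        stop("at least 2 features are required for a rank profile")
    if (is.null(names(ranks)))
        stop("ranks must be named by feature")
    r <- as.numeric(ranks)
    if (!setequal(r, seq(min(r), max(r))) || anyDuplicated(r))
        r <- rank(rank(r, ties.method = "average"), ties.method = "first")
    v <- 1 - 2 * (r - min(r)) / (max(r) - min(r))
    new("RankProfile", features = names(ranks), values = unname(v),
        pValues = numeric(0), drug = drug, replicates = 1L,
        cellContext = cellContext)
}

#' Aggregate replicate rank profiles with a one-sample t filter
#'
#' Per feature, the mean of the replicate values; features are retained when
#' a one-sample Student t-test against zero gives `p < alpha`. Replicates
#' that agree exactly (zero variance) are retained when their common value
#' is nonzero — the t statistic is degenerate but the evidence maximal. A
#' single profile is returned unfiltered with a warning (t undefined).
#'
#' @param profiles list of \linkS4class{RankProfile}s over a shared feature
#'   universe.
#' @param alpha significance level (default 0.05).
#' @return a \linkS4class{RankProfile} with the replicate count recorded and
#'   per-feature p-values attached.
#' @export
aggregateReplicates <- function(profiles, alpha = 0.05) {
    if (length(profiles) == 1L) {
        warning("single replicate: returned unfiltered (t undefined)")
        return(profiles[[1]])
    }
    feats <- profiles[[1]]@features
    for (p in profiles[-1])
        if (!identical(sort(p@features), sort(feats)))
            stop("replicate profiles must share a feature universe")
    M <- vapply(profiles, function(p) profileValues(p)[feats],
                numeric(length(feats)))
    if (is.null(dim(M))) M <- matrix(M, nrow = length(feats))
    tt <- .rowOneSampleT(M)
    keep <- tt$p < alpha
    new("RankProfile", features = feats[keep],
        values = unname(tt$mean[keep]), pValues = unname(tt$p[keep]),
        drug = profiles[[1]]@drug,
        replicates = as.integer(length(profiles)),
        cellContext = profiles[[1]]@cellContext)
}

#' Collapse probe-level profiles to gene level
#'
#' For each gene, the value of its largest-magnitude significant probe is
#' kept (the retained probes of a filtered profile are by construction the
#' significant ones); genes with no significant probe are absent. Probes
#' missing from the map are dropped with a warning stating their number.
#'
#' @param profile a probe-level \linkS4class{DrugProfile} or
#'   \linkS4class{RankProfile}.
#' @param map a \linkS4class{ProbeGeneMap}.
#' @return the same class of profile at gene level.
#' @export
collapseProbes <- function(profile, map) {
    feats <- geneIds(profile)
    idx <- match(feats, map@probes)
    unmapped <- is.na(idx)
    if (any(unmapped))
        warning(sum(unmapped), " unmapped probe(s) dropped")
    keep <- which(!unmapped)
    gene <- map@genes[idx[keep]]
    vals <- profileValues(profile)[keep]
    pick <- vapply(split(keep, gene), function(ii) {
        ii[which.max(abs(profileValues(profile)[ii]))]
    }, 1L)
    ord <- order(names(pick))
    pick <- pick[ord]
    if (is(profile, "RankProfile")) {
        new("RankProfile", features = names(pick),
            values = unname(profile@values[pick]),
            pValues = if (length(profile@pValues))
                unname(profile@pValues[pick]) else numeric(0),
            drug = profile@drug, replicates = profile@replicates,
            cellContext = profile@cellContext)
    } else {
        new("DrugProfile", genes = names(pick),
            values = unname(profile@values[pick]),
            stats = unname(profile@stats[pick]),
            statKind = profile@statKind, drug = profile@drug,
            plate = profile@plate, method = profile@method)
    }
}

#' Cell-identity relative-rank profile
#'
#' Compares a sample set's mean expression ranks to a background rank
#' reference. Ranks are scaled to [0, 1] with 0 the highest-expressed
#' feature. The relative rank is
#' \deqn{(r_0 - r)/r_0 \textrm{ for } r < r_0, \qquad
#'       (r_0 - r)/(1 - r_0) \textrm{ for } r > r_0,}
#' positive where the sample expresses the feature higher than the
#' background, 0 at `r = r_0`. The degenerate corners `r = r_0 = 0` and
#' `r = r_0 = 1` take the values +1 and -1 by continuity, with a warning.
#'
#' @param sampleRanks,backgroundRanks named numeric vectors in [0, 1] over
#'   the same features.
#' @param reference label of the background source.
#' @return a \linkS4class{CellIdentityProfile}
#' @export
cellIdentityProfile <- function(sampleRanks, backgroundRanks,
                                reference = "background") {
    if (is.null(names(sampleRanks)) || is.null(names(backgroundRanks)))
        stop("ranks must be named by feature")
    if (!setequal(names(sampleRanks), names(backgroundRanks)))
        stop("sample and background ranks must cover the same features")
    r <- sampleRanks
    r0 <- backgroundRanks[names(sampleRanks)]
    if (any(r < 0 | r > 1 | r0 < 0 | r0 > 1))
        stop("ranks must be scaled to [0, 1]")
    v <- ifelse(r < r0, (r0 - r) / r0, (r0 - r) / (1 - r0))
    v[r == r0] <- 0
    cornerHi <- r == 0 & r0 == 0
    cornerLo <- r == 1 & r0 == 1
    if (any(cornerHi | cornerLo)) {
        warning("background rank at 0 or 1: value set by continuity")
        v[cornerHi] <- 1
        v[cornerLo] <- -1
    }
    new("CellIdentityProfile", features = names(sampleRanks),
        values = unname(v), reference = reference)
}

#' Plate-normalised drug treatment profile
#'
#' Contrasts a drug-treated group with the vehicle control group on the
#' same plate. The `fold` method computes the scaled fold of treated vs
#' control means filtered by an equal-variance Student t-test at `alpha`;
#' the `zscore` method computes the plate-control-referenced standardised
#' difference
#' \deqn{Z = (\bar t - \bar c) / (s_c \sqrt{1/n_t + 1/n_c})}
#' retained when `|Z| > zThreshold`. Both statistics are invariant to the
#' shared per-plate gains the generator plants, which is what "normalising
#' to the plate control" buys. Genes whose control SD is zero cannot be
#' standardised and are dropped with a warning under `zscore`.
#'
#' @param se expression SummarizedExperiment with `group` and `plate`
#'   metadata.
#' @param drugGroup treated group label.
#' @param controlGroup vehicle group label (default "vehicle").
#' @param plate restrict to this plate id (default: the treated samples'
#'   plate).
#' @param method `"fold"` or `"zscore"`.
#' @param alpha t-filter level for the fold method (default 0.05).
#' @param zThreshold |Z| retention threshold for the zscore method
#'   (default 3).
#' @return a \linkS4class{DrugProfile}
#' @export
treatmentProfile <- function(se, drugGroup, controlGroup = "vehicle",
                             plate = NULL, method = c("zscore", "fold"),
                             alpha = 0.05, zThreshold = 3) {
    method <- match.arg(method)
    grp <- .sampleGroups(se)
    cd <- SummarizedExperiment::colData(se)
    plateCol <- if ("plate" %in% colnames(cd))
        as.character(cd$plate) else rep("", length(grp))
    if (is.null(plate)) {
        plate <- unique(plateCol[grp == drugGroup])
        if (length(plate) != 1L)
            stop("treated samples span ", length(plate),
                 " plates; specify one")
    }
    onPlate <- plateCol == plate
    if (!any(grp == drugGroup & onPlate))
        stop("drug group '", drugGroup, "' absent from plate '", plate, "'")
    if (!any(grp == controlGroup & onPlate))
        stop("control group '", controlGroup, "' absent from plate '",
             plate, "'")
    m <- .assayMatrix(se)
    x <- m[, grp == controlGroup & onPlate, drop = FALSE]
    y <- m[, grp == drugGroup & onPlate, drop = FALSE]
    if (ncol(x) < 2 || ncol(y) < 2)
        stop("at least 2 samples per group are required")
    if (method == "fold") {
        tt <- .rowTTest(x, y)
        ok <- tt$meanX > 0 & tt$meanY > 0
        if (any(!ok))
            warning(sum(!ok), " gene(s) dropped: non-positive group mean")
        f <- (tt$meanY - tt$meanX) / (tt$meanY + tt$meanX)
        keep <- ok & tt$p < alpha
        new("DrugProfile", genes = rownames(m)[keep],
            values = unname(f[keep]), stats = unname(tt$p[keep]),
            statKind = "p", drug = drugGroup, plate = plate,
            method = "fold")
    } else {
        mc <- rowMeans(x); mt <- rowMeans(y)
        sdc <- sqrt(rowSums((x - mc)^2) / (ncol(x) - 1L))
        z <- (mt - mc) / (sdc * sqrt(1 / ncol(y) + 1 / ncol(x)))
        degenerate <- sdc == 0
        if (any(degenerate)) {
            warning(sum(degenerate),
                    " gene(s) dropped: zero control variance")
            z[degenerate] <- NA_real_
        }
        keep <- !is.na(z) & abs(z) > zThreshold
        new("DrugProfile", genes = rownames(m)[keep],
            values = unname(z[keep]), stats = unname(abs(z[keep])),
            statKind = "absZ", drug = drugGroup, plate = plate,
            method = "zscore")
    }
}
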