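#' @import methods
#' @importFrom stats pt qnorm sd rnorm phyper p.adjust hclust as.dist
#'   cor setNames lm.fit model.matrix
#' @importFrom utils read.delim write.table combn head
NULL

.capZ <- 8.2

#' Planted ground truth for synthetic studies
#'
#' Records which genes carry the planted disease signature and which drugs
#' were generated as reversers, so downstream recovery can be scored against
#' a known answer.
#'
#' @slot geneIds character, the full gene universe.
#' @slot upGenes character, genes planted as upregulated in disease.
#' @slot downGenes character, genes planted as downregulated in disease.
#' @slot reverserDrugs named numeric, reversal fraction (0-1) per reverser
#'   drug; empty until drug plates are generated.
#' @slot effectSize numeric, planted shift in units of the noise SD.
#' @slot seed integer seed the generator was called with.
#' @export
setClass("PlantedTruth", representation(
    geneIds = "character",
    upGenes = "character",
    downGenes = "character",
    reverserDrugs = "numeric",
    effectSize = "numeric",
    seed = "integer"
))

setValidity("PlantedTruth", function(object) {
    msg <- character()
    if (length(intersect(object@upGenes, object@downGenes)) > 0L)
        msg <- c(msg, "up and down signature gene sets must be disjoint")
    if (!all(c(object@upGenes, object@downGenes) %in% object@geneIds))
        msg <- c(msg, "signature genes must belong to the gene universe")
    rf <- object@reverserDrugs
    if (length(rf) && (any(rf < 0) || any(rf > 1)))
        msg <- c(msg, "reversal fractions must lie in [0, 1]")
    if (length(rf) && is.null(names(rf)))
        msg <- c(msg, "reverserDrugs must be named by drug")
    if (length(msg)) msg else TRUE
})

#' Continuous disease/drug signature
#'
#' Per-gene signed change retained by the profile's significance filters.
#' `kind` distinguishes bounded scaled folds (in [-1, 1]) from regression
#' Z scores.
#'
#' @slot genes character, retained gene ids (unique).
#' @slot values numeric, signed change per gene (scaled fold or Z).
#' @slot pValues numeric, significance of each change.
#' @slot kind `"fold"` or `"Z"`.
#' @slot source free-text label of the originating study/contrast.
#' @export
setClass("SignatureProfile", representation(
    genes = "character",
    values = "numeric",
    pValues = "numeric",
    kind = "character",
    source = "character"
))

setValidity("SignatureProfile", function(object) {
    msg <- character()
    n <- length(object@genes)
    if (length(object@values) != n || length(object@pValues) != n)
        msg <- c(msg, "genes, values and pValues must have equal length")
    if (anyDuplicated(object@genes))
        msg <- c(msg, "gene ids must be unique")
    if (!(length(object@kind) == 1L && object@kind %in% c("fold", "Z")))
        msg <- c(msg, "kind must be 'fold' or 'Z'")
    if (identical(object@kind, "fold") && n > 0L &&
        any(abs(object@values) > 1 + 1e-12))
        msg <- c(msg, "scaled folds must lie in [-1, 1]")
    if (n > 0L && (any(object@pValues < 0) || any(object@pValues > 1)))
        msg <- c(msg, "p-values must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Categorical (consensus) signature
#'
#' Per-gene regulation sense with the net regulation fraction across the
#' contributing profiles; the query form used for connectivity scoring.
#'
#' @slot genes character, retained gene ids.
#' @slot senses integer, +1 (up) or -1 (down) per gene.
#' @slot fractions numeric, net regulation fraction in [-1, 1].
#' @slot support integer, number of contributing profiles per gene.
#' @slot nProfiles integer, number of profiles the signature was built from.
#' @export
setClass("CategoricalSignature", representation(
    genes = "character",
    senses = "integer",
    fractions = "numeric",
    support = "integer",
    nProfiles = "integer"
))

setValidity("CategoricalSignature", function(object) {
    msg <- character()
    n <- length(object@genes)
    if (length(object@senses) != n || length(object@fractions) != n ||
        length(object@support) != n)
        msg <- c(msg, "per-gene slots must have equal length")
    if (anyDuplicated(object@genes))
        msg <- c(msg, "gene ids must be unique")
    if (n > 0L && !all(object@senses %in% c(-1L, 1L)))
        msg <- c(msg, "senses must be +1 or -1")
    if (n > 0L && any(abs(object@fractions) > 1 + 1e-12))
        msg <- c(msg, "fractions must lie in [-1, 1]")
    if (n > 0L && any(object@support > object@nProfiles))
        msg <- c(msg, "support cannot exceed the number of input profiles")
    if (length(msg)) msg else TRUE
})

#' CMAP-style rank profile
#'
#' Per-feature value in [-1, 1] obtained by linearly mapping expression-change
#' ranks; +1 is the most upregulated feature, -1 the most downregulated.
#'
#' @slot features character feature (probe/gene) ids.
#' @slot values numeric in [-1, 1].
#' @slot pValues numeric; empty before replicate aggregation, one-sample
#'   t p-values afterwards.
#' @slot drug drug/perturbagen label.
#' @slot replicates integer, replicates aggregated into this profile.
#' @slot cellContext cell-context label (e.g. cell line).
#' @export
setClass("RankProfile", representation(
    features = "character",
    values = "numeric",
    pValues = "numeric",
    drug = "character",
    replicates = "integer",
    cellContext = "character"
))

setValidity("RankProfile", function(object) {
    msg <- character()
    n <- length(object@features)
    if (length(object@values) != n)
        msg <- c(msg, "features and values must have equal length")
    if (!(length(object@pValues) %in% c(0L, n)))
        msg <- c(msg, "pValues must be empty or one per feature")
    if (anyDuplicated(object@features))
        msg <- c(msg, "feature ids must be unique")
    if (n > 0L && any(abs(object@values) > 1 + 1e-12))
        msg <- c(msg, "rank values must lie in [-1, 1]")
    if (length(msg)) msg else TRUE
})

#' Cell-identity relative-rank profile
#'
#' Per-feature relative rank of a sample set against a background rank
#' reference; positive where the sample expresses the feature higher than
#' the background.
#'
#' @slot features character feature ids.
#' @slot values numeric in [-1, 1].
#' @slot reference label of the background rank source.
#' @export
setClass("CellIdentityProfile", representation(
    features = "character",
    values = "numeric",
    reference = "character"
))

setValidity("CellIdentityProfile", function(object) {
    msg <- character()
    if (length(object@values) != length(object@features))
        msg <- c(msg, "features and values must have equal length")
    if (length(object@values) && any(abs(object@values) > 1 + 1e-12))
        msg <- c(msg, "relative ranks must lie in [-1, 1]")
    if (length(msg)) msg else TRUE
})

#' Filtered drug treatment profile
#'
#' Gene-level signed changes for one drug treatment, retained by the declared
#' filter (t-test p below alpha for the fold method, |Z| above threshold for
#' the zscore method).
#'
#' @slot genes character gene ids.
#' @slot values numeric signed change (scaled fold or Z).
#' @slot stats numeric per-gene filter statistic (p-value or |Z|).
#' @slot statKind `"p"` or `"absZ"`.
#' @slot drug drug label.
#' @slot plate plate id the profile was derived from ("" if not applicable).
#' @slot method `"fold"`, `"zscore"` or `"rank"`.
#' @export
setClass("DrugProfile", representation(
    genes = "character",
    values = "numeric",
    stats = "numeric",
    statKind = "character",
    drug = "character",
    plate = "character",
    method = "character"
))

setValidity("DrugProfile", function(object) {
    msg <- character()
    n <- length(object@genes)
    if (length(object@values) != n || length(object@stats) != n)
        msg <- c(msg, "genes, values and stats must have equal length")
    if (anyDuplicated(object@genes))
        msg <- c(msg, "gene ids must be unique")
    if (!(object@statKind %in% c("p", "absZ")))
        msg <- c(msg, "statKind must be 'p' or 'absZ'")
    if (!(object@method %in% c("fold", "zscore", "rank")))
        msg <- c(msg, "method must be 'fold', 'zscore' or 'rank'")
    if (length(msg)) msg else TRUE
})

#' Result of one query x profile connectivity comparison
#'
#' @slot counts named integer: nUU, nDD, nUD, nDU sense-agreement counts.
#' @slot score concordance score in [-1, 1]; NA when overlap is empty.
#' @slot enrichmentP Poisson-binomial tail probability of a sense agreement
#'   (or disagreement, for negative scores) at least as extreme.
#' @slot direction `"concordant"` or `"discordant"` — which excess the
#'   enrichment probability refers to.
#' @slot overlap integer, genes compared.
#' @slot defined logical; FALSE when the gene overlap is empty.
#' @export
setClass("ConnectivityResult", representation(
    counts = "integer",
    score = "numeric",
    enrichmentP = "numeric",
    direction = "character",
    overlap = "integer",
    defined = "logical"
))

setValidity("ConnectivityResult", function(object) {
    msg <- character()
    if (length(object@counts) != 4L ||
        !identical(names(object@counts), c("nUU", "nDD", "nUD", "nDU")))
        msg <- c(msg, "counts must be named nUU, nDD, nUD, nDU")
    if (any(object@counts < 0L))
        msg <- c(msg, "counts must be non-negative")
    if (object@defined) {
        if (is.na(object@score) || abs(object@score) > 1 + 1e-12)
            msg <- c(msg, "score must lie in [-1, 1]")
        if (is.na(object@enrichmentP) || object@enrichmentP <= 0 ||
            object@enrichmentP > 1)
            msg <- c(msg, "enrichment probability must lie in (0, 1]")
    }
    if (length(msg)) msg else TRUE
})

#' Rank-enrichment result (KS running sum with Monte-Carlo null)
#'
#' @slot D maximal positive deviation of the cumulative hit curve from the
#'   zero-enrichment diagonal, in [0, 1].
#' @slot pMC Monte-Carlo probability (add-one estimator, never zero).
#' @slot nPermutations integer, permutations used.
#' @slot seed integer seed of the permutation stream.
#' @export
setClass("EnrichmentResult", representation(
    D = "numeric",
    pMC = "numeric",
    nPermutations = "integer",
    seed = "integer"
))

setValidity("EnrichmentResult", function(object) {
    msg <- character()
    if (object@D < -1e-12 || object@D > 1 + 1e-12)
        msg <- c(msg, "D must lie in [0, 1]")
    if (object@pMC < 1 / (object@nPermutations + 1) - 1e-12)
        msg <- c(msg, "pMC cannot fall below 1/(n_permutations + 1)")
    if (length(msg)) msg else TRUE
})

#' Sum-sense consensus over a set of drug profiles
#'
#' @slot genes character, selected genes.
#' @slot ratios numeric, mean sense over profiles in [-1, 1].
#' @slot senseMatrix integer matrix (selected genes x profiles) of senses,
#'   0 where a gene is absent from a profile.
#' @export
setClass("SenseConsensus", representation(
    genes = "character",
    ratios = "numeric",
    senseMatrix = "matrix"
))

setValidity("SenseConsensus", function(object) {
    msg <- character()
    n <- length(object@genes)
    if (length(object@ratios) != n || nrow(object@senseMatrix) != n)
        msg <- c(msg, "genes, ratios and senseMatrix rows must agree")
    if (n > 0L && any(abs(object@ratios) > 1 + 1e-12))
        msg <- c(msg, "ratios must lie in [-1, 1]")
    if (length(msg)) msg else TRUE
})

#' UPGMA dendrogram
#'
#' Ultrametric average-linkage tree; heights are node heights (half the
#' average inter-cluster distance at each merge) and are non-decreasing.
#'
#' @slot merge integer matrix in \code{\link[stats]{hclust}} encoding.
#' @slot heights numeric node heights, one per merge.
#' @slot labels character leaf labels.
#' @slot order integer leaf order for plotting.
#' @export
setClass("Dendrogram", representation(
    merge = "matrix",
    heights = "numeric",
    labels = "character",
    order = "integer"
))

setValidity("Dendrogram", function(object) {
    msg <- character()
    n <- length(object@labels)
    if (nrow(object@merge) != n - 1L || length(object@heights) != n - 1L)
        msg <- c(msg, "a tree on N leaves must have N-1 merges")
    if (is.unsorted(object@heights + 1e-9))
        msg <- c(msg, "UPGMA heights must be non-decreasing (ultrametric)")
    if (length(msg)) msg else TRUE
})

#' Gene-set collection (GMT)
#'
#' @slot sets named list of character vectors (member gene ids).
#' @slot descriptions character, one per set.
#' @export
setClass("GeneSetCollection", representation(
    sets = "list",
    descriptions = "character"
))

setValidity("GeneSetCollection", function(object) {
    msg <- character()
    if (length(object@sets) != length(object@descriptions))
        msg <- c(msg, "each set needs a description")
    if (length(object@sets)) {
        if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
            msg <- c(msg, "set names must be present and unique")
        if (any(vapply(object@sets, length, 1L) == 0L))
            msg <- c(msg, "sets must be non-empty")
        if (any(vapply(object@sets, anyDuplicated, 1L) > 0L))
            msg <- c(msg, "member ids must be unique within a set")
    }
    if (length(msg)) msg else TRUE
})

#' Probe-to-gene map
#'
#' Every probe maps to exactly one gene; genes may carry several probes.
#'
#' @slot probes character probe ids (unique).
#' @slot genes character gene id per probe.
#' @export
setClass("ProbeGeneMap", representation(
    probes = "character",
    genes = "character"
))

setValidity("ProbeGeneMap", function(object) {
    msg <- character()
    if (length(object@probes) != length(object@genes))
        msg <- c(msg, "probes and genes must have equal length")
    if (anyDuplicated(object@probes))
        msg <- c(msg, "every probe must map to exactly one gene")
    if (length(msg)) msg else TRUE
})
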