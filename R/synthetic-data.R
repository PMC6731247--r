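#' Build an ExpressionMatrix-style SummarizedExperiment
#'
#' The package's universal expression container is a
#' \link[SummarizedExperiment]{SummarizedExperiment} with a single assay
#' `exprs` (positive, intensity-like expression values) and per-sample
#' metadata in `colData` (at minimum a `group` column; optionally `plate`,
#' `stage` and arbitrary categorical covariate columns).
#'
#' @param values numeric matrix, features x samples.
#' @param metadata data.frame with one row per sample; must contain `group`.
#' @return a `SummarizedExperiment`
#' @export
ExpressionMatrix <- function(values, metadata) {
    if (is.null(rownames(values)) || is.null(colnames(values)))
        stop("expression values need feature and sample ids as dimnames")
    if (anyDuplicated(rownames(values)))
        stop("duplicate feature ids in expression matrix")
    if (anyDuplicated(colnames(values)))
        stop("duplicate sample ids in expression matrix")
    if (nrow(metadata) != ncol(values))
        stop("metadata must describe exactly the matrix samples")
    if (!"group" %in% colnames(metadata))
        stop("sample metadata must contain a 'group' column")
    rownames(metadata) <- colnames(values)
    SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = values),
        colData = S4Vectors::DataFrame(metadata, check.names = FALSE))
}

#' Simulate a control/disease expression study with a planted signature
#'
#' Generates a positive intensity-like expression matrix (additive Gaussian
#' noise of SD `noiseSd` around `baseline`) in which `nUp` genes are shifted
#' up and `nDown` genes down by `effect * noiseSd` in the disease group. The
#' planted genes are the ground truth against which downstream signature
#' recovery is scored.
#'
#' The default baseline of 4 units puts a 3-SD shift well past the 20%
#' scaled-fold filter (f = 3/11 for up, -3/5 for down genes), i.e. planted
#' genes represent strongly regulated transcripts.
#'
#' @param nGenes gene universe size.
#' @param nUp,nDown planted up-/down-regulated gene counts.
#' @param effect shift in units of the noise SD.
#' @param nControl,nDisease samples per group (>= 2 each).
#' @param baseline mean expression of unperturbed genes.
#' @param noiseSd Gaussian noise SD.
#' @param truth optional existing \linkS4class{PlantedTruth} whose planted
#'   genes are reused (an independent replicate study of the same disease).
#' @param seed integer seed; generation is fully reproducible from it.
#' @return list with elements `matrix` (SummarizedExperiment) and `truth`
#'   (\linkS4class{PlantedTruth}).
#' @export
generateDiseaseStudy <- function(nGenes = 1000, nUp = 50, nDown = 50,
                                 effect = 3, nControl = 5, nDisease = 5,
                                 baseline = 4, noiseSd = 1, truth = NULL,
                                 seed) {
    if (missing(seed)) stop("a seed is required")
    if (nUp + nDown > nGenes)
        stop("planted signature larger than the gene universe")
    if (nControl < 2 || nDisease < 2)
        stop("at least 2 samples per group are required")
    set.seed(seed)
    if (is.null(truth)) {
        genes <- sprintf("g%05d", seq_len(nGenes))
        up <- sample(genes, nUp)
        down <- sample(setdiff(genes, up), nDown)
        truth <- new("PlantedTruth", geneIds = genes, upGenes = up,
                     downGenes = down, reverserDrugs = numeric(0),
                     effectSize = as.numeric(effect), seed = as.integer(seed))
    } else {
        genes <- truth@geneIds
        up <- truth@upGenes
        down <- truth@downGenes
    }
    n <- nControl + nDisease
    m <- matrix(rnorm(length(genes) * n, mean = baseline, sd = noiseSd),
                nrow = length(genes),
                dimnames = list(genes,
                    c(sprintf("ctrl%02d", seq_len(nControl)),
                      sprintf("dis%02d", seq_len(nDisease)))))
    disCols <- nControl + seq_len(nDisease)
    m[up, disCols] <- m[up, disCols] + effect * noiseSd
    m[down, disCols] <- m[down, disCols] - effect * noiseSd
    md <- data.frame(
        group = rep(c("control", "disease"), c(nControl, nDisease)),
        stringsAsFactors = FALSE)
    list(matrix = ExpressionMatrix(m, md), truth = truth)
}

#' Simulate a disease-stage series with stage-linked genes
#'
#' Samples carry an ordinal stage (0..`stageRange`, balanced assignment) and
#' categorical covariates. `nLinked` genes depend linearly on stage (slope
#' sign random, recorded in the truth), `nCovariateOnly` genes are offset by
#' the first covariate but carry no stage slope (they must not be recovered
#' by a covariate-adjusted stage regression), and the remainder are pure
#' noise.
#'
#' @param nGenes gene universe size.
#' @param nSamples number of samples (>= stageRange + 2).
#' @param stageRange stages run 0..stageRange.
#' @param nLinked stage-linked gene count.
#' @param slope expression units per stage for linked genes.
#' @param nCovariateOnly genes offset by the first covariate only.
#' @param covariates named list of level vectors, e.g.
#'   `list(sex = c("F", "M"))`.
#' @param covariateEffect offset (expression units) of non-reference
#'   covariate levels for covariate-only genes.
#' @param baseline,noiseSd noise model as in [generateDiseaseStudy()].
#' @param seed integer seed.
#' @return list with `matrix`, `truth` (up/down = positive-/negative-slope
#'   linked genes) and `covariateOnlyGenes`.
#' @export
generateStageSeries <- function(nGenes = 2000, nSamples = 40, stageRange = 3,
                                nLinked = 100, slope = 2, nCovariateOnly = 0,
                                covariates = list(sex = c("F", "M")),
                                covariateEffect = 2, baseline = 4,
                                noiseSd = 1, seed) {
    if (missing(seed)) stop("a seed is required")
    if (nSamples < stageRange + 2)
        stop("need at least stageRange + 2 samples to fit the stage model")
    if (nLinked + nCovariateOnly > nGenes)
        stop("planted genes exceed the gene universe")
    set.seed(seed)
    genes <- sprintf("g%05d", seq_len(nGenes))
    stage <- sample(rep(seq(0L, stageRange), length.out = nSamples))
    md <- data.frame(group = "series", stage = stage,
                     stringsAsFactors = FALSE)
    for (cv in names(covariates))
        md[[cv]] <- sample(covariates[[cv]], nSamples, replace = TRUE)
    linked <- sample(genes, nLinked)
    covOnly <- if (nCovariateOnly > 0)
        sample(setdiff(genes, linked), nCovariateOnly) else character(0)
    slopeSign <- sample(c(-1, 1), nLinked, replace = TRUE)
    m <- matrix(rnorm(nGenes * nSamples, baseline, noiseSd), nrow = nGenes,
                dimnames = list(genes, sprintf("s%03d", seq_len(nSamples))))
    m[linked, ] <- m[linked, ] +
        outer(slopeSign * slope, stage)
    if (length(covOnly)) {
        firstCov <- md[[names(covariates)[1]]]
        offset <- as.numeric(firstCov != covariates[[1]][1]) * covariateEffect
        m[covOnly, ] <- m[covOnly, ] + rep(offset, each = length(covOnly))
    }
    truth <- new("PlantedTruth", geneIds = genes,
                 upGenes = linked[slopeSign > 0],
                 downGenes = linked[slopeSign < 0],
                 reverserDrugs = numeric(0),
                 effectSize = as.numeric(slope), seed = as.integer(seed))
    list(matrix = ExpressionMatrix(m, md), truth = truth,
         covariateOnlyGenes = covOnly)
}

#' Simulate plate-structured drug treatment experiments
#'
#' Each plate carries a vehicle control group plus a number of drugs, every
#' group in `replicates` cultures. Reverser drugs shift a fraction
#' `reversalFraction` of the planted disease signature in the opposite
#' sense; the remaining drugs perturb random gene sets of the same size (so
#' the specificity, not just the sensitivity, of downstream queries is
#' testable). Plate effects are per-gene multiplicative gains (additive on
#' the log scale), identical for all samples on a plate — exactly the
#' structure that plate-control normalisation removes.
#'
#' @param truth \linkS4class{PlantedTruth} defining universe and signature.
#' @param nDrugs,nReversers drug counts (`nReversers <= nDrugs`).
#' @param reversalFraction fraction of the planted signature a reverser
#'   flips.
#' @param effect perturbation size in noise-SD units.
#' @param replicates cultures per group (>= 2).
#' @param plates number of plates the drugs are spread over.
#' @param plateSd SD of the per-gene log2 plate gains.
#' @param baseline,noiseSd noise model as in [generateDiseaseStudy()].
#' @param seed integer seed.
#' @return list with `plates` (list of SummarizedExperiment, one per plate)
#'   and `truth` (reverser drugs recorded).
#' @export
generateDrugPlates <- function(truth, nDrugs = 50, nReversers = 5,
                               reversalFraction = 0.8, effect = 3,
                               replicates = 3, plates = 10, plateSd = 0.25,
                               baseline = 4, noiseSd = 1, seed) {
    if (missing(seed)) stop("a seed is required")
    if (nReversers > nDrugs)
        stop("cannot plant more reversers than drugs")
    if (replicates < 2)
        stop("at least 2 replicates per group are required")
    set.seed(seed)
    genes <- truth@geneIds
    sig <- c(truth@upGenes, truth@downGenes)
    k <- round(reversalFraction * length(sig))
    drugs <- sprintf("drug%02d", seq_len(nDrugs))
    reversers <- sample(drugs, nReversers)
    plateOf <- rep(seq_len(plates), length.out = nDrugs)

    perturbation <- lapply(drugs, function(d) {
        delta <- setNames(numeric(length(genes)), genes)
        if (k == 0L) return(delta)
        if (d %in% reversers) {
            rev <- sample(sig, k)
            delta[intersect(rev, truth@upGenes)] <- -effect * noiseSd
            delta[intersect(rev, truth@downGenes)] <- effect * noiseSd
        } else {
            hit <- sample(genes, k)
            delta[hit] <- sample(c(-1, 1), k, replace = TRUE) *
                effect * noiseSd
        }
        delta
    })
    names(perturbation) <- drugs

    plateList <- lapply(seq_len(plates), function(p) {
        onPlate <- drugs[plateOf == p]
        groups <- c("vehicle", onPlate)
        nCol <- length(groups) * replicates
        groupCol <- rep(groups, each = replicates)
        ids <- paste0("p", p, "_", groupCol, "_r",
                      rep(seq_len(replicates), times = length(groups)))
        m <- matrix(rnorm(length(genes) * nCol, baseline, noiseSd),
                    nrow = length(genes), dimnames = list(genes, ids))
        for (d in onPlate)
            m[, groupCol == d] <- m[, groupCol == d] + perturbation[[d]]
        gain <- 2^rnorm(length(genes), 0, plateSd)
        m <- m * gain
        md <- data.frame(group = groupCol, plate = paste0("plate", p),
                         stringsAsFactors = FALSE)
        ExpressionMatrix(m, md)
    })
    truth@reverserDrugs <- setNames(rep(reversalFraction, nReversers),
                                    sort(reversers))
    validObject(truth)
    list(plates = plateList, truth = truth)
}

#' Simulate a degenerate probe-to-gene map
#'
#' Each gene receives between 1 and `maxDegeneracy` probes (uniformly); when
#' `maxDegeneracy >= 2` at least one gene is guaranteed to carry multiple
#' probes.
#'
#' @param geneIds character vector of gene ids, or a single count.
#' @param maxDegeneracy maximum probes per gene (>= 1).
#' @param seed integer seed.
#' @return a \linkS4class{ProbeGeneMap}
#' @export
generateProbeMap <- function(geneIds, maxDegeneracy = 3, seed) {
    if (missing(seed)) stop("a seed is required")
    if (maxDegeneracy < 1) stop("maxDegeneracy must be >= 1")
    if (is.numeric(geneIds) && length(geneIds) == 1L)
        geneIds <- sprintf("g%05d", seq_len(geneIds))
    set.seed(seed)
    deg <- sample.int(maxDegeneracy, length(geneIds), replace = TRUE)
    if (maxDegeneracy >= 2 && all(deg == 1L)) deg[1L] <- 2L
    gene <- rep(geneIds, deg)
    probe <- paste0(gene, "_p",
                    unlist(lapply(deg, seq_len), use.names = FALSE))
    new("ProbeGeneMap", probes = probe, genes = gene)
}
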