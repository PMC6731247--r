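# Accessor generics shared by the profile classes.

#' Gene or feature ids of a profile-like object
#' @param x a profile, signature, consensus or truth object
#' @return character vector of ids
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' Per-gene values of a profile, named by gene/feature id
#' @param x a profile or signature object
#' @return named numeric vector
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

#' Per-gene regulation senses (+1/-1; 0 only for unretained entries)
#' @param x a profile or signature object
#' @return named integer vector
#' @export
setGeneric("senses", function(x) standardGeneric("senses"))

#' Per-gene p-values of a profile
#' @param x a profile object carrying significance values
#' @return named numeric vector
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))

#' @describeIn geneIds retained genes of a continuous signature
#' @export
setMethod("geneIds", "SignatureProfile", function(x) x@genes)
#' @describeIn geneIds retained genes of a categorical signature
#' @export
setMethod("geneIds", "CategoricalSignature", function(x) x@genes)
#' @describeIn geneIds retained genes of a drug profile
#' @export
setMethod("geneIds", "DrugProfile", function(x) x@genes)
#' @describeIn geneIds features of a rank profile
#' @export
setMethod("geneIds", "RankProfile", function(x) x@features)
#' @describeIn geneIds features of a cell-identity profile
#' @export
setMethod("geneIds", "CellIdentityProfile", function(x) x@features)
#' @describeIn geneIds selected genes of a sum-sense consensus
#' @export
setMethod("geneIds", "SenseConsensus", function(x) x@genes)
#' @describeIn geneIds planted signature genes (up then down)
#' @export
setMethod("geneIds", "PlantedTruth",
    function(x) c(x@upGenes, x@downGenes))

#' @describeIn profileValues signed changes of a continuous signature
#' @export
setMethod("profileValues", "SignatureProfile",
    function(x) setNames(x@values, x@genes))
#' @describeIn profileValues signed changes of a drug profile
#' @export
setMethod("profileValues", "DrugProfile",
    function(x) setNames(x@values, x@genes))
#' @describeIn profileValues scaled rank values
#' @export
setMethod("profileValues", "RankProfile",
    function(x) setNames(x@values, x@features))
#' @describeIn profileValues relative rank values
#' @export
setMethod("profileValues", "CellIdentityProfile",
    function(x) setNames(x@values, x@features))
#' @describeIn profileValues sum-sense ratios
#' @export
setMethod("profileValues", "SenseConsensus",
    function(x) setNames(x@ratios, x@genes))

#' @describeIn senses sign of the retained change
#' @export
setMethod("senses", "SignatureProfile",
    function(x) setNames(as.integer(sign(x@values)), x@genes))
#' @describeIn senses stored categorical senses
#' @export
setMethod("senses", "CategoricalSignature",
    function(x) setNames(x@senses, x@genes))
#' @describeIn senses sign of the retained change
#' @export
setMethod("senses", "DrugProfile",
    function(x) setNames(as.integer(sign(x@values)), x@genes))
#' @describeIn senses sign of the rank value
#' @export
setMethod("senses", "RankProfile",
    function(x) setNames(as.integer(sign(x@values)), x@features))

#' @describeIn pValues significance of each retained change
#' @export
setMethod("pValues", "SignatureProfile",
    function(x) setNames(x@pValues, x@genes))
#' @describeIn pValues one-sample t p-values (empty before aggregation)
#' @export
setMethod("pValues", "RankProfile", function(x) {
    if (length(x@pValues)) setNames(x@pValues, x@features) else x@pValues
})

setMethod("show", "SignatureProfile", function(object) {
    cat(sprintf("SignatureProfile (%s) '%s': %d retained genes\n",
        object@kind, object@source, length(object@genes)))
    if (length(object@genes)) {
        s <- senses(object)
        cat(sprintf("  %d up, %d down; |value| range %.3g..%.3g\n",
            sum(s > 0), sum(s < 0),
            min(abs(object@values)), max(abs(object@values))))
    }
    invisible(NULL)
})

setMethod("show", "CategoricalSignature", function(object) {
    cat(sprintf(
        "CategoricalSignature: %d genes (%d up, %d down) from %d profiles\n",
        length(object@genes), sum(object@senses > 0L),
        sum(object@senses < 0L), object@nProfiles))
    invisible(NULL)
})

setMethod("show", "DrugProfile", function(object) {
    cat(sprintf("DrugProfile '%s' (plate %s, method %s): %d genes\n",
        object@drug, ifelse(nzchar(object@plate), object@plate, "-"),
        object@method, length(object@genes)))
    invisible(NULL)
})

setMethod("show", "RankProfile", function(object) {
    cat(sprintf("RankProfile '%s' (%d replicate%s): %d features\n",
        object@drug, object@replicates,
        ifelse(object@replicates == 1L, "", "s"), length(object@features)))
    invisible(NULL)
})

setMethod("show", "ConnectivityResult", function(object) {
    if (!object@defined) {
        cat("ConnectivityResult: undefined (no gene overlap)\n")
    } else {
        cat(sprintf(
            "ConnectivityResult: score %.3f over %d genes (%s p = %.3g)\n",
            object@score, object@overlap, object@direction,
            object@enrichmentP))
        cat(sprintf("  counts: nUU=%d nDD=%d nUD=%d nDU=%d\n",
            object@counts["nUU"], object@counts["nDD"],
            object@counts["nUD"], object@counts["nDU"]))
    }
    invisible(NULL)
})

setMethod("show", "EnrichmentResult", function(object) {
    cat(sprintf("EnrichmentResult: D = %.4f, p_mc = %.4g (%d permutations)\n",
        object@D, object@pMC, object@nPermutations))
    invisible(NULL)
})

setMethod("show", "PlantedTruth", function(object) {
    cat(sprintf(
        "PlantedTruth: %d genes (%d up, %d down planted), %d reversers\n",
        length(object@geneIds), length(object@upGenes),
        length(object@downGenes), length(object@reverserDrugs)))
    invisible(NULL)
})

setMethod("show", "Dendrogram", function(object) {
    cat(sprintf("Dendrogram (UPGMA): %d leaves, height range %.3g..%.3g\n",
        length(object@labels),
        min(object@heights), max(object@heights)))
    invisible(NULL)
})

setMethod("show", "GeneSetCollection", function(object) {
    cat(sprintf("GeneSetCollection: %d sets, sizes %s\n",
        length(object@sets),
        if (length(object@sets))
            paste(range(vapply(object@sets, length, 1L)), collapse = "..")
        else "-"))
    invisible(NULL)
})

setMethod("show", "ProbeGeneMap", function(object) {
    cat(sprintf("ProbeGeneMap: %d probes -> %d genes\n",
        length(object@probes), length(unique(object@genes))))
    invisible(NULL)
})

setMethod("show", "SenseConsensus", function(object) {
    cat(sprintf(
        "SenseConsensus: %d genes over %d profiles (%d up, %d down)\n",
        length(object@genes), ncol(object@senseMatrix),
        sum(object@ratios > 0), sum(object@ratios < 0)))
    invisible(NULL)
})
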