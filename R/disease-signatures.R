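# Disease signature construction: scaled-fold case/control contrasts,
# covariate-adjusted stage regressions, sign reversal for inverted scales,
# and categorical consensus across studies.

#' Scaled-fold disease signature from a case/control contrast
#'
#' For each gene the bounded scaled fold
#' \deqn{f = (\langle d\rangle - \langle c\rangle) /
#'           (\langle d\rangle + \langle c\rangle)}
#' is computed from the control and disease group means on the positive
#' intensity scale, together with an equal-variance two-sample Student
#' t-test. Genes are retained when the t-test p-value is below `alpha` and
#' `|f| >= minFold`. Genes whose group means are not both positive cannot
#' carry a bounded fold and are dropped with a warning.
#'
#' @param se expression SummarizedExperiment (see [ExpressionMatrix()]).
#' @param controlGroup,diseaseGroup group labels in the sample metadata.
#' @param alpha significance level of the t filter (default 0.05).
#' @param minFold minimum absolute scaled fold (default 0.20).
#' @param source label stored on the profile.
#' @return a \linkS4class{SignatureProfile} of kind `"fold"`.
#' @export
scaledFoldProfile <- function(se, controlGroup = "control",
                              diseaseGroup = "disease", alpha = 0.05,
                              minFold = 0.20, source = "") {
    grp <- .sampleGroups(se)
    if (!controlGroup %in% grp)
        stop("group label absent from metadata: ", controlGroup)
    if (!diseaseGroup %in% grp)
        stop("group label absent from metadata: ", diseaseGroup)
    m <- .assayMatrix(se)
    x <- m[, grp == controlGroup, drop = FALSE]
    y <- m[, grp == diseaseGroup, drop = FALSE]
    if (ncol(x) < 2 || ncol(y) < 2)
        stop("at least 2 samples per group are required")
    tt <- .rowTTest(x, y)
    ok <- tt$meanX > 0 & tt$meanY > 0
    if (any(!ok))
        warning(sum(!ok), " gene(s) dropped: non-positive group mean")
    f <- (tt$meanY - tt$meanX) / (tt$meanY + tt$meanX)
    keep <- ok & tt$p < alpha & abs(f) >= minFold
    new("SignatureProfile", genes = rownames(m)[keep],
        values = unname(f[keep]), pValues = unname(tt$p[keep]),
        kind = "fold", source = source)
}

#' Stage-regression disease signature
#'
#' Fits, gene by gene, `expression ~ stage + covariates` by ordinary least
#' squares (categorical covariates enter as indicator columns), takes the
#' two-sided t p-value of the stage coefficient and converts it to a signed
#' Z via the standard-normal quantile (sign of the coefficient, capped at
#' +/- `zCap` to guard against p-value underflow for near-perfect fits).
#' Genes with `|Z|` significant at `alpha` are retained.
#'
#' @param se expression SummarizedExperiment with a `stage` metadata column
#'   (or the column named by `stageField`).
#' @param stageField name of the ordinal stage column.
#' @param covariateFields character vector of categorical metadata columns
#'   to adjust for; a covariate collinear with the rest of the model is
#'   dropped with a warning.
#' @param alpha significance level (default 0.05).
#' @param zCap cap on |Z| (default 8.2).
#' @param source label stored on the profile.
#' @return a \linkS4class{SignatureProfile} of kind `"Z"`.
#' @export
stageRegressionProfile <- function(se, stageField = "stage",
                                   covariateFields = character(0),
                                   alpha = 0.05, zCap = .capZ,
                                   source = "") {
    cd <- as.data.frame(SummarizedExperiment::colData(se))
    if (!stageField %in% colnames(cd))
        stop("stage column '", stageField, "' absent from metadata")
    stage <- as.numeric(cd[[stageField]])
    if (length(unique(stage)) < 2L)
        stop("stage is constant across samples; no regression possible")
    df0 <- data.frame(stage = stage)
    for (cv in covariateFields) {
        if (!cv %in% colnames(cd))
            stop("covariate column '", cv, "' absent from metadata")
        df0[[cv]] <- factor(cd[[cv]])
    }
    X <- stats::model.matrix(~ ., df0)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
        keepCols <- qrX$pivot[seq_len(qrX$rank)]
        dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keepCols)]
        if ("stage" %in% dropped)
            stop("stage is collinear with the covariates")
        warning("collinear covariate column(s) dropped: ",
                paste(dropped, collapse = ", "))
        X <- X[, sort(keepCols), drop = FALSE]
        qrX <- qr(X)
    }
    n <- nrow(X)
    if (n < ncol(X) + 2L)
        stop("fewer samples than model parameters + 2")
    m <- .assayMatrix(se)
    fit <- lm.fit(X, t(m))
    coefs <- fit$coefficients
    if (is.null(dim(coefs)))
        coefs <- matrix(coefs, ncol = 1, dimnames = list(names(coefs)))
    res <- as.matrix(fit$residuals)
    dfRes <- n - ncol(X)
    sigma2 <- colSums(res^2) / dfRes
    xtxInv <- solve(crossprod(X))
    iStage <- match("stage", rownames(coefs))
    b <- coefs[iStage, ]
    seB <- sqrt(sigma2 * xtxInv[iStage, iStage])
    t <- b / seB
    p <- 2 * pt(-abs(t), dfRes)
    zero <- seB == 0 | !is.finite(t)
    if (any(zero)) {
        p[zero] <- ifelse(abs(b[zero]) > 0, 0, 1)
    }
    p[b == 0] <- 1
    z <- .signedZ(p, b, cap = zCap)
    keep <- p < alpha
    new("SignatureProfile", genes = rownames(m)[keep],
        values = unname(z[keep]), pValues = unname(p[keep]), kind = "Z",
        source = source)
}

#' Negate a signature profile
#'
#' Flips the sign of every value (and hence every sense) while keeping
#' p-values; used for measures that decrease with disease progression
#' (e.g. cognitive scores), so that all signatures point in the
#' disease direction. Applying it twice returns the original profile.
#'
#' @param profile a \linkS4class{SignatureProfile}
#' @return the negated profile
#' @export
reverseProfile <- function(profile) {
    profile@values <- -profile@values
    profile
}

#' Categorical form of a single continuous signature
#'
#' Convenience conversion used when a single study's signature serves as a
#' connectivity query: senses are the signs of the retained values, each
#' with full fractional support.
#'
#' @param profile a \linkS4class{SignatureProfile}
#' @return a \linkS4class{CategoricalSignature} with `nProfiles = 1`
#' @export
asCategoricalSignature <- function(profile) {
    s <- as.integer(sign(profile@values))
    keep <- s != 0L
    new("CategoricalSignature", genes = profile@genes[keep],
        senses = s[keep], fractions = as.numeric(s[keep]),
        support = rep(1L, sum(keep)), nProfiles = 1L)
}

#' Representative (consensus) signature across studies
#'
#' Per gene, the regulation senses over the input profiles (0 where a gene
#' was not retained by a profile's filters) are summed; the regulation
#' fraction is `(n_up - n_down) / P` with `P` the total number of input
#' profiles. Genes are retained when the absolute fraction strictly exceeds
#' `minFraction` and a one-sample Student t-test of the per-profile senses
#' against zero gives `p < alpha`. A constant nonzero sense across all
#' profiles (zero variance, maximal evidence) is retained with `p = 0`.
#'
#' @param profiles list of at least two \linkS4class{SignatureProfile}s.
#' @param minFraction retention threshold on |fraction| (default 0.20,
#'   strict inequality).
#' @param alpha significance level of the sense t-test (default 0.05).
#' @return a \linkS4class{CategoricalSignature}
#' @export
representativeProfile <- function(profiles, minFraction = 0.20,
                                  alpha = 0.05) {
    if (length(profiles) < 2L)
        stop("need >= 2 profiles; use the single profile directly ",
             "(asCategoricalSignature)")
    P <- length(profiles)
    allGenes <- sort(unique(unlist(lapply(profiles, geneIds))))
    S <- matrix(0L, nrow = length(allGenes), ncol = P,
                dimnames = list(allGenes, NULL))
    for (i in seq_len(P)) {
        si <- senses(profiles[[i]])
        S[names(si), i] <- si
    }
    fraction <- rowSums(S) / P
    tt <- .rowOneSampleT(S)
    keep <- abs(fraction) > minFraction & tt$p < alpha
    sense <- as.integer(sign(fraction[keep]))
    new("CategoricalSignature", genes = allGenes[keep], senses = sense,
        fractions = unname(fraction[keep]),
        support = unname(as.integer(rowSums(S[keep, , drop = FALSE] != 0L))),
        nProfiles = as.integer(P))
}
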