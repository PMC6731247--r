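# Shared fixtures and independent oracles used across the suite.

# Small expression container from a plain matrix.
makeSE <- function(values, group, ...) {
    md <- data.frame(group = group, ..., stringsAsFactors = FALSE)
    ExpressionMatrix(values, md)
}

# Continuous signature built directly from named values (p-values default
# to "significant"), bypassing any filtering.
makeSignature <- function(values, kind = "Z", pValues = NULL, source = "") {
    new("SignatureProfile", genes = names(values), values = unname(values),
        pValues = if (is.null(pValues)) rep(1e-4, length(values))
                  else unname(pValues),
        kind = kind, source = source)
}

makeCategorical <- function(senses) {
    new("CategoricalSignature", genes = names(senses),
        senses = as.integer(unname(senses)),
        fractions = as.numeric(unname(sign(senses))),
        support = rep(1L, length(senses)), nProfiles = 1L)
}

makeDrugProfile <- function(values, drug = "drugX", plate = "plate1",
                            method = "fold") {
    new("DrugProfile", genes = names(values), values = unname(values),
        stats = rep(1e-4, length(values)), statKind = "p", drug = drug,
        plate = plate, method = method)
}

# Brute-force Poisson-binomial upper tail: sums P(outcome) over all 2^n
# success patterns with at least `matches` successes.
pbTailEnumeration <- function(matches, probs) {
    n <- length(probs)
    total <- 0
    for (code in 0:(2^n - 1)) {
        bits <- as.integer(intToBits(code))[seq_len(n)]
        if (sum(bits) >= matches)
            total <- total + prod(ifelse(bits == 1, probs, 1 - probs))
    }
    total
}

# Ordinary least squares of y on design X by explicit normal equations,
# returning the t test of the coefficient `which`.
olsOracle <- function(X, y, which) {
    XtXinv <- solve(t(X) %*% X)
    beta <- XtXinv %*% t(X) %*% y
    res <- y - X %*% beta
    df <- nrow(X) - ncol(X)
    sigma2 <- sum(res^2) / df
    se <- sqrt(sigma2 * XtXinv[which, which])
    t <- beta[which] / se
    p <- 2 * pt(-abs(t), df)
    list(slope = beta[which], t = t, p = p,
         z = sign(beta[which]) * min(qnorm(p / 2, lower.tail = FALSE), 8.2))
}

plantedSenses <- function(truth) {
    setNames(rep(c(1L, -1L),
                 c(length(truth@upGenes), length(truth@downGenes))),
             c(truth@upGenes, truth@downGenes))
}
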