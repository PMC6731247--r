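# Internal vectorised statistics shared across modules.

# Equal-variance two-sample t, one test per matrix row (y minus x).
# Degenerate rows: zero pooled variance gives p = 0 for a nonzero difference
# (maximal evidence) and p = 1 otherwise.
.rowTTest <- function(x, y) {
    nx <- ncol(x); ny <- ncol(y)
    mx <- rowMeans(x); my <- rowMeans(y)
    vx <- rowSums((x - mx)^2) / (nx - 1L)
    vy <- rowSums((y - my)^2) / (ny - 1L)
    df <- nx + ny - 2L
    sp2 <- ((nx - 1L) * vx + (ny - 1L) * vy) / df
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    d <- my - mx
    t <- d / se
    p <- 2 * pt(-abs(t), df)
    deg <- se == 0
    if (any(deg)) {
        p[deg] <- ifelse(d[deg] != 0, 0, 1)
        t[deg] <- ifelse(d[deg] != 0, sign(d[deg]) * Inf, 0)
    }
    list(t = t, p = p, df = df, meanX = mx, meanY = my)
}

# One-sample t against zero over matrix rows. Zero-variance rows follow the
# same degenerate rule: a perfectly reproduced nonzero value is retained.
.rowOneSampleT <- function(m) {
    k <- ncol(m)
    mu <- rowMeans(m)
    s <- sqrt(rowSums((m - mu)^2) / (k - 1L))
    t <- mu / (s / sqrt(k))
    p <- 2 * pt(-abs(t), k - 1L)
    deg <- s == 0
    if (any(deg)) {
        p[deg] <- ifelse(mu[deg] != 0, 0, 1)
        t[deg] <- ifelse(mu[deg] != 0, sign(mu[deg]) * Inf, 0)
    }
    list(t = t, p = p, mean = mu)
}

# Two-sided p to a signed standard-normal quantile, capped so that p-value
# underflow near double precision cannot produce infinities.
.signedZ <- function(p, sgn, cap = .capZ) {
    z <- qnorm(pmax(p, 0) / 2, lower.tail = FALSE)
    z <- pmin(z, cap)
    z * sign(sgn)
}

.assayMatrix <- function(se) {
    m <- SummarizedExperiment::assay(se)
    storage.mode(m) <- "double"
    m
}

.sampleGroups <- function(se) {
    cd <- SummarizedExperiment::colData(se)
    if (!"group" %in% colnames(cd))
        stop("expression matrix metadata must carry a 'group' column")
    as.character(cd$group)
}
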