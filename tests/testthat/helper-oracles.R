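# Independent brute-force oracles used to check the analytical code paths.
# These deliberately share no code with the package implementation.

# U statistic by explicit pair counting (ties count half), for group x.
pairCountU <- function(x, y) {
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# Exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled values to a group of size length(x).
enumerateMWp <- function(x, y) {
    pooled <- c(x, y)
    n1 <- length(x)
    splits <- combn(length(pooled), n1)
    u_all <- apply(splits, 2L, function(idx)
        pairCountU(pooled[idx], pooled[-idx]))
    u_obs <- pairCountU(x, y)
    mu <- n1 * length(y) / 2
    # two-sided: as extreme or more, measured as distance from the mean
    min(1, mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9))
}

# Empirical AUC as the concordance probability (ties half).
pairCountAuc <- function(scores, labels) {
    pos <- scores[labels]
    neg <- scores[!labels]
    pairCountU(pos, neg) / (length(pos) * length(neg))
}

# Youden maximisation by brute force over every midpoint of adjacent
# distinct processed scores.
bruteYouden <- function(scores, labels, direction = "up") {
    proc <- if (direction == "down") -scores else scores
    v <- sort(unique(proc))
    if (length(v) < 2L) return(list(cutoff = NA_real_, j = 0))
    mids <- (v[-length(v)] + v[-1L]) / 2
    stats <- t(vapply(mids, function(m) {
        pred <- proc > m
        sens <- sum(pred & labels) / sum(labels)
        spec <- sum(!pred & !labels) / sum(!labels)
        c(j = sens + spec - 1, spec = spec)
    }, c(j = 0, spec = 0)))
    raw <- if (direction == "down") -mids else mids
    ord <- order(-round(stats[, "j"], 10), -round(stats[, "spec"], 10),
                 raw)
    list(cutoff = unname(raw[ord[1L]]),
         j = unname(stats[ord[1L], "j"]))
}

# Bernoulli log-likelihood of a univariate logistic model.
logisticLogLik <- function(beta0, beta1, x, y) {
    eta <- beta0 + beta1 * x
    sum(y * eta - log1p(exp(eta)))
}

# Two-stage dense grid search over (intercept, slope).
gridLogistic <- function(x, y, span = 8, coarse = 0.2, fine = 0.01) {
    best <- c(0, 0)
    for (step in c(coarse, fine)) {
        b0 <- seq(best[1] - span, best[1] + span, by = step)
        b1 <- seq(best[2] - span, best[2] + span, by = step)
        ll <- outer(b0, b1, Vectorize(function(a, b)
            logisticLogLik(a, b, x, y)))
        idx <- which(ll == max(ll), arr.ind = TRUE)[1L, ]
        best <- c(b0[idx[1L]], b1[idx[2L]])
        span <- 2 * step
    }
    best
}

# Small toy fixtures written to tempfiles.
writeToyCtTable <- function(lines, path = tempfile(fileext = ".csv")) {
    writeLines(c("sample_id,assay_id,replicate,ct", lines), path)
    path
}

writeToySheet <- function(lines, path = tempfile(fileext = ".csv")) {
    writeLines(c("sample_id,group,cohort", lines), path)
    path
}
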