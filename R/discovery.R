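#' Mann-Whitney U test for two groups
#'
#' Rank-sum comparison of marker levels between two groups. The statistic is
#' counted for the first group: the number of (a, b) pairs with a > b plus
#' half the tied pairs. The two-sided p-value uses exact enumeration of the
#' null permutation distribution when `n1 + n2 <= 20` and the pooled data
#' are tie-free, and otherwise the normal approximation with tie and
#' continuity correction (the classic large-sample route).
#'
#' @param x,y numeric vectors, one per group; each non-empty, no `NA`.
#' @return list with `u` (the U statistic for `x`) and `p` (two-sided
#'   p-value in (0, 1\]).
#' @examples
#' mannWhitneyU(c(1, 2), c(3, 4, 5))  # u = 0, p = 0.2 (exact)
#' @export
mannWhitneyU <- function(x, y) {
    if (length(x) < 1L || length(y) < 1L)
        stop("both groups must be non-empty")
    if (anyNA(x) || anyNA(y))
        stop("missing values must be removed before testing")
    pooled <- c(x, y)
    n1 <- length(x); n2 <- length(y)
    r <- rank(pooled)
    u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    if (length(unique(pooled)) == 1L)  # fully tied: test is vacuous
        return(list(u = u, p = 1))
    ties <- anyDuplicated(pooled) > 0L
    exact <- (n1 + n2) <= 20L && !ties
    ht <- suppressWarnings(wilcox.test(x, y, exact = exact,
                                       correct = TRUE))
    p <- min(1, ht$p.value)
    list(u = u, p = p)
}

#' Geometric mean
#' @param x positive values; `NA` removed.
#' @return geometric mean, `NA` if nothing remains.
#' @keywords internal
geomMean <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    exp(mean(log(x)))
}

#' Between-group log2 fold change of relative expression
#'
#' `log2` of the ratio of group geometric means of `2^-ddCt` relative
#' expression (equivalently, minus the difference of group mean ddCt).
#' Missing values are excluded per group.
#'
#' @param values relative-expression values (> 0 or `NA`).
#' @param groups parallel vector of group labels.
#' @param case,control the numerator and denominator group labels.
#' @return log2 fold change (case vs control); `NA` with a warning when a
#'   group has no detected value.
#' @examples
#' groupFoldChange(c(1, 1, 4, 4), c("benign", "benign",
#'                                  "malignant", "malignant"))  # 2
#' @export
groupFoldChange <- function(values, groups, case = "malignant",
                            control = "benign") {
    stopifnot(length(values) == length(groups))
    gm_case <- geomMean(values[groups == case])
    gm_ctrl <- geomMean(values[groups == control])
    if (is.na(gm_case) || is.na(gm_ctrl)) {
        warning("a group has no detected value; fold change undefined")
        return(NA_real_)
    }
    log2(gm_case / gm_ctrl)
}

#' Combined significance / effect-size score
#'
#' Joint ranking score for the discovery screen, gated by the screen's two
#' thresholds: a record scores `-log10(p) + |log2fc|` when it passes both
#' `p < pThreshold` and `|log2fc| >= log2(fcThreshold)`, and 0 otherwise.
#' Both components are dimensionless and increase with evidence, so the sum
#' ranks jointly by significance and effect size.
#'
#' @param pValue p-value(s) in (0, 1].
#' @param log2fc log2 fold change(s).
#' @param pThreshold,fcThreshold the gates (defaults 0.05 and 2).
#' @return numeric score(s), 0 for non-significant records.
#' @examples
#' combinedScore(0.001, 2)   # 5
#' combinedScore(0.5, 3)     # 0: fails the p gate
#' @export
combinedScore <- function(pValue, log2fc, pThreshold = 0.05,
                          fcThreshold = 2) {
    stopifnot(all(pValue > 0 & pValue <= 1, na.rm = TRUE))
    pass <- !is.na(pValue) & !is.na(log2fc) &
        pValue < pThreshold & abs(log2fc) >= log2(fcThreshold)
    ifelse(pass, -log10(pValue) + abs(log2fc), 0)
}

#' Differential-expression screen over all assays
#'
#' Tests every sufficiently detected assay for a malignant-vs-benign shift
#' in relative expression: Mann-Whitney U p-value, geometric-mean log2 fold
#' change, Benjamini-Hochberg q-value (reported, not used for selection),
#' combined score and direction. Missing values are excluded pairwise; an
#' assay enters the screen only if at least `minDetectionFraction` of
#' samples is detected in at least one group and both groups retain at
#' least one value.
#'
#' @param x a \linkS4class{MiRExperiment}.
#' @param config a \linkS4class{RunConfig} supplying the thresholds.
#' @return data.frame with one row per tested assay: `assay_id`,
#'   `n_benign`, `n_malignant`, `log2fc`, `u_stat`, `p_value`, `q_value`,
#'   `combined_score`, `direction` (`up`/`down`/`ns`), ordered by
#'   decreasing combined score then increasing p.
#' @export
screenFeatures <- function(x, config = runConfig()) {
    grp <- sampleGroups(x)
    stopifnot(all(c("benign", "malignant") %in% grp))
    rel <- relExpr(x)
    nb_tot <- sum(grp == "benign"); nm_tot <- sum(grp == "malignant")
    rows <- lapply(rownames(rel), function(a) {
        v <- rel[a, ]
        vb <- v[grp == "benign"]; vm <- v[grp == "malignant"]
        fb <- mean(!is.na(vb)); fm <- mean(!is.na(vm))
        if (max(fb, fm) < config@minDetectionFraction)
            return(NULL)
        vb <- vb[!is.na(vb)]; vm <- vm[!is.na(vm)]
        if (!length(vb) || !length(vm))
            return(NULL)
        mw <- mannWhitneyU(vm, vb)   # U counted for the malignant group
        lfc <- suppressWarnings(groupFoldChange(v, grp))
        data.frame(assay_id = a, n_benign = length(vb),
                   n_malignant = length(vm),
                   det_frac_benign = fb, det_frac_malignant = fm,
                   log2fc = lfc, u_stat = mw$u, p_value = mw$p,
                   stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows))
        return(data.frame(assay_id = character(0)))
    out <- do.call(rbind, rows)
    out$q_value <- p.adjust(out$p_value, method = "BH")
    out$combined_score <- combinedScore(out$p_value, out$log2fc,
                                        config@pThreshold,
                                        config@fcThreshold)
    sig <- out$combined_score > 0
    out$direction <- ifelse(!sig, "ns",
                            ifelse(out$log2fc > 0, "up", "down"))
    out <- out[order(-out$combined_score, out$p_value, out$assay_id), ]
    rownames(out) <- NULL
    out
}

#' Select the top screen candidates per direction
#'
#' Ranks significant records by descending combined score, breaking ties by
#' smaller p-value and then lexicographic assay id, and returns the top
#' `topK` upregulated and top `topK` downregulated assays. When a direction
#' has fewer significant records than requested, all available are returned
#' with a warning.
#'
#' @param records screen output of [screenFeatures()].
#' @param topK candidates per direction (default 3).
#' @return list with data.frames `up` and `down`.
#' @export
selectTopCandidates <- function(records, topK = 3L) {
    pick <- function(dirn) {
        d <- records[records$direction == dirn, , drop = FALSE]
        d <- d[order(-d$combined_score, d$p_value, d$assay_id), ,
               drop = FALSE]
        if (nrow(d) < topK)
            warning("only ", nrow(d), " ", dirn,
                    "-regulated candidate(s) available (requested ",
                    topK, ")")
        head(d, topK)
    }
    list(up = pick("up"), down = pick("down"))
}
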