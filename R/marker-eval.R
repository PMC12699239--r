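#' Empirical ROC curve for one marker
#'
#' Builds the full empirical ROC over all distinct observed scores. For a
#' downregulated marker (`direction = "down"`) scores are negated first, so
#' that a higher processed score always indicates the positive (malignant)
#' class. Candidate thresholds are the midpoints between *adjacent* distinct
#' processed scores, flanked by `Inf` and `-Inf`; a sample is called
#' positive when its processed score exceeds the threshold. The AUC is the
#' trapezoid-rule area, which handles tied scores as half-concordant.
#'
#' @param scores numeric marker values (raw scale); `NA` not allowed.
#' @param labels logical (or 0/1) ground truth, `TRUE` = positive class.
#' @param direction `"up"` (high score = positive) or `"down"`.
#' @return a \linkS4class{RocCurve}.
#' @examples
#' rc <- rocCurve(c(3, 5, 1, 2, 4), c(TRUE, TRUE, FALSE, FALSE, FALSE))
#' auc(rc)  # 5/6
#' @export
rocCurve <- function(scores, labels, direction = c("up", "down")) {
    direction <- match.arg(direction)
    labels <- as.logical(labels)
    stopifnot(length(scores) == length(labels))
    if (anyNA(scores) || anyNA(labels))
        stop("scores and labels must not contain NA")
    if (!any(labels) || all(labels))
        stop("both classes must be present")
    proc <- if (direction == "down") -scores else scores
    v <- sort(unique(proc), decreasing = TRUE)
    npos <- sum(labels); nneg <- sum(!labels)
    tp_at <- cumsum(vapply(v, function(t) sum(proc == t & labels),
                           numeric(1)))
    fp_at <- cumsum(vapply(v, function(t) sum(proc == t & !labels),
                           numeric(1)))
    # threshold Inf calls nothing positive; the midpoint below v_i calls
    # exactly {v_1..v_i} positive; -Inf calls everything positive
    tpr <- c(0, tp_at / npos)
    fpr <- c(0, fp_at / nneg)
    if (length(v) > 1L) mids <- (v[-length(v)] + v[-1L]) / 2
    else mids <- numeric(0)
    thresholds <- c(Inf, mids, -Inf)
    auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
    new("RocCurve", thresholds = thresholds, fpr = fpr, tpr = tpr,
        auc = auc, direction = direction)
}

#' @describeIn RocCurve-accessors trapezoid-rule area under the curve.
#' @export
setMethod("auc", "RocCurve", function(x) x@auc)

setMethod("show", "RocCurve", function(object) {
    cat(sprintf("RocCurve: %d operating points, direction=%s, AUC=%.4f\n",
                length(object@thresholds), object@direction, object@auc))
})

#' Youden-index optimal cutoff
#'
#' Maximises J = sensitivity + specificity - 1 = TPR - FPR over the curve's
#' finite thresholds (midpoints between adjacent distinct observed scores,
#' so training samples are never on the boundary). Ties are broken by
#' higher specificity, then by the lower cutoff on the marker's raw scale.
#'
#' @param curve a \linkS4class{RocCurve}.
#' @return list with `cutoff` (raw marker scale; positive above for
#'   direction `"up"`, below for `"down"`; `NA` when the marker is
#'   constant) and `j` (the maximal Youden index).
#' @export
youdenCutoff <- function(curve) {
    finite <- is.finite(curve@thresholds)
    if (!any(finite))
        return(list(cutoff = NA_real_, j = 0))
    thr <- curve@thresholds[finite]
    j <- curve@tpr[finite] - curve@fpr[finite]
    spec <- 1 - curve@fpr[finite]
    raw <- if (curve@direction == "down") -thr else thr
    # round before ordering so exact rational ties are not broken by
    # floating-point noise
    ord <- order(-round(j, 10), -round(spec, 10), raw)
    best <- ord[1L]
    list(cutoff = raw[best], j = j[best])
}

#' Confusion-matrix metrics
#'
#' The five standard diagnostic proportions plus the Youden index, from
#' integer confusion counts. Ratios with a zero denominator are returned as
#' `NA`.
#'
#' @param tp,fp,fn,tn non-negative counts; at least one actual positive
#'   (`tp + fn`) and one actual negative (`tn + fp`) are required.
#' @return list with `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `accuracy`, `youden_j`.
#' @examples
#' m <- confusionMetrics(tp = 14, fp = 3, fn = 3, tn = 15)
#' round(100 * m$accuracy, 1)  # 82.9
#' @export
confusionMetrics <- function(tp, fp, fn, tn) {
    counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
    if (any(counts < 0))
        stop("confusion counts must be non-negative")
    if (tp + fn < 1 || tn + fp < 1)
        stop("both actual classes must be represented")
    ratio <- function(num, den) if (den > 0) num / den else NA_real_
    sens <- ratio(tp, tp + fn)
    spec <- ratio(tn, tn + fp)
    list(sensitivity = sens,
         specificity = spec,
         ppv = ratio(tp, tp + fp),
         npv = ratio(tn, tn + fn),
         accuracy = (tp + tn) / (tp + fp + fn + tn),
         youden_j = sens + spec - 1)
}

#' Full diagnostic evaluation of one marker
#'
#' Convenience wrapper chaining [rocCurve()], [youdenCutoff()] and the
#' confusion metrics at the chosen cutoff: the in-sample, Youden-optimal
#' operating point reported for each validated marker. Samples with a
#' missing marker value are excluded.
#'
#' @param scores marker values on the raw (relative-expression) scale;
#'   `NA` allowed and dropped together with its label.
#' @param labels logical ground truth (`TRUE` = malignant).
#' @param direction `"up"` or `"down"`.
#' @param assayId marker name carried into the output.
#' @return one-row data.frame: `assay_id`, `direction`, `cutoff`,
#'   `youden_j`, `tp`, `fp`, `fn`, `tn`, the five proportions, and `auc`.
#' @export
evaluateMarker <- function(scores, labels, direction = c("up", "down"),
                           assayId = "marker") {
    direction <- match.arg(direction)
    labels <- as.logical(labels)
    keep <- !is.na(scores)
    scores <- scores[keep]; labels <- labels[keep]
    curve <- rocCurve(scores, labels, direction)
    yc <- youdenCutoff(curve)
    pos <- if (direction == "up") scores > yc$cutoff else scores < yc$cutoff
    tp <- sum(pos & labels); fp <- sum(pos & !labels)
    fn <- sum(!pos & labels); tn <- sum(!pos & !labels)
    m <- confusionMetrics(tp, fp, fn, tn)
    data.frame(assay_id = assayId, direction = direction,
               cutoff = yc$cutoff, youden_j = yc$j,
               tp = tp, fp = fp, fn = fn, tn = tn,
               sensitivity = m$sensitivity, specificity = m$specificity,
               ppv = m$ppv, npv = m$npv, accuracy = m$accuracy,
               auc = curve@auc, stringsAsFactors = FALSE)
}

#' Univariate logistic regression for a marker
#'
#' Maximum-likelihood logistic fit of class membership on a single marker
#' (IRLS via [stats::glm()]), summarised as an odds ratio per unit of the
#' covariate with a Wald 95% CI (`exp(slope +/- 1.96 SE)`). Complete or
#' quasi-complete separation is detected (non-overlapping covariate ranges
#' or a diverging slope) and flagged; the reported estimates are then not
#' trustworthy maximum-likelihood values.
#'
#' @param x finite marker values (relative-expression scale).
#' @param labels logical ground truth (`TRUE` = malignant).
#' @param logScale fit per log2-unit of the marker instead of per linear
#'   unit (default `FALSE`).
#' @return a \linkS4class{LogisticFit}.
#' @examples
#' set.seed(1)
#' f <- fitLogisticUnivariate(rnorm(40), rep(c(TRUE, FALSE), 20))
#' oddsRatio(f)
#' @export
fitLogisticUnivariate <- function(x, labels, logScale = FALSE) {
    labels <- as.logical(labels)
    if (anyNA(x) || any(!is.finite(x)))
        stop("marker values must be finite")
    if (!any(labels) || all(labels))
        stop("both classes must be present")
    if (logScale) {
        stopifnot(all(x > 0))
        x <- log2(x)
    }
    separated <- max(x[!labels]) < min(x[labels]) ||
        max(x[labels]) < min(x[!labels])
    warned <- FALSE
    fit <- withCallingHandlers(
        glm(labels ~ x, family = binomial()),
        warning = function(w) {
            if (grepl("fitted probabilities|did not converge",
                      conditionMessage(w))) {
                warned <<- TRUE
                invokeRestart("muffleWarning")
            }
        })
    slope <- unname(coef(fit)[2L])
    se <- sqrt(diag(vcov(fit)))[2L]
    separated <- separated || warned || abs(slope) > 15
    z <- slope / se
    new("LogisticFit",
        intercept = unname(coef(fit)[1L]),
        slope = slope,
        orPerUnit = exp(slope),
        ciLow = exp(slope - 1.96 * se),
        ciHigh = if (separated) Inf else exp(slope + 1.96 * se),
        pWald = 2 * pnorm(-abs(z)),
        converged = fit$converged && !separated,
        separation = separated)
}

#' @describeIn LogisticFit-accessors odds ratio per covariate unit with its
#'   Wald 95% CI.
#' @export
setMethod("oddsRatio", "LogisticFit", function(x)
    c(or = x@orPerUnit, low = x@ciLow, high = x@ciHigh))

setMethod("show", "LogisticFit", function(object) {
    cat(sprintf(
        "LogisticFit: OR=%.3f (95%% CI %.3f-%.3f), p=%.4g%s\n",
        object@orPerUnit, object@ciLow, object@ciHigh, object@pWald,
        if (object@separation) " [separation]" else ""))
})
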