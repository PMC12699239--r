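#' Construct a k-of-n panel voting rule
#'
#' Builds a \linkS4class{PanelRule} from a per-marker performance table
#' (typically the row-bound output of [evaluateMarker()] across the
#' validated candidates): each marker contributes its direction-aware
#' Youden cutoff, and a sample is panel-positive when at least
#' `kMinPositive` markers vote positive.
#'
#' @param markers data.frame with columns `assay_id`, `cutoff`,
#'   `direction`.
#' @param kMinPositive minimum positive votes (default 3, the
#'   any-three-positive rule).
#' @return a \linkS4class{PanelRule}.
#' @export
panelRule <- function(markers, kMinPositive = 3L) {
    new("PanelRule",
        markers = as.data.frame(
            markers[, c("assay_id", "cutoff", "direction")]),
        kMinPositive = as.integer(kMinPositive))
}

#' Direction-aware positivity call
#'
#' A marker votes "positive" (malignant-like) when its expression lies
#' above the cutoff for an upregulated marker, or below the cutoff for a
#' downregulated one; both inequalities are strict ("above"/"below").
#' Missing values give a missing call.
#'
#' @param value expression value(s); `NA` = missing.
#' @param cutoff expression cutoff.
#' @param direction `"up"` or `"down"`.
#' @return logical vector with `NA` for missing calls.
#' @examples
#' callPositivity(4, 2, "up")      # TRUE
#' callPositivity(0.3, 0.5, "down") # TRUE
#' @export
callPositivity <- function(value, cutoff, direction = c("up", "down")) {
    direction <- match.arg(direction)
    if (direction == "up") value > cutoff else value < cutoff
}

#' Count positive votes for one sample
#'
#' Missing marker calls count as negative votes (the conservative choice:
#' absence of evidence is not a positive result), with the number of
#' missing calls reported alongside.
#'
#' @param calls logical vector of per-marker calls (`NA` = missing).
#' @return list with `votes` and `nMissing`; error when every call is
#'   missing.
#' @export
voteCount <- function(calls) {
    if (all(is.na(calls)))
        stop("all marker calls are missing for this sample")
    list(votes = sum(calls, na.rm = TRUE), nMissing = sum(is.na(calls)))
}

#' Apply a panel rule to an expression matrix
#'
#' @param x a \linkS4class{MiRExperiment} (or an assays x samples numeric
#'   matrix) containing the rule's markers as rows.
#' @param rule a \linkS4class{PanelRule}.
#' @return list with integer vectors `votes` and `nMissing`, named by
#'   sample.
#' @export
panelVotes <- function(x, rule) {
    mat <- if (is(x, "MiRExperiment")) relExpr(x) else x
    missing_markers <- setdiff(rule@markers$assay_id, rownames(mat))
    if (length(missing_markers))
        stop("marker(s) absent from the matrix: ",
             paste(missing_markers, collapse = ", "))
    calls <- vapply(seq_len(nrow(rule@markers)), function(i)
        callPositivity(mat[rule@markers$assay_id[i], ],
                       rule@markers$cutoff[i],
                       rule@markers$direction[i]),
        logical(ncol(mat)))
    if (is.null(dim(calls))) calls <- matrix(calls, nrow = 1L)
    votes <- apply(calls, 1L, function(cc) voteCount(cc)$votes)
    miss <- apply(calls, 1L, function(cc) sum(is.na(cc)))
    list(votes = setNames(as.integer(votes), colnames(mat)),
         nMissing = setNames(as.integer(miss), colnames(mat)))
}

#' AUC of a single binary decision rule
#'
#' The trapezoid area of the two-point ROC through (0,0),
#' (1 - specificity, sensitivity), (1,1), which reduces to the mean of
#' sensitivity and specificity. This is the AUC attributed to a yes/no
#' classifier such as a k-of-n panel call at a fixed k.
#'
#' @param sensitivity,specificity proportions in \[0, 1\].
#' @return AUC in \[0, 1\].
#' @examples
#' binaryRuleAuc(1, 15 / 18)  # 0.9167
#' @export
binaryRuleAuc <- function(sensitivity, specificity) {
    stopifnot(sensitivity >= 0, sensitivity <= 1,
              specificity >= 0, specificity <= 1)
    (sensitivity + specificity) / 2
}

#' Sweep the k-of-n panel over all k
#'
#' For each minimum-vote threshold k in 1..n, classifies a sample positive
#' when its vote count reaches k and computes the confusion metrics and the
#' binary-rule AUC. Because raising k can only shrink the positive set,
#' sensitivity is non-increasing and specificity non-decreasing in k. The
#' full ROC over the integer vote count is computed as well; the two AUC
#' notions are reported separately (neither dominates in general).
#'
#' @param votes integer per-sample vote counts.
#' @param labels logical ground truth (`TRUE` = malignant).
#' @param nMarkers panel size n.
#' @param nMissing optional per-sample missing-call counts (recorded in the
#'   result).
#' @return a \linkS4class{PanelPerformance}; `bestK` maximises the
#'   binary-rule AUC, ties resolved towards the larger (more specific) k.
#' @export
evaluateKofN <- function(votes, labels, nMarkers,
                         nMissing = integer(length(votes))) {
    labels <- as.logical(labels)
    stopifnot(length(votes) == length(labels),
              all(votes >= 0), all(votes <= nMarkers))
    if (!any(labels) || all(labels))
        stop("both classes must be present")
    perK <- do.call(rbind, lapply(seq_len(nMarkers), function(k) {
        pos <- votes >= k
        tp <- sum(pos & labels); fp <- sum(pos & !labels)
        fn <- sum(!pos & labels); tn <- sum(!pos & !labels)
        m <- confusionMetrics(tp, fp, fn, tn)
        data.frame(k = k, tp = tp, fp = fp, fn = fn, tn = tn,
                   sensitivity = m$sensitivity,
                   specificity = m$specificity,
                   auc_binary = binaryRuleAuc(m$sensitivity,
                                              m$specificity))
    }))
    best <- max(perK$k[perK$auc_binary == max(perK$auc_binary)])
    new("PanelPerformance",
        perK = perK,
        voteCounts = as.integer(votes),
        nMissing = as.integer(nMissing),
        bestK = as.integer(best),
        voteRoc = rocCurve(votes, labels, "up"))
}

#' End-to-end panel evaluation on a cohort
#'
#' Applies a \linkS4class{PanelRule} to an expression container and sweeps
#' k against the cohort's group labels.
#'
#' @param x a \linkS4class{MiRExperiment}.
#' @param rule a \linkS4class{PanelRule}.
#' @return a \linkS4class{PanelPerformance}.
#' @export
evaluatePanel <- function(x, rule) {
    pv <- panelVotes(x, rule)
    labels <- sampleGroups(x) == "malignant"
    evaluateKofN(pv$votes, labels, nrow(rule@markers), pv$nMissing)
}

#' @describeIn PanelPerformance-accessors per-k confusion table.
#' @export
setMethod("perK", "PanelPerformance", function(x) x@perK)

#' @describeIn PanelPerformance-accessors the AUC-optimal k.
#' @export
setMethod("bestK", "PanelPerformance", function(x) x@bestK)

#' @describeIn PanelPerformance-accessors per-sample positive-vote counts.
#' @export
setMethod("voteCounts", "PanelPerformance", function(x) x@voteCounts)

#' @describeIn PanelPerformance-accessors AUC of the vote-count ROC.
#' @export
setMethod("auc", "PanelPerformance", function(x) x@voteRoc@auc)

setMethod("show", "PanelPerformance", function(object) {
    b <- object@perK[object@perK$k == object@bestK, ]
    cat(sprintf(paste0(
        "PanelPerformance: n=%d samples, %d markers\n",
        "best k=%d: sens=%.3f spec=%.3f AUC(binary)=%.3f; ",
        "AUC(vote ROC)=%.3f\n"),
        length(object@voteCounts), nrow(object@perK), object@bestK,
        b$sensitivity, b$specificity, b$auc_binary, object@voteRoc@auc))
})
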