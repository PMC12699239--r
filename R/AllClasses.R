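#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats sd var p.adjust prcomp hclust dist as.dist cor cutree
#'   wilcox.test glm binomial coef vcov pnorm rnorm setNames
#' @importFrom utils read.csv write.table head
NULL

#' Run configuration for the two-phase qPCR workflow
#'
#' Bundles the tunable thresholds of the pipeline: the Ct negativity
#' threshold, the endogenous reference assays used for delta-Ct
#' normalisation, the minimum per-group detection fraction an assay needs to
#' be testable, the screen's p-value and fold-change thresholds, and the
#' number of top candidates to carry per direction into validation.
#'
#' @slot negativityThreshold numeric(1). Ct above this value is called
#'   undetected ("negative"); default 35 cycles.
#' @slot referenceAssays character. Assay ids of endogenous controls (e.g.
#'   an RNU48-like small RNA).
#' @slot minDetectionFraction numeric(1) in \[0,1\]. An assay is testable in
#'   the screen only if at least this fraction of samples is detected in at
#'   least one group; default 0.5.
#' @slot pThreshold numeric(1). Raw p-value threshold of the screen
#'   (default 0.05).
#' @slot fcThreshold numeric(1) > 1. Linear fold-change threshold of the
#'   screen (default 2, i.e. |log2 FC| >= 1).
#' @slot topK integer(1) >= 1. Candidates selected per direction
#'   (default 3).
#' @slot rngSeed integer(1). Seed recorded with the configuration.
#' @aliases RunConfig-class
#' @exportClass RunConfig
setClass("RunConfig",
    representation(
        negativityThreshold = "numeric",
        referenceAssays = "character",
        minDetectionFraction = "numeric",
        pThreshold = "numeric",
        fcThreshold = "numeric",
        topK = "integer",
        rngSeed = "integer"
    ),
    prototype(
        negativityThreshold = 35,
        referenceAssays = character(0),
        minDetectionFraction = 0.5,
        pThreshold = 0.05,
        fcThreshold = 2,
        topK = 3L,
        rngSeed = 1L
    )
)

setValidity("RunConfig", function(object) {
    msg <- character(0)
    if (length(object@negativityThreshold) != 1L ||
        !is.finite(object@negativityThreshold) ||
        object@negativityThreshold <= 0)
        msg <- c(msg, "negativityThreshold must be a single positive number")
    if (length(object@minDetectionFraction) != 1L ||
        object@minDetectionFraction < 0 || object@minDetectionFraction > 1)
        msg <- c(msg, "minDetectionFraction must lie in [0, 1]")
    if (length(object@pThreshold) != 1L ||
        object@pThreshold <= 0 || object@pThreshold > 1)
        msg <- c(msg, "pThreshold must lie in (0, 1]")
    if (length(object@fcThreshold) != 1L || object@fcThreshold <= 1)
        msg <- c(msg, "fcThreshold must be > 1")
    if (length(object@topK) != 1L || is.na(object@topK) || object@topK < 1L)
        msg <- c(msg, "topK must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Relative-expression container for a qPCR cohort
#'
#' A \linkS4class{SummarizedExperiment} with assays (microRNAs) as rows and
#' samples as columns. The `"relexpr"` assay holds 2^-ddCt relative
#' expression; `NA` marks undetected (missing) measurements. `colData`
#' carries the sample annotations (`group`, `cohort`); normalisation
#' provenance (reference assays, calibrator group, negativity threshold,
#' normalisation mode) lives in `metadata()`.
#'
#' @aliases MiRExperiment-class
#' @exportClass MiRExperiment
setClass("MiRExperiment", contains = "SummarizedExperiment")

setValidity("MiRExperiment", function(object) {
    a <- SummarizedExperiment::assayNames(object)
    if (!"relexpr" %in% a)
        return("assay 'relexpr' is required")
    x <- SummarizedExperiment::assay(object, "relexpr")
    if (any(!is.na(x) & x <= 0))
        return("relative expression must be > 0 wherever not missing")
    if (!all(c("sample_id", "group") %in%
             colnames(SummarizedExperiment::colData(object))))
        return("colData must contain sample_id and group")
    TRUE
})

#' Empirical ROC curve
#'
#' Thresholds are midpoints between adjacent distinct processed scores
#' (scores are negated first for direction `"down"`, so that a higher
#' processed score always means "more likely positive"), flanked by
#' `Inf`/`-Inf`. The curve runs from (0,0) to (1,1); the AUC is computed by
#' the trapezoid rule and equals the tie-corrected concordance probability.
#'
#' @slot thresholds numeric, decreasing, on the processed-score scale.
#' @slot fpr,tpr numeric, the operating points, one per threshold.
#' @slot auc numeric(1) in \[0,1\].
#' @slot direction `"up"` or `"down"` (whether high or low raw marker
#'   values indicate the positive class).
#' @aliases RocCurve-class
#' @exportClass RocCurve
setClass("RocCurve",
    representation(
        thresholds = "numeric",
        fpr = "numeric",
        tpr = "numeric",
        auc = "numeric",
        direction = "character"
    )
)

setValidity("RocCurve", function(object) {
    msg <- character(0)
    n <- length(object@thresholds)
    if (length(object@fpr) != n || length(object@tpr) != n)
        msg <- c(msg, "thresholds, fpr and tpr must have equal length")
    if (n >= 2 && (object@fpr[1] != 0 || object@tpr[1] != 0 ||
                   object@fpr[n] != 1 || object@tpr[n] != 1))
        msg <- c(msg, "curve must start at (0,0) and end at (1,1)")
    if (is.unsorted(object@fpr) || is.unsorted(object@tpr))
        msg <- c(msg, "fpr and tpr must be non-decreasing")
    if (length(object@auc) != 1L || object@auc < 0 || object@auc > 1)
        msg <- c(msg, "auc must lie in [0,1]")
    if (!object@direction %in% c("up", "down"))
        msg <- c(msg, "direction must be 'up' or 'down'")
    if (length(msg)) msg else TRUE
})

#' Univariate logistic regression fit
#'
#' Maximum-likelihood fit of `P(malignant) ~ marker` by iteratively
#' reweighted least squares, summarised as an odds ratio per unit of the
#' covariate with a Wald 95% confidence interval.
#'
#' @slot intercept,slope numeric(1), the fitted coefficients (log-odds).
#' @slot orPerUnit numeric(1), `exp(slope)`.
#' @slot ciLow,ciHigh numeric(1), Wald 95% CI bounds for the odds ratio.
#' @slot pWald numeric(1), Wald test p-value for the slope.
#' @slot converged logical(1).
#' @slot separation logical(1). `TRUE` when the covariate (quasi-)perfectly
#'   separates the classes, in which case the MLE diverges and the CI is
#'   not trustworthy.
#' @aliases LogisticFit-class
#' @exportClass LogisticFit
setClass("LogisticFit",
    representation(
        intercept = "numeric",
        slope = "numeric",
        orPerUnit = "numeric",
        ciLow = "numeric",
        ciHigh = "numeric",
        pWald = "numeric",
        converged = "logical",
        separation = "logical"
    )
)

setValidity("LogisticFit", function(object) {
    if (isTRUE(object@separation) && isTRUE(object@converged) &&
        is.finite(object@ciLow) && is.finite(object@ciHigh))
        return("separation implies non-convergence or an unbounded CI")
    TRUE
})

#' Marker panel voting rule
#'
#' A set of markers, each with a direction-aware expression cutoff, plus the
#' minimum number of positive calls (`k`) required to call a sample
#' panel-positive. Upregulated markers vote positive above their cutoff,
#' downregulated markers below.
#'
#' @slot markers data.frame with columns `assay_id`, `cutoff`, `direction`.
#' @slot kMinPositive integer(1), 1 <= k <= number of markers.
#' @aliases PanelRule-class
#' @exportClass PanelRule
setClass("PanelRule",
    representation(markers = "data.frame", kMinPositive = "integer")
)

setValidity("PanelRule", function(object) {
    msg <- character(0)
    need <- c("assay_id", "cutoff", "direction")
    if (!all(need %in% colnames(object@markers)))
        msg <- c(msg, "markers needs columns assay_id, cutoff, direction")
    else {
        if (!all(object@markers$direction %in% c("up", "down")))
            msg <- c(msg, "marker direction must be 'up' or 'down'")
        if (!all(is.finite(object@markers$cutoff)))
            msg <- c(msg, "cutoffs must be finite")
    }
    k <- object@kMinPositive
    if (length(k) != 1L || is.na(k) || k < 1L || k > nrow(object@markers))
        msg <- c(msg, "kMinPositive must satisfy 1 <= k <= n markers")
    if (length(msg)) msg else TRUE
})

#' Performance of a k-of-n voting panel
#'
#' @slot perK data.frame with one row per k (columns `k`, `tp`, `fp`, `fn`,
#'   `tn`, `sensitivity`, `specificity`, `auc_binary`).
#' @slot voteCounts integer, per-sample positive-vote counts.
#' @slot nMissing integer, per-sample missing-call counts.
#' @slot bestK integer(1), the k maximising the binary-rule AUC (ties go to
#'   the larger, more specific, k).
#' @slot voteRoc the full ROC over the integer vote count, a
#'   \linkS4class{RocCurve}.
#' @aliases PanelPerformance-class
#' @exportClass PanelPerformance
setClass("PanelPerformance",
    representation(
        perK = "data.frame",
        voteCounts = "integer",
        nMissing = "integer",
        bestK = "integer",
        voteRoc = "RocCurve"
    )
)

#' Principal-component embedding of an expression slice
#'
#' @slot sampleIds character, row order of `coordinates`.
#' @slot coordinates numeric matrix (samples x retained components).
#' @slot explainedVariance numeric, variance fractions of *all* components
#'   (non-increasing, summing to 1).
#' @aliases EmbeddingResult-class
#' @exportClass EmbeddingResult
setClass("EmbeddingResult",
    representation(
        sampleIds = "character",
        coordinates = "matrix",
        explainedVariance = "numeric"
    )
)

setValidity("EmbeddingResult", function(object) {
    msg <- character(0)
    if (nrow(object@coordinates) != length(object@sampleIds))
        msg <- c(msg, "coordinates must have one row per sample")
    ev <- object@explainedVariance
    if (length(ev) && (is.unsorted(rev(ev)) || sum(ev) > 1 + 1e-8))
        msg <- c(msg, "explained fractions must be non-increasing, sum <= 1")
    if (length(msg)) msg else TRUE
})

#' Specification of a synthetic qPCR cohort
#'
#' Describes a cohort the generator can draw: group sizes, per-assay
#' baseline delta-Ct levels and planted log2 fold changes, endogenous
#' reference assays, technical replication, and Ct-threshold dropout.
#' Noise is Gaussian on the Ct (log2) scale throughout.
#'
#' @slot nBenign,nMalignant integer(1) >= 1, group sizes.
#' @slot assays data.frame with columns `assay_id`, `baseline_mean_ct`
#'   (cycles above the reference), `baseline_sd_ct` (biological SD, cycles)
#'   and `planted_log2fc` (malignant vs benign; the planted delta-Ct shift
#'   is its negative).
#' @slot referenceAssays data.frame with columns `assay_id`, `mean_ct`,
#'   `sd_ct` for the endogenous controls.
#' @slot nReplicates integer(1), technical replicates per well.
#' @slot replicateSd numeric(1), technical SD per replicate (cycles).
#' @slot negativityThreshold numeric(1), Ct above which a well drops out.
#' @slot dropout logical(1), whether wells above the threshold are emitted
#'   as undetected.
#' @slot cohort character(1), label written to the sample sheet.
#' @slot rngSeed integer(1).
#' @aliases SyntheticCohortSpec-class
#' @exportClass SyntheticCohortSpec
setClass("SyntheticCohortSpec",
    representation(
        nBenign = "integer",
        nMalignant = "integer",
        assays = "data.frame",
        referenceAssays = "data.frame",
        nReplicates = "integer",
        replicateSd = "numeric",
        negativityThreshold = "numeric",
        dropout = "logical",
        cohort = "character",
        rngSeed = "integer"
    )
)

setValidity("SyntheticCohortSpec", function(object) {
    msg <- character(0)
    if (object@nBenign < 1L || object@nMalignant < 1L)
        msg <- c(msg, "both group sizes must be >= 1")
    need <- c("assay_id", "baseline_mean_ct", "baseline_sd_ct",
              "planted_log2fc")
    if (!all(need %in% colnames(object@assays)))
        msg <- c(msg, paste("assays needs columns",
                            paste(need, collapse = ", ")))
    else if (any(object@assays$baseline_sd_ct < 0))
        msg <- c(msg, "baseline SDs must be >= 0")
    needr <- c("assay_id", "mean_ct", "sd_ct")
    if (!all(needr %in% colnames(object@referenceAssays)))
        msg <- c(msg, paste("referenceAssays needs columns",
                            paste(needr, collapse = ", ")))
    else if (any(object@referenceAssays$sd_ct < 0))
        msg <- c(msg, "reference SDs must be >= 0")
    if (any(duplicated(c(object@assays$assay_id,
                         object@referenceAssays$assay_id))))
        msg <- c(msg, "assay ids must be unique across targets + references")
    if (object@nReplicates < 1L)
        msg <- c(msg, "nReplicates must be >= 1")
    if (object@replicateSd < 0)
        msg <- c(msg, "replicateSd must be >= 0")
    if (object@negativityThreshold <= 0)
        msg <- c(msg, "negativityThreshold must be > 0")
    if (length(msg)) msg else TRUE
})
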