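#' Detection call for a Ct value
#'
#' A well is detected when a Ct was measured and it does not exceed the
#' negativity threshold; "over threshold" is read strictly, so a Ct exactly
#' at the threshold is still detected. Undetected wells (`NA`) are negative.
#'
#' @param ct numeric vector of Ct values; `NA` = undetected.
#' @param threshold positive Ct negativity threshold (default 35 cycles).
#' @return logical vector.
#' @examples
#' callDetection(c(34, 35, 35.01, NA))  # TRUE TRUE FALSE FALSE
#' @export
callDetection <- function(ct, threshold = 35) {
    stopifnot(length(threshold) == 1L, is.finite(threshold), threshold > 0)
    !is.na(ct) & ct <= threshold
}

#' Aggregate technical replicates per (sample, assay)
#'
#' Collapses replicate wells to one aggregated Ct per sample/assay pair.
#' Mean and sample SD are computed over *detected* replicates only; a pair
#' with zero detected replicates is undetected (`mean_ct = NA`). Pairs whose
#' replicate scatter exceeds `qcSd` cycles are flagged but never dropped —
#' discarding is left to the analyst via the QC columns.
#'
#' @param records Ct table data.frame (columns `sample_id`, `assay_id`,
#'   `replicate`, `ct`); replicate counts may differ between pairs.
#' @param threshold Ct negativity threshold.
#' @param qcSd replicate-SD flag threshold in cycles (default 0.5).
#' @return data.frame with one row per (sample, assay): `mean_ct`, `sd_ct`
#'   (0 for a single detected replicate), `n_detected`, `n_total`,
#'   `detected`, `qc_flag`.
#' @export
aggregateReplicates <- function(records, threshold = 35, qcSd = 0.5) {
    stopifnot(nrow(records) >= 1L)
    det <- callDetection(records$ct, threshold)
    key <- interaction(records$sample_id, records$assay_id, drop = TRUE,
                       sep = "\r")
    idx <- split(seq_len(nrow(records)), key)
    rows <- lapply(idx, function(i) {
        cts <- records$ct[i][det[i]]
        n_det <- length(cts)
        if (n_det == 0L) {
            m <- NA_real_; s <- NA_real_
        } else {
            m <- mean(cts)
            s <- if (n_det == 1L) 0 else sd(cts)
        }
        data.frame(sample_id = records$sample_id[i[1L]],
                   assay_id = records$assay_id[i[1L]],
                   mean_ct = m, sd_ct = s,
                   n_detected = n_det, n_total = length(i),
                   detected = n_det >= 1L,
                   qc_flag = !is.na(s) && s > qcSd,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Delta-Ct against endogenous reference assays
#'
#' Normalises a target's aggregated Ct by the arithmetic mean of the
#' reference assays' mean Cts measured in the same sample:
#' \eqn{\Delta Ct = Ct_{target} - \overline{Ct}_{ref}}. With a single
#' reference this is the usual single-control delta-Ct.
#'
#' @param targetCt aggregated mean Ct of the target (numeric).
#' @param referenceCts numeric vector of the sample's reference mean Cts;
#'   any undetected (`NA`) reference is a normalisation error.
#' @return delta-Ct in cycles.
#' @examples
#' deltaCt(25, 20)          # 5
#' deltaCt(25, c(20, 22))   # 4
#' @export
deltaCt <- function(targetCt, referenceCts) {
    if (length(referenceCts) < 1L || anyNA(referenceCts))
        stop("undetected reference assay: cannot normalise this sample")
    if (is.na(targetCt)) return(NA_real_)
    targetCt - mean(referenceCts)
}

#' Fold change from a delta-delta-Ct
#'
#' The standard exponential readout of qPCR relative quantification:
#' \eqn{2^{-\Delta\Delta Ct}}, assuming perfect doubling per cycle.
#'
#' @param ddct finite delta-delta-Ct in cycles.
#' @return relative expression ratio.
#' @examples
#' foldChangeFromDdct(c(0, -2, 1))  # 1 4 0.5
#' @export
foldChangeFromDdct <- function(ddct) {
    2^(-ddct)
}

#' Build the relative-expression matrix (2^-ddCt)
#'
#' Runs the full relative-quantification chain on aggregated Cts: per-sample
#' delta-Ct against the configured reference assays (or the sample's global
#' mean Ct over detected target assays), then per-assay delta-delta-Ct
#' against the calibrator group's mean delta-Ct (computed over calibrator
#' samples with detected values), then `2^-ddCt`. By construction the
#' geometric mean of relative expression over complete calibrator samples is
#' 1 for every assay. Undetected wells stay missing (`NA`) — they are never
#' imputed at the threshold. An assay with zero detected calibrator samples
#' is returned all-missing with a warning.
#'
#' @param aggregates output of [aggregateReplicates()].
#' @param sheet sample sheet data.frame ([readSampleSheet()]).
#' @param config \linkS4class{RunConfig}; `referenceAssays` must be
#'   non-empty unless `normalization = "global_mean"`.
#' @param normalization `"reference"` (endogenous controls; default) or
#'   `"global_mean"` (mean Ct of all detected target assays per sample,
#'   the usual fallback for array cards without a designated control).
#' @param calibrator group used as the calibrator (default `"benign"`).
#' @return a \linkS4class{MiRExperiment} (assays x samples); reference
#'   assays are not included as rows.
#' @export
buildExpressionMatrix <- function(aggregates, sheet, config = runConfig(),
                                  normalization = c("reference",
                                                    "global_mean"),
                                  calibrator = "benign") {
    normalization <- match.arg(normalization)
    stopifnot(calibrator %in% sheet$group)
    refs <- config@referenceAssays
    if (normalization == "reference" && length(refs) == 0L)
        stop("reference normalisation requested but config has no ",
             "referenceAssays")
    known <- aggregates$sample_id %in% sheet$sample_id
    if (!all(known))
        stop("sample(s) missing from sheet: ",
             paste(unique(aggregates$sample_id[!known]), collapse = ", "))
    samples <- sheet$sample_id
    targets <- setdiff(unique(aggregates$assay_id), refs)

    agg_key <- paste(aggregates$sample_id, aggregates$assay_id, sep = "\r")
    ct_of <- setNames(ifelse(aggregates$detected, aggregates$mean_ct,
                             NA_real_), agg_key)

    ref_mean <- vapply(samples, function(s) {
        if (normalization == "reference") {
            rc <- ct_of[paste(s, refs, sep = "\r")]
            if (length(rc) == 0L || anyNA(rc))
                stop("sample ", s, " has no detected reference assay; ",
                     "cannot normalise")
            mean(rc)
        } else {
            tc <- ct_of[paste(s, targets, sep = "\r")]
            tc <- tc[!is.na(tc)]
            if (length(tc) == 0L)
                stop("sample ", s, " has no detected assay; cannot normalise")
            mean(tc)
        }
    }, numeric(1))

    dct <- matrix(NA_real_, nrow = length(targets), ncol = length(samples),
                  dimnames = list(targets, samples))
    for (s in samples) {
        tc <- ct_of[paste(s, targets, sep = "\r")]
        dct[, s] <- tc - ref_mean[[s]]
    }

    cal_samples <- sheet$sample_id[sheet$group == calibrator]
    rel <- dct
    for (a in targets) {
        cal <- dct[a, cal_samples]
        cal <- cal[!is.na(cal)]
        if (length(cal) == 0L) {
            warning("assay ", a, " has no detected ", calibrator,
                    " (calibrator) sample; returned all-missing")
            rel[a, ] <- NA_real_
        } else {
            rel[a, ] <- foldChangeFromDdct(dct[a, ] - mean(cal))
        }
    }

    cd <- S4Vectors::DataFrame(sample_id = sheet$sample_id,
                               group = sheet$group,
                               cohort = sheet$cohort,
                               row.names = sheet$sample_id)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(relexpr = rel, delta_ct = dct),
        colData = cd,
        metadata = list(reference_assays = refs,
                        calibrator_group = calibrator,
                        normalization = normalization,
                        negativity_threshold = config@negativityThreshold))
    new("MiRExperiment", se)
}

#' @describeIn MiRExperiment the samples x assays relative-expression
#'   matrix is stored assays x samples; this returns it as stored.
#' @export
setMethod("relExpr", "MiRExperiment", function(x)
    SummarizedExperiment::assay(x, "relexpr"))

#' @describeIn MiRExperiment the endogenous-control assay ids used for
#'   normalisation.
#' @export
setMethod("referenceAssays", "MiRExperiment", function(x)
    S4Vectors::metadata(x)$reference_assays)

#' @describeIn MiRExperiment the calibrator group label.
#' @export
setMethod("calibratorGroup", "MiRExperiment", function(x)
    S4Vectors::metadata(x)$calibrator_group)

#' @describeIn MiRExperiment per-sample group labels, named by sample id.
#' @export
setMethod("sampleGroups", "MiRExperiment", function(x)
    setNames(as.character(SummarizedExperiment::colData(x)$group),
             colnames(x)))

setMethod("show", "MiRExperiment", function(object) {
    callNextMethod()
    cat("normalization:", S4Vectors::metadata(object)$normalization,
        "| reference:",
        paste(referenceAssays(object), collapse = ","),
        "| calibrator:", calibratorGroup(object), "\n")
    x <- relExpr(object)
    cat(sprintf("missing: %.1f%% of %d entries\n",
                100 * mean(is.na(x)), length(x)))
})
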