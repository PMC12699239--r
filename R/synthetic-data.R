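#' Create a synthetic cohort specification
#'
#' @param nBenign,nMalignant group sizes.
#' @param assays data.frame with `assay_id`, `baseline_mean_ct` (cycles
#'   above the reference level), `baseline_sd_ct`, `planted_log2fc`.
#' @param referenceAssays data.frame with `assay_id`, `mean_ct`, `sd_ct`.
#' @param nReplicates technical replicates per well.
#' @param replicateSd technical noise SD per replicate, in cycles.
#' @param negativityThreshold Ct dropout threshold.
#' @param dropout emit wells above the threshold as undetected.
#' @param cohort cohort label (`"discovery"` or `"validation"`).
#' @param rngSeed integer seed; the same seed reproduces the cohort
#'   bit-identically.
#' @return a \linkS4class{SyntheticCohortSpec}.
#' @export
syntheticCohortSpec <- function(nBenign, nMalignant, assays,
                                referenceAssays,
                                nReplicates = 3L, replicateSd = 0.15,
                                negativityThreshold = 35, dropout = TRUE,
                                cohort = "validation", rngSeed = 1L) {
    new("SyntheticCohortSpec",
        nBenign = as.integer(nBenign), nMalignant = as.integer(nMalignant),
        assays = as.data.frame(assays),
        referenceAssays = as.data.frame(referenceAssays),
        nReplicates = as.integer(nReplicates),
        replicateSd = as.numeric(replicateSd),
        negativityThreshold = as.numeric(negativityThreshold),
        dropout = isTRUE(dropout),
        cohort = as.character(cohort),
        rngSeed = as.integer(rngSeed))
}

#' Simulate a raw qPCR Ct cohort with planted effects
#'
#' Draws a cohort with the statistical structure the analysis assumes,
#' entirely on the Ct (log2 expression) scale. Per sample, each reference
#' assay has a true level `Normal(mean_ct, sd_ct)`; the sample's
#' normalising level is their mean. Per target assay, the biological
#' delta-Ct is `Normal(baseline_mean_ct - group * planted_log2fc,
#' baseline_sd_ct)` (malignant group indicator; an upregulated marker has
#' a *lower* delta-Ct), and a raw well reads
#' `reference level + delta-Ct + Normal(0, replicateSd)`. When dropout is
#' enabled, wells above the negativity threshold are emitted as
#' undetected — deterministic truncation matching the Ct > threshold rule.
#' The caller's RNG state is preserved.
#'
#' @param spec a \linkS4class{SyntheticCohortSpec}.
#' @return list with `ct` (long Ct table, undetected = `NA`), `samples`
#'   (sample sheet) and `truth` (per-assay `planted_log2fc` and planted
#'   `direction`: `up`/`down`/`null`).
#' @export
simulateCohort <- function(spec) {
    validObject(spec)
    if (exists(".Random.seed", envir = globalenv())) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(spec@rngSeed)

    tag <- toupper(substr(spec@cohort, 1L, 1L))
    ids <- c(sprintf("%s_B%02d", tag, seq_len(spec@nBenign)),
             sprintf("%s_M%02d", tag, seq_len(spec@nMalignant)))
    grp <- c(rep("benign", spec@nBenign),
             rep("malignant", spec@nMalignant))
    nS <- length(ids)
    mal <- as.numeric(grp == "malignant")

    refs <- spec@referenceAssays
    nR <- nrow(refs)
    ref_level <- matrix(rnorm(nR * nS, mean = rep(refs$mean_ct, nS),
                              sd = rep(refs$sd_ct, nS)),
                        nrow = nR, ncol = nS,
                        dimnames = list(refs$assay_id, ids))
    norm_level <- colMeans(ref_level)

    aa <- spec@assays
    nA <- nrow(aa)
    mu <- outer(aa$baseline_mean_ct, rep(1, nS)) -
        outer(aa$planted_log2fc, mal)
    dct_true <- matrix(rnorm(nA * nS, mean = as.vector(mu),
                             sd = rep(aa$baseline_sd_ct, nS)),
                       nrow = nA, ncol = nS,
                       dimnames = list(aa$assay_id, ids))

    nrep <- spec@nReplicates
    well <- function(true_ct) {
        # true_ct: assays x samples; returns long data.frame of replicates
        n <- length(true_ct)
        noise <- matrix(rnorm(n * nrep, 0, spec@replicateSd), nrow = n)
        ct <- as.vector(true_ct) + noise          # n x nrep
        data.frame(
            sample_id = rep(rep(colnames(true_ct),
                                each = nrow(true_ct)), nrep),
            assay_id = rep(rownames(true_ct), ncol(true_ct) * nrep),
            replicate = rep(seq_len(nrep), each = n),
            ct = round(as.vector(ct), 3L),
            stringsAsFactors = FALSE)
    }
    target_ct <- sweep(dct_true, 2L, norm_level, `+`)
    ct_long <- rbind(well(target_ct), well(ref_level))
    if (spec@dropout)
        ct_long$ct[ct_long$ct > spec@negativityThreshold] <- NA_real_
    ct_long <- ct_long[order(ct_long$sample_id, ct_long$assay_id,
                             ct_long$replicate), ]
    rownames(ct_long) <- NULL

    samples <- data.frame(sample_id = ids, group = grp,
                          cohort = spec@cohort, stringsAsFactors = FALSE)
    truth <- data.frame(
        assay_id = aa$assay_id,
        planted_log2fc = aa$planted_log2fc,
        direction = ifelse(aa$planted_log2fc > 0, "up",
                           ifelse(aa$planted_log2fc < 0, "down", "null")),
        stringsAsFactors = FALSE)
    list(ct = ct_long, samples = samples, truth = truth)
}

#' Two-cohort preset mirroring a TLDA discovery / qPCR validation design
#'
#' Returns the study-shaped pair of cohort specifications the package's
#' examples and tests run on: a discovery cohort of 5 benign + 6 malignant
#' samples measured single-well on a 768-assay low-density card (50
#' planted effects: 27 up- and 23 downregulated, log2 fold changes of
#' magnitude 1.2-3), and a validation cohort of 18 benign + 17 malignant
#' samples measured in triplicate on the 6 candidate assays (planted log2
#' fold change +2 for the upregulated and -2 for the downregulated
#' candidates) plus one RNU48-like endogenous reference. Baseline levels
#' spread target wells over roughly Ct 26-34 so that, with the reference
#' near Ct 22, the highest-Ct assays drop out above the threshold of 35.
#' Biological SD is 1.5 cycles in discovery and 0.8 in validation;
#' technical replicate SD is 0.15 cycles.
#'
#' @param rngSeed integer seed applied to both cohorts.
#' @return list with \linkS4class{SyntheticCohortSpec} elements
#'   `discovery` and `validation`.
#' @export
presetPaperShape <- function(rngSeed = 1L) {
    up_ids <- c("miR-181c-5p", "miR-182b-5p", "miR-196b-5p")
    down_ids <- c("miR-145-5p", "miR-199a-3p", "miR-214-3p")
    candidates <- data.frame(
        assay_id = c(up_ids, down_ids),
        baseline_mean_ct = c(6, 7, 5, 6, 8, 7),
        baseline_sd_ct = 0.8,
        planted_log2fc = c(2, 2, 2, -2, -2, -2),
        stringsAsFactors = FALSE)
    reference <- data.frame(assay_id = "RNU48", mean_ct = 22,
                            sd_ct = 0.25, stringsAsFactors = FALSE)

    extra_up <- data.frame(
        assay_id = sprintf("miR-up-%02d", seq_len(24)),
        baseline_mean_ct = seq(4, 9, length.out = 24),
        baseline_sd_ct = 1.5,
        planted_log2fc = seq(1.2, 3, length.out = 24),
        stringsAsFactors = FALSE)
    extra_down <- data.frame(
        assay_id = sprintf("miR-down-%02d", seq_len(20)),
        baseline_mean_ct = seq(4, 9, length.out = 20),
        baseline_sd_ct = 1.5,
        planted_log2fc = -seq(1.2, 3, length.out = 20),
        stringsAsFactors = FALSE)
    n_null <- 768L - nrow(candidates) - nrow(extra_up) - nrow(extra_down)
    nulls <- data.frame(
        assay_id = sprintf("miR-null-%03d", seq_len(n_null)),
        baseline_mean_ct = rep_len(seq(4, 12, by = 0.5), n_null),
        baseline_sd_ct = 1.5,
        planted_log2fc = 0,
        stringsAsFactors = FALSE)
    disc_assays <- rbind(
        transform(candidates, baseline_sd_ct = 1.5),
        extra_up, extra_down, nulls)

    list(
        discovery = syntheticCohortSpec(
            nBenign = 5L, nMalignant = 6L,
            assays = disc_assays, referenceAssays = reference,
            nReplicates = 1L, replicateSd = 0.15,
            negativityThreshold = 35, dropout = TRUE,
            cohort = "discovery", rngSeed = rngSeed),
        validation = syntheticCohortSpec(
            nBenign = 18L, nMalignant = 17L,
            assays = candidates, referenceAssays = reference,
            nReplicates = 3L, replicateSd = 0.15,
            negativityThreshold = 35, dropout = TRUE,
            cohort = "validation", rngSeed = rngSeed))
}
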