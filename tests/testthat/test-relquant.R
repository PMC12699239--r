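test_that("detection calling reads 'over threshold' strictly", {
    expect_equal(callDetection(c(36, 35, 34.9, NA), 35),
                 c(FALSE, TRUE, TRUE, FALSE))
    expect_error(callDetection(30, threshold = 0))
})

test_that("replicate aggregation computes detected-only mean/SD and QC flag", {
    rec <- data.frame(
        sample_id = rep("S1", 8),
        assay_id = rep(c("a", "b", "c", "d"), each = 2),
        replicate = rep(1:2, 4),
        ct = c(25, 25,          # a: exact triplicate-style agreement
               24.8, 25.2,      # b: sd 0.283
               NA, NA,          # c: fully undetected
               24, 25.5))       # d: scatter > 0.5 cycles
    agg <- aggregateReplicates(rec, threshold = 35)
    agg <- agg[order(agg$assay_id), ]
    expect_equal(agg$mean_ct[1:2], c(25, 25))
    expect_equal(agg$sd_ct[2], sd(c(24.8, 25.2)))
    expect_false(agg$qc_flag[2])
    expect_false(agg$detected[3])
    expect_true(is.na(agg$mean_ct[3]))
    expect_true(agg$qc_flag[4])
    # partial detection: mean over detected replicates only
    one <- aggregateReplicates(data.frame(
        sample_id = "S1", assay_id = "e", replicate = 1:3,
        ct = c(34, 36, NA)), threshold = 35)
    expect_equal(one$mean_ct, 34)
    expect_equal(one$n_detected, 1L)
    expect_equal(one$sd_ct, 0)
})

test_that("delta-Ct subtracts the mean reference level", {
    expect_equal(deltaCt(25, 20), 5)
    expect_equal(deltaCt(25, c(20, 22)), 4)
    expect_error(deltaCt(25, c(20, NA)), "reference")
})

test_that("2^-ddCt readout matches its closed form", {
    expect_equal(foldChangeFromDdct(c(0, -2, 1)), c(1, 4, 0.5))
})

test_that("expression matrix normalises to the benign calibrator", {
    # hand-built: 2 benign, 1 malignant; target dCts benign {7,7}, mal 5
    ct <- data.frame(
        sample_id = rep(c("B1", "B2", "M1"), each = 2),
        assay_id = rep(c("miR-x", "RNU48"), 3),
        replicate = 1L,
        ct = c(27, 20, 27, 20, 25, 20))
    sheet <- data.frame(sample_id = c("B1", "B2", "M1"),
                        group = c("benign", "benign", "malignant"),
                        cohort = "validation")
    cfg <- runConfig(referenceAssays = "RNU48")
    x <- buildExpressionMatrix(aggregateReplicates(ct), sheet, cfg)
    expect_s4_class(x, "MiRExperiment")
    expect_equal(unname(relExpr(x)["miR-x", ]), c(1, 1, 4))
    expect_equal(referenceAssays(x), "RNU48")
    expect_equal(calibratorGroup(x), "benign")
})

test_that("calibrator geometric mean is 1 for complete assays", {
    sim <- simulateCohort(presetPaperShape(11)$validation)
    cfg <- runConfig(referenceAssays = "RNU48")
    x <- buildExpressionMatrix(aggregateReplicates(sim$ct), sim$samples,
                               cfg)
    rel <- relExpr(x)
    benign <- sampleGroups(x) == "benign"
    for (a in rownames(rel)) {
        v <- rel[a, benign]
        if (!anyNA(v))
            expect_equal(exp(mean(log(v))), 1, tolerance = 1e-10)
    }
    expect_true(all(rel[!is.na(rel)] > 0))
})

test_that("adding a constant to every Ct of a sample leaves expression unchanged", {
    sim <- simulateCohort(presetPaperShape(5)$validation)
    cfg <- runConfig(referenceAssays = "RNU48")
    x1 <- buildExpressionMatrix(aggregateReplicates(sim$ct), sim$samples,
                                cfg)
    shifted <- sim$ct
    pick <- shifted$sample_id == "V_B03"
    shifted$ct[pick] <- shifted$ct[pick] + 1   # more input RNA, all wells
    x2 <- suppressWarnings(buildExpressionMatrix(
        aggregateReplicates(shifted), sim$samples, cfg))
    keep <- !is.na(relExpr(x1)) & !is.na(relExpr(x2))
    expect_equal(relExpr(x1)[keep], relExpr(x2)[keep])
})

test_that("lower target Ct means strictly higher relative expression", {
    base <- data.frame(
        sample_id = rep(c("B1", "M1"), each = 2),
        assay_id = rep(c("miR-x", "RNU48"), 2),
        replicate = 1L,
        ct = c(27, 20, 26, 20))
    sheet <- data.frame(sample_id = c("B1", "M1"),
                        group = c("benign", "malignant"),
                        cohort = "validation")
    cfg <- runConfig(referenceAssays = "RNU48")
    vals <- vapply(c(26, 25.5, 25), function(tc) {
        b <- base; b$ct[3] <- tc
        x <- buildExpressionMatrix(aggregateReplicates(b), sheet, cfg)
        relExpr(x)["miR-x", "M1"]
    }, numeric(1))
    expect_true(all(diff(vals) > 0))
})

test_that("degenerate normalisation inputs error or warn as promised", {
    ct <- data.frame(sample_id = c("B1", "B1", "M1"),
                     assay_id = c("miR-x", "RNU48", "miR-x"),
                     replicate = 1L, ct = c(27, 20, 25))
    sheet <- data.frame(sample_id = c("B1", "M1"),
                        group = c("benign", "malignant"),
                        cohort = "validation")
    cfg <- runConfig(referenceAssays = "RNU48")
    # M1 has no reference well at all
    expect_error(buildExpressionMatrix(aggregateReplicates(ct), sheet, cfg),
                 "reference")
    # assay undetected in every calibrator sample -> all-missing + warning
    ct2 <- data.frame(sample_id = c("B1", "B1", "M1", "M1"),
                      assay_id = rep(c("miR-x", "RNU48"), 2),
                      replicate = 1L, ct = c(NA, 20, 25, 20))
    expect_warning(
        x <- buildExpressionMatrix(aggregateReplicates(ct2), sheet, cfg),
        "calibrator")
    expect_true(all(is.na(relExpr(x)["miR-x", ])))
})

test_that("global-mean normalisation is available for card data", {
    sim <- simulateCohort(presetPaperShape(6)$validation)
    x <- buildExpressionMatrix(aggregateReplicates(sim$ct), sim$samples,
                               runConfig(referenceAssays = "RNU48"),
                               normalization = "global_mean")
    rel <- relExpr(x)
    benign <- sampleGroups(x) == "benign"
    a <- rownames(rel)[1L]
    if (!anyNA(rel[a, benign]))
        expect_equal(exp(mean(log(rel[a, benign]))), 1, tolerance = 1e-10)
})
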