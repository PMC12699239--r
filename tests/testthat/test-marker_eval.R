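test_that("ROC curve reproduces hand-counted operating points and AUC", {
    scores <- c(3, 5, 1, 2, 4)
    labels <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
    rc <- rocCurve(scores, labels, "up")
    expect_equal(auc(rc), 5 / 6)          # 5 of 6 pairs concordant
    expect_equal(rc@fpr[1], 0); expect_equal(rc@tpr[1], 0)
    expect_equal(tail(rc@fpr, 1), 1); expect_equal(tail(rc@tpr, 1), 1)

    sep <- rocCurve(c(10, 9, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
    expect_equal(auc(sep), 1)

    flat <- rocCurve(rep(2, 6), rep(c(TRUE, FALSE), 3))
    expect_equal(auc(flat), 0.5)

    expect_error(rocCurve(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("AUC equals U/(n1 n2) on tie-free data (1000 random instances)", {
    set.seed(2024)
    for (i in 1:1000) {
        n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
        scores <- sample(seq_len(50), n1 + n2)   # distinct, tie-free
        labels <- c(rep(TRUE, n1), rep(FALSE, n2))
        u <- mannWhitneyU(scores[labels], scores[!labels])$u
        expect_equal(auc(rocCurve(scores, labels, "up")), u / (n1 * n2))
    }
})

test_that("ROC agrees with pROC on random instances with ties", {
    skip_if_not_installed("pROC")
    set.seed(99)
    for (i in 1:25) {
        n <- sample(8:20, 1)
        scores <- sample(1:6, n, replace = TRUE)
        labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
        if (!any(labels) || all(labels)) next
        ours <- auc(rocCurve(scores, labels, "up"))
        ref <- as.numeric(pROC::auc(pROC::roc(
            labels, scores, direction = "<", quiet = TRUE)))
        expect_equal(ours, ref)
    }
})

test_that("Youden cutoff lands on the documented midpoint with tie rules", {
    # malignant {5,6,7}, benign {1,2,6}: J = 2/3 at the 2|5 midpoint 3.5
    rc <- rocCurve(c(5, 6, 7, 1, 2, 6),
                   c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE), "up")
    yc <- youdenCutoff(rc)
    expect_equal(yc$cutoff, 3.5)
    expect_equal(yc$j, 2 / 3)

    sep <- youdenCutoff(rocCurve(c(9, 8, 1, 2),
                                 c(TRUE, TRUE, FALSE, FALSE), "up"))
    expect_equal(sep$j, 1)
    expect_equal(sep$cutoff, 5)   # midpoint of the separating gap

    flat <- youdenCutoff(rocCurve(rep(1, 4), c(TRUE, FALSE, TRUE, FALSE),
                                  "up"))
    expect_equal(flat$j, 0)
})

test_that("Youden cutoff matches brute force on 1000 random instances", {
    set.seed(31)
    for (i in 1:1000) {
        n <- sample(6:14, 1)
        scores <- sample(1:8, n, replace = TRUE)  # ties likely
        labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
        if (!any(labels) || all(labels) || length(unique(scores)) < 2) next
        dirn <- sample(c("up", "down"), 1)
        got <- youdenCutoff(rocCurve(scores, labels, dirn))
        want <- bruteYouden(scores, labels, dirn)
        expect_equal(got$j, want$j)
        expect_equal(got$cutoff, want$cutoff)
    }
})

test_that("confusion metrics reproduce the documented validation rows", {
    # 17 malignant / 18 benign cohort; counts recovered from printed
    # sensitivity/specificity
    m196 <- confusionMetrics(tp = 14, fp = 3, fn = 3, tn = 15)
    expect_equal(round(100 * m196$ppv, 1), 82.4)
    expect_equal(round(100 * m196$npv, 1), 83.3)
    expect_equal(round(100 * m196$accuracy, 1), 82.9)
    expect_equal(m196$youden_j, 14 / 17 + 15 / 18 - 1)

    m181 <- confusionMetrics(tp = 12, fp = 7, fn = 5, tn = 11)
    expect_equal(round(100 * m181$ppv, 1), 63.2)
    expect_equal(round(100 * m181$npv, 1), 68.8)
    expect_equal(round(100 * m181$accuracy, 1), 65.7)

    none <- confusionMetrics(tp = 0, fp = 0, fn = 5, tn = 5)
    expect_true(is.na(none$ppv))
    expect_error(confusionMetrics(-1, 1, 1, 1), "non-negative")
    expect_error(confusionMetrics(0, 0, 0, 5), "classes")
})

test_that("direction handling: negated scores with flipped direction are identical", {
    set.seed(8)
    for (i in 1:20) {
        scores <- rnorm(15)
        labels <- sample(c(TRUE, FALSE), 15, replace = TRUE)
        if (!any(labels) || all(labels)) next
        up <- evaluateMarker(scores, labels, "up")
        dn <- evaluateMarker(-scores, labels, "down")
        expect_equal(up$auc, dn$auc)
        expect_equal(up$youden_j, dn$youden_j)
        expect_equal(up[c("tp", "fp", "fn", "tn")],
                     dn[c("tp", "fp", "fn", "tn")])
        expect_equal(up$cutoff, -dn$cutoff)
    }
})

test_that("marker evaluation classifies at its own cutoff consistently", {
    set.seed(5)
    scores <- c(rnorm(10, 2), rnorm(10, 0))
    labels <- rep(c(TRUE, FALSE), each = 10)
    perf <- evaluateMarker(scores, labels, "up", "m")
    expect_equal(perf$sensitivity, perf$tp / (perf$tp + perf$fn))
    expect_equal(perf$specificity, perf$tn / (perf$tn + perf$fp))
    expect_equal(perf$youden_j,
                 perf$sensitivity + perf$specificity - 1)
    # missing scores are dropped with their labels
    with_na <- evaluateMarker(c(scores, NA), c(labels, TRUE), "up", "m")
    expect_equal(with_na$auc, perf$auc)
})

test_that("logistic fit recovers the closed-form 2x2 odds ratio", {
    # binary covariate, table a=14 b=3 c=3 d=15 -> OR = (14*15)/(3*3)
    x <- c(rep(1, 14 + 3), rep(0, 3 + 15))
    y <- c(rep(TRUE, 14), rep(FALSE, 3), rep(TRUE, 3), rep(FALSE, 15))
    fit <- fitLogisticUnivariate(x, y)
    expect_equal(unname(oddsRatio(fit)["or"]), 14 * 15 / 9,
                 tolerance = 1e-4)
    expect_true(fit@converged)
    expect_false(fit@separation)
    expect_true(fit@ciLow < 14 * 15 / 9 && 14 * 15 / 9 < fit@ciHigh)

    # balanced independence -> OR 1, slope 0
    x0 <- rep(c(0, 1), each = 10)
    y0 <- rep(c(TRUE, FALSE, TRUE, FALSE), each = 5)
    fit0 <- fitLogisticUnivariate(x0, y0)
    expect_equal(fit0@slope, 0, tolerance = 1e-8)
    expect_equal(fit0@orPerUnit, 1, tolerance = 1e-8)

    sep <- fitLogisticUnivariate(c(1, 2, 3, 10, 11, 12),
                                 c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
    expect_true(sep@separation)
    expect_false(sep@converged)
})

test_that("logistic MLE agrees with dense grid-search likelihood maximisation", {
    set.seed(17)
    done <- 0
    while (done < 50) {
        n <- 12
        y <- sample(c(TRUE, FALSE), n, replace = TRUE)
        if (!any(y) || all(y)) next
        x <- round(rnorm(n) + 0.8 * y, 2)
        if (max(x[!y]) < min(x[y]) || max(x[y]) < min(x[!y])) next
        fit <- fitLogisticUnivariate(x, y)
        if (!fit@converged || abs(fit@slope) > 6 ||
            abs(fit@intercept) > 6) next
        grid <- gridLogistic(x, as.numeric(y))
        expect_lt(abs(fit@intercept - grid[1]), 0.05)
        expect_lt(abs(fit@slope - grid[2]), 0.05)
        done <- done + 1
    }
})
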