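test_that("FFPC keeps the leading scores in component order", {
    s <- c(5, -2, 1, 0.1, 0.05)
    expect_equal(as.numeric(ffpcFeatures(s, 3)), c(5, -2, 1))
    expect_equal(as.numeric(ffpcFeatures(s, 5)), s)   # n = l: identity
    expect_error(ffpcFeatures(s, 0), "nComponents")
    expect_error(ffpcFeatures(s, 6), "nComponents")
})

test_that("energy measure sums squared scores up to the truncation", {
    s <- c(3, 4, 0, 0, 0, 0)
    expect_equal(energyMeasure(s, 2), 25)
    expect_equal(energyMeasure(s, 6), 25)
    # default truncation is floor(l / 2)
    expect_equal(energyMeasure(s), energyMeasure(s, 3))
    # monotone non-decreasing in the truncation
    set.seed(1)
    r <- rnorm(10)
    en <- vapply(1:10, function(t) energyMeasure(r, t), numeric(1))
    expect_true(all(diff(en) >= 0))
    expect_error(energyMeasure(s, 7), "truncation")
})

test_that("full-truncation energy equals the squared centered norm (Parseval)", {
    set.seed(5)
    X <- matrix(rnorm(50 * 16), 50, 16)
    fit <- fitWindowPCA(windowMatrixFromMatrix(X))
    for (rep in 1:25) {
        w <- rnorm(16) * sample(1:5, 1)
        s <- projectWindow(fit, w)
        expect_equal(energyMeasure(s, 16), sum((w - trainingMean(fit))^2),
                     tolerance = 1e-8)
    }
    # energy is invariant to the eigenvector sign convention
    sFlip <- s * sample(c(-1, 1), 16, replace = TRUE)
    expect_equal(energyMeasure(sFlip, 16), energyMeasure(s, 16))
})

test_that("PCPEM is FFPC of size nPcs concatenated with the energy scalar", {
    s <- c(1, 2, 2, 0, 0, 0)
    expect_equal(as.numeric(pcpemFeatures(s, nPcs = 2, truncation = 3)),
                 c(1, 2, 9))
    set.seed(9)
    S <- matrix(rnorm(12 * 8), 12, 8)
    pc <- pcpemFeatures(S, nPcs = 2, truncation = 4)
    expect_identical(dim(pc), c(12L, 3L))
    expect_equal(pc[, 1:2], ffpcFeatures(S, 2))
    expect_equal(pc[, 3], energyMeasure(S, 4))
})

test_that("zero-score window yields zero feature vectors in both schemes", {
    z <- rep(0, 8)
    expect_equal(as.numeric(ffpcFeatures(z, 3)), c(0, 0, 0))
    expect_equal(as.numeric(pcpemFeatures(z)), c(0, 0, 0))
})

test_that("truncated FFPC reconstruction is the rank-limited approximation, lossless at full rank", {
    set.seed(13)
    X <- matrix(rnorm(30 * 6), 30, 6)
    fit <- fitWindowPCA(windowMatrixFromMatrix(X))
    w <- rnorm(6)
    s <- projectWindow(fit, w)
    full <- as.numeric(ffpcFeatures(s, 6))
    expect_equal(reconstructWindow(fit, full), w, tolerance = 1e-8)
    # truncation error shrinks as components are added
    errs <- vapply(1:6, function(n)
        sum((reconstructWindow(fit, as.numeric(ffpcFeatures(s, n))) - w)^2),
        numeric(1))
    expect_true(all(diff(errs) <= 1e-10))
    expect_lt(errs[6], 1e-16)
})

test_that("ictal-like 5x-amplitude class carries >= 10x the mean energy coordinate", {
    base <- classSpec("base", 10, 2, amplitudeScale = 1, noiseSd = 0.2)
    ictal <- classSpec("ictal", 10, 2, amplitudeScale = 5, noiseSd = 0.2)
    sigs <- c(lapply(1:4, function(i)
                  generateSignal(base, 8192, 173.61, i,
                                 sourceId = sprintf("b%d", i))),
              lapply(1:4, function(i)
                  generateSignal(ictal, 8192, 173.61, 100 + i,
                                 sourceId = sprintf("i%d", i))))
    tm <- stackTrainingMatrix(sigs, 512, 1)
    fit <- fitWindowPCA(tm)
    fs <- windowFeatures(fit, tm, "PCPEM")
    en <- featureValues(fs)[, 3]
    expect_gt(mean(en[rowLabels(fs) == "ictal"]),
              10 * mean(en[rowLabels(fs) == "base"]))
})

test_that("windowFeatures records scheme, labels and window provenance", {
    sigs <- list(randomSignal(1024, label = "A", id = "a", seed = 1),
                 randomSignal(1024, label = "B", id = "b", seed = 2))
    tm <- stackTrainingMatrix(sigs, 128, 3)
    fit <- fitWindowPCA(tm)
    ff <- windowFeatures(fit, tm, "FFPC")
    pe <- windowFeatures(fit, tm, "PCPEM")
    em <- windowFeatures(fit, tm, "EM")
    expect_identical(featureScheme(ff), "FFPC")
    expect_identical(ncol(featureValues(ff)), 3L)
    expect_identical(ncol(featureValues(pe)), 3L)
    expect_identical(ncol(featureValues(em)), 1L)
    expect_identical(rowLabels(ff), rowLabels(tm))
    expect_identical(rowWindows(ff), rowWindows(tm))
})
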