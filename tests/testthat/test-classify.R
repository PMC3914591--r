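test_that("1-NN assigns the label of the closest training vector", {
    tr <- featureSetFromMatrix(rbind(c(0, 0, 0), c(10, 10, 10)),
                               c("A", "B"))
    expect_identical(predict1NN(tr, c(1, 0, 0)), "A")
    expect_identical(predict1NN(tr, c(9, 9, 9)), "B")
    # zero distance returns that vector's label
    expect_identical(predict1NN(tr, c(10, 10, 10)), "B")
    # exact ties break to the smallest training index
    tie <- featureSetFromMatrix(rbind(c(1, 0), c(-1, 0)), c("B", "A"))
    expect_identical(predict1NN(tie, c(0, 0)), "B")
})

test_that("1-NN rejects dimension mismatches and empty training sets", {
    tr <- featureSetFromMatrix(rbind(c(0, 0, 0)), "A")
    expect_error(predict1NN(tr, c(1, 2)), "dimension 2.*dimension 3")
    trNA <- featureSetFromMatrix(rbind(c(0, 0)), NA_character_)
    expect_error(predict1NN(trNA, c(0, 0)), "labeled")
})

test_that("1-NN agrees with an exhaustive all-pairs scan", {
    set.seed(77)
    for (rep in 1:20) {
        ntr <- sample(5:40, 1)
        d <- sample(1:4, 1)
        train <- matrix(rnorm(ntr * d), ntr, d)
        labels <- sample(LETTERS[1:3], ntr, replace = TRUE)
        query <- matrix(rnorm(10 * d), 10, d)
        fs <- featureSetFromMatrix(train, labels)
        expect_identical(predict1NN(fs, query),
                         unname(oracle1NN(train, labels, query)))
    }
})

test_that("stratified folds partition windows and balance labels within one window", {
    labels <- rep(c("A", "B", "C"), times = c(53, 47, 30))
    fold <- dpcaw:::makeStratifiedFolds(labels, 10, seed = 3)
    expect_identical(sort(unique(fold)), 1:10)
    expect_identical(length(fold), length(labels))
    for (lv in unique(labels)) {
        per <- table(factor(fold[labels == lv], levels = 1:10))
        expect_lte(max(per) - min(per), 1)
    }
    expect_error(dpcaw:::makeStratifiedFolds(rep(c("A", "B"), c(5, 50)),
                                             10, 1),
                 "smaller k")
})

test_that("perfectly separated clusters give accuracy 1 with zero spread", {
    set.seed(4)
    X <- rbind(matrix(rnorm(50 * 3, 0, 0.5), 50, 3),
               matrix(rnorm(50 * 3, 100, 0.5), 50, 3))
    fs <- featureSetFromMatrix(X, rep(c("A", "B"), each = 50))
    rep10 <- kfoldAccuracy(fs, k = 10, seed = 1)
    expect_equal(meanAccuracy(rep10), 1)
    expect_equal(sdAccuracy(rep10), 0)
    expect_equal(foldAccuracies(rep10), rep(1, 10))
    ct <- confusionTotals(rep10)
    expect_equal(ct$correct, c(50L, 50L))
    expect_equal(ct$incorrect, c(0L, 0L))
})

test_that("label-randomized features classify at chance level", {
    # 2 and 5 classes, 20 seeded repetitions each; the mean accuracy over
    # repetitions should sit within 3 standard errors of 1/g
    for (g in c(2L, 5L)) {
        accs <- vapply(1:20, function(r) {
            set.seed(1000 * g + r)
            X <- matrix(rnorm(500 * 3), 500, 3)
            labels <- sample(LETTERS[1:g], 500, replace = TRUE)
            meanAccuracy(kfoldAccuracy(featureSetFromMatrix(X, labels),
                                       k = 10, seed = r))
        }, numeric(1))
        se <- sd(accs) / sqrt(length(accs))
        expect_lt(abs(mean(accs) - 1 / g), 3 * se)
    }
})

test_that("cross-validation reports are deterministic given the seed", {
    set.seed(8)
    X <- matrix(rnorm(120 * 3), 120, 3)
    fs <- featureSetFromMatrix(X, rep(c("A", "B"), 60))
    r1 <- kfoldAccuracy(fs, k = 10, seed = 42)
    r2 <- kfoldAccuracy(fs, k = 10, seed = 42)
    expect_identical(foldAccuracies(r1), foldAccuracies(r2))
    expect_identical(confusionTotals(r1), confusionTotals(r2))
    expect_identical(configEcho(r1), configEcho(r2))
})

test_that("report statistics are internally consistent", {
    set.seed(9)
    X <- matrix(rnorm(100 * 2), 100, 2)
    fs <- featureSetFromMatrix(X, sample(c("A", "B"), 100, replace = TRUE))
    rp <- kfoldAccuracy(fs, k = 5, seed = 2)
    expect_equal(meanAccuracy(rp), mean(foldAccuracies(rp)))
    expect_equal(sdAccuracy(rp), sd(foldAccuracies(rp)))
    expect_true(all(foldAccuracies(rp) >= 0 & foldAccuracies(rp) <= 1))
    ct <- confusionTotals(rp)
    expect_equal(sum(ct$correct) + sum(ct$incorrect), 100L)
})

test_that("pipeline separates amplitude-contrasted classes and favors PCPEM", {
    base <- classSpec("base", 10, 2, amplitudeScale = 1, noiseSd = 0.2)
    ictal <- classSpec("ictal", 10, 2, amplitudeScale = 5, noiseSd = 0.2)
    sigs <- c(lapply(1:6, function(i)
                  generateSignal(base, 4096, 173.61, i,
                                 sourceId = sprintf("b%d", i))),
              lapply(1:6, function(i)
                  generateSignal(ictal, 4096, 173.61, 200 + i,
                                 sourceId = sprintf("i%d", i))))
    pe <- evaluatePipeline(sigs, 256, "PCPEM", k = 10, seed = 7)
    ff <- evaluatePipeline(sigs, 256, "FFPC", k = 10, seed = 7)
    expect_gte(meanAccuracy(pe), 0.95)
    expect_gte(meanAccuracy(pe), meanAccuracy(ff))
    expect_identical(configEcho(pe)$scheme, "PCPEM")
    expect_identical(configEcho(pe)$window_length, 256L)
    expect_true(configEcho(pe)$standardize)
    expect_false(configEcho(ff)$standardize)
})

test_that("pipeline refuses single-class input", {
    sigs <- lapply(1:3, function(i) randomSignal(512, label = "A", seed = i))
    expect_error(evaluatePipeline(sigs, 128, "FFPC", k = 2, seed = 1),
                 ">= 2 groups")
})

test_that("per-fold PCA refit never sees held-out windows", {
    # perturb a window assigned to fold 1 and refit the fold-1
    # training-fold model the same way the pipeline does: the model must
    # be bit-identical, because fold-1 training rows exclude fold-1 windows
    set.seed(15)
    sigs <- list(randomSignal(2048, label = "A", id = "a", seed = 1),
                 randomSignal(2048, label = "B", id = "b", seed = 2))
    embed <- function(ss) {
        parts <- lapply(ss, embedNonoverlapping, windowLength = 128)
        do.call(rbind, lapply(parts, windowData))
    }
    X <- embed(sigs)
    rl <- rep(c("A", "B"), each = 16)
    fold <- dpcaw:::makeStratifiedFolds(rl, 4, 9)
    victim <- which(fold == 1L)[1L]
    perturbed <- sigs
    src <- if (victim <= 16) 1L else 2L
    w <- if (victim <= 16) victim else victim - 16L
    x <- samples(perturbed[[src]])
    x[((w - 1) * 128 + 1):(w * 128)] <- rnorm(128, sd = 50)
    perturbed[[src]] <- Signal(x, 256, classLabel(perturbed[[src]]),
                               sourceId(perturbed[[src]]))
    X2 <- embed(perturbed)
    expect_false(identical(X[victim, ], X2[victim, ]))
    trainRows <- fold != 1L
    fit1 <- fitWindowPCA(windowMatrixFromMatrix(X[trainRows, ]))
    fit2 <- fitWindowPCA(windowMatrixFromMatrix(X2[trainRows, ]))
    expect_identical(pcEigenvalues(fit1), pcEigenvalues(fit2))
    expect_identical(pcLoadings(fit1), pcLoadings(fit2))
    expect_identical(trainingMean(fit1), trainingMean(fit2))
})
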