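test_that("eigendecomposition matches an independent SVD oracle on random matrices", {
    set.seed(101)
    for (rep in 1:40) {
        n <- sample(2:20, 1)
        l <- sample(2:8, 1)
        X <- matrix(rnorm(n * l), n, l)
        fit <- fitWindowPCA(windowMatrixFromMatrix(X))
        oracle <- pcaOracleSVD(X)
        expect_lt(max(abs(pcEigenvalues(fit) - oracle$values)), 1e-8)
        # eigenvectors compared up to sign where the eigenvalue is
        # separated from its neighbours (vectors are unstable under ties)
        vals <- oracle$values
        for (j in seq_len(l)) {
            gap <- min(abs(vals[j] - vals[-j]))
            if (gap > 1e-6)
                expect_gt(abs(sum(pcLoadings(fit)[, j] * oracle$vectors[, j])),
                          1 - 1e-8)
        }
    }
})

test_that("explicit 4x3 training matrix matches a long-form covariance eigendecomposition", {
    X <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1))
    # long-form oracle: covariance entries accumulated by explicit loops
    mu <- colMeans(X)
    C <- matrix(0, 3, 3)
    for (a in 1:3) for (b in 1:3)
        C[a, b] <- sum((X[, a] - mu[a]) * (X[, b] - mu[b])) / (nrow(X) - 1)
    oracleVals <- eigen(C, symmetric = TRUE)$values
    fit <- fitWindowPCA(windowMatrixFromMatrix(X))
    expect_lt(max(abs(pcEigenvalues(fit) - oracleVals)), 1e-8)
    expect_lt(abs(sum(pcEigenvalues(fit)) -
                  sum(apply(X, 2, var))), 1e-8)
})

test_that("loadings are orthonormal and eigenvalues sorted nonnegative", {
    set.seed(7)
    X <- matrix(rnorm(30 * 12), 30, 12)
    fit <- fitWindowPCA(windowMatrixFromMatrix(X))
    V <- pcLoadings(fit)
    expect_lt(max(abs(crossprod(V) - diag(12))), 1e-8)
    expect_true(all(diff(pcEigenvalues(fit)) <= 1e-10))
    expect_true(all(pcEigenvalues(fit) >= 0))
    # sign convention: largest-magnitude entry of every column positive
    for (j in 1:12)
        expect_gt(V[which.max(abs(V[, j])), j], 0)
})

test_that("identical training rows give zero eigenvalues and zero scores", {
    X <- matrix(rep(c(3, -1, 2, 7), each = 5), nrow = 5)
    fit <- fitWindowPCA(windowMatrixFromMatrix(X))
    expect_equal(pcEigenvalues(fit), rep(0, 4))
    expect_equal(projectWindow(fit, X[1, ]), rep(0, 4))
    expect_equal(explainedVarianceRatio(fit, 1), 1)  # degenerate convention
})

test_that("leading eigenvector recovers the factor direction of a 1-factor model", {
    set.seed(11)
    l <- 8
    u <- rnorm(l); u <- u / sqrt(sum(u^2))
    f <- rnorm(10000)
    X <- outer(f, u) + matrix(rnorm(10000 * l, sd = 0.1), 10000, l)
    fit <- fitWindowPCA(windowMatrixFromMatrix(X))
    expect_gt(abs(sum(pcLoadings(fit)[, 1] * u)), 0.99)
})

test_that("projection centers, preserves norm, and inverts exactly at full rank", {
    set.seed(21)
    X <- matrix(rnorm(40 * 10), 40, 10)
    fit <- fitWindowPCA(windowMatrixFromMatrix(X))

    # mean window projects to the origin
    expect_equal(projectWindow(fit, trainingMean(fit)), rep(0, 10))

    # mean + c V_1 projects to (c, 0, ..., 0)
    w <- trainingMean(fit) + 2.5 * pcLoadings(fit)[, 1]
    expect_equal(projectWindow(fit, w), c(2.5, rep(0, 9)), tolerance = 1e-10)

    for (rep in 1:20) {
        w <- rnorm(10)
        s <- projectWindow(fit, w)
        centered <- w - trainingMean(fit)
        # Parseval: scores preserve the centered norm
        expect_equal(sum(s^2), sum(centered^2), tolerance = 1e-8)
        # full-rank reconstruction is exact
        expect_equal(reconstructWindow(fit, s), w, tolerance = 1e-8)
    }

    # matrix projection agrees with the per-window path
    S <- projectWindows(fit, X[1:5, ])
    for (i in 1:5)
        expect_equal(S[i, ], projectWindow(fit, X[i, ]), tolerance = 1e-12)
})

test_that("explained variance ratio is correct, monotone and validated", {
    set.seed(31)
    X <- matrix(rnorm(25 * 6), 25, 6)
    fit <- fitWindowPCA(windowMatrixFromMatrix(X))
    ev <- pcEigenvalues(fit)
    expect_equal(explainedVarianceRatio(fit, 1), ev[1] / sum(ev))
    expect_equal(explainedVarianceRatio(fit, 6), 1)
    ratios <- vapply(1:6, explainedVarianceRatio, numeric(1), model = fit)
    expect_true(all(diff(ratios) >= -1e-12))
    expect_error(explainedVarianceRatio(fit, 0), "nComponents")
    expect_error(explainedVarianceRatio(fit, 7), "nComponents")
})

test_that("degenerate and invalid PCA inputs are rejected informatively", {
    one <- windowMatrixFromMatrix(matrix(1:4, 1, 4))
    expect_error(fitWindowPCA(one), "at least 2")
    X <- matrix(rnorm(12), 3, 4)
    X[2, 3] <- NaN
    wm <- new("WindowMatrix", windowData = X, windowLength = 4L,
              rowLabels = rep("A", 3), rowSources = c("f1", "f2", "f3"),
              rowWindows = 1:3, embeddingMode = "nonoverlapping")
    expect_error(fitWindowPCA(wm), "non-finite.*f2#2")
    fit <- fitWindowPCA(windowMatrixFromMatrix(matrix(rnorm(12), 3, 4)))
    expect_error(projectWindow(fit, rnorm(3)), "length 3.*length 4")
})
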