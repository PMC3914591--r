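# Shared fixtures, built in code.

rampSignal <- function(n, rate = 173.61, label = "A", id = "ramp") {
    Signal(seq_len(n), rate, classLabel = label, sourceId = id)
}

randomSignal <- function(n, rate = 256, label = "A", id = "rand", seed = 1) {
    set.seed(seed)
    Signal(rnorm(n), rate, classLabel = label, sourceId = id)
}

# Small labeled WindowMatrix straight from a numeric matrix.
windowMatrixFromMatrix <- function(X, labels = rep("A", nrow(X)),
                                   sources = rep("src", nrow(X))) {
    new("WindowMatrix", windowData = X, windowLength = ncol(X),
        rowLabels = labels, rowSources = sources,
        rowWindows = seq_len(nrow(X)),
        embeddingMode = "nonoverlapping")
}

featureSetFromMatrix <- function(X, labels, scheme = "FFPC",
                                 sources = sprintf("s%d", seq_len(nrow(X)))) {
    new("FeatureSet", featureValues = X, featureScheme = scheme,
        rowLabels = labels, rowSources = sources,
        rowWindows = rep(1L, nrow(X)))
}

# Independent PCA oracle: SVD of the centered data matrix (a different
# numerical route from the covariance eigendecomposition under test).
pcaOracleSVD <- function(X) {
    Xc <- scale(X, center = TRUE, scale = FALSE)
    sv <- svd(Xc, nu = 0, nv = ncol(X))
    vals <- rep(0, ncol(X))
    vals[seq_along(sv$d)] <- sv$d^2 / (nrow(X) - 1)
    list(values = vals, vectors = sv$v)
}

# Independent 1-NN oracle: explicit all-pairs scan with loops.
oracle1NN <- function(train, labels, query) {
    apply(query, 1L, function(q) {
        d <- apply(train, 1L, function(t) sqrt(sum((t - q)^2)))
        labels[which.min(d)]
    })
}
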