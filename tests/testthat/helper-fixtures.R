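# Shared fixtures: tiny simulated datasets and hand-built models.

tiny_config <- function(...) {
    defaults <- list(n_cells = 90L, n_genes = 40L, n_types = 3L,
                     n_key_genes = 6L, targets_per_regulator = 2L,
                     seed = 42L)
    do.call(simConfig, utils::modifyList(defaults, list(...)))
}

# A linear softmax model: no hidden layers, logits = X %*% W + b.
linear_model <- function(W, b = NULL, classes = NULL, genes = NULL) {
    d <- nrow(W); K <- ncol(W)
    if (is.null(b)) b <- numeric(K)
    if (is.null(classes)) classes <- paste0("c", seq_len(K))
    if (is.null(genes)) genes <- paste0("g", seq_len(d))
    methods::new("MLPClassifier", weights = list(W), biases = list(b),
                 hidden = integer(0), classes = classes,
                 featureNames = genes, history = numeric(0))
}

# A random small MLP with ReLU hidden layers, for numerical checks.
random_mlp <- function(d = 6L, hidden = c(5L, 4L), K = 3L, seed = 7L) {
    widths <- c(d, hidden, K)
    withr::with_seed(seed, {
        W <- lapply(seq_len(length(widths) - 1L), function(l)
            matrix(rnorm(widths[l] * widths[l + 1L], sd = 0.8),
                   widths[l], widths[l + 1L]))
        b <- lapply(seq_len(length(widths) - 1L), function(l)
            rnorm(widths[l + 1L], sd = 0.2))
        methods::new("MLPClassifier", weights = W, biases = b,
                     hidden = as.integer(hidden),
                     classes = paste0("c", seq_len(K)),
                     featureNames = paste0("g", seq_len(d)),
                     history = numeric(0))
    })
}

# Two well-separated Gaussian blobs, linearly separable.
blob_data <- function(n_per = 40L, d = 5L, sep = 4, seed = 3L) {
    withr::with_seed(seed, {
        X <- rbind(matrix(rnorm(n_per * d, -sep / 2), n_per),
                   matrix(rnorm(n_per * d, sep / 2), n_per))
        colnames(X) <- paste0("g", seq_len(d))
        rownames(X) <- paste0("cell", seq_len(2L * n_per))
        list(X = X, y = rep(c("a", "b"), each = n_per))
    })
}

# Preprocessed tiny dataset ready for the model layer.
tiny_dataset <- function(config = tiny_config(), split_seed = 2L) {
    sce <- simulateDataset(config)
    sp <- splitTrainTest(sce, 0.8, seed = split_seed)
    ntr <- normalizeLogScale(sp$train)
    nte <- normalizeLogScale(sp$test, fit = ntr$fit)
    list(
        Xtr = t(as.matrix(SummarizedExperiment::assay(ntr$data, "scaled"))),
        ytr = as.character(SummarizedExperiment::colData(sp$train)$cell_type),
        Xte = t(as.matrix(SummarizedExperiment::assay(nte$data, "scaled"))),
        yte = as.character(SummarizedExperiment::colData(sp$test)$cell_type),
        truth = keyGeneTruth(sce), sce = sce)
}

# Brute-force Shapley values by direct enumeration of all subsets.
exact_shapley <- function(f, x, baseline) {
    d <- length(x)
    phi <- numeric(d)
    subsets <- expand.grid(rep(list(c(0, 1)), d))
    for (i in seq_len(d)) {
        without_i <- subsets[subsets[[i]] == 0, , drop = FALSE]
        for (r in seq_len(nrow(without_i))) {
            S <- as.numeric(without_i[r, ])
            s <- sum(S)
            w <- factorial(s) * factorial(d - s - 1) / factorial(d)
            xS <- S * x + (1 - S) * baseline
            xSi <- xS; xSi[i] <- x[i]
            phi[i] <- phi[i] +
                w * (f(matrix(xSi, 1L)) - f(matrix(xS, 1L)))
        }
    }
    phi
}
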