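test_that("saliency equals the gradient contract and linear weights", {
    m <- random_mlp(d = 8L)
    withr::with_seed(1, X <- matrix(rnorm(24), 3, 8))
    colnames(X) <- paste0("g", 1:8)
    expect_identical(saliencyMap(m, X, 2), gradInputScore(m, X, 2))
    withr::with_seed(2, W <- matrix(rnorm(8), 4, 2))
    lin <- linear_model(W)
    S <- saliencyMap(lin, matrix(rnorm(12), 3, 4), 1)
    for (i in 1:3) expect_equal(unname(S[i, ]), W[, 1], tolerance = 1e-12)
    # constant model: zero weights give zero scores
    zero <- linear_model(matrix(0, 4, 2))
    expect_true(all(saliencyMap(zero, matrix(rnorm(8), 2, 4), 1) == 0))
})

test_that("activation maximization solves the linear case and ascends", {
    withr::with_seed(3, w <- rnorm(6))
    m <- linear_model(cbind(w, -w))
    r <- 2.5
    am <- activationMaximization(m, 1, constraint_radius = r, n_steps = 200,
                                 seed = 4)
    expect_equal(unname(am$x_star), r * w / sqrt(sum(w^2)), tolerance = 1e-3)
    expect_true(all(diff(am$objective) >= 0))
    expect_equal(am$importance, abs(am$x_star))
})

test_that("activation maximization matches a random-search oracle on a toy net", {
    # two hidden units, fixed weights
    W1 <- matrix(c(1, -0.5, 0.3, 0.8, -0.2, 0.6), 3, 2)
    W2 <- matrix(c(1.2, 0.7, -0.4, 0.5), 2, 2)
    m <- methods::new("MLPClassifier", weights = list(W1, W2),
                      biases = list(c(0.1, -0.1), c(0, 0)),
                      hidden = 2L, classes = c("c1", "c2"),
                      featureNames = paste0("g", 1:3), history = numeric(0))
    r <- 1.5
    am <- activationMaximization(m, 1, constraint_radius = r, n_steps = 300,
                                 step_size = 0.5, seed = 5)
    best_rand <- withr::with_seed(6, max(vapply(1:1000, function(i) {
        v <- rnorm(3); v <- v / sqrt(sum(v^2)) * r * runif(1)^(1/3)
        predictScore(m, matrix(v, 1))[1, 1]
    }, 0)))
    expect_gte(tail(am$objective, 1), best_rand - 0.05)
})

test_that("DeepLIFT is complete and exact on linear and hand-worked cases", {
    withr::with_seed(7, W <- matrix(rnorm(10), 5, 2))
    lin <- linear_model(W, b = c(0.3, -0.3))
    x <- matrix(rnorm(5), 1); b0 <- rnorm(5)
    contrib <- deepliftRescale(lin, x, b0, 1)
    expect_equal(unname(contrib[1, ]), W[, 1] * (as.numeric(x) - b0),
                 tolerance = 1e-12)
    # x = baseline: all contributions vanish
    expect_true(all(deepliftRescale(lin, matrix(b0, 1), b0, 1) == 0))
})

test_that("DeepLIFT reproduces the hand-computed rescale chain on a ReLU net", {
    # 2 inputs -> 1 ReLU unit -> 1 output; weights chosen by hand
    W1 <- matrix(c(2, -1), 2, 1); W2 <- matrix(3, 1, 1)
    m <- methods::new("MLPClassifier", weights = list(W1, W2),
                      biases = list(0.5, -1), hidden = 1L,
                      classes = c("c1"), featureNames = c("g1", "g2"),
                      history = numeric(0))
    x <- c(1, 1); ref <- c(0, 0)
    # by hand: z = 2*1 - 1*1 + 0.5 = 1.5, z_ref = 0.5; both positive so the
    # ReLU multiplier is (1.5 - 0.5)/(1.5 - 0.5) = 1; output multiplier 3.
    # contributions: (x - ref) * (W1 * 1 * 3) = c(1*6, 1*(-3))
    contrib <- deepliftRescale(m, matrix(x, 1), ref, 1)
    expect_equal(unname(contrib[1, ]), c(6, -3), tolerance = 1e-12)
    # crossing the kink: reference below zero activates the rescale slope
    x2 <- c(0, 2)     # z = -1.5 -> ReLU output 0
    ref2 <- c(1, 0)   # z_ref = 2.5 -> output 2.5
    # multiplier = (0 - 2.5)/(-1.5 - 2.5) = 0.625; chain with W2 = 3
    expected <- (x2 - ref2) * W1[, 1] * 0.625 * 3
    contrib2 <- deepliftRescale(m, matrix(x2, 1), ref2, 1)
    expect_equal(unname(contrib2[1, ]), expected, tolerance = 1e-12)
})

test_that("DeepLIFT completeness holds on random networks", {
    m <- random_mlp(d = 7L, hidden = c(6L, 4L), K = 3L, seed = 11)
    withr::with_seed(12, {
        X <- matrix(rnorm(35), 5, 7)
        b0 <- rnorm(7)
    })
    colnames(X) <- paste0("g", 1:7)
    contrib <- deepliftRescale(m, X, b0, 2)
    gap <- predictScore(m, X)[, 2] - predictScore(m, matrix(b0, 1))[1, 2]
    expect_equal(unname(rowSums(contrib)), unname(gap), tolerance = 1e-5)
})

test_that("expected gradients are exact for linear models and reduce cleanly", {
    withr::with_seed(13, {
        W <- matrix(rnorm(8), 4, 2)
        X <- matrix(rnorm(8), 2, 4)
        B <- matrix(rnorm(40), 10, 4)
    })
    m <- linear_model(W)
    eg <- expectedGradients(m, X, B, 1, n_samples = 200, seed = 14)
    # per-sample terms are exact for a linear score, so the estimate
    # converges to w * (x - mean(baseline))
    expected <- sweep(X, 2, colMeans(B)) * rep(W[, 1], each = 2)
    expect_equal(unname(eg), unname(expected), tolerance = 0.15)
    # single baseline: every sample reduces to gradient * (x - x')
    b1 <- B[1, , drop = FALSE]
    eg1 <- expectedGradients(m, X, b1, 1, n_samples = 1, seed = 15)
    expect_equal(unname(eg1), unname(sweep(X, 2, b1) *
                                         rep(W[, 1], each = 2)),
                 tolerance = 1e-12)
    expect_error(expectedGradients(m, X, B[0, ], 1), "empty")
})

test_that("expected-gradient estimates tighten with the sample count", {
    m <- random_mlp(d = 5L, hidden = 4L, K = 2L, seed = 16)
    withr::with_seed(17, {
        x <- matrix(rnorm(5), 1)
        B <- matrix(rnorm(100), 20, 5)
    })
    colnames(x) <- paste0("g", 1:5)
    est <- function(n, s) expectedGradients(m, x, B, 1, n_samples = n,
                                            seed = s)[1, 1]
    sd_small <- sd(vapply(1:10, function(s) est(5L, s), 0))
    sd_large <- sd(vapply(1:10, function(s) est(80L, s), 0))
    expect_lt(sd_large, sd_small)
})

test_that("kernel SHAP is exact for additive models and matches enumeration", {
    # additive model: f(x) = sum_i f_i(x_i) with distinct nonlinear pieces
    f <- function(M) M[, 1]^2 + 3 * M[, 2] - 2 * sin(M[, 3])
    x <- c(1.2, -0.5, 0.7); b0 <- c(0, 1, -1)
    phi <- kernelShap(f, x, b0)
    expected <- c(x[1]^2 - b0[1]^2, 3 * (x[2] - b0[2]),
                  -2 * (sin(x[3]) - sin(b0[3])))
    expect_equal(unname(phi), expected, tolerance = 1e-9)
})

test_that("kernel SHAP equals brute-force Shapley enumeration at small d", {
    m <- random_mlp(d = 8L, hidden = 5L, K = 2L, seed = 18)
    withr::with_seed(19, {
        x <- rnorm(8); b0 <- rnorm(8)
    })
    f <- function(M) predictScore(m, M)[, 2]
    phi <- kernelShap(m, x, b0, class_index = 2)
    oracle <- exact_shapley(f, x, b0)
    expect_equal(unname(phi), oracle, tolerance = 1e-6)
    # completeness, also on the sampled (non-enumerated) path
    expect_equal(sum(phi), f(matrix(x, 1)) - f(matrix(b0, 1)),
                 tolerance = 1e-9)
    d <- 20L
    m2 <- random_mlp(d = d, hidden = 6L, K = 2L, seed = 20)
    withr::with_seed(21, { x2 <- rnorm(d); b2 <- rnorm(d) })
    phi2 <- kernelShap(m2, x2, b2, class_index = 1, n_coalitions = 400L,
                       seed = 22)
    f2 <- function(M) predictScore(m2, M)[, 1]
    expect_equal(sum(phi2), f2(matrix(x2, 1)) - f2(matrix(b2, 1)),
                 tolerance = 1e-6)
    expect_error(kernelShap(m2, x2, b2, n_coalitions = 10L), "at least")
})

test_that("LIME recovers linear coefficients and is seed-deterministic", {
    withr::with_seed(23, w <- rnorm(12))
    f <- function(M) as.numeric(M %*% w) + 0.5
    x <- withr::with_seed(24, rnorm(12))
    coef <- limeTabular(f, x, n_perturbations = 2000, n_features_kept = 12,
                        seed = 25)
    cosine <- sum(coef * w) / sqrt(sum(coef^2) * sum(w^2))
    expect_gt(cosine, 0.99)
    expect_identical(coef, limeTabular(f, x, n_perturbations = 2000,
                                       n_features_kept = 12, seed = 25))
    # constant model: coefficients collapse to zero
    coef0 <- limeTabular(function(M) rep(2, nrow(M)), x, seed = 26)
    expect_true(all(abs(coef0) < 1e-8))
    expect_error(limeTabular(f, x, n_perturbations = 5), "n_perturbations")
})

test_that("sparsity keeps only the requested number of LIME features", {
    withr::with_seed(27, w <- c(5, -4, 3, rep(0.01, 9)))
    f <- function(M) as.numeric(M %*% w)
    x <- rep(1, 12)
    coef <- limeTabular(f, x, n_perturbations = 1500, n_features_kept = 3,
                        seed = 28)
    expect_equal(sum(coef != 0), 3L)
    expect_setequal(which(coef != 0), 1:3)
})

test_that("per-class aggregation averages absolute attributions per type", {
    ds <- tiny_dataset()
    m <- trainClassifier(ds$Xtr, ds$ytr, hidden = 16L, epochs = 10, seed = 1)
    am <- perClassImportance(m, ds$Xte, ds$yte, method = "saliency",
                             reference = ds$Xtr, cells_per_type = 3L,
                             seed = 31)
    expect_s4_class(am, "AttributionMatrix")
    S <- attributionScores(am)
    expect_equal(dim(S), c(ncol(ds$Xte), length(unique(ds$yte))))
    expect_true(all(S >= 0))
    # independent group-by oracle for one type
    tp <- colnames(S)[1]
    pred <- predictClass(m, ds$Xte)
    ok <- which(ds$yte == tp & pred == tp)
    chosen <- withr::with_seed(31 + 1L,
        if (length(ok) > 3L) sort(sample(ok, 3L)) else ok)
    manual <- colMeans(abs(saliencyMap(m, ds$Xte[chosen, , drop = FALSE], 1)))
    expect_equal(unname(S[, 1]), unname(manual), tolerance = 1e-12)
})

test_that("aggregation handles signs, single cells and misclassified types", {
    # mean of |+3| and |-3| is 3: build it directly from a linear model
    W <- matrix(c(3, 0, 0, -3), 2, 2)  # gradient of class1 score is (3, 0)
    m <- linear_model(W, classes = c("a", "b"))
    X <- matrix(c(10, -10, 10.5, -9), 2, 2, byrow = TRUE,
                dimnames = list(NULL, c("g1", "g2")))
    expect_warning(
        am <- perClassImportance(m, X, c("a", "a"), method = "saliency",
                                 cells_per_type = 5L),
        "no cells of type")  # the model knows class b; the data lack it
    expect_equal(unname(attributionScores(am)[, "a"]), c(3, 0))
    # a single-cell class equals that cell's absolute attribution
    X1 <- matrix(c(10, -10, -5, -5), 2, 2, byrow = TRUE,
                 dimnames = list(NULL, c("g1", "g2")))
    am1 <- perClassImportance(m, X1, c("a", "b"), method = "saliency")
    expect_equal(unname(attributionScores(am1)[, "b"]),
                 abs(c(W[1, 2], W[2, 2])))
    # class never predicted correctly falls back to all its cells
    Xbad <- matrix(c(10, -10, 11, -11), 2, 2, byrow = TRUE,
                   dimnames = list(NULL, c("g1", "g2")))
    expect_warning(perClassImportance(m, Xbad, c("a", "b"),
                                      method = "saliency"),
                   "no correctly classified")
    expect_warning(perClassImportance(m, Xbad, c("a", "a"),
                                      method = "saliency"),
                   "no cells of type")
})

test_that("all six methods rank genes like the weights of a linear model", {
    # weight magnitudes well separated; x - baseline held constant across
    # genes so multiplicative methods agree with |w|
    w <- c(6, -5, 4, 0.3, -0.2, 0.1)
    m <- linear_model(cbind(w, -w), classes = c("a", "b"))
    x <- rep(1, 6); b0 <- rep(0, 6)
    X <- matrix(x, 1, dimnames = list(NULL, paste0("g", 1:6)))
    top3 <- function(s) order(-abs(s))[1:3]
    expect_equal(top3(saliencyMap(m, X, 1)[1, ]), 1:3)
    am <- activationMaximization(m, 1, constraint_radius = 2, n_steps = 200,
                                 seed = 1)
    expect_equal(top3(am$importance), 1:3)
    expect_equal(top3(deepliftRescale(m, X, b0, 1)[1, ]), 1:3)
    expect_equal(top3(expectedGradients(m, X, matrix(b0, 1), 1,
                                        n_samples = 10, seed = 2)[1, ]), 1:3)
    expect_equal(top3(kernelShap(m, x, b0, 1)), 1:3)
    expect_equal(top3(limeTabular(m, x, 1, n_perturbations = 1500,
                                  n_features_kept = 6, seed = 3)), 1:3)
})
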