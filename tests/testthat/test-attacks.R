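test_that("zero attack level leaves the input untouched", {
    m <- random_mlp(d = 8L)
    withr::with_seed(1, X <- matrix(rnorm(48), 6, 8))
    colnames(X) <- paste0("g", 1:8)
    y <- rep(c("c1", "c2", "c3"), 2)
    expect_equal(fgsm(m, X, y, 0), X, ignore_attr = TRUE)
    expect_equal(pgd(m, X, y, 0, n_iter = 5), X, ignore_attr = TRUE)
    expect_error(fgsm(m, X, y, -1), "epsilon")
})

test_that("FGSM equals the closed-form sign gradient on a logistic model", {
    withr::with_seed(2, W <- matrix(rnorm(6), 3, 2))
    m <- linear_model(W)
    X <- matrix(c(0.5, -1, 2), 1)
    colnames(X) <- paste0("g", 1:3)
    y <- "c1"
    P <- predictProba(m, X)
    onehot <- c(1, 0)
    expected <- X + 0.3 * sign((P - onehot) %*% t(W))
    expect_equal(fgsm(m, X, y, 0.3), expected, ignore_attr = TRUE)
})

test_that("single-step PGD with alpha = epsilon reproduces FGSM bitwise", {
    ds <- tiny_dataset()
    m <- trainClassifier(ds$Xtr, ds$ytr, hidden = 16L, epochs = 5, seed = 1)
    a <- fgsm(m, ds$Xte, ds$yte, 0.7)
    b <- pgd(m, ds$Xte, ds$yte, 0.7, alpha = 0.7, n_iter = 1L)
    expect_identical(a, b)
})

test_that("every PGD iterate stays inside the infinity-norm ball", {
    m <- random_mlp(d = 10L, hidden = 6L, K = 3L)
    withr::with_seed(8, X <- matrix(rnorm(200), 20, 10))
    colnames(X) <- paste0("g", 1:10)
    y <- rep(c("c1", "c2", "c3"), length.out = 20)
    eps <- 0.5
    x_adv <- pgd(m, X, y, eps, alpha = 0.4, n_iter = 10L)
    expect_lte(max(abs(x_adv - X)), eps + 1e-12)
    # the bound is active: some coordinate reaches it
    expect_gt(max(abs(x_adv - X)), 0.9 * eps)
})

test_that("adversarial augmentation doubles the data and aligns labels", {
    ds <- tiny_dataset()
    m <- trainClassifier(ds$Xtr, ds$ytr, hidden = 16L, epochs = 5, seed = 1)
    aug <- buildAdversarialTrainingSet(ds$Xtr, ds$ytr, m,
                                       attackConfig("fgsm", 0.8))
    n <- nrow(ds$Xtr)
    expect_equal(nrow(aug$x), 2L * n)
    expect_identical(aug$labels[seq_len(n)], aug$labels[n + seq_len(n)])
    expect_equal(as.vector(table(aug$provenance)), c(n, n))
    expect_lte(max(abs(aug$x[n + seq_len(n), ] - ds$Xtr)), 0.8 + 1e-12)
    wrong <- ds$Xtr[, 1:10]
    expect_error(buildAdversarialTrainingSet(wrong, ds$ytr, m,
                                             attackConfig("fgsm", 0.8)),
                 "features")
})

test_that("neighborhood preservation is 1 for identity and tracks structure", {
    withr::with_seed(4, X <- matrix(rnorm(100), 20, 5))
    expect_equal(neighborhoodPreservation(X, X, 5), 1.0)
    expect_error(neighborhoodPreservation(X, X, 0), "positive")
    expect_error(neighborhoodPreservation(X, X[1:3, ], 2), "same shape")
})

test_that("a hand-built 5-point move gives the hand-counted Jaccard mean", {
    # two clusters on a line; point 5 crosses from one to the other
    X <- matrix(c(0, 1, 2, 10, 11), ncol = 1)
    Xa <- X; Xa[5, 1] <- 1.5
    # k = 2 sets before: {2,3},{1,3},{2,1},{5,3},{4,3}
    # after (5 at 1.5):  {2,5},{5,1},{5,2},{3,5},{2,3}
    # Jaccard per point: 1/3, 1/3, 1/3, 1, 1/3 -> mean = 7/15
    expect_equal(neighborhoodPreservation(X, Xa, 2), 7 / 15)
})

test_that("destroying all structure drives preservation to the random level", {
    withr::with_seed(6, {
        X <- matrix(rnorm(60 * 4), 60, 4)
        Xa <- matrix(rnorm(60 * 4), 60, 4)
    })
    k <- 5
    score <- neighborhoodPreservation(X, Xa, k)
    # independent null: Jaccard of two random k-subsets of the other 59 cells
    null_mean <- withr::with_seed(7, mean(replicate(2000, {
        a <- sample(59, k); b <- sample(59, k)
        i <- length(intersect(a, b)); i / (2 * k - i)
    })))
    expect_lt(abs(score - null_mean), 0.06)
})

test_that("the epsilon sweep anchors at zero and trends downward", {
    ds <- tiny_dataset(tiny_config(n_cells = 150L))
    m <- trainClassifier(ds$Xtr, ds$ytr, hidden = 16L, epochs = 15, seed = 1)
    sw <- epsilonSweep(m, ds$Xte, ds$yte, eps_grid = c(0, 0.5, 1, 2),
                       k_neighbors = 5L)
    clean <- evaluateClassifier(m, ds$Xte, ds$yte)$accuracy
    at0 <- sw$curve[sw$curve$epsilon == 0, ]
    expect_equal(at0$attacked_accuracy, clean)
    expect_equal(at0$preservation, 1.0)
    # monotone non-increasing trend in epsilon (Spearman)
    expect_lte(cor(sw$curve$epsilon, sw$curve$attacked_accuracy,
                   method = "spearman"), 0)
    expect_true(all(sw$curve$attacked_accuracy >= 0 &
                        sw$curve$attacked_accuracy <= 1))
    expect_error(epsilonSweep(m, ds$Xte, ds$yte, eps_grid = numeric(0)),
                 "non-empty")
    expect_error(epsilonSweep(m, ds$Xte, ds$yte, eps_grid = c(1, 0.5)),
                 "ascending")
})

test_that("zero-epsilon adversarial training behaves like duplicated training", {
    ds <- tiny_dataset()
    std <- trainClassifier(ds$Xtr, ds$ytr, hidden = 16L, epochs = 10, seed = 1)
    adv0 <- adversarialTrain(ds$Xtr, ds$ytr,
                             attack = attackConfig("fgsm", 0),
                             hidden = 16L, epochs = 10, seed = 1,
                             warm_start = std)
    acc_std <- evaluateClassifier(std, ds$Xte, ds$yte)$accuracy
    acc_adv <- evaluateClassifier(adv0, ds$Xte, ds$yte)$accuracy
    expect_lt(abs(acc_std - acc_adv), 0.1)
})

test_that("per-epoch adversarial training produces a working robust model", {
    ds <- tiny_dataset()
    m <- adversarialTrain(ds$Xtr, ds$ytr, attack = attackConfig("fgsm", 0.5),
                          mode = "per_epoch", hidden = 16L, epochs = 30,
                          batch_size = 16L, seed = 1)
    expect_s4_class(m, "MLPClassifier")
    expect_gt(evaluateClassifier(m, ds$Xte, ds$yte)$accuracy, 0.5)
})

test_that("attack configurations are validated", {
    expect_error(attackConfig("fgsm", epsilon = -0.1), "epsilon")
    expect_error(attackConfig("pgd", epsilon = 1, alpha = 0), "alpha")
    expect_error(attackConfig("pgd", epsilon = 1, n_iter = 0), "n_iter")
})
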