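# Feed-forward network internals. The model is a stack of affine layers
# with ReLU nonlinearities and a linear output layer scored through a
# softmax. Everything is dense matrix algebra with cells in rows, so BLAS
# carries the load; gradients w.r.t. both parameters and inputs are exact
# backpropagation, which the finite-difference tests verify.

.softmax <- function(Z) {
    Z <- Z - apply(Z, 1L, max)
    E <- exp(Z)
    E / rowSums(E)
}

.mlp_new <- function(n_in, hidden, n_out) {
    widths <- c(n_in, hidden, n_out)
    W <- vector("list", length(widths) - 1L)
    b <- vector("list", length(widths) - 1L)
    for (l in seq_along(W)) {
        fan_in <- widths[l]
        W[[l]] <- matrix(stats::rnorm(fan_in * widths[l + 1L],
                                      sd = sqrt(2 / fan_in)),
                         fan_in, widths[l + 1L])
        b[[l]] <- numeric(widths[l + 1L])
    }
    list(W = W, b = b)
}

# Forward pass keeping every pre-activation (needed for backprop and for
# the DeepLIFT multipliers). A[[1]] is the input; Z[[l]] the l-th
# pre-activation; the last Z are the logits (no nonlinearity).
.mlp_forward <- function(par, X) {
    L <- length(par$W)
    Z <- vector("list", L)
    A <- vector("list", L + 1L)
    A[[1L]] <- X
    for (l in seq_len(L)) {
        Z[[l]] <- sweep(A[[l]] %*% par$W[[l]], 2L, par$b[[l]], "+")
        A[[l + 1L]] <- if (l < L) pmax(Z[[l]], 0) else Z[[l]]
    }
    list(Z = Z, A = A, logits = Z[[L]])
}

# Backpropagate a logit-level error signal `delta` (n x K). Returns the
# gradient w.r.t. the input and, if wanted, w.r.t. all parameters.
.mlp_backward <- function(par, fw, delta, params = FALSE) {
    L <- length(par$W)
    dW <- if (params) vector("list", L) else NULL
    db <- if (params) vector("list", L) else NULL
    for (l in rev(seq_len(L))) {
        if (params) {
            dW[[l]] <- crossprod(fw$A[[l]], delta)
            db[[l]] <- colSums(delta)
        }
        delta <- tcrossprod(delta, par$W[[l]])
        if (l > 1L) delta <- delta * (fw$Z[[l - 1L]] > 0)
    }
    list(dX = delta, dW = dW, db = db)
}

.mlp_ce_loss <- function(P, Y) {
    -mean(log(pmax(rowSums(P * Y), 1e-12)))
}

# Adam minimiser of the mean categorical cross-entropy. An optional
# `regen` callback can rebuild the epoch's training data from the current
# parameters (used for per-epoch adversarial augmentation); optimiser
# state persists across epochs either way.
.mlp_train <- function(X, Y, hidden, epochs, batch_size, learning_rate,
                       par = NULL, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       regen = NULL) {
    if (is.null(par)) par <- .mlp_new(ncol(X), hidden, ncol(Y))
    L <- length(par$W)
    m <- lapply(par$W, function(w) w * 0); v <- m
    mb <- lapply(par$b, function(b) b * 0); vb <- mb
    step <- 0L
    history <- numeric(epochs)
    Xe <- X; Ye <- Y
    for (ep in seq_len(epochs)) {
        if (!is.null(regen)) {
            dat <- regen(par)
            Xe <- dat$X; Ye <- dat$Y
        }
        n <- nrow(Xe)
        ord <- sample.int(n)
        losses <- c()
        for (start in seq(1L, n, by = batch_size)) {
            idx <- ord[start:min(start + batch_size - 1L, n)]
            fw <- .mlp_forward(par, Xe[idx, , drop = FALSE])
            P <- .softmax(fw$logits)
            losses <- c(losses, .mlp_ce_loss(P, Ye[idx, , drop = FALSE]))
            delta <- (P - Ye[idx, , drop = FALSE]) / length(idx)
            bw <- .mlp_backward(par, fw, delta, params = TRUE)
            step <- step + 1L
            corr1 <- 1 - beta1^step; corr2 <- 1 - beta2^step
            for (l in seq_len(L)) {
                m[[l]] <- beta1 * m[[l]] + (1 - beta1) * bw$dW[[l]]
                v[[l]] <- beta2 * v[[l]] + (1 - beta2) * bw$dW[[l]]^2
                par$W[[l]] <- par$W[[l]] - learning_rate * (m[[l]] / corr1) /
                    (sqrt(v[[l]] / corr2) + eps)
                mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * bw$db[[l]]
                vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * bw$db[[l]]^2
                par$b[[l]] <- par$b[[l]] - learning_rate * (mb[[l]] / corr1) /
                    (sqrt(vb[[l]] / corr2) + eps)
            }
        }
        history[ep] <- mean(losses)
        if (!is.finite(history[ep]))
            stop(sprintf("training diverged (non-finite loss) at epoch %d", ep),
                 call. = FALSE)
    }
    list(par = par, history = history)
}

.mlp_par <- function(model) list(W = model@weights, b = model@biases)

.check_features <- function(model, X) {
    if (ncol(X) != length(model@featureNames))
        stop(sprintf("input has %d features but the model expects %d",
                     ncol(X), length(model@featureNames)), call. = FALSE)
    if (any(!is.finite(X)))
        stop("input contains non-finite values", call. = FALSE)
    invisible(TRUE)
}

#' Train the multilayer perceptron cell-type classifier
#'
#' Fits a ReLU network with a softmax output by minimising the categorical
#' cross-entropy with mini-batch Adam. Training is fully seeded
#' (initialisation and batch shuffling), so a fixed seed reproduces the
#' model exactly.
#'
#' @param x training data: a \code{SingleCellExperiment} carrying a
#'   \code{"scaled"} assay (see [normalizeLogScale()]) or a cells x genes
#'   numeric matrix.
#' @param labels per-cell type labels; taken from
#'   \code{colData(x)$cell_type} when \code{x} is an SCE.
#' @param hidden integer vector of hidden-layer widths
#'   (default \code{c(256, 128)}).
#' @param epochs number of passes over the training data (default 30).
#' @param batch_size mini-batch size (default 64).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed integer seed.
#' @param warm_start optional \code{MLPClassifier} whose weights
#'   initialise training (architecture and classes must match).
#' @return an [MLPClassifier-class] object.
#' @examples
#' X <- rbind(matrix(rnorm(200, -2), 50), matrix(rnorm(200, 2), 50))
#' y <- rep(c("a", "b"), each = 50)
#' m <- trainClassifier(X, y, hidden = 8L, epochs = 20, seed = 1)
#' evaluateClassifier(m, X, y)$accuracy
#' @export
trainClassifier <- function(x, labels = NULL, hidden = c(256L, 128L),
                            epochs = 30L, batch_size = 64L,
                            learning_rate = 1e-3, seed = 1L,
                            warm_start = NULL) {
    d <- .xy(x, labels)
    X <- d$X; y <- d$y
    classes <- sort(unique(y))
    if (length(classes) < 2L)
        stop("need at least 2 classes to train a classifier", call. = FALSE)
    if (any(!is.finite(X))) stop("features must be finite", call. = FALSE)
    Y <- .one_hot(y, classes)
    par0 <- NULL
    if (!is.null(warm_start)) {
        stopifnot(identical(modelClasses(warm_start), classes),
                  nrow(warm_start@weights[[1L]]) == ncol(X))
        par0 <- .mlp_par(warm_start)
        hidden <- warm_start@hidden
    }
    fit <- .with_seed(seed,
        .mlp_train(X, Y, hidden = as.integer(hidden), epochs = epochs,
                   batch_size = batch_size, learning_rate = learning_rate,
                   par = par0))
    methods::new("MLPClassifier",
        weights = fit$par$W, biases = fit$par$b,
        hidden = as.integer(hidden), classes = classes,
        featureNames = colnames(X), history = fit$history)
}

#' Class probabilities, scores and predictions
#'
#' \code{predictProba} returns the softmax class probabilities (rows sum
#' to one); \code{predictScore} the pre-softmax class scores (logits);
#' \code{predictClass} the argmax labels.
#'
#' @param model an [MLPClassifier-class].
#' @param x cells x genes matrix (or SCE with a \code{"scaled"} assay) in
#'   the model's feature space.
#' @return matrix of probabilities / logits, or character vector of labels.
#' @export
predictProba <- function(model, x) {
    X <- .xy(x)$X
    .check_features(model, X)
    P <- .softmax(.mlp_forward(.mlp_par(model), X)$logits)
    colnames(P) <- model@classes
    P
}

#' @rdname predictProba
#' @export
predictScore <- function(model, x) {
    X <- .xy(x)$X
    .check_features(model, X)
    S <- .mlp_forward(.mlp_par(model), X)$logits
    colnames(S) <- model@classes
    S
}

#' @rdname predictProba
#' @export
predictClass <- function(model, x) {
    P <- predictProba(model, x)
    model@classes[max.col(P, ties.method = "first")]
}

#' Input gradient of the cross-entropy loss
#'
#' Exact gradient, for every cell, of the categorical cross-entropy of the
#' model's prediction against the true label with respect to the input
#' features. This is the gradient the FGSM and PGD attacks perturb along.
#'
#' @param model an [MLPClassifier-class].
#' @param x cells x genes matrix in the model's feature space.
#' @param y true labels, one per row of \code{x}.
#' @return matrix of the same shape as \code{x}.
#' @export
gradInputLoss <- function(model, x, y) {
    X <- .xy(x)$X
    .check_features(model, X)
    par <- .mlp_par(model)
    fw <- .mlp_forward(par, X)
    delta <- .softmax(fw$logits) - .one_hot(as.character(y), model@classes)
    G <- .mlp_backward(par, fw, delta)$dX
    dimnames(G) <- dimnames(X)
    G
}

#' Input gradient of a class score
#'
#' Exact gradient of the pre-softmax score of one class with respect to
#' the input, for every cell. This is the saliency-map primitive and the
#' inner derivative of the expected-gradients estimator.
#'
#' @param model an [MLPClassifier-class].
#' @param x cells x genes matrix in the model's feature space.
#' @param class_index class position in \code{modelClasses(model)}, or a
#'   class label.
#' @return matrix of the same shape as \code{x}.
#' @export
gradInputScore <- function(model, x, class_index) {
    X <- .xy(x)$X
    .check_features(model, X)
    k <- .class_index(model, class_index)
    par <- .mlp_par(model)
    fw <- .mlp_forward(par, X)
    delta <- matrix(0, nrow(X), length(model@classes))
    delta[, k] <- 1
    G <- .mlp_backward(par, fw, delta)$dX
    dimnames(G) <- dimnames(X)
    G
}

.class_index <- function(model, class_index) {
    if (is.character(class_index)) {
        k <- match(class_index, model@classes)
        if (is.na(k)) stop("unknown class label: ", class_index, call. = FALSE)
        return(k)
    }
    k <- as.integer(class_index)
    if (k < 1L || k > length(model@classes))
        stop(sprintf("class_index %d out of range 1..%d", k,
                     length(model@classes)), call. = FALSE)
    k
}

#' Evaluate a classifier on labeled data
#'
#' @param model an [MLPClassifier-class].
#' @param x labeled test data (SCE with \code{"scaled"} assay, or matrix).
#' @param labels true labels when \code{x} is a matrix.
#' @return list with \code{accuracy}, \code{confusion} (true types in
#'   rows, predictions in columns), \code{per_class} (precision, recall,
#'   F1 and support per type) and \code{macro_f1}.
#' @export
evaluateClassifier <- function(model, x, labels = NULL) {
    d <- .xy(x, labels)
    if (nrow(d$X) == 0L) stop("test set is empty", call. = FALSE)
    y <- d$y
    unseen <- setdiff(unique(y), model@classes)
    if (length(unseen))
        stop("test labels unseen at training time: ",
             paste(unseen, collapse = ", "), call. = FALSE)
    pred <- predictClass(model, d$X)
    cls <- model@classes
    confusion <- table(truth = factor(y, cls), prediction = factor(pred, cls))
    tp <- diag(confusion)
    support <- rowSums(confusion)
    predicted <- colSums(confusion)
    precision <- ifelse(predicted > 0, tp / predicted, 0)
    recall <- ifelse(support > 0, tp / support, 0)
    f1 <- ifelse(precision + recall > 0,
                 2 * precision * recall / (precision + recall), 0)
    list(accuracy = sum(tp) / length(y),
         confusion = unclass(confusion),
         per_class = data.frame(cell_type = cls, precision = precision,
                                recall = recall, f1 = f1,
                                support = as.integer(support),
                                row.names = NULL),
         macro_f1 = mean(f1))
}

#' Grid search over depth and width
#'
#' Trains one model per (number of layers, nodes per layer) combination on
#' 90% of the training cells and scores it on a stratified 10% validation
#' split. The best architecture is the one with the highest validation
#' accuracy; exact ties go to the model with fewer parameters.
#'
#' @param x,labels training data as in [trainClassifier()].
#' @param n_layers integer vector of hidden-layer counts to try.
#' @param n_nodes integer vector of layer widths to try.
#' @param epochs,seed passed to [trainClassifier()].
#' @return list with \code{best} (the winning \code{hidden} vector) and
#'   \code{table} (one row per grid cell: layers, nodes, parameter count,
#'   validation accuracy).
#' @export
hyperparameterSearch <- function(x, labels = NULL, n_layers = c(1L, 2L),
                                 n_nodes = c(64L, 128L, 256L), epochs = 15L,
                                 seed = 1L) {
    if (!length(n_layers) || !length(n_nodes))
        stop("the architecture grid must be non-empty", call. = FALSE)
    d <- .xy(x, labels)
    y <- d$y
    val_idx <- .with_seed(seed, {
        unlist(lapply(unique(y), function(tp) {
            idx <- which(y == tp)
            sample(idx, max(1L, round(0.1 * length(idx))))
        }), use.names = FALSE)
    })
    tr <- setdiff(seq_along(y), val_idx)
    grid <- expand.grid(layers = as.integer(n_layers),
                        nodes = as.integer(n_nodes))
    res <- lapply(seq_len(nrow(grid)), function(i) {
        hidden <- rep(grid$nodes[i], grid$layers[i])
        m <- trainClassifier(d$X[tr, , drop = FALSE], y[tr], hidden = hidden,
                             epochs = epochs, seed = seed)
        acc <- evaluateClassifier(m, d$X[val_idx, , drop = FALSE],
                                  y[val_idx])$accuracy
        n_par <- sum(vapply(m@weights, length, 0)) +
            sum(vapply(m@biases, length, 0))
        data.frame(layers = grid$layers[i], nodes = grid$nodes[i],
                   n_parameters = n_par, val_accuracy = acc)
    })
    tab <- do.call(rbind, res)
    best_i <- order(-tab$val_accuracy, tab$n_parameters)[1L]
    list(best = rep(tab$nodes[best_i], tab$layers[best_i]), table = tab)
}
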