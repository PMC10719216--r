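#' Attack configuration
#'
#' @param method \code{"fgsm"} or \code{"pgd"}.
#' @param epsilon attack level: the maximum per-feature perturbation, in
#'   the (normalized) units of the model's input space.
#' @param alpha PGD per-iteration step size; defaults to
#'   \code{epsilon / 4}.
#' @param n_iter number of PGD iterations (default 10).
#' @param clip_non_negative if \code{TRUE}, the perturbed input is clipped
#'   at zero (only meaningful when the model consumes raw counts; off by
#'   default because attacks operate in standardized space).
#' @return a validated list of class \code{AttackConfig}.
#' @export
attackConfig <- function(method = c("fgsm", "pgd"), epsilon = 1.2,
                         alpha = epsilon / 4, n_iter = 10L,
                         clip_non_negative = FALSE) {
    method <- match.arg(method)
    if (epsilon < 0) stop("'epsilon' must be >= 0", call. = FALSE)
    if (method == "pgd" && (alpha <= 0 || n_iter < 1L))
        stop("PGD needs alpha > 0 and n_iter >= 1", call. = FALSE)
    structure(list(method = method, epsilon = epsilon, alpha = alpha,
                   n_iter = as.integer(n_iter),
                   clip_non_negative = isTRUE(clip_non_negative)),
              class = "AttackConfig")
}

#' Fast gradient sign method
#'
#' Single-step white-box attack: each feature moves by \code{epsilon} in
#' the sign direction of the loss gradient,
#' \code{x_adv = x + epsilon * sign(grad_x L(f(x), y))}, so the
#' perturbation has infinity-norm exactly \code{epsilon} wherever the
#' gradient is nonzero.
#'
#' @param model an [MLPClassifier-class].
#' @param x cells x genes matrix in the model's feature space.
#' @param y true labels, one per row.
#' @param epsilon attack level (>= 0).
#' @param clip_non_negative clip the result at zero.
#' @return the perturbed matrix, same shape as \code{x}.
#' @export
fgsm <- function(model, x, y, epsilon, clip_non_negative = FALSE) {
    if (epsilon < 0) stop("'epsilon' must be >= 0", call. = FALSE)
    X <- .xy(x)$X
    x_adv <- X + epsilon * sign(gradInputLoss(model, X, y))
    if (clip_non_negative) x_adv <- pmax(x_adv, 0)
    x_adv
}

#' Projected gradient descent attack
#'
#' Iterated sign-gradient ascent on the loss with step size \code{alpha},
#' projecting each iterate back onto the infinity-norm ball of radius
#' \code{epsilon} around the original input. With \code{n_iter = 1} and
#' \code{alpha = epsilon} it reduces exactly to [fgsm()].
#'
#' @inheritParams fgsm
#' @param alpha per-iteration step size (> 0).
#' @param n_iter number of iterations (>= 1).
#' @return the perturbed matrix, with
#'   \code{max |x_adv - x| <= epsilon} elementwise.
#' @export
pgd <- function(model, x, y, epsilon, alpha = epsilon / 4, n_iter = 10L,
                clip_non_negative = FALSE) {
    if (epsilon < 0) stop("'epsilon' must be >= 0", call. = FALSE)
    if (epsilon == 0) return(.xy(x)$X)
    if (alpha <= 0 || n_iter < 1L)
        stop("PGD needs alpha > 0 and n_iter >= 1", call. = FALSE)
    X <- .xy(x)$X
    lo <- X - epsilon; hi <- X + epsilon
    x_adv <- X
    for (i in seq_len(n_iter)) {
        g <- gradInputLoss(model, x_adv, y)
        x_adv <- pmin(pmax(x_adv + alpha * sign(g), lo), hi)
    }
    if (clip_non_negative) x_adv <- pmax(x_adv, 0)
    x_adv
}

.run_attack <- function(model, X, y, attack) {
    if (attack$method == "fgsm")
        fgsm(model, X, y, attack$epsilon, attack$clip_non_negative)
    else
        pgd(model, X, y, attack$epsilon, attack$alpha, attack$n_iter,
            attack$clip_non_negative)
}

#' Augment a training set with adversarial copies
#'
#' Generates one adversarial counterpart for every training cell with the
#' configured attack against the supplied model and stacks it under the
#' originals, doubling the number of rows. Adversarial copies keep the
#' label of their source cell; a provenance vector marks which rows are
#' original and which adversarial.
#'
#' @param x training cells x genes matrix (or SCE with \code{"scaled"}
#'   assay).
#' @param labels per-row labels (from \code{colData} for an SCE).
#' @param model the model the attack is computed against.
#' @param attack an [attackConfig()].
#' @return list with \code{x} (2n x genes), \code{labels} (length 2n) and
#'   \code{provenance} (factor \code{original}/\code{adversarial}).
#' @export
buildAdversarialTrainingSet <- function(x, labels = NULL, model, attack) {
    d <- .xy(x, labels)
    .check_features(model, d$X)
    x_adv <- .run_attack(model, d$X, d$y, attack)
    rownames(x_adv) <- paste0(rownames(d$X), "_adv")
    list(x = rbind(d$X, x_adv),
         labels = c(d$y, d$y),
         provenance = factor(rep(c("original", "adversarial"),
                                 each = nrow(d$X)),
                             levels = c("original", "adversarial")))
}

#' Adversarially train a classifier
#'
#' In \code{"static"} mode (the default) a warm-start model is first
#' trained normally, one adversarial copy of every training cell is
#' generated against it, and a fresh model is trained on the doubled
#' (original + adversarial) training set. In \code{"per_epoch"} mode the
#' adversarial half is regenerated against the current model before every
#' epoch.
#'
#' @param x,labels training data as in [trainClassifier()].
#' @param attack an [attackConfig()].
#' @param mode \code{"static"} or \code{"per_epoch"}.
#' @param hidden,epochs,batch_size,learning_rate,seed as in
#'   [trainClassifier()].
#' @param warm_start optional pre-trained standard model to generate the
#'   static adversarial set from (trained internally if missing).
#' @return an [MLPClassifier-class] trained on the augmented data.
#' @export
adversarialTrain <- function(x, labels = NULL, attack = attackConfig(),
                             mode = c("static", "per_epoch"),
                             hidden = c(256L, 128L), epochs = 30L,
                             batch_size = 64L, learning_rate = 1e-3,
                             seed = 1L, warm_start = NULL) {
    mode <- match.arg(mode)
    d <- .xy(x, labels)
    if (mode == "static") {
        if (is.null(warm_start))
            warm_start <- trainClassifier(d$X, d$y, hidden = hidden,
                                          epochs = epochs,
                                          batch_size = batch_size,
                                          learning_rate = learning_rate,
                                          seed = seed)
        aug <- buildAdversarialTrainingSet(d$X, d$y, warm_start, attack)
        return(trainClassifier(aug$x, aug$labels, hidden = hidden,
                               epochs = epochs, batch_size = batch_size,
                               learning_rate = learning_rate, seed = seed))
    }
    # per-epoch: regenerate the adversarial half against the live model
    # at the start of every epoch, keeping the optimiser state
    classes <- sort(unique(d$y))
    Y <- .one_hot(d$y, classes)
    regen <- function(par) {
        live <- methods::new("MLPClassifier", weights = par$W,
                             biases = par$b, hidden = as.integer(hidden),
                             classes = classes,
                             featureNames = colnames(d$X),
                             history = numeric(0))
        x_adv <- .run_attack(live, d$X, d$y, attack)
        list(X = rbind(d$X, x_adv), Y = rbind(Y, Y))
    }
    fit <- .with_seed(seed,
        .mlp_train(d$X, Y, hidden = as.integer(hidden), epochs = epochs,
                   batch_size = batch_size, learning_rate = learning_rate,
                   regen = regen))
    methods::new("MLPClassifier", weights = fit$par$W, biases = fit$par$b,
                 hidden = as.integer(hidden), classes = classes,
                 featureNames = colnames(d$X), history = fit$history)
}

#' k-nearest-neighbour structure preservation
#'
#' Quantifies how much a perturbation changes the global arrangement of
#' the cells: for every cell, the Jaccard overlap between its k-nearest
#' neighbour set (Euclidean distance in feature space) before and after
#' the perturbation, averaged over cells. 1 means identical neighbourhood
#' structure; random destruction of structure drives the score towards
#' the small overlap expected between unrelated k-sets.
#'
#' @param x original cells x genes matrix.
#' @param x_adv perturbed matrix of the same shape.
#' @param k_neighbors neighbourhood size (positive, < number of cells).
#' @return a score in [0, 1].
#' @export
neighborhoodPreservation <- function(x, x_adv, k_neighbors = 15L) {
    X <- .xy(x)$X; Xa <- .xy(x_adv)$X
    if (!all(dim(X) == dim(Xa)))
        stop("x and x_adv must have the same shape", call. = FALSE)
    k <- as.integer(k_neighbors)
    nn0 <- .knn_indices(X, k)
    nn1 <- .knn_indices(Xa, k)
    mean(vapply(seq_len(nrow(X)), function(i) {
        inter <- length(intersect(nn0[i, ], nn1[i, ]))
        inter / (2L * k - inter)
    }, 0))
}

#' Sweep the attack level and measure robustness and structure
#'
#' For every epsilon on the grid, perturbs the evaluation cells with an
#' attack generated against the \emph{source} model (by default the
#' first, i.e. the standard-trained model) and records every model's
#' accuracy on those same perturbed cells, plus the
#' [neighborhoodPreservation()] of the perturbation. Evaluating all
#' models on the source model's adversarial examples is the protocol the
#' adversarial training set is built under: the robust model is judged on
#' the attack it was trained to withstand, while the source model is
#' attacked white-box. The recommended epsilon is the smallest grid value
#' whose source-model attacked accuracy falls below
#' \code{accuracy_threshold} times the clean accuracy while preservation
#' stays at or above \code{preservation_threshold} — an attack level that
#' hurts the classifier without destroying the data structure.
#'
#' @param models a named list of [MLPClassifier-class] objects (e.g.
#'   \code{list(standard = m1, adversarial = m2)}); a bare model is
#'   wrapped as \code{list(standard = model)}. The first model is the
#'   attack source unless \code{source_model} says otherwise.
#' @param x,labels evaluation data (typically the held-out test split).
#' @param eps_grid increasing numeric grid of attack levels.
#' @param method \code{"fgsm"} or \code{"pgd"}.
#' @param k_neighbors neighbourhood size for the preservation score.
#' @param accuracy_threshold,preservation_threshold selection rule
#'   thresholds (defaults 0.5 and 0.8).
#' @param source_model name or position of the model the attack is
#'   generated against (default 1).
#' @param ... further arguments passed to [attackConfig()] (e.g.
#'   \code{alpha}, \code{n_iter}).
#' @return list with \code{curve} (data.frame: epsilon, model,
#'   attacked_accuracy, preservation) and \code{recommended_epsilon}
#'   (NA if no grid point satisfies the rule).
#' @export
epsilonSweep <- function(models, x, labels = NULL, eps_grid = seq(0, 3.2, 0.2),
                         method = c("fgsm", "pgd"), k_neighbors = 15L,
                         accuracy_threshold = 0.5,
                         preservation_threshold = 0.8, source_model = 1L,
                         ...) {
    method <- match.arg(method)
    if (!length(eps_grid)) stop("'eps_grid' must be non-empty", call. = FALSE)
    if (is.unsorted(eps_grid))
        stop("'eps_grid' must be sorted ascending", call. = FALSE)
    if (methods::is(models, "MLPClassifier")) models <- list(standard = models)
    if (is.null(names(models)))
        names(models) <- paste0("model", seq_along(models))
    src <- if (is.character(source_model)) source_model else
        names(models)[source_model]
    d <- .xy(x, labels)
    rows <- list()
    for (i in seq_along(eps_grid)) {
        eps <- eps_grid[i]
        cfg <- attackConfig(method = method, epsilon = eps, ...)
        x_adv <- if (eps == 0) d$X else
            .run_attack(models[[src]], d$X, d$y, cfg)
        pres <- if (eps == 0) 1 else
            neighborhoodPreservation(d$X, x_adv, k_neighbors)
        for (nm in names(models)) {
            acc <- evaluateClassifier(models[[nm]], x_adv, d$y)$accuracy
            rows[[length(rows) + 1L]] <-
                data.frame(epsilon = eps, model = nm,
                           attacked_accuracy = acc, preservation = pres)
        }
    }
    curve <- do.call(rbind, rows)
    first <- curve[curve$model == src, ]
    clean <- first$attacked_accuracy[first$epsilon == min(eps_grid)][1L]
    ok <- first$attacked_accuracy < accuracy_threshold * clean &
        first$preservation >= preservation_threshold
    list(curve = curve,
         recommended_epsilon = if (any(ok)) min(first$epsilon[ok]) else NA_real_)
}
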