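# Six attribution methods mapping (model, cells) to per-gene importance,
# plus the aggregation to gene x cell-type matrices. All methods score the
# pre-softmax class output, not the probability, so that confident
# predictions do not flatten the gradients; comparisons across methods are
# then on an equal footing.

#' Saliency map
#'
#' Per-gene importance as the raw gradient of the class score with respect
#' to the input — identical, by definition, to [gradInputScore()].
#'
#' @param model an [MLPClassifier-class].
#' @param x cells x genes matrix.
#' @param class_index class position or label.
#' @return gradient matrix of the same shape as \code{x}.
#' @export
saliencyMap <- function(model, x, class_index) {
    gradInputScore(model, x, class_index)
}

#' Activation maximization
#'
#' Constructs the input that maximizes one class's pre-softmax score by
#' projected gradient ascent over an L2 ball of radius
#' \code{constraint_radius} (default \code{sqrt(n_genes)}, the typical
#' norm of a standardized cell). Steps are accepted only when the
#' objective does not decrease (backtracking halves the step otherwise),
#' so the recorded objective trace is monotone non-decreasing. Per-gene
#' importance is the absolute value of the constructed input.
#'
#' @param model an [MLPClassifier-class].
#' @param class_index class position or label.
#' @param constraint_radius L2 radius of the feasible ball (> 0).
#' @param n_steps maximum number of ascent steps (default 100).
#' @param step_size initial step size (default 1).
#' @param seed seed for the random start.
#' @return list with \code{x_star} (the constructed input),
#'   \code{objective} (accepted-objective trace) and \code{importance}
#'   (\code{abs(x_star)}).
#' @export
activationMaximization <- function(model, class_index,
                                   constraint_radius = NULL, n_steps = 100L,
                                   step_size = 1, seed = 1L) {
    d <- length(model@featureNames)
    r <- if (is.null(constraint_radius)) sqrt(d) else constraint_radius
    if (r <= 0) stop("'constraint_radius' must be > 0", call. = FALSE)
    k <- .class_index(model, class_index)
    proj <- function(v) {
        nv <- sqrt(sum(v^2))
        if (nv > r) v * (r / nv) else v
    }
    obj <- function(v) {
        o <- predictScore(model, matrix(v, 1L))[1L, k]
        if (!is.finite(o)) stop("activation objective diverged", call. = FALSE)
        o
    }
    x <- .with_seed(seed, proj(stats::rnorm(d, sd = 0.01)))
    cur <- obj(x)
    trace <- cur
    step <- step_size
    for (i in seq_len(n_steps)) {
        g <- gradInputScore(model, matrix(x, 1L), k)[1L, ]
        gn <- sqrt(sum(g^2))
        if (gn < 1e-12) break
        accepted <- FALSE
        while (step > 1e-10) {
            cand <- proj(x + step * g / gn)
            o <- obj(cand)
            if (o >= cur) {
                x <- cand; cur <- o
                trace <- c(trace, o)
                step <- step * 1.5
                accepted <- TRUE
                break
            }
            step <- step / 2
        }
        if (!accepted) break
    }
    names(x) <- model@featureNames
    list(x_star = x, objective = trace, importance = abs(x))
}

#' DeepLIFT contributions (rescale rule)
#'
#' Decomposes the difference between the class score at \code{x} and at a
#' reference input into per-gene contributions. Each nonlinearity
#' propagates the finite-difference multiplier
#' \code{(f(z) - f(z_ref)) / (z - z_ref)} instead of the local gradient;
#' where activation and reference pre-activation coincide (difference
#' below \code{1e-7}) the multiplier falls back to the local gradient.
#' Contributions satisfy completeness: they sum to
#' \code{score(x) - score(baseline)}.
#'
#' @param model an [MLPClassifier-class] (affine layers + ReLU).
#' @param x cells x genes matrix.
#' @param baseline reference input: a single vector of length n_genes.
#' @param class_index class position or label.
#' @return contributions matrix of the same shape as \code{x}.
#' @export
deepliftRescale <- function(model, x, baseline, class_index) {
    X <- .xy(x)$X
    .check_features(model, X)
    b <- as.numeric(baseline)
    if (length(b) != ncol(X))
        stop("baseline length must equal the number of genes", call. = FALSE)
    k <- .class_index(model, class_index)
    par <- .mlp_par(model)
    fx <- .mlp_forward(par, X)
    fb <- .mlp_forward(par, matrix(b, 1L))
    L <- length(par$W)
    n <- nrow(X)
    delta <- matrix(0, n, length(model@classes))
    delta[, k] <- 1
    for (l in rev(seq_len(L))) {
        delta <- tcrossprod(delta, par$W[[l]])
        if (l > 1L) {
            Z <- fx$Z[[l - 1L]]
            A <- fx$A[[l]]
            Zb <- fb$Z[[l - 1L]][1L, ]
            Ab <- fb$A[[l]][1L, ]
            dz <- sweep(Z, 2L, Zb)
            da <- sweep(A, 2L, Ab)
            mult <- ifelse(abs(dz) > 1e-7, da / ifelse(dz == 0, 1, dz),
                           (Z > 0) * 1)
            delta <- delta * mult
        }
    }
    contrib <- delta * sweep(X, 2L, b)
    dimnames(contrib) <- dimnames(X)
    contrib
}

#' Expected gradients (SHAP-style path attribution)
#'
#' Monte-Carlo estimate of
#' \code{E[ grad score(x' + t (x - x')) * (x - x') ]} with baselines
#' \code{x'} drawn from a reference pool and interpolation coefficients
#' \code{t} drawn uniformly on [0, 1]. For a linear model the per-sample
#' term is exact, so the estimate converges to
#' \code{w * (x - mean(baseline))}.
#'
#' @param model an [MLPClassifier-class].
#' @param x cells x genes matrix.
#' @param baselines reference pool, cells x genes matrix (>= 1 row).
#' @param class_index class position or label.
#' @param n_samples number of Monte-Carlo samples (default 25).
#' @param seed seed.
#' @return attribution matrix of the same shape as \code{x}.
#' @export
expectedGradients <- function(model, x, baselines, class_index,
                              n_samples = 25L, seed = 1L) {
    X <- .xy(x)$X
    .check_features(model, X)
    B <- .xy(baselines)$X
    if (nrow(B) < 1L) stop("baseline pool is empty", call. = FALSE)
    if (n_samples < 1L) stop("'n_samples' must be >= 1", call. = FALSE)
    k <- .class_index(model, class_index)
    n <- nrow(X)
    acc <- matrix(0, n, ncol(X))
    .with_seed(seed, {
        for (s in seq_len(n_samples)) {
            bi <- sample.int(nrow(B), n, replace = TRUE)
            tt <- stats::runif(n)
            diff <- X - B[bi, , drop = FALSE]
            pt <- B[bi, , drop = FALSE] + diff * tt
            G <- gradInputScore(model, pt, k)
            acc <- acc + G * diff
        }
    })
    out <- acc / n_samples
    dimnames(out) <- dimnames(X)
    out
}

# Shapley kernel weight for a coalition of size s out of d players.
.shapley_kernel <- function(d, s) {
    (d - 1) / (choose(d, s) * s * (d - s))
}

#' Kernel SHAP per-gene Shapley estimates
#'
#' Approximates Shapley values for one cell by weighted least squares over
#' feature coalitions: masked features are replaced by the baseline value,
#' coalitions are weighted by the Shapley kernel, and the completeness
#' constraint (estimates sum to \code{score(x) - score(baseline)}) is
#' enforced by eliminating one feature from the regression. When
#' \code{2^d - 2 <= n_coalitions} every non-trivial coalition is
#' enumerated with its analytic kernel weight and the result equals the
#' exact Shapley value; otherwise coalitions are sampled from the kernel's
#' size distribution.
#'
#' @param model an [MLPClassifier-class] (or any function of a cells x
#'   genes matrix returning a score per row, for testing).
#' @param x a single cell: vector of length n_genes or 1 x n_genes matrix.
#' @param baseline reference vector of length n_genes.
#' @param class_index class position or label (ignored when \code{model}
#'   is a plain function).
#' @param n_coalitions number of coalitions (>= n_genes + 2); default
#'   enumerates fully up to d = 12 and uses \code{d + 200} samples above.
#' @param seed seed for coalition sampling.
#' @return named numeric vector of Shapley estimates, one per gene.
#' @export
kernelShap <- function(model, x, baseline, class_index = 1L,
                       n_coalitions = NULL, seed = 1L) {
    xv <- as.numeric(x)
    d <- length(xv)
    b <- as.numeric(baseline)
    if (length(b) != d) stop("baseline length mismatch", call. = FALSE)
    f <- if (is.function(model)) {
        function(M) as.numeric(model(M))
    } else {
        k <- .class_index(model, class_index)
        function(M) predictScore(model, M)[, k]
    }
    full_enum <- d <= 12 && (is.null(n_coalitions) || 2^d - 2 <= n_coalitions)
    if (is.null(n_coalitions))
        n_coalitions <- if (full_enum) 2^d - 2 else d + 200L
    if (!full_enum && n_coalitions < d + 2)
        stop("'n_coalitions' must be at least n_genes + 2", call. = FALSE)

    if (full_enum) {
        nz <- 2^d - 2
        Z <- matrix(0, nz, d)
        for (i in seq_len(nz))
            Z[i, ] <- as.integer(intToBits(i)[seq_len(d)])
        w <- .shapley_kernel(d, rowSums(Z))
    } else {
        sizes <- seq_len(d - 1L)
        p <- (d - 1) / (sizes * (d - sizes))
        Z <- .with_seed(seed, {
            s <- sample(sizes, n_coalitions, replace = TRUE, prob = p / sum(p))
            t(vapply(s, function(si) {
                z <- numeric(d); z[sample.int(d, si)] <- 1; z
            }, numeric(d)))
        })
        w <- rep(1, nrow(Z))  # sampled in proportion to the kernel
    }

    Xmask <- Z * rep(xv, each = nrow(Z)) + (1 - Z) * rep(b, each = nrow(Z))
    y <- f(Xmask)
    f0 <- f(matrix(b, 1L))
    fx <- f(matrix(xv, 1L))
    Delta <- fx - f0

    # eliminate the last feature to impose sum(phi) = Delta
    A <- Z[, -d, drop = FALSE] - Z[, d]
    yadj <- y - f0 - Z[, d] * Delta
    AtW <- t(A * w)
    phi_rest <- tryCatch(
        solve(AtW %*% A, AtW %*% yadj),
        error = function(e)
            stop("kernel SHAP regression is singular; increase n_coalitions",
                 call. = FALSE))
    phi <- c(as.numeric(phi_rest), Delta - sum(phi_rest))
    names(phi) <- if (!is.null(names(xv))) names(xv) else
        if (is.function(model)) paste0("f", seq_len(d)) else model@featureNames
    phi
}

#' LIME surrogate coefficients for one cell
#'
#' Fits a locally weighted ridge surrogate to the model's class score on
#' Gaussian perturbations of the cell. Perturbations are weighted by the
#' exponential kernel \code{exp(-dist^2 / kernel_width^2)}; the
#' interpretable-model complexity penalty is realised by keeping only the
#' \code{n_features_kept} largest-magnitude coefficients of a full ridge
#' fit and refitting on those. The returned vector has one coefficient
#' per gene (zero for genes not kept).
#'
#' @param model an [MLPClassifier-class] or a plain score function.
#' @param x a single cell (vector or 1-row matrix).
#' @param class_index class position or label.
#' @param n_perturbations number of perturbed samples (>= 10, default
#'   1000).
#' @param kernel_width locality kernel width; default
#'   \code{0.75 * sqrt(n_genes)}.
#' @param n_features_kept surrogate sparsity (default 50).
#' @param perturb_sd standard deviation of the Gaussian perturbations
#'   (scalar or per-gene vector, default 1: one standardized unit).
#' @param lambda ridge penalty (default 1).
#' @param seed seed.
#' @return named numeric coefficient vector of length n_genes.
#' @export
limeTabular <- function(model, x, class_index = 1L, n_perturbations = 1000L,
                        kernel_width = NULL, n_features_kept = 50L,
                        perturb_sd = 1, lambda = 1, seed = 1L) {
    xv <- as.numeric(x)
    d <- length(xv)
    if (n_perturbations < 10L)
        stop("'n_perturbations' must be >= 10", call. = FALSE)
    if (is.null(kernel_width)) kernel_width <- 0.75 * sqrt(d)
    if (kernel_width <= 0) stop("'kernel_width' must be > 0", call. = FALSE)
    f <- if (is.function(model)) {
        function(M) as.numeric(model(M))
    } else {
        k <- .class_index(model, class_index)
        function(M) predictScore(model, M)[, k]
    }
    n_features_kept <- min(as.integer(n_features_kept), d)

    Xp <- .with_seed(seed,
        matrix(stats::rnorm(n_perturbations * d, sd = perturb_sd),
               n_perturbations, d, byrow = TRUE) +
            rep(xv, each = n_perturbations))
    y <- f(Xp)
    dist2 <- rowSums(sweep(Xp, 2L, xv)^2)
    w <- exp(-dist2 / kernel_width^2)
    if (sum(w) < 1e-12)
        stop("kernel width leaves no mass on the perturbations", call. = FALSE)

    ridge_fit <- function(cols) {
        Xc <- Xp[, cols, drop = FALSE]
        wm <- colSums(Xc * w) / sum(w)
        ym <- sum(y * w) / sum(w)
        Xc <- sweep(Xc, 2L, wm)
        yc <- y - ym
        XtW <- t(Xc * w)
        beta <- solve(XtW %*% Xc + diag(lambda, length(cols)), XtW %*% yc)
        as.numeric(beta)
    }
    beta_full <- ridge_fit(seq_len(d))
    coef <- numeric(d)
    if (n_features_kept == d) {
        coef <- beta_full
    } else {
        keep <- sort(order(-abs(beta_full))[seq_len(n_features_kept)])
        coef[keep] <- ridge_fit(keep)
    }
    names(coef) <- if (!is.null(names(xv))) names(xv) else
        if (is.function(model)) paste0("f", seq_len(d)) else model@featureNames
    coef
}

#' Aggregate per-cell attributions to a gene x cell-type matrix
#'
#' For every cell type, attribution is computed for that type's output
#' class on a subset of its correctly classified cells, and the per-gene
#' score is the mean absolute attribution across those cells (so opposing
#' signs do not cancel). If a type has no correctly classified cell the
#' aggregation falls back to all cells of the type, with a warning.
#' Activation maximization is the exception: it constructs one synthetic
#' input per class and uses its absolute coordinates directly.
#'
#' @param model an [MLPClassifier-class].
#' @param x labeled cells (SCE with \code{"scaled"} assay, or matrix).
#' @param labels per-cell labels when \code{x} is a matrix.
#' @param method one of \code{"saliency"}, \code{"actmax"},
#'   \code{"deeplift"}, \code{"expgrad"}, \code{"kernelshap"},
#'   \code{"lime"}.
#' @param reference training cells used to build baselines (mean vector
#'   for DeepLIFT and kernel SHAP, sampled pool for expected gradients);
#'   defaults to \code{x} itself.
#' @param cells_per_type maximum number of correctly classified cells
#'   aggregated per type (default 5; attribution cost scales linearly in
#'   this for the perturbation-based methods).
#' @param n_baseline_samples pool size for expected gradients (default
#'   25).
#' @param seed seed controlling cell subsampling and the stochastic
#'   methods.
#' @param ... further arguments to the underlying method (e.g.
#'   \code{n_coalitions}, \code{n_perturbations}).
#' @return an [AttributionMatrix-class].
#' @export
perClassImportance <- function(model, x, labels = NULL,
                               method = c("saliency", "actmax", "deeplift",
                                          "expgrad", "kernelshap", "lime"),
                               reference = NULL, cells_per_type = 5L,
                               n_baseline_samples = 25L, seed = 1L, ...) {
    method <- match.arg(method)
    d <- .xy(x, labels)
    X <- d$X; y <- d$y
    .check_features(model, X)
    cls <- model@classes
    genes <- model@featureNames
    R <- if (is.null(reference)) X else .xy(reference)$X
    base_mean <- colMeans(R)
    scores <- matrix(0, length(genes), length(cls),
                     dimnames = list(genes, cls))
    n_cells <- integer(length(cls))

    if (method == "actmax") {
        for (k in seq_along(cls)) {
            am <- activationMaximization(model, k, seed = seed, ...)
            scores[, k] <- am$importance
        }
        return(methods::new("AttributionMatrix", method = method,
                            scores = scores, nCells = n_cells,
                            baseline = "none (constructed input)"))
    }

    pred <- predictClass(model, X)
    eg_pool <- .with_seed(seed,
        R[sample.int(nrow(R), min(n_baseline_samples, nrow(R))), ,
          drop = FALSE])
    for (k in seq_along(cls)) {
        idx <- which(y == cls[k])
        if (!length(idx)) {
            warning(sprintf(
                "no cells of type '%s' in the data; its scores stay zero",
                cls[k]), call. = FALSE)
            next
        }
        ok <- idx[pred[idx] == cls[k]]
        if (!length(ok)) {
            warning(sprintf(
                "no correctly classified cell of type '%s'; using all its cells",
                cls[k]), call. = FALSE)
            ok <- idx
        }
        chosen <- .with_seed(seed + k,
            if (length(ok) > cells_per_type) sort(sample(ok, cells_per_type))
            else ok)
        Xi <- X[chosen, , drop = FALSE]
        A <- switch(method,
            saliency = saliencyMap(model, Xi, k),
            deeplift = deepliftRescale(model, Xi, base_mean, k),
            expgrad = expectedGradients(model, Xi, eg_pool, k,
                                        seed = seed + k, ...),
            kernelshap = t(vapply(seq_len(nrow(Xi)), function(i)
                kernelShap(model, Xi[i, ], base_mean, k,
                           seed = seed + k + i, ...),
                numeric(ncol(Xi)))),
            lime = t(vapply(seq_len(nrow(Xi)), function(i)
                limeTabular(model, Xi[i, ], k, seed = seed + k + i, ...),
                numeric(ncol(Xi)))))
        scores[, k] <- colMeans(abs(A))
        n_cells[k] <- nrow(Xi)
    }
    baseline_desc <- switch(method,
        saliency = "none (raw gradient)",
        deeplift = , kernelshap = "reference mean vector",
        expgrad = sprintf("%d sampled reference cells", nrow(eg_pool)),
        lime = "Gaussian perturbations around each cell")
    methods::new("AttributionMatrix", method = method, scores = scores,
                 nCells = n_cells, baseline = baseline_desc)
}
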