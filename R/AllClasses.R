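#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment assay assay<- assayNames colData colData<-
#' @importFrom SingleCellExperiment SingleCellExperiment
NULL

#' Multilayer perceptron cell-type classifier
#'
#' A fully connected feed-forward network with ReLU hidden layers and a
#' linear (pre-softmax) output layer, one output unit per cell type.
#' The class stores the weights explicitly so that exact input gradients
#' of both the cross-entropy loss and any class score can be computed by
#' backpropagation; those gradients are the contract consumed by the
#' adversarial attacks and by every gradient-based attribution method.
#'
#' @slot weights list of weight matrices, one per layer; layer \code{l}
#'   maps \code{ncol(weights[[l-1]])} inputs to \code{ncol(weights[[l]])}
#'   outputs (inputs are cells-in-rows, so the forward map is
#'   \code{X \%*\% W + b}).
#' @slot biases list of bias vectors matching \code{weights}.
#' @slot hidden integer vector of hidden layer widths.
#' @slot classes character vector, the label vocabulary; output unit
#'   \code{k} scores class \code{classes[k]}.
#' @slot featureNames character vector of gene identifiers the model was
#'   trained on, in column order.
#' @slot history numeric vector of mean training loss per epoch.
#'
#' @seealso [trainClassifier()], [gradInputLoss()], [gradInputScore()]
#' @export
setClass("MLPClassifier",
    representation(
        weights      = "list",
        biases       = "list",
        hidden       = "integer",
        classes      = "character",
        featureNames = "character",
        history      = "numeric"
    )
)

setValidity("MLPClassifier", function(object) {
    nl <- length(object@weights)
    if (nl != length(object@biases))
        return("weights and biases differ in length")
    if (nl != length(object@hidden) + 1L)
        return("need exactly one weight matrix per hidden layer plus the output layer")
    for (l in seq_len(nl)) {
        if (ncol(object@weights[[l]]) != length(object@biases[[l]]))
            return(sprintf("bias length mismatch in layer %d", l))
        if (l > 1L && nrow(object@weights[[l]]) != ncol(object@weights[[l - 1L]]))
            return(sprintf("weight shape mismatch between layers %d and %d", l - 1L, l))
    }
    if (ncol(object@weights[[nl]]) != length(object@classes))
        return("output width must equal the number of classes")
    if (nrow(object@weights[[1L]]) != length(object@featureNames))
        return("input width must equal the number of feature names")
    TRUE
})

#' Per-method gene-by-cell-type attribution scores
#'
#' Container for the output of one attribution method aggregated to the
#' cell-type level: a genes x cell-types matrix of non-negative importance
#' scores, together with how many cells contributed per type and a
#' description of the baseline (reference input) the method used.
#'
#' @slot method single string naming the attribution method.
#' @slot scores numeric matrix, genes in rows, cell types in columns.
#' @slot nCells integer vector, cells aggregated per cell type (0 for
#'   methods such as activation maximization that construct a single
#'   synthetic input per class).
#' @slot baseline single string describing the reference input.
#' @export
setClass("AttributionMatrix",
    representation(
        method   = "character",
        scores   = "matrix",
        nCells   = "integer",
        baseline = "character"
    )
)

setValidity("AttributionMatrix", function(object) {
    if (length(object@method) != 1L) return("method must be a single string")
    if (!is.numeric(object@scores)) return("scores must be numeric")
    if (any(!is.finite(object@scores))) return("scores must be finite")
    if (is.null(rownames(object@scores)) || is.null(colnames(object@scores)))
        return("scores must carry gene rownames and cell-type colnames")
    if (length(object@nCells) != ncol(object@scores))
        return("nCells must have one entry per cell type")
    TRUE
})

#' Consensus importance votes across attribution methods
#'
#' For every (gene, cell type) pair, the number of attribution methods that
#' rank the gene among their top-N genes for that type. Votes range from 0
#' to the number of contributing methods (six for the full method panel).
#' A secondary mean normalized score is kept to order genes with equal
#' votes.
#'
#' @slot votes integer matrix, genes x cell types, each entry in
#'   \code{0..length(methods)}.
#' @slot meanScore numeric matrix of per-method max-normalized scores
#'   averaged across methods; used only to break vote ties.
#' @slot nTop integer, the N of the top-N membership rule.
#' @slot methods character vector of contributing method names.
#' @export
setClass("ConsensusTable",
    representation(
        votes     = "matrix",
        meanScore = "matrix",
        nTop      = "integer",
        methods   = "character"
    )
)

setValidity("ConsensusTable", function(object) {
    if (!all(object@votes >= 0L & object@votes <= length(object@methods)))
        return("votes must lie in 0..number of methods")
    if (object@nTop < 1L) return("nTop must be >= 1")
    if (!identical(dim(object@votes), dim(object@meanScore)))
        return("votes and meanScore must share dimensions")
    TRUE
})

#' @describeIn MLPClassifier compact description of architecture and classes
#' @param object an \code{MLPClassifier}
#' @export
setMethod("show", "MLPClassifier", function(object) {
    cat(sprintf(
        "MLPClassifier: %d -> %s -> %d classes (ReLU hidden, linear output)\n",
        length(object@featureNames),
        if (length(object@hidden)) paste(object@hidden, collapse = " -> ") else "(no hidden)",
        length(object@classes)))
    cat("classes:", paste(object@classes, collapse = ", "), "\n")
    if (length(object@history))
        cat(sprintf("trained %d epochs; loss %.4f -> %.4f\n",
                    length(object@history),
                    object@history[1L], object@history[length(object@history)]))
    invisible(NULL)
})

#' @describeIn AttributionMatrix summary of dimensions and top score
#' @param object an \code{AttributionMatrix}
#' @export
setMethod("show", "AttributionMatrix", function(object) {
    cat(sprintf("AttributionMatrix '%s': %d genes x %d cell types (baseline: %s)\n",
                object@method, nrow(object@scores), ncol(object@scores),
                object@baseline))
    invisible(NULL)
})

#' @describeIn ConsensusTable summary of vote distribution
#' @param object a \code{ConsensusTable}
#' @export
setMethod("show", "ConsensusTable", function(object) {
    cat(sprintf("ConsensusTable: %d genes x %d cell types, %d methods, top-%d rule\n",
                nrow(object@votes), ncol(object@votes),
                length(object@methods), object@nTop))
    print(table(votes = as.vector(object@votes)))
    invisible(NULL)
})

# ---- accessors ----

#' @rdname MLPClassifier-accessors
#' @param object an \code{MLPClassifier}
#' @return \code{modelClasses}: the label vocabulary.
#' @export
modelClasses <- function(object) object@classes

#' Accessors for MLPClassifier
#'
#' @name MLPClassifier-accessors
#' @param object an \code{MLPClassifier}
#' @return \code{architecture}: list with the input width, hidden widths
#'   and number of classes. \code{trainingHistory}: per-epoch mean loss.
#' @export
architecture <- function(object) {
    list(n_features = length(object@featureNames),
         hidden     = object@hidden,
         n_classes  = length(object@classes))
}

#' @rdname MLPClassifier-accessors
#' @export
trainingHistory <- function(object) object@history

#' @rdname AttributionMatrix-accessors
#' @name AttributionMatrix-accessors
#' @title Accessors for AttributionMatrix and ConsensusTable
#' @param object an \code{AttributionMatrix} or \code{ConsensusTable}
#' @return \code{attributionScores}: the genes x cell-types score matrix;
#'   \code{attributionMethod}: the method name; \code{consensusVotes}: the
#'   integer vote matrix.
#' @export
attributionScores <- function(object) object@scores

#' @rdname AttributionMatrix-accessors
#' @export
attributionMethod <- function(object) object@method

#' @rdname AttributionMatrix-accessors
#' @export
consensusVotes <- function(object) object@votes
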