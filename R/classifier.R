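# Linear maximum-margin classification. All decoding in the package goes
# through .fitLinearSVM / .svmDecision so the fitted weight vector is
# applied directly to test patterns (identical to predict() on the model,
# verified in the test suite, but without its per-call overhead).

.fitLinearSVM <- function(trainX, trainY, cost = 1) {
    y <- factor(trainY)
    if (nlevels(y) != 2L)
        stop("degenerate training set: exactly 2 classes required, got ",
             nlevels(y))
    m <- e1071::svm(trainX, y, kernel = "linear", cost = cost,
                    scale = FALSE)
    w <- crossprod(m$coefs, m$SV)  # 1 x p weight vector
    list(w = as.numeric(w), rho = m$rho,
         positive = m$levels[m$labels[1L]],
         negative = m$levels[m$labels[2L]])
}

.svmDecision <- function(model, testX) {
    drop(testX %*% model$w) - model$rho
}

.svmPredict <- function(model, testX) {
    ifelse(.svmDecision(model, testX) > 0, model$positive,
           model$negative)
}

#' Train and test a binary linear classifier
#'
#' Fits a linear C-support-vector classifier (libsvm, no feature scaling,
#' regularization constant \code{cost}) on the training patterns and
#' returns the percentage of correctly classified test patterns. Chance
#' level is 50\% for balanced binary problems.
#'
#' @param trainX,testX numeric matrices, samples x features.
#' @param trainY,testY class labels (exactly two classes in
#'   \code{trainY}; \code{testY} drawn from the same two classes).
#' @param cost regularization constant C (default 1, untuned).
#' @return Accuracy in percent.
#' @examples
#' tr <- rbind(matrix(rnorm(20, -3), 10), matrix(rnorm(20, 3), 10))
#' y <- rep(c("a", "b"), each = 10)
#' trainTestLinear(tr, y, tr, y)  # separable: 100
#' @export
trainTestLinear <- function(trainX, trainY, testX, testY, cost = 1) {
    stopifnot(is.matrix(trainX), is.matrix(testX),
              nrow(trainX) == length(trainY),
              nrow(testX) == length(testY))
    if (!all(testY %in% unique(trainY)))
        stop("test labels must be drawn from the training classes")
    model <- .fitLinearSVM(trainX, trainY, cost = cost)
    mean(.svmPredict(model, testX) == as.character(testY)) * 100
}
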