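#' Train the stage-1 superclass classifier
#'
#' Maps time-domain feature vectors to gesture superclasses with a classical
#' lightweight method. The default is an RBF-kernel SVM with penalty C = 18
#' (the middle of the 15-20 range that works well for this task) and the
#' "scale" gamma heuristic `1 / (n_features * var(X))`.
#'
#' @param features Feature table from [extract_feature_table()] (needs a
#'   `superclass` column and `ch*` feature columns), or a plain numeric
#'   matrix/data.frame of features if `superclass` is given separately.
#' @param superclass Optional integer vector of superclass ids (otherwise
#'   taken from the table).
#' @param method One of `"svm"`, `"rf"` (random forest), `"dt"` (decision
#'   tree), `"knn"` (k = 5), `"nb"` (naive Bayes), `"lda"`.
#' @param seed Seed for the stochastic learners (rf).
#' @param cost,gamma SVM hyperparameters; `gamma = NULL` uses the scale
#'   heuristic.
#' @return A `stage1_model` with a [predict.stage1_model()] method.
#' @export
train_stage1 <- function(features, superclass = NULL, method = "svm",
                         seed = 1L, cost = 18, gamma = NULL) {
  X <- stage1_feature_matrix(features)
  if (is.null(superclass)) {
    if (!"superclass" %in% names(features))
      stop("no superclass labels supplied", call. = FALSE)
    superclass <- features$superclass
  }
  y <- factor(as.integer(superclass))
  if (nlevels(y) < 2L)
    stop("stage-1 training needs at least 2 superclasses present",
         call. = FALSE)
  if (nrow(X) != length(y)) stop("feature/label length mismatch", call. = FALSE)
  method <- match.arg(method, c("svm", "rf", "dt", "knn", "nb", "lda"))
  set.seed(seed)
  fit <- switch(method,
    svm = {
      if (is.null(gamma)) gamma <- 1 / (ncol(X) * stats::var(as.vector(X)))
      e1071::svm(X, y, kernel = "radial", cost = cost, gamma = gamma)
    },
    rf = randomForest::randomForest(X, y),
    dt = {
      df <- data.frame(.y = y, X)
      rpart::rpart(.y ~ ., data = df, method = "class")
    },
    knn = list(X = X, y = y, k = 5L),
    nb = e1071::naiveBayes(X, y),
    lda = MASS::lda(X, grouping = y))
  structure(list(method = method, fit = fit,
                 feature_cols = colnames(X), seed = as.integer(seed)),
            class = "stage1_model")
}

stage1_feature_matrix <- function(features) {
  if (is.matrix(features)) {
    X <- features
  } else {
    cols <- grep("^ch[0-9]+_", names(features), value = TRUE)
    if (!length(cols)) {
      X <- as.matrix(features[vapply(features, is.numeric, logical(1))])
    } else {
      X <- as.matrix(features[cols])
    }
  }
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  X
}

#' Predict superclasses with a stage-1 model
#' @param object A `stage1_model`.
#' @param features As in [train_stage1()].
#' @param ... Unused.
#' @return Integer superclass ids.
#' @export
predict.stage1_model <- function(object, features, ...) {
  X <- stage1_feature_matrix(features)
  colnames(X) <- object$feature_cols
  pred <- switch(object$method,
    svm = stats::predict(object$fit, X),
    rf = stats::predict(object$fit, X),
    dt = {
      p <- stats::predict(object$fit, data.frame(X), type = "class")
      p
    },
    knn = class::knn(object$fit$X, X, object$fit$y, k = object$fit$k),
    nb = stats::predict(object$fit, X),
    lda = stats::predict(object$fit, X)$class)
  as.integer(as.character(pred))
}
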