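# Filter feature selection (ANOVA F) and the five-classifier bank behind one
# S3 fitting function with deterministic training/prediction contracts.

ALGORITHMS <- c("knn", "svm", "dt", "nb", "etc")

#' ANOVA-F filter scores per feature
#'
#' One-way F statistic of each feature against the binary class labels:
#' between-class mean square over within-class mean square. Higher scores
#' mean stronger class separation. A feature with zero between-class
#' difference and zero within-class variance scores 0.
#'
#' @param x numeric feature matrix (rows = segments).
#' @param labels binary 0/1 labels, both classes present.
#' @return named numeric vector of F scores, one per column.
#' @export
filter_scores <- function(x, labels) {
  x <- as.matrix(x)
  if (nrow(x) != length(labels)) stop("labels must align with rows", call. = FALSE)
  if (!is_binary(labels)) stop("labels must be binary 0/1", call. = FALSE)
  if (length(unique(labels)) < 2) stop("both classes must be present", call. = FALSE)
  g0 <- labels == 0; g1 <- !g0
  n0 <- sum(g0); n1 <- sum(g1); n <- n0 + n1
  vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    m0 <- mean(v[g0]); m1 <- mean(v[g1]); gm <- mean(v)
    ssb <- n0 * (m0 - gm)^2 + n1 * (m1 - gm)^2
    ssw <- sum((v[g0] - m0)^2) + sum((v[g1] - m1)^2)
    if (ssw == 0) {
      if (ssb == 0) 0 else Inf
    } else {
      (ssb / 1) / (ssw / (n - 2))
    }
  }, numeric(1), USE.NAMES = FALSE) -> f
  names(f) <- colnames(x)
  f
}

#' Indices of the k highest-scoring features
#'
#' Ties are broken in favor of the lower column index, so the selection is
#' deterministic.
#'
#' @param scores numeric score vector.
#' @param k number of features to keep, `1 <= k <= length(scores)`.
#' @return integer index vector of length `k`.
#' @export
select_top_k <- function(scores, k = 10) {
  if (k < 1 || k > length(scores))
    stop(sprintf("`k` must be in 1..%d", length(scores)), call. = FALSE)
  order(-scores, seq_along(scores))[seq_len(k)]
}

#' Fit a spindle frame classifier
#'
#' One fitting surface over five algorithms: k-nearest neighbors (`"knn"`,
#' k = 5, Euclidean), RBF support vector machine (`"svm"`, C = 1,
#' gamma = 1/d), CART decision tree (`"dt"`, Gini, effectively unlimited
#' depth), Gaussian naive Bayes (`"nb"`), and extremely randomized trees
#' (`"etc"`, 100 trees). Features are z-score standardized from the
#' training rows only; the stored centering/scaling is reapplied at
#' prediction time, so no test-set statistics leak into training.
#' Training is deterministic given `seed`.
#'
#' @param x numeric feature matrix with column names (rows = segments).
#' @param labels binary 0/1 labels, at least two rows per class.
#' @param algorithm one of `"knn"`, `"svm"`, `"dt"`, `"nb"`, `"etc"`.
#' @param hyperparameters named list overriding the defaults above
#'   (`k` for knn; `cost`, `gamma` for svm; `num_trees` for etc).
#' @param seed integer seed funnelled to every stochastic component.
#' @param selected optional integer vector of feature columns to use
#'   (e.g. from [select_top_k()]); default all columns.
#' @return object of class `spindle_classifier`.
#' @seealso [predict.spindle_classifier()]
#' @export
spindle_classifier <- function(x, labels, algorithm = ALGORITHMS,
                               hyperparameters = list(), seed = 1L,
                               selected = NULL) {
  if (length(algorithm) != 1L || !algorithm %in% ALGORITHMS)
    stop("`algorithm` must be one of: ", paste(ALGORITHMS, collapse = ", "),
         call. = FALSE)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (nrow(x) != length(labels)) stop("labels must align with rows", call. = FALSE)
  if (!is_binary(labels)) stop("labels must be binary 0/1", call. = FALSE)
  if (min(table(labels)) < 2 || length(unique(labels)) < 2)
    stop("need at least two rows per class", call. = FALSE)
  if (is.null(selected)) selected <- seq_len(ncol(x))
  if (!length(selected) || any(selected < 1 | selected > ncol(x)))
    stop("`selected` must be non-empty column indices", call. = FALSE)
  xs <- x[, selected, drop = FALSE]

  center <- colMeans(xs)
  scale_ <- apply(xs, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  z <- sweep(sweep(xs, 2, center), 2, scale_, "/")
  y <- factor(labels, levels = c(0, 1))

  hp <- hyperparameters
  fit <- with_seed(seed, switch(
    algorithm,
    knn = list(train_z = z, train_y = labels,
               k = if (is.null(hp$k)) 5L else as.integer(hp$k)),
    svm = e1071::svm(z, y, kernel = "radial",
                     cost = if (is.null(hp$cost)) 1 else hp$cost,
                     gamma = if (is.null(hp$gamma)) 1 / ncol(z) else hp$gamma,
                     scale = FALSE),
    dt = rpart::rpart(y ~ ., data = data.frame(z, y = y),
                      method = "class",
                      parms = list(split = "gini"),
                      control = rpart::rpart.control(cp = 0, minsplit = 2,
                                                     xval = 0)),
    nb = e1071::naiveBayes(z, y),
    etc = ranger::ranger(y = y, x = as.data.frame(z),
                         num.trees = if (is.null(hp$num_trees)) 100L else hp$num_trees,
                         splitrule = "extratrees",
                         probability = TRUE,
                         num.threads = 1L,
                         seed = seed)))

  structure(list(algorithm = algorithm, fit = fit,
                 center = center, scale = scale_,
                 feature_names = colnames(x), selected = selected,
                 hyperparameters = hp, seed = as.integer(seed),
                 n_train = nrow(x), class_balance = mean(labels)),
            class = "spindle_classifier")
}

#' @export
print.spindle_classifier <- function(x, ...) {
  cat(sprintf("Spindle frame classifier (%s)\n", toupper(x$algorithm)))
  cat(sprintf("  trained on %d segments (%.1f%% spindle frames), %d of %d features\n",
              x$n_train, 100 * x$class_balance, length(x$selected),
              length(x$feature_names)))
  cat("  features:", paste(x$feature_names[x$selected], collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.spindle_classifier <- function(object, ...) {
  print(object)
  cat(sprintf("  seed %d; standardization learned from training rows only\n",
              object$seed))
  invisible(object)
}

knn_scores <- function(fit, z) {
  tz <- fit$train_z; ty <- fit$train_y; k <- fit$k
  apply(z, 1, function(row) {
    d <- sqrt(colSums((t(tz) - row)^2))
    nn <- order(d, seq_along(d))[seq_len(k)]   # distance ties -> lower row index
    mean(ty[nn])
  })
}

#' Predict spindle presence for new segments
#'
#' `type = "score"` returns a positive-class score in `[0, 1]` (KNN:
#' positive-neighbor fraction; SVM: logistic of the decision value; tree
#' models: positive-class probability/vote share); `type = "class"`
#' thresholds the score at 0.5.
#'
#' @param object a [spindle_classifier()].
#' @param newdata feature matrix whose columns match the training columns.
#' @param type `"class"` (default) or `"score"`.
#' @param ... unused.
#' @return numeric vector: 0/1 labels or scores in `[0, 1]`.
#' @export
predict.spindle_classifier <- function(object, newdata,
                                       type = c("class", "score"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata)))
    colnames(newdata) <- paste0("V", seq_len(ncol(newdata)))
  missing <- setdiff(object$feature_names, colnames(newdata))
  if (length(missing))
    stop("newdata lacks feature column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  xs <- newdata[, object$feature_names[object$selected], drop = FALSE]
  z <- sweep(sweep(xs, 2, object$center), 2, object$scale, "/")

  scores <- switch(
    object$algorithm,
    knn = knn_scores(object$fit, z),
    svm = {
      dec <- attr(stats::predict(object$fit, z, decision.values = TRUE),
                  "decision.values")
      # decision values are oriented toward the first factor level
      if (grepl("^0/1", colnames(dec)[1])) stats::plogis(-dec[, 1])
      else stats::plogis(dec[, 1])
    },
    dt = stats::predict(object$fit, data.frame(z), type = "prob")[, "1"],
    nb = stats::predict(object$fit, z, type = "raw")[, "1"],
    etc = stats::predict(object$fit, as.data.frame(z),
                         num.threads = 1L)$predictions[, "1"])
  scores <- pmin(pmax(as.numeric(scores), 0), 1)
  if (type == "score") scores else as.integer(scores >= 0.5)
}
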