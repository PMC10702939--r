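#' Decode a continuous position into a feature mask
#'
#' Wolves move in the continuous unit hypercube; a coordinate above
#' \code{threshold} selects the corresponding feature. If no coordinate
#' exceeds the threshold the single largest coordinate is selected (first on
#' ties), so a mask used for classification is never empty.
#'
#' @param position numeric vector with coordinates in [0, 1].
#' @param threshold selection cut-off (default 0.5; the comparison is strict).
#' @return Logical vector of the same length as \code{position}.
#' @export
binarize_position <- function(position, threshold = 0.5) {
  mask <- position > threshold
  if (!any(mask)) mask[which.max(position)] <- TRUE
  mask
}

#' k-nearest-neighbour classification on binary features
#'
#' Majority vote among the \code{k} nearest training rows by Hamming distance
#' (equivalent to squared Euclidean on 0/1 data). Ties are deterministic:
#' equal distances resolve by training-row order, and an even vote split
#' resolves to the label of the single nearest neighbour.
#'
#' @param train binary matrix of training documents (rows) by features.
#' @param labels binary (0/1) training labels, one per row of \code{train}.
#' @param query binary matrix of documents to classify, same columns.
#' @param k number of neighbours; \code{1 <= k <= nrow(train)}.
#' @return Integer vector of 0/1 predictions, one per query row.
#' @export
knn_predict <- function(train, labels, query, k = 5L) {
  train <- as.matrix(train)
  query <- as.matrix(query)
  if (nrow(train) == 0L) stop("empty training set", call. = FALSE)
  if (ncol(train) != ncol(query))
    stop("`train` and `query` must have the same columns", call. = FALSE)
  if (length(labels) != nrow(train))
    stop("one label per training row required", call. = FALSE)
  k <- as.integer(k)
  if (k < 1L || k > nrow(train))
    stop("`k` must satisfy 1 <= k <= nrow(train)", call. = FALSE)
  # Hamming distance via one matrix product: mismatches between binary rows
  # x and y equal sum(x) + sum(y) - 2 <x, y>
  storage.mode(train) <- "double"
  storage.mode(query) <- "double"
  d <- outer(rowSums(train), rowSums(query), "+") - 2 * tcrossprod(train, query)
  .knn_vote_cpp(d, as.integer(labels), k)
}

#' Fitness specification for wrapper feature selection
#'
#' The multi-objective fitness of a candidate feature subset S is
#' \deqn{w_1 \cdot \mathrm{acc}_{KNN} + w_2 \cdot \mathrm{FeaturesRatio}}
#' where the accuracy term is KNN validation accuracy on the selected
#' columns. With \code{feature_term = "reduction"} (the default) the ratio is
#' \eqn{(M - |S|)/M}, so fitness rewards smaller subsets at equal accuracy;
#' \code{"literal"} uses \eqn{|S|/M} instead.
#'
#' @param w1,w2 objective weights; must sum to 1 (defaults 0.9 and 0.1).
#' @param k_neighbors KNN neighbourhood size (default 5).
#' @param feature_term \code{"reduction"} or \code{"literal"} (see above).
#' @param threshold position binarization cut-off (default 0.5).
#' @return An object of class \code{"fitness_spec"}.
#' @export
fitness_spec <- function(w1 = 0.9, w2 = 0.1, k_neighbors = 5L,
                         feature_term = c("reduction", "literal"),
                         threshold = 0.5) {
  feature_term <- match.arg(feature_term)
  if (abs(w1 + w2 - 1) > 1e-12)
    stop("`w1 + w2` must equal 1", call. = FALSE)
  structure(list(w1 = w1, w2 = w2, k_neighbors = as.integer(k_neighbors),
                 feature_term = feature_term, threshold = threshold),
            class = "fitness_spec")
}

#' Score a feature mask
#'
#' Evaluates the wrapper fitness of one feature subset: KNN is fit on the
#' training rows restricted to the masked columns and scored on the
#' validation rows, then combined with the feature-ratio term.
#'
#' @param mask logical feature-selection vector (must select at least one
#'   feature).
#' @param x_train,y_train training documents and 0/1 labels.
#' @param x_val,y_val validation documents and labels, disjoint from training.
#' @param spec a \code{\link{fitness_spec}}.
#' @return A list with components \code{fitness}, \code{accuracy},
#'   \code{feature_ratio}, and \code{n_features}.
#' @export
mask_fitness <- function(mask, x_train, y_train, x_val, y_val,
                         spec = fitness_spec()) {
  mask <- as.logical(mask)
  ns <- sum(mask)
  if (ns == 0L) stop("mask selects no features", call. = FALSE)
  pred <- knn_predict(x_train[, mask, drop = FALSE], y_train,
                      x_val[, mask, drop = FALSE], spec$k_neighbors)
  acc <- mean(pred == y_val)
  m <- length(mask)
  ratio <- if (spec$feature_term == "reduction") (m - ns) / m else ns / m
  list(fitness = spec$w1 * acc + spec$w2 * ratio,
       accuracy = acc, feature_ratio = ratio, n_features = ns)
}
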