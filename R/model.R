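#' Wrapper feature selection with chaos-integrated grey wolf optimization
#'
#' Fits the depression-detection model: a grey wolf search (NI-GWO or one
#' of the chaotic CNI-GWO variants) over the continuous unit hypercube
#' selects a column subset of a binary document-term matrix; each candidate
#' subset is scored by the multi-objective fitness
#' \eqn{w_1 \cdot \mathrm{acc}_{KNN} + w_2 \cdot \mathrm{FeaturesRatio}}
#' on an internal validation holdout. The returned object classifies new
#' documents by KNN on the selected terms, which makes the model directly
#' interpretable: the fitted coefficients are the selected words.
#'
#' By default the fitness accuracy is measured on a stratified validation
#' fraction held out from the supplied training rows, so the final test set
#' never leaks into the search. Supply \code{x_val}/\code{y_val} to score
#' fitness on an external set instead (e.g. to mimic protocols that search
#' against the test split).
#'
#' @param x binary training matrix (documents x terms) or a \code{"dtm"}
#'   object (then \code{y} is taken from its labels).
#' @param y 0/1 labels, one per row of \code{x}.
#' @param variant optimizer variant: \code{"nigwo"}, \code{"cni1"} (chaotic
#'   initialization), \code{"cni2"}/\code{"cni3"}/\code{"cni4"} (chaotic
#'   \eqn{C_1}/\eqn{C_2}/\eqn{C_3}).
#' @param map a \code{\link{chaotic_map}}; ignored by \code{"nigwo"}.
#' @param pop_size,max_iter search budget (defaults 30 wolves, 100
#'   iterations).
#' @param seed integer seed covering the validation split and all uniform
#'   draws of the search.
#' @param spec a \code{\link{fitness_spec}} (weights, k, feature term,
#'   binarization threshold).
#' @param val_fraction fraction of training rows held out (stratified) for
#'   fitness evaluation; ignored when \code{x_val} is given.
#' @param x_val,y_val optional external validation data.
#' @param ... passed to \code{\link{gwo_optimize}} (e.g.
#'   \code{literal_distance}).
#' @return An object of class \code{"gwo_knn"}. Key elements:
#'   \code{mask} (logical selection over columns), \code{fitness} (best
#'   multi-objective value), \code{val_accuracy} (KNN accuracy of the best
#'   mask on the validation rows), \code{run} (the underlying
#'   \code{"gwo_run"} with its convergence history).
#' @seealso \code{\link{predict.gwo_knn}}, \code{\link{run_experiment}}
#' @examples
#' sim <- synth_dtm(synth_spec(n_docs = 120, vocab_size = 20,
#'                             n_informative = 4, seed = 1))
#' fit <- gwo_knn(sim$dtm, variant = "cni1", pop_size = 10, max_iter = 10,
#'                seed = 1)
#' fit
#' @export
gwo_knn <- function(x, y = NULL, variant = .gwo_variants,
                    map = chaotic_map("logistic"),
                    pop_size = 30L, max_iter = 100L, seed = NULL,
                    spec = fitness_spec(), val_fraction = 0.25,
                    x_val = NULL, y_val = NULL, ...) {
  cl <- match.call()
  variant <- match.arg(variant)
  if (inherits(x, "dtm")) {
    if (is.null(y)) y <- x$labels
    x <- x$x
  }
  x <- as.matrix(x)
  y <- as.integer(y)
  stopifnot(nrow(x) == length(y), all(y %in% 0:1))
  m <- ncol(x)

  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(x_val)) {
    idx_val <- .stratified_holdout(y, val_fraction)
    x_fit <- x[-idx_val, , drop = FALSE]; y_fit <- y[-idx_val]
    x_v <- x[idx_val, , drop = FALSE];   y_v <- y[idx_val]
  } else {
    x_fit <- x; y_fit <- y
    x_v <- as.matrix(x_val); y_v <- as.integer(y_val)
    idx_val <- integer(0)
  }
  if (nrow(x_fit) < spec$k_neighbors)
    stop("fewer fitting rows than `k_neighbors`", call. = FALSE)

  fitness_fn <- function(pos) {
    mask <- binarize_position(pos, spec$threshold)
    mask_fitness(mask, x_fit, y_fit, x_v, y_v, spec)$fitness
  }
  run <- gwo_optimize(fitness_fn, dim = m, variant = variant, map = map,
                      pop_size = pop_size, max_iter = max_iter,
                      seed = NULL, lower = 0, upper = 1, ...)
  mask <- binarize_position(run$best_position, spec$threshold)
  best <- mask_fitness(mask, x_fit, y_fit, x_v, y_v, spec)

  structure(list(call = cl, variant = variant,
                 map = if (variant == "nigwo") NULL else map,
                 spec = spec, run = run, mask = mask,
                 features = if (!is.null(colnames(x))) colnames(x)[mask]
                            else which(mask),
                 fitness = best$fitness, val_accuracy = best$accuracy,
                 feature_ratio = best$feature_ratio,
                 n_features = best$n_features, n_terms = m,
                 x = x, y = y, idx_val = idx_val, seed = seed),
            class = "gwo_knn")
}

.stratified_holdout <- function(y, fraction) {
  stopifnot(fraction > 0, fraction < 1)
  idx <- integer(0)
  for (cl in sort(unique(y))) {
    rows <- which(y == cl)
    n_v <- max(1L, round(length(rows) * fraction))
    idx <- c(idx, sample(rows, n_v))
  }
  sort(idx)
}

#' @export
print.gwo_knn <- function(x, ...) {
  cat(sprintf("Chaotic grey wolf KNN feature selector (%s%s)\n",
              toupper(x$variant),
              if (is.null(x$map)) "" else paste0(", ", x$map$kind, " map")))
  cat(sprintf("  %d of %d terms selected; fitness %.4f (validation accuracy %.4f)\n",
              x$n_features, x$n_terms, x$fitness, x$val_accuracy))
  invisible(x)
}

#' @export
summary.gwo_knn <- function(object, ...) {
  s <- list(variant = object$variant,
            map = if (is.null(object$map)) NA_character_ else object$map$kind,
            n_features = object$n_features, n_terms = object$n_terms,
            fitness = object$fitness,
            accuracy_term = object$spec$w1 * object$val_accuracy,
            feature_term = object$spec$w2 * object$feature_ratio,
            val_accuracy = object$val_accuracy,
            evaluations = object$run$evaluations,
            features = object$features)
  class(s) <- "summary.gwo_knn"
  s
}

#' @export
print.summary.gwo_knn <- function(x, ...) {
  cat(sprintf("%s%s: %d/%d terms\n", toupper(x$variant),
              if (is.na(x$map)) "" else paste0(" (", x$map, " map)"),
              x$n_features, x$n_terms))
  cat(sprintf("  fitness %.4f = accuracy term %.4f + feature term %.4f\n",
              x$fitness, x$accuracy_term, x$feature_term))
  cat(sprintf("  validation accuracy %.4f; %d fitness evaluations\n",
              x$val_accuracy, x$evaluations))
  n_show <- min(10L, length(x$features))
  cat("  selected terms: ", paste(utils::head(x$features, n_show), collapse = ", "),
      if (length(x$features) > n_show) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Selected features of a fitted model
#'
#' @param object a \code{"gwo_knn"} fit.
#' @param ... unused.
#' @return Named logical vector over all terms (names are the vocabulary
#'   when available); \code{TRUE} marks a selected term.
#' @export
coef.gwo_knn <- function(object, ...) {
  out <- object$mask
  names(out) <- if (!is.null(colnames(object$x))) colnames(object$x)
                else seq_along(out)
  out
}

#' Classify new documents with a fitted model
#'
#' KNN prediction on the selected columns, using all rows supplied at fit
#' time as the reference set.
#'
#' @param object a \code{"gwo_knn"} fit.
#' @param newx binary matrix with the same columns as the training matrix,
#'   or a \code{"dtm"} object.
#' @param ... unused.
#' @return Integer 0/1 predictions, one per row of \code{newx}.
#' @export
predict.gwo_knn <- function(object, newx, ...) {
  if (inherits(newx, "dtm")) newx <- newx$x
  newx <- as.matrix(newx)
  if (ncol(newx) != object$n_terms)
    stop("`newx` must have the training columns", call. = FALSE)
  knn_predict(object$x[, object$mask, drop = FALSE], object$y,
              newx[, object$mask, drop = FALSE],
              object$spec$k_neighbors)
}

#' Convergence plot of a fitted model
#'
#' Best-so-far fitness per iteration of the underlying wolf search.
#'
#' @param x a \code{"gwo_knn"} or \code{"gwo_run"} object.
#' @param ... passed to \code{\link[graphics]{plot}}.
#' @export
plot.gwo_knn <- function(x, ...) plot(x$run, ...)

#' @export
plot.gwo_run <- function(x, ...) {
  graphics::plot(seq_along(x$history) - 1L, x$history, type = "s",
                 xlab = "iteration", ylab = "best-so-far fitness",
                 main = toupper(x$variant), ...)
  invisible(x)
}
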