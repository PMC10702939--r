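#' Binary confusion matrix
#'
#' Tallies a 2x2 confusion matrix with label 1 ("depressive") as the
#' positive class.
#'
#' @param truth,pred 0/1 vectors of equal length.
#' @return An object of class \code{"confusion_matrix"} with integer fields
#'   \code{tp}, \code{fp}, \code{fn}, \code{tn}.
#' @export
confusion_matrix <- function(truth, pred) {
  stopifnot(length(truth) == length(pred),
            all(truth %in% c(0, 1)), all(pred %in% c(0, 1)))
  structure(list(tp = sum(truth == 1 & pred == 1),
                 fp = sum(truth == 0 & pred == 1),
                 fn = sum(truth == 1 & pred == 0),
                 tn = sum(truth == 0 & pred == 0)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tn, x$fn, x$fp, x$tp), 2, 2,
              dimnames = list(predicted = c("0", "1"), truth = c("0", "1")))
  print(m)
  invisible(x)
}

.safe_div <- function(num, den) if (den == 0) 0 else num / den

#' Classification metrics from a confusion matrix
#'
#' Standard binary definitions: accuracy (tp+tn)/n, precision tp/(tp+fp),
#' sensitivity tp/(tp+fn), F-measure (harmonic mean of precision and
#' sensitivity), and the Matthews correlation coefficient
#' \eqn{(tp\,tn - fp\,fn)/\sqrt{(tp+fp)(tp+fn)(tn+fp)(tn+fn)}}. Any 0/0 is
#' defined as 0, so degenerate matrices (e.g. no positive predictions) are
#' handled without error.
#'
#' @param cm a \code{\link{confusion_matrix}}, or the \code{truth} vector if
#'   \code{pred} is supplied.
#' @param pred optional prediction vector (shortcut building the matrix).
#' @return Named numeric vector: accuracy, precision, sensitivity,
#'   f_measure, mcc.
#' @export
classification_metrics <- function(cm, pred = NULL) {
  if (!is.null(pred)) cm <- confusion_matrix(cm, pred)
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$fp + cm$fn + cm$tn
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  precision <- .safe_div(cm$tp, cm$tp + cm$fp)
  sensitivity <- .safe_div(cm$tp, cm$tp + cm$fn)
  f <- .safe_div(2 * precision * sensitivity, precision + sensitivity)
  mcc_den <- sqrt(cm$tp + cm$fp) * sqrt(cm$tp + cm$fn) *
             sqrt(cm$tn + cm$fp) * sqrt(cm$tn + cm$fn)
  mcc <- if (mcc_den == 0) 0 else
    (cm$tp * cm$tn - cm$fp * cm$fn) / mcc_den
  c(accuracy = (cm$tp + cm$tn) / total, precision = precision,
    sensitivity = sensitivity, f_measure = f, mcc = mcc)
}

#' Box-plot quartile summary
#'
#' Lower quartile, median, and upper quartile by linear interpolation
#' (\code{\link[stats]{quantile}} type 7, the convention behind standard
#' box plots).
#'
#' @param values numeric vector, at least one value.
#' @param type quantile algorithm, passed to \code{quantile()}.
#' @return Named numeric vector \code{q1}, \code{median}, \code{q3}.
#' @export
box_quartiles <- function(values, type = 7) {
  if (length(values) == 0L) stop("no values", call. = FALSE)
  q <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = type)
  c(q1 = q[1], median = q[2], q3 = q[3])
}

#' Friedman rank test across algorithms
#'
#' Nonparametric test for differences among k algorithms measured on n
#' matched blocks (e.g. n independent runs scored for each algorithm on a
#' common seed list). Within each block values are ranked with average
#' ranks on ties; with \code{larger_is_better} (default) the best value in
#' a block receives rank k, matching the convention in which the winning
#' algorithm shows the largest mean rank. The tie-corrected statistic
#' \deqn{\chi^2 = \frac{(k-1)\sum_j (R_j - n(k+1)/2)^2}
#'       {\sum_{ij} r_{ij}^2 - nk(k+1)^2/4}}
#' is referred to the chi-squared distribution with k-1 degrees of freedom;
#' the null is rejected when it exceeds the (1-alpha) quantile.
#'
#' @param results n x k numeric matrix: blocks (runs) by algorithms.
#' @param alpha significance level (default 0.05).
#' @param larger_is_better rank direction (see above).
#' @return An object of class \code{"friedman_test"}: sum and mean ranks per
#'   algorithm, \code{chi2}, \code{df}, \code{p_value},
#'   \code{critical_value}, \code{reject_h0}.
#' @examples
#' m <- matrix(c(1, 2, 3, 1, 2, 3, 1, 2, 3), 3, 3, byrow = TRUE)
#' friedman_rank_test(m)$chi2 # 6
#' @export
friedman_rank_test <- function(results, alpha = 0.05,
                               larger_is_better = TRUE) {
  results <- as.matrix(results)
  n <- nrow(results)
  k <- ncol(results)
  if (n < 2L || k < 2L)
    stop("need at least 2 blocks and 2 algorithms", call. = FALSE)
  ranks <- t(apply(results, 1L, function(row)
    rank(if (larger_is_better) row else -row)))
  sum_ranks <- colSums(ranks)
  mean_ranks <- sum_ranks / n
  # tie-corrected Friedman statistic
  num <- (k - 1) * sum((sum_ranks - n * (k + 1) / 2)^2)
  den <- sum(ranks^2) - n * k * (k + 1)^2 / 4
  chi2 <- if (den == 0) 0 else num / den
  df <- k - 1L
  crit <- qchisq(1 - alpha, df)
  structure(list(sum_ranks = sum_ranks, mean_ranks = mean_ranks,
                 chi2 = chi2, df = df,
                 p_value = pchisq(chi2, df, lower.tail = FALSE),
                 critical_value = crit, alpha = alpha,
                 reject_h0 = chi2 > crit, n_blocks = n, k = k),
            class = "friedman_test")
}

#' @export
print.friedman_test <- function(x, ...) {
  cat(sprintf("Friedman rank test: %d algorithms, %d blocks\n", x$k, x$n_blocks))
  tab <- rbind(`sum of ranks` = x$sum_ranks, `mean rank` = x$mean_ranks)
  print(round(tab, 3))
  cat(sprintf("chi-squared = %.6g, df = %d, p = %.3g\n", x$chi2, x$df, x$p_value))
  cat(sprintf("critical value at alpha = %g: %.3f -> H0 %s\n", x$alpha,
              x$critical_value, if (x$reject_h0) "rejected" else "not rejected"))
  invisible(x)
}

#' Repeated-run experiment for one optimizer configuration
#'
#' Runs the wrapper feature-selection model \code{n_runs} times with
#' distinct seeds and summarizes the per-run best fitness as best / mean /
#' worst together with the feature count of the best run — the layout used
#' to compare stochastic optimizers.
#'
#' @param x,y training document-term matrix and 0/1 labels (see
#'   \code{\link{gwo_knn}}).
#' @param variant,map optimizer variant and chaotic map.
#' @param n_runs number of independent runs (default 20).
#' @param seeds integer vector of distinct seeds, length \code{n_runs}.
#' @param ... further arguments to \code{\link{gwo_knn}}.
#' @return An object of class \code{"gwo_experiment"}: per-run fitness and
#'   accuracy values, fitted models' masks, and the summary row.
#' @export
run_experiment <- function(x, y, variant = "cni1",
                           map = chaotic_map("logistic"),
                           n_runs = 20L, seeds = seq_len(n_runs), ...) {
  seeds <- as.integer(seeds)
  if (length(seeds) != n_runs || anyDuplicated(seeds))
    stop("`seeds` must hold n_runs distinct seeds", call. = FALSE)
  fits <- lapply(seeds, function(s)
    gwo_knn(x, y, variant = variant, map = map, seed = s, ...))
  fitness <- vapply(fits, function(f) f$fitness, numeric(1))
  accuracy <- vapply(fits, function(f) f$val_accuracy, numeric(1))
  n_feat <- vapply(fits, function(f) sum(f$mask), numeric(1))
  best <- which.max(fitness)
  structure(list(variant = variant, map = map, seeds = seeds,
                 fitness = fitness, val_accuracy = accuracy,
                 n_features = n_feat, best_run = best,
                 best_mask = fits[[best]]$mask,
                 summary = c(best = max(fitness), mean = mean(fitness),
                             worst = min(fitness),
                             n_features_best = n_feat[best]),
                 quartiles = box_quartiles(fitness)),
            class = "gwo_experiment")
}

#' @export
print.gwo_experiment <- function(x, ...) {
  cat(sprintf("%s (%s map): %d runs\n", toupper(x$variant), x$map$kind,
              length(x$seeds)))
  print(round(x$summary, 4))
  invisible(x)
}

#' Compare optimizer variants with a common seed list
#'
#' Runs \code{\link{run_experiment}} for each configuration on the same
#' data and seeds (matched blocks), assembles the best/mean/worst summary
#' table, and applies the \code{\link{friedman_rank_test}} to the per-run
#' best fitness values.
#'
#' @param x,y training data as in \code{\link{gwo_knn}}.
#' @param variants character vector of variant names; recycled against
#'   \code{maps}.
#' @param maps list of \code{\link{chaotic_map}} objects, one per entry of
#'   \code{variants}.
#' @param n_runs,seeds runs per variant and the shared seed list.
#' @param alpha significance level for the Friedman test.
#' @param ... further arguments to \code{\link{gwo_knn}}.
#' @return List with \code{experiments}, the summary \code{table}
#'   (one row per configuration), and \code{friedman}.
#' @export
compare_variants <- function(x, y, variants, maps = NULL,
                             n_runs = 20L, seeds = seq_len(n_runs),
                             alpha = 0.05, ...) {
  if (length(variants) < 2L) stop("need at least 2 configurations", call. = FALSE)
  if (is.null(maps)) maps <- rep(list(chaotic_map("logistic")), length(variants))
  exps <- Map(function(v, m)
    run_experiment(x, y, variant = v, map = m, n_runs = n_runs,
                   seeds = seeds, ...),
    variants, maps)
  tab <- do.call(rbind, lapply(exps, function(e)
    data.frame(variant = e$variant, map = e$map$kind,
               t(as.data.frame(e$summary)), row.names = NULL)))
  results <- vapply(exps, function(e) e$fitness, numeric(n_runs))
  colnames(results) <- names(exps)
  list(experiments = exps, table = tab,
       friedman = friedman_rank_test(results, alpha = alpha))
}
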