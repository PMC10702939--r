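#' @useDynLib chaoswolf, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif quantile pchisq qchisq
NULL

#' Exploration schedules
#'
#' `gwo_schedule_a()` is the encircling coefficient schedule, decreasing
#' linearly from 2 at \code{t = 0} to 0 at \code{t = max_iter}.
#' `gwo_schedule_r1()` is the deterministic replacement for the random
#' \eqn{r_1} draw that defines the NI-GWO family:
#' \eqn{r_1 = \alpha - t\,\alpha/\mathrm{MaxIter}} with \eqn{\alpha = 2}.
#'
#' @param t iteration index, \code{0 <= t <= max_iter}.
#' @param max_iter total number of iterations, at least 1.
#' @param alpha_const the constant \eqn{\alpha} (default 2).
#' @return A single numeric value.
#' @export
gwo_schedule_a <- function(t, max_iter) {
  stopifnot(max_iter >= 1)
  if (any(t < 0) || any(t > max_iter))
    stop("`t` must lie in [0, max_iter]", call. = FALSE)
  2 * (1 - t / max_iter)
}

#' @rdname gwo_schedule_a
#' @export
gwo_schedule_r1 <- function(t, max_iter, alpha_const = 2) {
  stopifnot(max_iter >= 1)
  if (any(t < 0) || any(t > max_iter))
    stop("`t` must lie in [0, max_iter]", call. = FALSE)
  alpha_const - t * (alpha_const / max_iter)
}

#' Movement coefficients
#'
#' \code{gwo_coef_A(a, r1) = 2 a r_1 - a} scales the step towards or away
#' from a leader; \code{gwo_coef_C(r2) = 2 r_2} perturbs the leader's
#' apparent position. In the chaotic variants CNI-GWO2/3/4 the \eqn{r_2}
#' feeding \eqn{C_1}/\eqn{C_2}/\eqn{C_3} comes from a chaotic stream.
#'
#' @param a current value of the \code{a} schedule.
#' @param r1,r2 draw in [0, 1] (or the scheduled \eqn{r_1} in [0, 2]).
#' @return Numeric, vectorized over the inputs.
#' @export
gwo_coef_A <- function(a, r1) 2 * a * r1 - a

#' @rdname gwo_coef_A
#' @export
gwo_coef_C <- function(r2) 2 * r2

.clamp <- function(x, lower, upper) pmin(pmax(x, lower), upper)

#' Leader-guided (canonical GWO) candidate position
#'
#' For each leader \eqn{X_k} (alpha, beta, delta), the distance
#' \eqn{D_k = |C_k X_k - X|} and trial position \eqn{X_k' = X_k - A_k D_k}
#' are computed; the candidate is the coordinate-wise mean of the three
#' trials, clamped to the bounds.
#'
#' @param position current position vector.
#' @param leaders 3 x M matrix; rows are the alpha, beta, delta positions.
#' @param A,C numeric vectors of length 3, one coefficient per leader.
#' @param lower,upper bounds, recycled across dimensions.
#' @param literal_distance use the subtractive form \eqn{|C_k - X_k - X|}
#'   exactly as sometimes printed, instead of the canonical multiplicative
#'   distance. Off by default.
#' @return Candidate position vector, within bounds.
#' @export
gwo_candidate <- function(position, leaders, A, C, lower = 0, upper = 1,
                          literal_distance = FALSE) {
  stopifnot(nrow(leaders) == 3L, length(A) == 3L, length(C) == 3L)
  trials <- vapply(1:3, function(k) {
    D <- if (literal_distance) abs(C[k] - leaders[k, ] - position)
         else abs(C[k] * leaders[k, ] - position)
    leaders[k, ] - A[k] * D
  }, numeric(length(position)))
  if (!is.matrix(trials)) trials <- matrix(trials, nrow = length(position))
  .clamp(rowMeans(trials), lower, upper)
}

#' Dimension-learning-based hunting (DLH) neighbourhood and candidate
#'
#' `dlh_neighbors()` returns the indices of all wolves whose Euclidean
#' distance from \code{position} does not exceed the radius
#' \eqn{R_i = \|X_i - X_{i,GWO}\|}; the wolf itself always qualifies
#' (distance 0). `dlh_candidate()` builds the second candidate: per
#' dimension \eqn{d}, \eqn{X_{i,d} + rand\,(X_{n,d} - X_{r,d})} with a
#' fresh random neighbour \eqn{n}, population member \eqn{r}, and
#' multiplier for every dimension, clamped to bounds.
#'
#' @param position the wolf's current position.
#' @param gwo_cand its leader-guided candidate for this iteration.
#' @param population N x M matrix of all current positions.
#' @param neighbors integer indices from `dlh_neighbors()`.
#' @param lower,upper bounds.
#' @param n_idx,r_idx,rand optional pinned draws (length-M vectors) for
#'   reproducing a hand trace; sampled fresh when \code{NULL}.
#' @return `dlh_neighbors()`: integer vector; `dlh_candidate()`: position.
#' @export
dlh_neighbors <- function(position, gwo_cand, population) {
  radius <- sqrt(sum((position - gwo_cand)^2))
  d2 <- sqrt(colSums((t(population) - position)^2))
  which(d2 <= radius + 1e-15)
}

#' @rdname dlh_neighbors
#' @export
dlh_candidate <- function(position, population, neighbors,
                          lower = 0, upper = 1,
                          n_idx = NULL, r_idx = NULL, rand = NULL) {
  m <- length(position)
  n_pop <- nrow(population)
  if (is.null(n_idx)) n_idx <- neighbors[sample.int(length(neighbors), m, replace = TRUE)]
  if (is.null(r_idx)) r_idx <- sample.int(n_pop, m, replace = TRUE)
  if (is.null(rand)) rand <- runif(m)
  cand <- position + rand *
    (population[cbind(n_idx, seq_len(m))] - population[cbind(r_idx, seq_len(m))])
  .clamp(cand, lower, upper)
}

.gwo_variants <- c("nigwo", "cni1", "cni2", "cni3", "cni4")

#' Initialize a wolf population
#'
#' Positions are \eqn{X_{ij} = l_j + s (u_j - l_j)} where \eqn{s} is a fresh
#' uniform draw (under the caller's RNG state) or, for
#' \code{source = "chaotic"}, the next value of the chaotic stream consumed
#' in row-major order (wolf by wolf).
#'
#' @param pop_size,dim population size and dimension, both positive.
#' @param lower,upper bounds, recycled over dimensions.
#' @param source \code{"uniform"} or \code{"chaotic"}.
#' @param stream a \code{\link{chaos_stream}} (required when chaotic).
#' @return A \code{pop_size} x \code{dim} numeric matrix.
#' @export
gwo_init_population <- function(pop_size, dim, lower = 0, upper = 1,
                                source = c("uniform", "chaotic"),
                                stream = NULL) {
  source <- match.arg(source)
  pop_size <- as.integer(pop_size)
  dim <- as.integer(dim)
  if (pop_size < 1L || dim < 1L)
    stop("`pop_size` and `dim` must be positive", call. = FALSE)
  lower <- rep_len(lower, dim)
  upper <- rep_len(upper, dim)
  if (any(lower > upper)) stop("`lower` must not exceed `upper`", call. = FALSE)
  s <- if (source == "chaotic") {
    if (is.null(stream)) stop("chaotic initialization needs `stream`", call. = FALSE)
    stream$take(pop_size * dim)
  } else runif(pop_size * dim)
  matrix(rep(lower, each = pop_size), pop_size, dim) +
    matrix(s, pop_size, dim, byrow = TRUE) *
    matrix(rep(upper - lower, each = pop_size), pop_size, dim)
}

#' Run the NI-GWO / CNI-GWO optimizer
#'
#' Maximizes \code{fitness} over \code{[lower, upper]^dim} with a population
#' of grey wolves. Every iteration each wolf generates two candidates — the
#' leader-guided move of the canonical GWO (with the deterministic
#' \eqn{r_1} schedule) and the DLH move — and greedily keeps the better one
#' if it strictly improves on its current position (ties between the two
#' candidates go to the leader-guided one).
#'
#' Variants differ only in where chaotic draws replace uniform ones:
#' \describe{
#'   \item{\code{"nigwo"}}{no chaos; uniform initialization and \eqn{r_2} draws.}
#'   \item{\code{"cni1"}}{chaotic population initialization (values consumed
#'     row by row, one wolf at a time).}
#'   \item{\code{"cni2"}/\code{"cni3"}/\code{"cni4"}}{the \eqn{r_2} behind
#'     \eqn{C_1}/\eqn{C_2}/\eqn{C_3} respectively is chaotic (one value per
#'     wolf per iteration, in wolf order); all other draws stay uniform.}
#' }
#' A run is reproducible from \code{(seed, map)}: the chaotic stream is
#' deterministic and all uniform draws come from R's RNG under \code{seed}.
#'
#' @param fitness function mapping a position vector to a finite scalar
#'   (maximized).
#' @param dim problem dimension.
#' @param variant one of \code{"nigwo"}, \code{"cni1"}, \code{"cni2"},
#'   \code{"cni3"}, \code{"cni4"}.
#' @param map a \code{\link{chaotic_map}} (ignored by \code{"nigwo"}).
#' @param pop_size population size (default 30).
#' @param max_iter iterations (default 100; 0 evaluates only the initial
#'   population).
#' @param seed integer seed for the uniform draws.
#' @param lower,upper search-space bounds, recycled over dimensions.
#' @param literal_distance see \code{\link{gwo_candidate}}.
#' @return An object of class \code{"gwo_run"} with elements
#'   \code{best_position}, \code{best_fitness}, \code{history} (best-so-far
#'   fitness: initial population followed by one entry per iteration, hence
#'   non-decreasing of length \code{max_iter + 1}), \code{evaluations}
#'   (\code{N + 2 N max_iter}), and the effective configuration.
#' @examples
#' r <- gwo_optimize(function(x) 1 - mean(abs(x - 0.7)), dim = 5,
#'                   variant = "cni1", pop_size = 10, max_iter = 20, seed = 1)
#' r$best_fitness
#' @export
gwo_optimize <- function(fitness, dim, variant = .gwo_variants,
                         map = chaotic_map("logistic"),
                         pop_size = 30L, max_iter = 100L, seed = NULL,
                         lower = 0, upper = 1, literal_distance = FALSE) {
  variant <- match.arg(variant)
  pop_size <- as.integer(pop_size)
  dim <- as.integer(dim)
  max_iter <- as.integer(max_iter)
  if (pop_size < 3L)
    stop("`pop_size` must be at least 3 (alpha, beta, delta leaders)",
         call. = FALSE)
  if (dim < 1L) stop("`dim` must be positive", call. = FALSE)
  if (max_iter < 0L) stop("`max_iter` must be non-negative", call. = FALSE)
  lower <- rep_len(lower, dim)
  upper <- rep_len(upper, dim)
  if (any(lower > upper)) stop("`lower` must not exceed `upper`", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  stream <- if (variant != "nigwo") chaos_stream(map)

  eval_fit <- local({
    n_evals <- 0L
    function(x, t, i) {
      f <- fitness(x)
      if (!is.finite(f))
        stop(sprintf("non-finite fitness at iteration %d, wolf %d", t, i),
             call. = FALSE)
      n_evals <<- n_evals + 1L
      f
    }
  })
  count_evals <- function() environment(eval_fit)$n_evals

  X <- gwo_init_population(pop_size, dim, lower, upper,
                           source = if (variant == "cni1") "chaotic" else "uniform",
                           stream = stream)
  fit <- vapply(seq_len(pop_size), function(i) eval_fit(X[i, ], 0L, i),
                numeric(1))

  history <- numeric(max_iter + 1L)
  history[1L] <- max(fit)

  for (t in seq_len(max_iter)) {
    ord <- order(fit, decreasing = TRUE)
    leaders <- X[ord[1:3], , drop = FALSE]
    a <- gwo_schedule_a(t, max_iter)
    r1 <- gwo_schedule_r1(t, max_iter)
    A <- rep(gwo_coef_A(a, r1), 3L)
    # r2 draws: one uniform pop x 3 block, chaotic column substituted
    r2 <- matrix(runif(pop_size * 3L), pop_size, 3L)
    chaotic_col <- switch(variant, cni2 = 1L, cni3 = 2L, cni4 = 3L, NULL)
    if (!is.null(chaotic_col)) r2[, chaotic_col] <- stream$take(pop_size)
    C <- gwo_coef_C(r2)

    cand_gwo <- t(vapply(seq_len(pop_size), function(i)
      gwo_candidate(X[i, ], leaders, A, C[i, ], lower, upper,
                    literal_distance), numeric(dim)))
    for (i in seq_len(pop_size)) {
      nbrs <- dlh_neighbors(X[i, ], cand_gwo[i, ], X)
      cand_dlh <- dlh_candidate(X[i, ], X, nbrs, lower, upper)
      f_gwo <- eval_fit(cand_gwo[i, ], t, i)
      f_dlh <- eval_fit(cand_dlh, t, i)
      if (f_gwo >= f_dlh) {          # tie goes to the leader-guided move
        if (f_gwo > fit[i]) { X[i, ] <- cand_gwo[i, ]; fit[i] <- f_gwo }
      } else if (f_dlh > fit[i]) { X[i, ] <- cand_dlh; fit[i] <- f_dlh }
    }
    history[t + 1L] <- max(history[t], max(fit))
  }

  best <- which.max(fit)
  structure(list(best_position = X[best, ], best_fitness = max(history),
                 history = history, evaluations = count_evals(),
                 seed = seed, variant = variant,
                 map = if (variant == "nigwo") NULL else map,
                 pop_size = pop_size, max_iter = max_iter, dim = dim),
            class = "gwo_run")
}

#' @export
print.gwo_run <- function(x, ...) {
  cat(sprintf("Grey wolf run (%s%s): dim %d, pop %d, %d iterations\n",
              toupper(x$variant),
              if (is.null(x$map)) "" else paste0(", ", x$map$kind, " map"),
              x$dim, x$pop_size, x$max_iter))
  cat(sprintf("  best fitness %.6g after %d evaluations\n",
              x$best_fitness, x$evaluations))
  invisible(x)
}
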