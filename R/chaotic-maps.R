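#' Chaotic map specification
#'
#' Defines one of three one-dimensional chaotic maps used in place of
#' pseudo-random draws inside the optimizer: the circle map
#' \eqn{z_{m+1} = z_m + y_2 - (y_1/2\pi)\sin(2\pi z_m)}, the logistic map
#' \eqn{z_{m+1} = \mu z_m (1 - z_m)}, and the iterative chaotic map with
#' infinite collapse \eqn{z_{m+1} = \sin(y\pi/z_m)}.
#'
#' Defaults follow the standard parameterization for chaos-seeded
#' metaheuristics: \code{y1 = 0.5}, \code{y2 = 0.2} for the circle map,
#' \code{mu = 4} for the logistic map (the fully chaotic regime), and a
#' shared initial value \code{z1 = 0.7}. The iterative map parameter
#' \code{y} must lie in (0, 1) with \code{y/z1} not an integer: when
#' \code{y/z1} is integral, \eqn{\sin(y\pi/z_1) = 0}, so the very first
#' step lands on the degeneracy guard and the reseed-to-\code{z1} policy
#' would freeze the stream at zero. The default \code{y = 0.9} keeps the
#' orbit chaotic from \code{z1 = 0.7}.
#'
#' @param kind one of \code{"circle"}, \code{"logistic"}, \code{"iterative"}.
#' @param z1 initial value, in (0, 1].
#' @param y1,y2 circle map parameters.
#' @param mu logistic map growth rate, positive.
#' @param y iterative map parameter, in (0, 1).
#' @return An object of class \code{"chaotic_map"}.
#' @examples
#' chaotic_map("logistic")
#' chaos_sequence(chaotic_map("logistic"), 3) # 0.84 0.5376 0.99434496
#' @export
chaotic_map <- function(kind = c("circle", "logistic", "iterative"),
                        z1 = 0.7, y1 = 0.5, y2 = 0.2, mu = 4, y = 0.9) {
  kind <- match.arg(kind)
  if (!is.numeric(z1) || length(z1) != 1L || z1 <= 0 || z1 > 1)
    stop("`z1` must be a single value in (0, 1]", call. = FALSE)
  if (mu <= 0) stop("`mu` must be positive", call. = FALSE)
  if (y <= 0 || y >= 1) stop("`y` must lie in (0, 1)", call. = FALSE)
  if (kind == "iterative" && abs(y / z1 - round(y / z1)) < 1e-9)
    warning("y/z1 is an integer: the iterative map starts on sin(y*pi/z1) = 0 ",
            "and the stream degenerates under the reseed guard",
            call. = FALSE)
  structure(list(kind = kind, z1 = z1, y1 = y1, y2 = y2, mu = mu, y = y),
            class = "chaotic_map")
}

#' @export
print.chaotic_map <- function(x, ...) {
  params <- switch(x$kind,
    circle    = sprintf("y1 = %g, y2 = %g", x$y1, x$y2),
    logistic  = sprintf("mu = %g", x$mu),
    iterative = sprintf("y = %g", x$y))
  cat(sprintf("Chaotic map: %s (%s), z1 = %g\n", x$kind, params, x$z1))
  invisible(x)
}

# |z| below this reseeds the iterative map to z1: sin(y*pi/z) is undefined
# at z = 0 and exact arithmetic can reach it (y = 0.7, z = 0.35).
.chaos_eps <- 1e-12

.chaos_step_raw <- function(map, z) {
  switch(map$kind,
    circle   = z + map$y2 - (map$y1 / (2 * pi)) * sin(2 * pi * z),
    logistic = map$mu * z * (1 - z),
    iterative = {
      if (abs(z) < .chaos_eps) z <- map$z1
      sin(map$y * pi / z)
    })
}

.chaos_to_unit <- function(map, z) {
  switch(map$kind,
    circle    = z %% 1,
    logistic  = z,
    iterative = abs(z))
}

#' Stateful chaotic number stream
#'
#' Wraps a \code{\link{chaotic_map}} in a mutable stream. The stream is fully
#' deterministic: two streams built from the same map emit identical values.
#'
#' @param map a \code{chaotic_map}.
#' @return An object of class \code{"chaos_stream"}: a list of closures
#'   \code{next_raw()} (one raw recurrence step; the iterative map can return
#'   negative values), \code{next_unit()} (raw value normalized into [0, 1]:
#'   circle reduced modulo 1, logistic passed through, iterative by absolute
#'   value), \code{take(n)} (vector of n unit values), and \code{state()}.
#' @examples
#' s <- chaos_stream(chaotic_map("logistic"))
#' s$next_unit() # 0.84
#' @export
chaos_stream <- function(map) {
  stopifnot(inherits(map, "chaotic_map"))
  z <- map$z1
  m <- 0L
  next_raw <- function() {
    z <<- .chaos_step_raw(map, z)
    m <<- m + 1L
    z
  }
  next_unit <- function() .chaos_to_unit(map, next_raw())
  take <- function(n) {
    if (n == 0L) return(numeric(0))
    vapply(seq_len(n), function(i) next_unit(), numeric(1))
  }
  structure(list(next_raw = next_raw, next_unit = next_unit, take = take,
                 state = function() list(z = z, m = m), map = map),
            class = "chaos_stream")
}

#' Generate a chaotic number sequence
#'
#' The first \code{n} unit-interval values of a chaotic map started from its
#' initial value \code{z1}. Repeated calls with an identical map specification
#' return identical sequences.
#'
#' @param map a \code{\link{chaotic_map}}.
#' @param n number of values (\code{n = 0} gives an empty vector).
#' @param raw if \code{TRUE}, return the raw recurrence values without unit
#'   normalization (circle values can exceed 1; iterative values can be
#'   negative).
#' @return Numeric vector of length \code{n}; in [0, 1] unless \code{raw}.
#' @export
chaos_sequence <- function(map, n, raw = FALSE) {
  stopifnot(inherits(map, "chaotic_map"), n >= 0)
  n <- as.integer(n)
  out <- numeric(n)
  z <- map$z1
  for (i in seq_len(n)) {
    z <- .chaos_step_raw(map, z)
    out[i] <- if (raw) z else .chaos_to_unit(map, z)
  }
  out
}
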