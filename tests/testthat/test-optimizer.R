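test_that("coefficient schedules hit their endpoints and interpolate linearly", {
  expect_equal(gwo_schedule_a(0, 100), 2)
  expect_equal(gwo_schedule_a(100, 100), 0)
  expect_equal(gwo_schedule_a(50, 100), 1)
  expect_equal(gwo_schedule_r1(0, 100), 2)
  expect_equal(gwo_schedule_r1(100, 100), 0)
  expect_equal(gwo_schedule_r1(25, 100), 1.5)
  expect_error(gwo_schedule_a(101, 100), "max_iter")
  expect_error(gwo_schedule_r1(101, 100), "max_iter")
})

test_that("movement coefficients follow their closed forms", {
  expect_equal(gwo_coef_A(2, 0.5), 0)
  expect_equal(gwo_coef_A(2, 1), 2)
  expect_equal(gwo_coef_A(1.5, 0.2), -0.9)
  expect_equal(gwo_coef_C(0), 0)
  expect_equal(gwo_coef_C(1), 2)
  expect_equal(gwo_coef_C(0.84), 1.68)
})

test_that("leader-guided candidate matches hand computation", {
  # coincident population: wolf sits on all three leaders, C = 1
  x <- c(0.3, 0.6)
  leaders <- rbind(x, x, x)
  expect_equal(gwo_candidate(x, leaders, A = c(0.7, 0.2, -1), C = rep(1, 3)), x)
  # A = 0 suppresses the distance term entirely
  leaders <- rbind(c(0.9, 0.3), c(0.6, 0.6), c(0.3, 0.9))
  expect_equal(gwo_candidate(c(0.1, 0.1), leaders, A = rep(0, 3), C = runif(3)),
               colMeans(leaders))
  # 1-D hand trace
  expect_equal(
    gwo_candidate(0.2, rbind(0.8, 0.6, 0.4), A = rep(0.5, 3), C = rep(1, 3)),
    0.4)
  # literal subtractive distance form stays available
  expect_equal(
    gwo_candidate(0.2, rbind(0.8, 0.6, 0.4), A = rep(0.5, 3), C = rep(1, 3),
                  literal_distance = TRUE),
    mean(c(0.8 - 0.5 * abs(1 - 0.8 - 0.2),
           0.6 - 0.5 * abs(1 - 0.6 - 0.2),
           0.4 - 0.5 * abs(1 - 0.4 - 0.2))))
})

test_that("DLH neighbourhood and candidate follow the radius rule", {
  # degenerate swarm collapsed onto one point
  pop <- matrix(0.4, 4, 3)
  nb <- dlh_neighbors(pop[1, ], pop[1, ], pop)
  expect_identical(nb, 1:4)
  expect_equal(dlh_candidate(pop[1, ], pop, nb), rep(0.4, 3))
  # zero radius keeps at least the wolf itself
  pop <- matrix(c(0, 0.5, 1), 3, 1)
  expect_identical(dlh_neighbors(0, 0, pop), 1L)
  # 1-D hand trace with pinned draws
  nb <- dlh_neighbors(0, 0.6, pop)
  expect_identical(nb, c(1L, 2L))
  cand <- dlh_candidate(0, pop, nb, n_idx = 2L, r_idx = 3L, rand = 0.5)
  expect_equal(cand, 0)  # 0 + 0.5*(0.5 - 1) = -0.25, clamped to 0
})

test_that("DLH neighbour sets match brute-force distance filtering", {
  set.seed(11)
  for (rep in 1:20) {
    pop <- matrix(runif(10 * 4), 10, 4)
    i <- sample(10, 1)
    cand <- runif(4)
    expect_identical(dlh_neighbors(pop[i, ], cand, pop),
                     dlh_neighbors_oracle(pop[i, ], cand, pop))
  }
})

test_that("population initialization honours bounds and draw sources", {
  # zero-width bounds collapse every wolf onto the bound
  set.seed(1)
  x <- gwo_init_population(5, 3, lower = c(1, 2, 3), upper = c(1, 2, 3))
  expect_equal(x, matrix(rep(c(1, 2, 3), each = 5), 5, 3))
  # chaotic source consumes the map sequence in row-major order
  x <- gwo_init_population(1, 2, source = "chaotic",
                           stream = chaos_stream(chaotic_map("logistic")))
  expect_equal(as.vector(x), c(0.84, 0.5376))
  # same seed, uniform source: identical populations
  set.seed(42); a <- gwo_init_population(6, 4)
  set.seed(42); b <- gwo_init_population(6, 4)
  expect_identical(a, b)
  expect_error(gwo_init_population(0, 3), "positive")
})

test_that("runs are reproducible, monotone, and account for every evaluation", {
  for (variant in c("nigwo", "cni1", "cni2", "cni3", "cni4")) {
    r1 <- gwo_optimize(toy_objective, dim = 5, variant = variant,
                       pop_size = 8, max_iter = 25, seed = 9)
    r2 <- gwo_optimize(toy_objective, dim = 5, variant = variant,
                       pop_size = 8, max_iter = 25, seed = 9)
    expect_identical(r1, r2)
    expect_true(all(diff(r1$history) >= 0), info = variant)
    expect_identical(r1$evaluations, 8L + 2L * 8L * 25L)
    expect_identical(r1$best_fitness, r1$history[length(r1$history)])
    expect_gte(r1$best_fitness, r1$history[1])
  }
})

test_that("degenerate and invalid configurations are handled", {
  r <- gwo_optimize(toy_objective, dim = 3, pop_size = 5, max_iter = 0, seed = 1)
  expect_length(r$history, 1L)
  expect_identical(r$evaluations, 5L)
  expect_error(gwo_optimize(toy_objective, dim = 0, pop_size = 5), "dim")
  expect_error(gwo_optimize(toy_objective, dim = 3, pop_size = 2), "at least 3")
  expect_error(gwo_optimize(function(x) NaN, dim = 3, pop_size = 5,
                            max_iter = 2, seed = 1),
               "non-finite fitness")
})

test_that("every evaluated position stays inside the bounds", {
  seen_outside <- FALSE
  lo <- c(-1, 0, 2); hi <- c(1, 0.5, 5)
  probe <- function(x) {
    if (any(x < lo - 1e-12) || any(x > hi + 1e-12)) seen_outside <<- TRUE
    -sum(x^2)
  }
  for (variant in c("nigwo", "cni1", "cni3")) {
    gwo_optimize(probe, dim = 3, variant = variant, pop_size = 6,
                 max_iter = 20, seed = 3, lower = lo, upper = hi)
  }
  expect_false(seen_outside)
})

test_that("all variants close in on a separable optimum", {
  for (variant in c("nigwo", "cni1", "cni2", "cni3", "cni4")) {
    hits <- sum(vapply(1:5, function(s)
      gwo_optimize(toy_objective, dim = 5, variant = variant, pop_size = 30,
                   max_iter = 100, seed = s)$best_fitness >= 0.95,
      logical(1)))
    expect_gte(hits, 4)
  }
})
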