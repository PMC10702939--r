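# Independent brute-force oracles used to cross-check the fast paths.

# Quadratic-time KNN: explicit Euclidean distances, order() with explicit
# index tie-break, majority vote, even splits to the nearest neighbour.
knn_oracle <- function(train, labels, query, k) {
  apply(query, 1L, function(qrow) {
    d <- apply(train, 1L, function(trow) sqrt(sum((trow - qrow)^2)))
    nb <- order(d, seq_along(d))[seq_len(k)]
    ones <- sum(labels[nb] == 1)
    if (2 * ones > k) 1L else if (2 * ones < k) 0L else labels[nb[1L]]
  })
}

# Brute-force DLH neighbourhood: every wolf within the Euclidean radius
# defined by the distance to the leader-guided candidate.
dlh_neighbors_oracle <- function(position, gwo_cand, population) {
  radius <- sqrt(sum((position - gwo_cand)^2))
  d <- apply(population, 1L, function(row) sqrt(sum((row - position)^2)))
  which(d <= radius)
}

# Separable toy objective with a known optimum at x = 0.7 everywhere.
toy_objective <- function(x) 1 - mean(abs(x - 0.7))
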