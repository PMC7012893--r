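# Independent oracles used across tests. These deliberately use the most
# naive formulation available (exhaustive scans, refined grid search) so
# they share no code path with the implementation they check.

# Exhaustive all-pairs nearest-neighbour scan: for each row of `a`, the
# minimum Euclidean distance to any row of `b`.
brute_force_nn <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    min(sqrt((a$x_nm[i] - b$x_nm)^2 + (a$y_nm[i] - b$y_nm)^2))
  }, numeric(1))
}

# Pairwise concordance AUC: fraction of case/control pairs in which the
# case scores higher, ties counted one half.
concordance_auc <- function(cases, controls) {
  cmp <- outer(cases, controls, ">") + 0.5 * outer(cases, controls, "==")
  mean(cmp)
}

# Refined grid search for least-squares v = a / d + b, independent of lm().
grid_search_inverse_fit <- function(d, v, iterations = 12) {
  sse <- function(a, b) sum((v - (a / d + b))^2)
  ca <- 0
  cb <- 0
  wa <- 4 * max(abs(v)) * max(d) + 1
  wb <- 4 * max(abs(v)) + 1
  for (i in seq_len(iterations)) {
    as <- seq(ca - wa, ca + wa, length.out = 41)
    bs <- seq(cb - wb, cb + wb, length.out = 41)
    grid <- expand.grid(a = as, b = bs)
    err <- mapply(sse, grid$a, grid$b)
    best <- grid[which.min(err), ]
    ca <- best$a
    cb <- best$b
    wa <- wa * 0.1
    wb <- wb * 0.1
  }
  c(a = ca, b = cb)
}

# Uniform points on a disc of the given radius (area-uniform in r^2).
uniform_disc <- function(n, radius) {
  r <- radius * sqrt(runif(n))
  theta <- runif(n, 0, 2 * pi)
  tibble::tibble(x_nm = r * cos(theta), y_nm = r * sin(theta))
}
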