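# Independent oracles used across tests.

# Brute-force bottleneck value between two nodes of a grid (king moves):
# smallest threshold v such that start and end are connected in the subgraph
# of cells with value <= v. Independent of the Dijkstra implementation.
oracle_bottleneck <- function(values, dims, start, end) {
  d <- length(dims)
  n <- prod(dims)
  sub <- as.matrix(do.call(expand.grid, lapply(dims, seq_len)))
  offs <- as.matrix(do.call(expand.grid, rep(list(-1:1), d)))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  lin_of <- function(idx) as.integer((idx - 1) %*% cumprod(c(1, dims[-d]))) + 1L
  connected_at <- function(v) {
    ok <- values <= v
    if (!ok[start] || !ok[end]) return(FALSE)
    seen <- logical(n)
    seen[start] <- TRUE
    queue <- start
    while (length(queue)) {
      u <- queue[[1]]; queue <- queue[-1]
      if (u == end) return(TRUE)
      for (o in seq_len(nrow(offs))) {
        nb <- sub[u, ] + offs[o, ]
        if (any(nb < 1 | nb > dims)) next
        l <- lin_of(nb)
        if (ok[l] && !seen[l]) { seen[l] <- TRUE; queue <- c(queue, l) }
      }
    }
    FALSE
  }
  for (v in sort(unique(values))) if (connected_at(v)) return(v)
  Inf
}

# Exhaustive enumeration of all simple king-move paths on a small grid,
# returning the minimal max-value en route.
oracle_enumerate_paths <- function(values, dims, start, end) {
  d <- length(dims)
  sub <- as.matrix(do.call(expand.grid, lapply(dims, seq_len)))
  offs <- as.matrix(do.call(expand.grid, rep(list(-1:1), d)))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  lin_of <- function(idx) as.integer((idx - 1) %*% cumprod(c(1, dims[-d]))) + 1L
  best <- Inf
  visit <- function(u, seen, mx) {
    mx <- max(mx, values[u])
    if (mx >= best) return(invisible())
    if (u == end) { best <<- mx; return(invisible()) }
    for (o in seq_len(nrow(offs))) {
      nb <- sub[u, ] + offs[o, ]
      if (any(nb < 1 | nb > dims)) next
      l <- lin_of(nb)
      if (!seen[l]) { seen[l] <- TRUE; visit(l, seen, mx); seen[l] <- FALSE }
    }
  }
  seen <- logical(prod(dims))
  seen[start] <- TRUE
  visit(start, seen, -Inf)
  best
}

# Gradient-descent oracle for surface minima
oracle_minimize <- function(surface, start) {
  stats::optim(start, function(s) surface_energy(surface, s),
               function(s) as.numeric(surface_gradient(surface, s)),
               method = "BFGS")$par
}

# central finite differences of a scalar function of a coordinate matrix
fd_gradient <- function(f, coords, step = 1e-6) {
  g <- matrix(0, nrow(coords), 3)
  for (i in seq_len(nrow(coords))) for (j in 1:3) {
    cp <- coords; cm <- coords
    cp[i, j] <- cp[i, j] + step
    cm[i, j] <- cm[i, j] - step
    g[i, j] <- (f(cp) - f(cm)) / (2 * step)
  }
  g
}

rigid_motion <- function(coords, seed = 1) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  sweep(coords %*% t(R), 2, rnorm(3, sd = 5), "+")
}
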