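# Independent oracles used across test files. These deliberately use naive
# formulations (triple loops, BFS, enumeration) distinct from the package's
# matrix/igraph implementations.

# symmetric random weighted adjacency with zero diagonal
random_adjacency <- function(n) {
  a <- matrix(stats::runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  rownames(a) <- colnames(a) <- sprintf("g%03d", seq_len(n))
  a
}

# topological overlap by direct triple loop over the printed equation
naive_tom <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

# largest connected component size of a logical adjacency matrix, by BFS
naive_largest_component <- function(adj) {
  n <- nrow(adj)
  if (n == 0) return(0)
  seen <- rep(FALSE, n)
  best <- 0
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE; size <- 0
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]; size <- size + 1
      nb <- which(adj[v, ] & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    best <- max(best, size)
  }
  best
}

# sigma trajectory for a fixed removal order, recomputing components from
# scratch after every single removal
naive_attack <- function(adj, order_idx) {
  n0 <- nrow(adj)
  sigma <- numeric(n0)
  alive <- rep(TRUE, n0)
  for (i in seq_along(order_idx)) {
    alive[order_idx[i]] <- FALSE
    sub <- adj[alive, alive, drop = FALSE]
    sigma[i] <- naive_largest_component(sub) / n0
  }
  sigma
}

# BH step-up by direct enumeration of the definition
naive_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  adj <- p[ord] * m / seq_len(m)
  for (i in seq_len(m)) q[ord[i]] <- min(1, min(adj[i:m]))
  q
}

# two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration
naive_fisher2x2 <- function(x11, x12, x21, x22) {
  m <- x11 + x12; n <- x21 + x22; k <- x11 + x21
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(x11, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# hypergeometric upper-tail p by summing the pmf
naive_hyper_upper <- function(overlap, set_size, bg_size, module_size) {
  support <- overlap:min(set_size, module_size)
  sum(stats::dhyper(support, set_size, bg_size - set_size, module_size))
}

# adjacency matrices of small named graphs used by robustness tests
star_graph <- function(n = 5) {
  a <- matrix(FALSE, n, n)
  a[1, 2:n] <- a[2:n, 1] <- TRUE
  rownames(a) <- colnames(a) <- sprintf("n%d", seq_len(n))
  a
}
complete_graph <- function(n) {
  a <- matrix(TRUE, n, n); diag(a) <- FALSE
  rownames(a) <- colnames(a) <- sprintf("n%d", seq_len(n))
  a
}
as_igraph <- function(a) igraph::graph_from_adjacency_matrix(a, "undirected")
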