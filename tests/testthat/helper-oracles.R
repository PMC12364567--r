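# Independent oracles and fixture builders shared across the suite.
# Oracles deliberately use different representations from the package
# (bitmasks, exhaustive enumeration) so they cannot share a defect with
# the code paths they check.

# --- graphs as adjacency matrices -------------------------------------------

path_network <- function(nodes = c("A", "B", "C", "D")) {
  compartment_network(nodes, cbind(nodes[-length(nodes)], nodes[-1]))
}

star_network <- function() default_compartment_network()

# all labeled connected graphs on n nodes, as logical adjacency matrices
all_connected_graphs <- function(n) {
  stopifnot(n >= 1, n <= 5)
  if (n == 1) return(list(matrix(FALSE, 1, 1)))
  pairs <- utils::combn(n, 2)
  npairs <- ncol(pairs)
  out <- list()
  for (mask in 0:(2^npairs - 1)) {
    adj <- matrix(FALSE, n, n)
    for (b in seq_len(npairs)) {
      if (bitwAnd(mask, bitwShiftL(1L, b - 1L)) != 0L) {
        adj[pairs[1, b], pairs[2, b]] <- TRUE
        adj[pairs[2, b], pairs[1, b]] <- TRUE
      }
    }
    if (is_connected_adj(adj)) out[[length(out) + 1L]] <- adj
  }
  out
}

is_connected_adj <- function(adj) {
  n <- nrow(adj)
  if (n == 1) return(TRUE)
  seen <- c(TRUE, rep(FALSE, n - 1))
  frontier <- 1L
  while (length(frontier) > 0) {
    nxt <- which(apply(adj[frontier, , drop = FALSE], 2, any) & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

random_connected_graph <- function(n, p = 0.4) {
  repeat {
    adj <- matrix(FALSE, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      if (stats::runif(1) < p) adj[i, j] <- adj[j, i] <- TRUE
    if (is_connected_adj(adj)) return(adj)
  }
}

adj_to_network <- function(adj, nodes = NULL) {
  n <- nrow(adj)
  if (is.null(nodes)) nodes <- paste0("n", seq_len(n))
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  edges <- if (nrow(idx) == 0) matrix(character(), ncol = 2) else
    cbind(nodes[idx[, 1]], nodes[idx[, 2]])
  compartment_network(nodes, edges)
}

# independent pattern classifier working on index vectors + adjacency matrix
oracle_classify <- function(idx, adj) {
  n <- nrow(adj)
  k <- length(idx)
  if (k == 0) return("ABSENT")
  if (k == n) return("A")
  if (k == 1) return("U")
  if (k == 2) return(if (adj[idx[1], idx[2]]) "B" else "N2")
  "PARTIAL"
}

# --- JTC brute force over all C(n,k1) x C(n,k2) placements -------------------

oracle_jtc_p <- function(n, k1, k2, m_obs) {
  jac <- function(a, b) {
    i <- length(intersect(a, b)); u <- length(union(a, b))
    if (u == 0) 1 else i / u
  }
  j_obs <- if (k1 + k2 == 0) 1 else m_obs / (k1 + k2 - m_obs)
  A <- if (k1 == 0) list(integer()) else utils::combn(n, k1, simplify = FALSE)
  B <- if (k2 == 0) list(integer()) else utils::combn(n, k2, simplify = FALSE)
  vals <- unlist(lapply(A, function(a) vapply(B, function(b) jac(a, b), 1)))
  mean(vals <= j_obs + 1e-12)
}

# --- exact rank-sum by exhaustive enumeration --------------------------------

oracle_ranksum_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)])
  combos <- utils::combn(nx + ny, nx)
  w_null <- colSums(matrix(r[combos], nrow = nx))
  mu <- nx * (nx + ny + 1) / 2
  mean(abs(w_null - mu) >= abs(w_obs - mu) - 1e-9)
}

# --- small abundance fixtures ------------------------------------------------

toy_table <- function(values, samples = paste0("s", seq_len(nrow(values)))) {
  abundance_table(samples, values)
}

write_toy_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}
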