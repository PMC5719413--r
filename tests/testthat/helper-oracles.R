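# Independent oracles and small graph builders shared across tests.

# Brute-force triplet census: enumerate all C(n, 3) node triples and
# classify their 2-paths directly.  Independent of the package's
# adjacency-matrix computation.
oracle_census <- function(net) {
  A <- matrix(FALSE, n_nodes(net), n_nodes(net),
              dimnames = list(net$nodes, net$nodes))
  for (k in seq_len(n_edges(net))) {
    a <- net$edges$from[k]; b <- net$edges$to[k]
    A[a, b] <- TRUE; A[b, a] <- TRUE
  }
  T_conn <- 0L; T_closed <- 0L; n_tri <- 0L
  if (n_nodes(net) >= 3L) {
    triples <- combn(net$nodes, 3L)
    for (j in seq_len(ncol(triples))) {
      tr <- triples[, j]
      m <- sum(A[tr[1], tr[2]], A[tr[1], tr[3]], A[tr[2], tr[3]])
      if (m == 2L) {
        T_conn <- T_conn + 1L
      } else if (m == 3L) {
        T_conn <- T_conn + 3L
        T_closed <- T_closed + 3L
        n_tri <- n_tri + 1L
      }
    }
  }
  list(T = T_conn, T_closed = T_closed, n_triangles = n_tri)
}

# Erdos-Renyi signed network with uniform random valences.
rand_signed_net <- function(n, p, nodes = sprintf("v%02d", seq_len(n))) {
  pairs <- t(combn(nodes, 2L))
  keep <- runif(nrow(pairs)) < p
  signed_network(
    data.frame(from = pairs[keep, 1L], to = pairs[keep, 2L],
               valence = sample(c(1L, -1L), sum(keep), replace = TRUE),
               stringsAsFactors = FALSE),
    nodes = nodes)
}

# Compact builder: net_of("a-b", "b-c", valence = c(1, -1))
net_of <- function(..., valence = 1L, nodes = NULL) {
  pairs <- do.call(rbind, strsplit(c(...), "-", fixed = TRUE))
  signed_network(
    data.frame(from = pairs[, 1L], to = pairs[, 2L],
               valence = rep_len(valence, nrow(pairs)),
               stringsAsFactors = FALSE),
    nodes = nodes)
}
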