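#' Construct a signed, undirected social network
#'
#' A `signed_network` is an undirected simple graph over named characters in
#' which every tie carries a valence: `+1` (liking) or `-1` (disliking).
#' Optionally a tie may carry a free-text relationship label (e.g. a kin
#' term); labels are metadata only and never influence structure or model
#' behaviour.
#'
#' Edges are stored canonically with the lexicographically smaller endpoint
#' first and rows sorted by endpoint pair, so two networks with the same
#' ties compare equal regardless of input order.
#'
#' @param edges data frame with character columns `from` and `to`, a
#'   `valence` column (accepted tokens: `1`, `-1`, `"+1"`, `"-1"`,
#'   `"like"`, `"dislike"`), and an optional `label` column.
#' @param nodes optional character vector of node names; node names
#'   appearing in `edges` are added automatically, so this is only needed
#'   for isolated nodes.
#' @return An object of class `signed_network`.
#' @examples
#' net <- signed_network(data.frame(
#'   from = c("A", "B", "A"), to = c("B", "C", "C"),
#'   valence = c(1, 1, -1)
#' ))
#' n_nodes(net)
#' network_density(net)
#' @export
signed_network <- function(edges, nodes = NULL) {
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    edges <- data.frame(from = character(), to = character(),
                        valence = integer(), label = character(),
                        stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  required <- c("from", "to", "valence")
  missing_cols <- setdiff(required, names(edges))
  if (length(missing_cols) > 0L) {
    stop("edges is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  from <- as.character(edges$from)
  to <- as.character(edges$to)
  if (anyNA(from) || anyNA(to) || any(!nzchar(from)) || any(!nzchar(to))) {
    stop("node names must be non-empty, non-missing strings")
  }
  if (any(grepl("[\t\n]", c(from, to)))) {
    stop("node names may not contain tab or newline characters")
  }
  valence <- as_valence(edges$valence)
  label <- if ("label" %in% names(edges)) as.character(edges$label) else
    rep(NA_character_, length(from))

  loops <- from == to
  if (any(loops)) {
    stop("self-loops are not allowed (node ", from[which(loops)[1L]], ")")
  }
  swap <- from > to
  tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  key <- paste(from, to, sep = "\t")
  if (anyDuplicated(key)) {
    stop("duplicate edge: ", sub("\t", " -- ", key[duplicated(key)][1L]))
  }
  ord <- order(from, to, method = "radix")
  edges <- data.frame(from = from[ord], to = to[ord],
                      valence = valence[ord], label = label[ord],
                      stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  nodes <- sort(unique(c(as.character(nodes), edges$from, edges$to)),
                method = "radix")
  if (length(nodes) > 0L && any(grepl("[\t\n]", nodes))) {
    stop("node names may not contain tab or newline characters")
  }
  structure(list(nodes = nodes, edges = edges), class = "signed_network")
}

as_valence <- function(v) {
  out <- integer(length(v))
  vc <- tolower(trimws(as.character(v)))
  pos <- vc %in% c("1", "+1", "like")
  neg <- vc %in% c("-1", "dislike")
  bad <- !(pos | neg)
  if (any(bad)) {
    stop("invalid valence token: '", as.character(v)[which(bad)[1L]],
         "' (expected +1/-1/like/dislike)")
  }
  out[pos] <- 1L
  out[neg] <- -1L
  out
}

#' @export
print.signed_network <- function(x, ...) {
  np <- sum(x$edges$valence == 1L)
  nn <- sum(x$edges$valence == -1L)
  cat(sprintf("Signed network: %d nodes, %d edges (%d positive, %d negative)\n",
              n_nodes(x), n_edges(x), np, nn))
  if (n_nodes(x) >= 2L) {
    cat(sprintf("Density %.3f; %d component(s)\n", network_density(x),
                length(network_components(x))))
  }
  invisible(x)
}

#' Number of nodes / edges of a signed network
#' @param net a [signed_network] object.
#' @return Integer count.
#' @export
n_nodes <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  length(net$nodes)
}

#' @rdname n_nodes
#' @export
n_edges <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  nrow(net$edges)
}

# internal: canonical "a\tb" key with a < b
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\t")
}

edge_keys <- function(net) pair_key(net$edges$from, net$edges$to)

# internal: named valence lookup vector keyed by pair_key
valence_map <- function(net) {
  setNames(net$edges$valence, edge_keys(net))
}

# internal: logical adjacency matrix with node-name dimnames
adjacency_matrix <- function(net) {
  n <- n_nodes(net)
  A <- matrix(FALSE, n, n, dimnames = list(net$nodes, net$nodes))
  if (n_edges(net) > 0L) {
    i <- match(net$edges$from, net$nodes)
    j <- match(net$edges$to, net$nodes)
    A[cbind(i, j)] <- TRUE
    A[cbind(j, i)] <- TRUE
  }
  A
}

#' Network density
#'
#' The number of observed ties divided by the number of ties mathematically
#' possible, `|E| / (n(n-1)/2)`.
#'
#' @param net a [signed_network] with at least two nodes.
#' @return A fraction in `[0, 1]`.
#' @export
network_density <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  n <- n_nodes(net)
  if (n < 2L) stop("density is undefined for networks with fewer than 2 nodes")
  n_edges(net) / (n * (n - 1) / 2)
}

#' Census of connected and closed triplets
#'
#' A connected triplet is a set of three nodes holding at least two of the
#' three possible ties (a 2-path); it is closed when all three ties are
#' present.  Counting convention: each unordered node triple contributes
#' one connected triplet per distinct 2-path within it, so a triangle
#' contributes three connected triplets, all closed.  Under
#' `mode = "triplets"` (the default) `T_closed` is therefore three times
#' the triangle count and the ratio `T_closed / T` equals the global
#' clustering coefficient.  Under `mode = "triangles"` the closed count is
#' the raw triangle count instead, while `T` is unchanged.
#'
#' @param net a [signed_network]. The census ignores valences.
#' @param mode `"triplets"` or `"triangles"`; see Details.
#' @return A list of class `triplet_census` with elements `T` (connected
#'   triplets), `T_closed` (closed connected triplets under `mode`),
#'   `n_triangles`, and `mode`.
#' @examples
#' tri <- signed_network(data.frame(from = c("a", "a", "b"),
#'                                  to = c("b", "c", "c"), valence = 1))
#' triplet_census(tri) # T = 3, T_closed = 3
#' @export
triplet_census <- function(net, mode = c("triplets", "triangles")) {
  stopifnot(inherits(net, "signed_network"))
  mode <- match.arg(mode)
  A <- adjacency_matrix(net) * 1L
  deg <- rowSums(A)
  n_paths2 <- sum(choose(deg, 2))
  n_tri <- if (n_nodes(net) >= 3L) sum(diag(A %*% A %*% A)) / 6 else 0
  structure(list(T = as.integer(round(n_paths2)),
                 T_closed = as.integer(round(
                   if (mode == "triplets") 3 * n_tri else n_tri)),
                 n_triangles = as.integer(round(n_tri)),
                 mode = mode),
            class = "triplet_census")
}

#' @export
print.triplet_census <- function(x, ...) {
  cat(sprintf("Triplet census (%s mode): T = %d connected, T_closed = %d closed (%d triangles)\n",
              x$mode, x$T, x$T_closed, x$n_triangles))
  invisible(x)
}

#' Edges incident to a set of characters
#'
#' Returns every tie with at least one endpoint in `characters` (the union
#' over the set, so an edge joining two listed characters is returned
#' once).
#'
#' @param net a [signed_network].
#' @param characters character vector of node names; may be empty.
#' @return A data frame of edges (subset of `net$edges`).
#' @export
incident_edges <- function(net, characters) {
  stopifnot(inherits(net, "signed_network"))
  characters <- as.character(characters)
  unknown <- setdiff(characters, net$nodes)
  if (length(unknown) > 0L) {
    stop("unknown character(s): ", paste(unknown, collapse = ", "))
  }
  keep <- net$edges$from %in% characters | net$edges$to %in% characters
  out <- net$edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Connected components of a signed network
#'
#' @param net a [signed_network].
#' @return A list of character vectors (node names per component), sorted
#'   by decreasing size, ties broken by the lexicographically smallest
#'   member.  Singleton (isolated) nodes form their own components.
#' @export
network_components <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  g <- as_igraph(net)
  comp <- igraph::components(g)
  groups <- split(names(comp$membership), comp$membership)
  groups <- lapply(groups, function(v) sort(v, method = "radix"))
  sizes <- vapply(groups, length, integer(1))
  first <- vapply(groups, `[[`, character(1), 1L)
  groups <- groups[order(-sizes, first, method = "radix")]
  names(groups) <- NULL
  groups
}

#' Convert a signed network to an igraph object
#'
#' Vertices keep their names; edges carry `valence` (+1/-1) and `label`
#' attributes.
#'
#' @param net a [signed_network].
#' @return An undirected `igraph` graph.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}
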