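test_that("construction canonicalises edges and enforces invariants", {
  net <- signed_network(data.frame(from = c("B", "c"), to = c("a", "B"),
                                   valence = c("like", "dislike")))
  expect_equal(net$edges$from, c("B", "B"))
  expect_equal(net$edges$to, c("a", "c"))
  expect_equal(net$edges$valence, c(1L, -1L))
  # input order and endpoint order do not matter
  net2 <- signed_network(data.frame(from = c("B", "a"), to = c("c", "B"),
                                    valence = c(-1, 1)))
  expect_equal(net$edges, net2$edges)

  expect_error(signed_network(data.frame(from = "A", to = "A", valence = 1)),
               "self-loop")
  expect_error(
    signed_network(data.frame(from = c("A", "B"), to = c("B", "A"),
                              valence = c(1, -1))),
    "duplicate")
  expect_error(signed_network(data.frame(from = "A", to = "B", valence = 2)),
               "valence")
})

test_that("density matches the observed/possible tie ratio", {
  expect_equal(network_density(net_of("a-b", "a-c", "b-c")), 1)
  empty <- signed_network(NULL, nodes = sprintf("n%02d", 1:15))
  expect_equal(network_density(empty), 0)
  expect_error(network_density(signed_network(NULL, nodes = "solo")),
               "undefined")
  # invariant under node relabelling
  net <- net_of("a-b", "b-c", "c-d", "a-d")
  relab <- signed_network(data.frame(
    from = c("w", "x", "y", "w"), to = c("x", "y", "z", "z"),
    valence = net$edges$valence))
  expect_equal(network_density(net), network_density(relab))
})

test_that("triplet census counts 2-paths and closed triplets", {
  tri <- net_of("a-b", "a-c", "b-c")
  cen <- triplet_census(tri)
  expect_equal(cen$T, 3L)
  expect_equal(cen$T_closed, 3L)

  path <- net_of("a-b", "b-c")
  expect_equal(triplet_census(path)$T, 1L)
  expect_equal(triplet_census(path)$T_closed, 0L)

  star <- net_of("hub-a", "hub-b", "hub-c")
  expect_equal(triplet_census(star)$T, 3L)
  expect_equal(triplet_census(star)$T_closed, 0L)

  # triangles mode keeps T but reports the raw triangle count
  cen_t <- triplet_census(tri, mode = "triangles")
  expect_equal(cen_t$T, 3L)
  expect_equal(cen_t$T_closed, 1L)
})

test_that("census agrees with brute-force triple enumeration", {
  set.seed(421)
  for (i in 1:40) {
    n <- sample(4:12, 1)
    net <- rand_signed_net(n, runif(1, 0.15, 0.7))
    cen <- triplet_census(net)
    ora <- oracle_census(net)
    expect_equal(cen$T, ora$T)
    expect_equal(cen$T_closed, ora$T_closed)
    expect_equal(cen$n_triangles, ora$T_closed / 3L)
    expect_equal(triplet_census(net, mode = "triangles")$T_closed,
                 ora$n_triangles)
  }
})

test_that("census is structure-only: flipping valences changes nothing", {
  set.seed(99)
  net <- rand_signed_net(10, 0.4)
  flipped <- signed_network(transform(net$edges, valence = -valence),
                            nodes = net$nodes)
  expect_equal(unclass(triplet_census(net)),
               unclass(triplet_census(flipped)))
})

test_that("incident_edges returns the union of touching ties", {
  net <- net_of("a-b", "a-c", "b-c", "c-d", "d-e")
  expect_equal(nrow(incident_edges(net, c("a", "b"))), 3L)  # shared a-b once
  expect_equal(nrow(incident_edges(net, "e")), 1L)
  expect_equal(nrow(incident_edges(net, character())), 0L)
  expect_error(incident_edges(net, "nobody"), "unknown character")
})

test_that("components partition the nodes in canonical order", {
  net <- net_of("a-b", "b-c", "x-y", nodes = c("a", "b", "c", "x", "y", "z"))
  comps <- network_components(net)
  expect_length(comps, 3L)
  expect_equal(comps[[1]], c("a", "b", "c"))  # largest first
  expect_equal(comps[[2]], c("x", "y"))
  expect_equal(comps[[3]], "z")
  expect_equal(sum(lengths(comps)), n_nodes(net))

  edgeless <- signed_network(NULL, nodes = c("p", "q", "r", "s"))
  expect_length(network_components(edgeless), 4L)
  full <- net_of("a-b", "a-c", "b-c")
  expect_length(network_components(full), 1L)
})

test_that("edge-list TSV round-trips losslessly", {
  net <- canonical_fixture("balanced")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_signed_edgelist(net, f)
  expect_equal(read_signed_edgelist(f), net)
})

test_that("edge-list parser reports offending line numbers", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("source\ttarget\tvalence\tlabel",
               "A\tB\t+1\t",
               "A\tA\t+1\t"), f)
  expect_error(read_signed_edgelist(f), "line 3: self-loop")

  writeLines(c("source\ttarget\tvalence\tlabel",
               "A\tB\tlike\t",
               "B\tA\tdislike\t"), f)
  expect_error(read_signed_edgelist(f), "line 3: duplicate edge")

  writeLines(c("source\ttarget\tvalence\tlabel",
               "A\tB\tmaybe\t"), f)
  expect_error(read_signed_edgelist(f), "line 2.*valence")

  writeLines(c("who\twith\thow", "A\tB\t+1"), f)
  expect_error(read_signed_edgelist(f), "line 1")

  # valence aliases map onto signs
  writeLines(c("source\ttarget\tvalence",
               "A\tB\tlike", "B\tC\tdislike"), f)
  net <- read_signed_edgelist(f)
  expect_equal(net$edges$valence, c(1L, -1L))
})

test_that("closure ratio equals igraph's global clustering coefficient", {
  set.seed(7)
  for (i in 1:10) {
    net <- rand_signed_net(9, 0.5)
    cen <- triplet_census(net)
    if (cen$T == 0L) next
    expect_equal(p_triangle(net),
                 igraph::transitivity(as_igraph(net), type = "global"))
  }
})

test_that("GraphML export carries the valence attribute", {
  net <- net_of("a-b", "b-c", valence = c(1, -1))
  f <- withr::local_tempfile(fileext = ".graphml")
  write_signed_graphml(net, f)
  g <- igraph::read_graph(f, format = "graphml")
  expect_setequal(igraph::edge_attr(g, "valence"), c(1, -1))
})
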