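test_that("default fixture spec encodes the stimulus constraints", {
  spec <- default_fixture_spec("balanced")
  expect_equal(spec$n_edges, 23L)
  expect_equal(spec$n_positive, 15L)
  expect_equal(spec$n_negative, 8L)
  expect_equal(spec$n_components, 2L)
  expect_equal(sort(spec$component_sizes, decreasing = TRUE), c(8L, 7L))
  expect_equal(spec$degree_constraints[["Peter"]], 5L)
  expect_equal(spec$degree_constraints[["Isabelle"]], 2L)
  # Lewis and Alyssa sit in different components; Lewis's is the larger
  expect_true(spec$hub_assignment[["Lewis"]] != spec$hub_assignment[["Alyssa"]])
  expect_equal(spec$component_sizes[[spec$hub_assignment[["Lewis"]]]], 8L)
  # every pair co-listed in the seed-set catalogue is required non-adjacent
  nonadj <- paste(pmin(spec$nonadjacency$a, spec$nonadjacency$b),
                  pmax(spec$nonadjacency$a, spec$nonadjacency$b))
  sets <- canonical_seed_sets()$characters
  for (s in sets[lengths(sets) > 1L]) {
    prs <- combn(sort(s), 2L)
    expect_true(all(paste(prs[1, ], prs[2, ]) %in% nonadj))
  }
  expect_error(default_fixture_spec("chaotic"))
})

test_that("spec constructor rejects inconsistent constraint sets", {
  expect_error(fixture_spec(n_positive = 10L), "n_edges")
  expect_error(fixture_spec(component_sizes = c(9L, 7L)), "sum")
  expect_error(fixture_spec(degree_constraints = c(Zorro = 3L)),
               "unknown characters")
})

test_that("generation is deterministic in the seed and satisfies its spec", {
  spec <- default_fixture_spec("balanced")
  a <- generate_fixture(spec)
  b <- generate_fixture(spec)
  expect_identical(a, b)
  expect_length(validate_fixture(a, spec), 0L)

  other <- generate_fixture(default_fixture_spec("balanced", rng_seed = 4242L))
  expect_false(identical(a$edges, other$edges))
  expect_length(validate_fixture(other,
                                 default_fixture_spec("balanced",
                                                      rng_seed = 4242L)), 0L)
})

test_that("packaged canonical fixtures are the frozen generator output", {
  for (cond in c("balanced", "imbalanced")) {
    frozen <- canonical_fixture(cond)
    expect_identical(frozen$edges[c("from", "to", "valence")],
                     generate_fixture(
                       default_fixture_spec(cond))$edges[c("from", "to",
                                                           "valence")])
    expect_length(validate_fixture(frozen, default_fixture_spec(cond)), 0L)
  }
})

test_that("balanced and imbalanced conditions share one structure", {
  bal <- canonical_fixture("balanced")
  imb <- canonical_fixture("imbalanced")
  expect_identical(bal$edges[c("from", "to")], imb$edges[c("from", "to")])
  expect_equal(sum(imb$edges$valence == 1L), 15L)
  expect_equal(sum(imb$edges$valence == -1L), 8L)
  expect_equal(balance_report(bal)$n_imbalanced_triangles, 0L)
  expect_gte(balance_report(imb)$n_imbalanced_triangles, 1L)
})

test_that("the partially recoverable motif around Henry is pinned down", {
  net <- canonical_fixture("balanced")
  keys <- paste(net$edges$from, net$edges$to)
  expect_true(all(c("Anne Henry", "Elizabeth Henry", "Henry James",
                    "Elizabeth James") %in% keys))
  expect_false("Anne Elizabeth" %in% keys)
  # <James, Henry, Elizabeth> closed; <Anne, Henry, Elizabeth> open
  expect_gte(triplet_census(net)$n_triangles, 1L)
})

test_that("balance_report classifies triangles by valence sign product", {
  expect_equal(balance_report(net_of("a-b", "a-c", "b-c",
                                     valence = c(1, 1, 1)))$n_balanced_triangles,
               1L)
  rep_ <- balance_report(net_of("a-b", "a-c", "b-c", valence = c(1, 1, -1)))
  expect_equal(rep_$n_imbalanced_triangles, 1L)
  expect_equal(rep_$n_balanced_triangles + rep_$n_imbalanced_triangles,
               rep_$n_triangles)
  # two negatives keep the product positive (balanced)
  expect_equal(balance_report(net_of("a-b", "a-c", "b-c",
                                     valence = c(1, -1, -1)))$n_imbalanced_triangles,
               0L)
})

test_that("validator reports violated constraints by name", {
  spec <- default_fixture_spec("balanced")
  net <- canonical_fixture("balanced")

  # flip the valence of one triangle edge: balance and counts break
  tampered <- net$edges
  rep0 <- balance_report(net)
  tri_edge <- which(tampered$from == "Elizabeth" & tampered$to == "Henry")
  tampered$valence[tri_edge] <- -tampered$valence[tri_edge]
  bad <- signed_network(tampered, nodes = net$nodes)
  v <- validate_fixture(bad, spec)
  expect_true(any(grepl("balance", v)))
  expect_true(any(grepl("n_positive|n_negative", v)))

  # drop one Isabelle edge: degree and edge-count constraints break
  drop <- which(tampered$from == "Isabelle" | tampered$to == "Isabelle")[1]
  bad2 <- signed_network(net$edges[-drop, ], nodes = net$nodes)
  v2 <- validate_fixture(bad2, spec)
  expect_true(any(grepl("degree of Isabelle", v2)))
  expect_true(any(grepl("n_edges", v2)))
})

test_that("components of generated fixtures are internally connected", {
  net <- canonical_fixture("balanced")
  comps <- network_components(net)
  expect_length(comps, 2L)
  expect_equal(sort(lengths(comps), decreasing = TRUE), c(8L, 7L))
})
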