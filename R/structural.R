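# Structural recall model.
#
# Recall of tie existence proceeds in two phases: (i) every tie incident to
# a pre-selected set of seed characters is recalled exactly; (ii) every
# pair of characters still unconnected after seeding is visited exactly
# once, in random order.  A visited pair that would close at least one
# triangle in the current recalled graph gains a tie with probability
# p_triangle = T_closed / T (the target network's closed/open triplet
# ratio); any other pair gains a tie with a background probability derived
# from the target's density.  Both probabilities are computed from the
# target network, never from the recalled graph.

#' Parameters of the structural recall model
#'
#' @param p_triangle,p_background optional explicit probabilities; when
#'   `NULL` (default) they are computed from the target network by
#'   [p_triangle()] / [p_background()].
#' @param t_closed_override optional count substituted for the target's
#'   closed-triplet count in both probability formulas, used by the
#'   closure mis-recall robustness sweep; must lie in `[0, T]`.
#' @param census_mode `"triplets"` (closed count = 3 x triangles; the
#'   closure probability equals the global clustering coefficient) or
#'   `"triangles"` (closed count = raw triangle count).
#' @param background_mode how the background probability's denominator is
#'   formed: `"literal"` uses `(n(n-1)/2) * T`; `"subtractive"` uses
#'   `n(n-1)/2 - T`.
#' @param closure_against `"recalled"` (default) evaluates triangle
#'   closure against the evolving recalled graph, so ties added earlier in
#'   the pass can close later triads; `"seed_only"` evaluates closure
#'   against the seed graph only.
#' @return An object of class `structural_params`.
#' @export
structural_params <- function(p_triangle = NULL, p_background = NULL,
                              t_closed_override = NULL,
                              census_mode = c("triplets", "triangles"),
                              background_mode = c("literal", "subtractive"),
                              closure_against = c("recalled", "seed_only")) {
  chk01 <- function(p, nm) {
    if (!is.null(p) && (!is.numeric(p) || length(p) != 1L || p < 0 || p > 1)) {
      stop(nm, " must be a single probability in [0, 1]")
    }
  }
  chk01(p_triangle, "p_triangle")
  chk01(p_background, "p_background")
  if (!is.null(t_closed_override) &&
      (length(t_closed_override) != 1L || t_closed_override < 0)) {
    stop("t_closed_override must be a single non-negative count")
  }
  structure(list(p_triangle = p_triangle, p_background = p_background,
                 t_closed_override = t_closed_override,
                 census_mode = match.arg(census_mode),
                 background_mode = match.arg(background_mode),
                 closure_against = match.arg(closure_against)),
            class = "structural_params")
}

# closed-triplet count actually used: the override, bounded by [0, T]
resolve_t_closed <- function(census, params) {
  tc <- params$t_closed_override
  if (is.null(tc)) return(census$T_closed)
  if (tc > census$T) {
    stop("t_closed_override (", tc, ") exceeds the connected-triplet count T (",
         census$T, ")")
  }
  tc
}

#' Triadic-closure probability of a target network
#'
#' `T_closed / T`: the target network's closed connected triplets divided
#' by its connected triplets (the global clustering coefficient under the
#' default census mode).  An explicit `p_triangle` in `params` takes
#' precedence; a `t_closed_override` replaces the closed count.
#'
#' @param target a [signed_network].
#' @param params a [structural_params] object.
#' @return A probability.
#' @export
p_triangle <- function(target, params = structural_params()) {
  if (!is.null(params$p_triangle)) return(params$p_triangle)
  census <- triplet_census(target, mode = params$census_mode)
  if (census$T == 0L) {
    stop("p_triangle is undefined: the target network has no connected triplets")
  }
  resolve_t_closed(census, params) / census$T
}

#' Background tie probability of a target network
#'
#' The probability that a visited pair which closes no triangle gains a
#' tie.  It reflects the density of the non-triadic part of the target:
#' the numerator is `|E| - T_closed`; the denominator is
#' `(n(n-1)/2) * T` in `"literal"` mode or `n(n-1)/2 - T` in
#' `"subtractive"` mode.  The result is clamped into `[0, 1]` with a
#' warning when the raw formula leaves that range (e.g. a negative
#' numerator in triangle-dense targets).
#'
#' @inheritParams p_triangle
#' @return A probability.
#' @export
p_background <- function(target, params = structural_params()) {
  if (!is.null(params$p_background)) return(params$p_background)
  census <- triplet_census(target, mode = params$census_mode)
  n <- n_nodes(target)
  pairs <- n * (n - 1) / 2
  tc <- resolve_t_closed(census, params)
  num <- n_edges(target) - tc
  den <- switch(params$background_mode,
                literal = pairs * census$T,
                subtractive = pairs - census$T)
  if (den <= 0) {
    stop("p_background is undefined: non-positive denominator (", den, ")")
  }
  p <- num / den
  if (p < 0 || p > 1) {
    warning("background probability ", signif(p, 4),
            " clamped into [0, 1]")
    p <- min(max(p, 0), 1)
  }
  p
}

#' Simulate one structural recall pass
#'
#' Seeds the recalled graph with every target tie incident to
#' `seed_characters`, then visits every still-unconnected node pair exactly
#' once in a seeded random order.  A visited pair with at least one common
#' neighbour in the current recalled graph gains a tie with probability
#' `p_triangle`; otherwise with probability `p_background` (one draw per
#' pair; a rejected closure draw gets no second chance).  The pass ends
#' when all pairs have been considered.
#'
#' @param target a [signed_network] (the true stimulus network).
#' @param seed_characters character vector of seed node names; may be
#'   empty, giving pure-heuristic recall.
#' @param params a [structural_params] object.
#' @param rng_seed integer seed for the replicate; `NULL` uses (and
#'   advances) the current RNG stream.
#' @return An object of class `recalled_network`: a list with `nodes`,
#'   `edges` (data frame `from`, `to`, `is_seed`), `additions` (data frame
#'   of heuristically added edges in addition order, with a `closed` flag
#'   and the list-column `witnesses` of common neighbours at the moment of
#'   addition), `seed_characters`, and the resolved probabilities.
#' @examples
#' net <- canonical_fixture("balanced")
#' rec <- simulate_structural_recall(net, c("Lewis", "Alyssa"), rng_seed = 1)
#' score_structure(net, rec)
#' @export
simulate_structural_recall <- function(target, seed_characters = character(),
                                       params = structural_params(),
                                       rng_seed = NULL) {
  stopifnot(inherits(target, "signed_network"))
  seed_characters <- as.character(seed_characters)
  seed_df <- incident_edges(target, seed_characters)  # validates names
  pt <- if (!is.null(params$p_triangle)) params$p_triangle else
    p_triangle(target, params)
  pb <- if (!is.null(params$p_background)) params$p_background else
    p_background(target, params)

  nodes <- target$nodes
  n <- length(nodes)
  R <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (nrow(seed_df) > 0L) {
    i <- match(seed_df$from, nodes)
    j <- match(seed_df$to, nodes)
    R[cbind(i, j)] <- TRUE
    R[cbind(j, i)] <- TRUE
  }
  S <- R  # seed-only adjacency, for closure_against = "seed_only"

  with_rng_seed(rng_seed, {
    pairs <- which(upper.tri(R) & !R, arr.ind = TRUE)
    pairs <- pairs[sample.int(nrow(pairs)), , drop = FALSE]
    add_i <- add_j <- integer(0)
    add_closed <- logical(0)
    add_wit <- list()
    for (k in seq_len(nrow(pairs))) {
      a <- pairs[k, 1L]; b <- pairs[k, 2L]
      wit <- if (params$closure_against == "recalled") {
        which(R[a, ] & R[b, ])
      } else {
        which(S[a, ] & S[b, ])
      }
      closes <- length(wit) > 0L
      p <- if (closes) pt else pb
      if (p > 0 && runif(1) < p) {
        R[a, b] <- TRUE; R[b, a] <- TRUE
        add_i <- c(add_i, a); add_j <- c(add_j, b)
        add_closed <- c(add_closed, closes)
        add_wit <- c(add_wit, list(nodes[wit]))
      }
    }
    from <- c(seed_df$from, pmin(nodes[add_i], nodes[add_j]))
    to <- c(seed_df$to, pmax(nodes[add_i], nodes[add_j]))
    is_seed <- c(rep(TRUE, nrow(seed_df)), rep(FALSE, length(add_i)))
    additions <- data.frame(
      from = pmin(nodes[add_i], nodes[add_j]),
      to = pmax(nodes[add_i], nodes[add_j]),
      closed = add_closed, stringsAsFactors = FALSE)
    additions$witnesses <- add_wit
    structure(list(nodes = nodes,
                   edges = data.frame(from = from, to = to,
                                      is_seed = is_seed,
                                      stringsAsFactors = FALSE),
                   additions = additions,
                   seed_characters = seed_characters,
                   p_triangle = pt, p_background = pb,
                   params = params),
              class = "recalled_network")
  })
}

#' @export
print.recalled_network <- function(x, ...) {
  cat(sprintf(
    "Recalled network: %d edges (%d seed, %d heuristic) over %d nodes\n",
    nrow(x$edges), sum(x$edges$is_seed), sum(!x$edges$is_seed),
    length(x$nodes)))
  cat(sprintf("Seeds: %s; p_triangle = %.4f, p_background = %.6f%s\n",
              if (length(x$seed_characters)) {
                paste(x$seed_characters, collapse = ", ")
              } else "(none)",
              x$p_triangle, x$p_background,
              if (!is.null(x$edges$valence)) "; valences assigned" else ""))
  invisible(x)
}
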