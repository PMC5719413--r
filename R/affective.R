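# Affective (valence) recall model.
#
# Seed ties start from their true valences, except that a fraction x of
# them is remembered with a randomly chosen valence (uniform over +1/-1,
# so about half of the corrupted ties stay accidentally correct).
# Heuristically added ties are valenced by structural balance: a tie
# closing one open triplet takes the sign product of the two existing
# valences; a tie closing several takes the sign of the mean of the sign
# products; a tie closing none takes +1 (positivity bias).  Valences are
# assigned in the same visit order and graph state as the structural pass.

#' Parameters of the affective recall model
#'
#' @param x fraction in `[0, 1]` of seed ties remembered with a randomly
#'   chosen valence (default 0.30, the model's operating point).
#' @param zero_tiebreak valence used when a tie closes several open
#'   triplets whose sign products average exactly zero: `"positive"`
#'   (default, consistent with the positivity bias), `"negative"`, or
#'   `"random"`.
#' @return An object of class `affect_params`.
#' @export
affect_params <- function(x = 0.30,
                          zero_tiebreak = c("positive", "negative", "random")) {
  if (!is.numeric(x) || length(x) != 1L || x < 0 || x > 1) {
    stop("x must be a single fraction in [0, 1]")
  }
  structure(list(x = x, zero_tiebreak = match.arg(zero_tiebreak)),
            class = "affect_params")
}

#' Corrupt a fraction of seed valences
#'
#' Chooses `round(x * n)` seed ties uniformly at random (half-up rounding)
#' and replaces each of their valences with an independent uniform draw
#' from `{+1, -1}`; a draw may coincide with the true valence.  The other
#' ties keep their true valences.
#'
#' @param true_valences integer vector of true valences (+1/-1).
#' @param params an [affect_params] object.
#' @param rng_seed integer seed; `NULL` uses the current RNG stream.
#' @return A list with `valence` (the possibly corrupted vector) and
#'   `corrupted` (logical vector marking the redrawn entries).
#' @export
corrupt_seed_valences <- function(true_valences, params = affect_params(),
                                  rng_seed = NULL) {
  stopifnot(inherits(params, "affect_params"))
  n <- length(true_valences)
  k <- floor(params$x * n + 0.5)  # round half up
  with_rng_seed(rng_seed, {
    corrupted <- rep(FALSE, n)
    valence <- as.integer(true_valences)
    if (k > 0L) {
      idx <- sample.int(n, k)
      corrupted[idx] <- TRUE
      valence[idx] <- sample(c(1L, -1L), k, replace = TRUE)
    }
    list(valence = valence, corrupted = corrupted)
  })
}

#' Valence of a newly recalled tie from its triadic context
#'
#' @param witness_products integer vector of sign products of the open
#'   triplets the new tie closes (one per common neighbour: the product of
#'   the two existing valences).  Empty when the tie closes no triplet.
#' @param params an [affect_params] object (for the zero tiebreak).
#' @return `+1` or `-1`.
#' @export
valence_for_new_tie <- function(witness_products,
                                params = affect_params()) {
  if (length(witness_products) == 0L) {
    return(1L)  # positivity bias
  }
  m <- mean(witness_products)
  if (m > 0) return(1L)
  if (m < 0) return(-1L)
  switch(params$zero_tiebreak,
         positive = 1L,
         negative = -1L,
         random = sample(c(1L, -1L), 1L))
}

#' Assign valences to a structurally recalled network
#'
#' Seed ties receive their true target valences, corrupted at rate
#' `params$x`; heuristically added ties are valenced in their original
#' addition order using the common neighbours recorded at the moment each
#' tie was added, so the triadic context matches the structural pass
#' exactly (ties added earlier can valence later ones).
#'
#' @param target the [signed_network] the recall was simulated from.
#' @param structural_result a `recalled_network` from
#'   [simulate_structural_recall()].
#' @param params an [affect_params] object.
#' @param rng_seed integer seed; `NULL` uses the current RNG stream.
#' @return The `recalled_network` with a `valence` column on `edges` and a
#'   `corrupted` flag on seed rows.
#' @export
simulate_affective_recall <- function(target, structural_result,
                                      params = affect_params(),
                                      rng_seed = NULL) {
  stopifnot(inherits(target, "signed_network"),
            inherits(structural_result, "recalled_network"))
  res <- structural_result
  edges <- res$edges
  truth <- valence_map(target)
  seed_idx <- which(edges$is_seed)
  seed_keys <- pair_key(edges$from[seed_idx], edges$to[seed_idx])
  if (anyNA(truth[seed_keys])) {
    stop("structural result contains seed edges absent from the target")
  }

  with_rng_seed(rng_seed, {
    cor <- corrupt_seed_valences(unname(truth[seed_keys]), params,
                                 rng_seed = NULL)
    val <- setNames(cor$valence, seed_keys)
    add <- res$additions
    add_val <- integer(nrow(add))
    for (k in seq_len(nrow(add))) {
      a <- add$from[k]; b <- add$to[k]
      wit <- add$witnesses[[k]]
      products <- vapply(wit, function(cc) {
        va <- unname(val[pair_key(a, cc)])
        vb <- unname(val[pair_key(b, cc)])
        if (is.na(va) || is.na(vb)) {
          stop("missing valence on an adjacent recalled tie")
        }
        va * vb
      }, integer(1))
      v <- valence_for_new_tie(products, params)
      add_val[k] <- v
      val[[pair_key(a, b)]] <- v
    }
    edges$valence <- unname(val[pair_key(edges$from, edges$to)])
    edges$corrupted <- FALSE
    edges$corrupted[seed_idx] <- cor$corrupted
    res$edges <- edges
    res$affect_params <- params
    res
  })
}

#' Simulate a full recall replicate (structure then affect)
#'
#' Convenience wrapper running [simulate_structural_recall()] and
#' [simulate_affective_recall()] in a single seeded RNG stream.
#'
#' @inheritParams simulate_structural_recall
#' @param affect an [affect_params] object.
#' @param structural a [structural_params] object.
#' @return A `recalled_network` with valences.
#' @export
simulate_recall <- function(target, seed_characters = character(),
                            structural = structural_params(),
                            affect = affect_params(), rng_seed = NULL) {
  with_rng_seed(rng_seed, {
    res <- simulate_structural_recall(target, seed_characters, structural,
                                      rng_seed = NULL)
    simulate_affective_recall(target, res, affect, rng_seed = NULL)
  })
}
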