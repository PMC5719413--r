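utils::globalVariables(c(".x", ".y", ".ymin", ".ymax"))

# Monte Carlo sweep drivers.
#
# Reproducibility policy: a master seed spawns one child seed per
# (block, replicate) through a counter-based derivation (see rng.R), where
# a block is a seed set, an override value, or a (condition, x) cell.  The
# same master seed therefore yields identical results whether replicates
# are run in one batch or split, and sweeps are reproducible end to end.

#' Catalogue of canonical seed sets
#'
#' The tested combinations of initially recalled characters, together with
#' the number of target ties incident to each combination.  The counts are
#' additive over members because the catalogued characters are mutually
#' non-adjacent in the canonical stimulus.
#'
#' @return A data frame with columns `label`, `characters` (list column of
#'   character vectors) and `n_ties`, in catalogue order, from
#'   (`Isabelle`, 2) to (`Peter+Alyssa+Victoria`, 12).
#' @export
canonical_seed_sets <- function() {
  spec <- c(
    "Isabelle" = 2, "Victoria" = 3, "James" = 3, "Alyssa" = 4,
    "Catherine" = 4, "Lewis" = 5, "Peter" = 5,
    "James+Isabelle" = 5, "Alyssa+Isabelle" = 6, "James+Victoria" = 6,
    "Catherine+Isabelle" = 6, "Peter+Isabelle" = 7, "Alyssa+Victoria" = 7,
    "Catherine+Victoria" = 7, "Lewis+Isabelle" = 7, "Catherine+James" = 7,
    "Lewis+Victoria" = 8, "Peter+Victoria" = 8, "Lewis+James" = 8,
    "Peter+James" = 8, "Catherine+Alyssa" = 8, "Lewis+Alyssa" = 9,
    "Peter+Alyssa" = 9, "Catherine+James+Isabelle" = 9,
    "Peter+James+Isabelle" = 10, "Catherine+James+Victoria" = 10,
    "Lewis+James+Isabelle" = 10, "Catherine+Alyssa+Isabelle" = 10,
    "Peter+Alyssa+Isabelle" = 11, "Lewis+James+Victoria" = 11,
    "Lewis+Alyssa+Isabelle" = 11, "Peter+James+Victoria" = 11,
    "Catherine+Alyssa+Victoria" = 11, "Lewis+Alyssa+Victoria" = 12,
    "Peter+Alyssa+Victoria" = 12
  )
  out <- data.frame(label = names(spec), n_ties = as.integer(unname(spec)),
                    stringsAsFactors = FALSE)
  out$characters <- strsplit(out$label, "+", fixed = TRUE)
  out[, c("label", "characters", "n_ties")]
}

#' Configuration of a Monte Carlo sweep
#'
#' @param target a [signed_network] (typically a canonical fixture).
#' @param seed_sets data frame as returned by [canonical_seed_sets()]
#'   (columns `label`, `characters`, optionally `n_ties` used as a
#'   fixture/seed consistency precondition), or a named list of character
#'   vectors.  Default: the full canonical catalogue.
#' @param replicates simulations per sweep cell (default 1000).
#' @param structural a [structural_params] object.
#' @param affect an [affect_params] object.
#' @param master_seed integer master seed for the whole sweep.
#' @param condition label recorded on output rows (e.g. `"balanced"`).
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(target, seed_sets = canonical_seed_sets(),
                         replicates = 1000L,
                         structural = structural_params(),
                         affect = affect_params(),
                         master_seed = 1L, condition = "balanced") {
  stopifnot(inherits(target, "signed_network"), replicates >= 1L)
  if (is.list(seed_sets) && !is.data.frame(seed_sets)) {
    if (is.null(names(seed_sets))) {
      names(seed_sets) <- vapply(seed_sets, paste, character(1),
                                 collapse = "+")
    }
    seed_sets <- data.frame(label = names(seed_sets),
                            n_ties = NA_integer_, stringsAsFactors = FALSE,
                            row.names = NULL)
    seed_sets$characters <- strsplit(seed_sets$label, "+", fixed = TRUE)
  }
  if (nrow(seed_sets) == 0L) stop("seed_sets must be a non-empty collection")
  structure(list(target = target, seed_sets = seed_sets,
                 replicates = as.integer(replicates),
                 structural = structural, affect = affect,
                 master_seed = as.integer(master_seed),
                 condition = condition),
            class = "sweep_config")
}

#' Per-replicate scores for one sweep cell
#'
#' Runs `simulate_recall()` once per requested replicate, each in its own
#' child RNG stream derived from `(master_seed, block, replicate)`, and
#' scores every replicate against the target.  Because streams are derived
#' per replicate, running replicates `1:1000` in one call or as two split
#' batches yields identical rows.
#'
#' @param target a [signed_network].
#' @param seed_characters character vector of seed node names.
#' @param structural a [structural_params] object.
#' @param affect an [affect_params] object.
#' @param master_seed sweep master seed.
#' @param block integer block index of the sweep cell.
#' @param replicates integer vector of replicate indices (e.g. `1:1000`).
#' @return Data frame with one row per replicate: `replicate`,
#'   `precision`, `coverage`, `quality`, `n_recalled`, `n_correct`.
#' @export
replicate_scores <- function(target, seed_characters,
                             structural = structural_params(),
                             affect = affect_params(),
                             master_seed = 1L, block = 1L,
                             replicates = 1:1000) {
  # resolve the probabilities once per cell: they depend only on the
  # target census, and any clamping warning should fire once, not per
  # replicate
  structural$p_triangle <- p_triangle(target, structural)
  structural$p_background <- p_background(target, structural)
  rows <- lapply(replicates, function(r) {
    child <- derive_seed(master_seed, block, r)
    sim <- simulate_recall(target, seed_characters, structural, affect,
                           rng_seed = child)
    sc <- score_structure(target, sim)
    data.frame(replicate = r, precision = sc$precision,
               coverage = sc$coverage,
               quality = score_quality(target, sim),
               n_recalled = sc$n_recalled, n_correct = sc$n_correct)
  })
  do.call(rbind, rows)
}

# mean/sd aggregation of replicate rows; undefined (NA) metrics are
# excluded from the moments and counted instead
aggregate_scores <- function(scores) {
  agg <- function(v) {
    ok <- !is.na(v)
    c(mean = if (any(ok)) mean(v[ok]) else NA_real_,
      sd = if (sum(ok) > 1L) sd(v[ok]) else if (any(ok)) 0 else NA_real_,
      n_missing = sum(!ok))
  }
  p <- agg(scores$precision)
  co <- agg(scores$coverage)
  q <- agg(scores$quality)
  data.frame(
    replicates = nrow(scores),
    precision_mean = p[["mean"]], precision_sd = p[["sd"]],
    coverage_mean = co[["mean"]], coverage_sd = co[["sd"]],
    quality_mean = q[["mean"]], quality_sd = q[["sd"]],
    n_recalled_mean = mean(scores$n_recalled),
    n_precision_missing = as.integer(p[["n_missing"]]),
    n_quality_missing = as.integer(q[["n_missing"]])
  )
}

#' Sweep over seed sets
#'
#' For every seed set in the configuration, runs `replicates` independent
#' structural + affective recall simulations against the target and
#' aggregates precision, coverage and quality.  As a precondition, any
#' seed set with a catalogued tie count must match the target's incident
#' tie count exactly; a mismatch means the fixture and catalogue disagree
#' and is a hard error.
#'
#' @param config a [sweep_config].
#' @return A `sweep_table` data frame with one row per seed set.
#' @export
run_seed_sweep <- function(config) {
  stopifnot(inherits(config, "sweep_config"))
  sets <- config$seed_sets
  for (i in seq_len(nrow(sets))) {
    expected <- sets$n_ties[i]
    if (!is.na(expected)) {
      observed <- nrow(incident_edges(config$target, sets$characters[[i]]))
      if (observed != expected) {
        stop("fixture/seed mismatch for '", sets$label[i], "': catalogue says ",
             expected, " incident ties, fixture has ", observed)
      }
    }
  }
  rows <- lapply(seq_len(nrow(sets)), function(i) {
    scores <- replicate_scores(config$target, sets$characters[[i]],
                               config$structural, config$affect,
                               config$master_seed, block = i,
                               replicates = seq_len(config$replicates))
    cbind(data.frame(condition = config$condition, seed_set = sets$label[i],
                     n_seed_ties = sets$n_ties[i],
                     stringsAsFactors = FALSE),
          aggregate_scores(scores))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_table", class(out))
  attr(out, "master_seed") <- config$master_seed
  out
}

#' Robustness sweep over the closed-triplet count
#'
#' Fixes the seed set (by default the high-degree character in each
#' component, Lewis + Alyssa) and re-runs the recall model with the
#' closed-triplet count overridden by each grid value, which moves both
#' the closure probability and the background probability.
#'
#' @param config a [sweep_config]; its `structural` settings are reused
#'   with the override substituted.
#' @param t_closed_grid integer vector of override values, each in
#'   `[0, T]` of the target census.
#' @param seed_characters seed set used for all rows.
#' @return A `sweep_table` with one row per override value (column
#'   `t_closed`).
#' @export
run_tclosed_sweep <- function(config, t_closed_grid,
                              seed_characters = c("Lewis", "Alyssa")) {
  stopifnot(inherits(config, "sweep_config"))
  census <- triplet_census(config$target, mode = config$structural$census_mode)
  if (any(t_closed_grid < 0 | t_closed_grid > census$T)) {
    stop("t_closed_grid values must lie in [0, ", census$T, "]")
  }
  rows <- lapply(seq_along(t_closed_grid), function(i) {
    sp <- config$structural
    sp$t_closed_override <- t_closed_grid[i]
    scores <- replicate_scores(config$target, seed_characters, sp,
                               config$affect, config$master_seed, block = i,
                               replicates = seq_len(config$replicates))
    cbind(data.frame(condition = config$condition,
                     seed_set = paste(seed_characters, collapse = "+"),
                     t_closed = t_closed_grid[i], stringsAsFactors = FALSE),
          aggregate_scores(scores))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_table", class(out))
  attr(out, "master_seed") <- config$master_seed
  out
}

#' Robustness sweep over the valence-corruption fraction
#'
#' Fixes the seed set and varies the fraction `x` of seed ties remembered
#' with random valences, for each supplied target condition.  The default
#' grid covers 0 to 1 in steps of 0.05 and so includes the model's
#' operating point `x = 0.30` and the well-fitting 0.20--0.45 band.
#'
#' @param config a [sweep_config]; its `affect` settings are reused with
#'   `x` substituted.
#' @param x_grid numeric vector of corruption fractions in `[0, 1]`.
#' @param targets named list of target networks, one per condition
#'   (default: the single target in `config`, under its condition label).
#' @param seed_characters seed set used for all rows.
#' @return A `sweep_table` with one row per (condition, x) cell.
#' @export
run_x_sweep <- function(config, x_grid = seq(0, 1, by = 0.05),
                        targets = NULL,
                        seed_characters = c("Lewis", "Alyssa")) {
  stopifnot(inherits(config, "sweep_config"))
  if (any(x_grid < 0 | x_grid > 1)) stop("x_grid values must lie in [0, 1]")
  if (is.null(targets)) {
    targets <- setNames(list(config$target), config$condition)
  }
  if (is.null(names(targets)) || any(!nzchar(names(targets)))) {
    stop("targets must be a named list (names are condition labels)")
  }
  rows <- list()
  block <- 0L
  for (cond in names(targets)) {
    for (x in x_grid) {
      block <- block + 1L
      ap <- config$affect
      ap$x <- x
      scores <- replicate_scores(targets[[cond]], seed_characters,
                                 config$structural, ap,
                                 config$master_seed, block = block,
                                 replicates = seq_len(config$replicates))
      rows[[block]] <- cbind(
        data.frame(condition = cond,
                   seed_set = paste(seed_characters, collapse = "+"),
                   x = x, stringsAsFactors = FALSE),
        aggregate_scores(scores))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_table", class(out))
  attr(out, "master_seed") <- config$master_seed
  out
}

#' Write a sweep table to disk (CSV + JSON)
#'
#' Writes `sweep.csv` and `sweep.json` into `dir`.  When experimental
#' summaries are supplied, a `<metric>_delta` column is appended for each
#' summarised metric using [delta()]; without them no delta columns are
#' written.
#'
#' @param sweep_table a `sweep_table`.
#' @param dir output directory (created if needed).
#' @param experimental optional data frame with columns `metric` (one of
#'   `"precision"`, `"coverage"`, `"quality"`), `mean` and `sd`, and
#'   optionally `condition` to match specific rows (otherwise applied to
#'   all rows).
#' @return The (possibly delta-augmented) table, invisibly.
#' @export
write_sweep <- function(sweep_table, dir, experimental = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- as.data.frame(sweep_table)
  if (!is.null(experimental)) {
    experimental <- as.data.frame(experimental)
    stopifnot(all(c("metric", "mean", "sd") %in% names(experimental)))
    for (i in seq_len(nrow(experimental))) {
      metric <- experimental$metric[i]
      col <- paste0(metric, "_mean")
      if (!col %in% names(tab)) next
      rows <- if ("condition" %in% names(experimental) &&
                  !is.na(experimental$condition[i])) {
        tab$condition == experimental$condition[i]
      } else {
        rep(TRUE, nrow(tab))
      }
      dcol <- paste0(metric, "_delta")
      if (!dcol %in% names(tab)) tab[[dcol]] <- NA_real_
      tab[[dcol]][rows] <- delta(tab[[col]][rows], experimental$mean[i],
                                 experimental$sd[i])
    }
  }
  write.csv(tab, file.path(dir, "sweep.csv"), row.names = FALSE)
  jsonlite::write_json(tab, file.path(dir, "sweep.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(tab)
}

#' Read back a sweep table written by [write_sweep()]
#'
#' @param dir directory containing `sweep.csv`.
#' @return A `sweep_table` data frame.
#' @export
read_sweep <- function(dir) {
  out <- read.csv(file.path(dir, "sweep.csv"), stringsAsFactors = FALSE)
  class(out) <- c("sweep_table", class(out))
  out
}

#' Read a sweep configuration from YAML
#'
#' Recognised keys: `replicates`, `master_seed`, `condition`, `seed_sets`
#' (list of character vectors or `+`-joined labels), `structural`
#' (sub-keys passed to [structural_params()]) and `affect` (sub-keys
#' passed to [affect_params()]).
#'
#' @param path YAML file path.
#' @param target a [signed_network] the sweep will run against.
#' @return A [sweep_config].
#' @export
read_sweep_config <- function(path, target) {
  y <- yaml::read_yaml(path)
  structural <- do.call(structural_params, as.list(y$structural))
  affect <- do.call(affect_params, as.list(y$affect))
  seed_sets <- if (is.null(y$seed_sets)) {
    canonical_seed_sets()
  } else {
    lapply(y$seed_sets, function(s) {
      if (length(s) == 1L) strsplit(s, "+", fixed = TRUE)[[1L]] else
        as.character(s)
    })
  }
  sweep_config(target, seed_sets = seed_sets,
               replicates = if (is.null(y$replicates)) 1000L else y$replicates,
               structural = structural, affect = affect,
               master_seed = if (is.null(y$master_seed)) 1L else y$master_seed,
               condition = if (is.null(y$condition)) "balanced" else y$condition)
}

#' Bar-panel plot of a sweep table
#'
#' Mean of the chosen metric per sweep cell with +/- 1 SD error bars,
#' faceted by condition.  Requires ggplot2.
#'
#' @param sweep_table a `sweep_table`.
#' @param metric `"precision"`, `"coverage"` or `"quality"`.
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep_table, metric = c("coverage", "precision",
                                               "quality")) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_sweep() requires the ggplot2 package")
  }
  metric <- match.arg(metric)
  tab <- as.data.frame(sweep_table)
  xvar <- if ("x" %in% names(tab)) "x" else
    if ("t_closed" %in% names(tab)) "t_closed" else "seed_set"
  mcol <- paste0(metric, "_mean")
  scol <- paste0(metric, "_sd")
  tab$.x <- if (xvar == "seed_set") {
    factor(tab$seed_set, levels = unique(tab$seed_set))
  } else {
    tab[[xvar]]
  }
  tab$.y <- tab[[mcol]]
  tab$.ymin <- tab[[mcol]] - tab[[scol]]
  tab$.ymax <- tab[[mcol]] + tab[[scol]]
  p <- ggplot2::ggplot(tab, ggplot2::aes(
    x = .x, y = .y, ymin = .ymin, ymax = .ymax)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(width = 0.25) +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = xvar, y = metric) +
    ggplot2::theme_minimal()
  if (xvar == "seed_set") {
    p <- p + ggplot2::theme(
      axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
  }
  p
}
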