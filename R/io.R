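# Signed edge-list TSV I/O.
#
# Format: tab-separated, header "source\ttarget\tvalence\tlabel" (label
# column optional), valence tokens +1 / -1 / like / dislike.  Output is
# canonical (lexicographic endpoint order within and across rows) so that
# write -> read round-trips to an identical network.

#' Read a signed network from a tab-separated edge list
#'
#' @param path path to a TSV file with header
#'   `source<TAB>target<TAB>valence` and an optional `label` column.
#'   Valence tokens `+1`, `1`, `-1`, `like`, `dislike` are accepted.
#' @param nodes optional character vector of extra (isolated) node names.
#' @return A [signed_network].
#' @seealso [write_signed_edgelist()]
#' @export
read_signed_edgelist <- function(path, nodes = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!(seq_along(lines) > 1L & !nzchar(trimws(lines)))]
  if (length(lines) == 0L) stop("empty edge-list file: ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 3L ||
      !identical(tolower(header[1:3]), c("source", "target", "valence"))) {
    stop("line 1: expected header 'source\\ttarget\\tvalence[\\tlabel]', got '",
         lines[[1L]], "'")
  }
  has_label <- length(header) >= 4L && tolower(header[4L]) == "label"
  n_fields <- if (has_label) 4L else 3L

  from <- to <- lab <- character(0)
  val <- integer(0)
  for (i in seq_along(lines)[-1L]) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L || length(fields) > n_fields) {
      stop("line ", i, ": expected ", n_fields, " tab-separated fields, got ",
           length(fields))
    }
    if (fields[1L] == fields[2L]) {
      stop("line ", i, ": self-loop on node '", fields[1L], "'")
    }
    v <- tryCatch(as_valence(fields[3L]), error = function(e) {
      stop("line ", i, ": ", conditionMessage(e), call. = FALSE)
    })
    k <- pair_key(fields[1L], fields[2L])
    if (k %in% pair_key(from, to)) {
      stop("line ", i, ": duplicate edge ", fields[1L], " -- ", fields[2L])
    }
    from <- c(from, fields[1L])
    to <- c(to, fields[2L])
    val <- c(val, v)
    lab <- c(lab, if (length(fields) >= 4L && nzchar(fields[4L]))
      fields[4L] else NA_character_)
  }
  signed_network(data.frame(from = from, to = to, valence = val, label = lab,
                            stringsAsFactors = FALSE),
                 nodes = nodes)
}

#' Write a signed network as a tab-separated edge list
#'
#' Rows are emitted in canonical order (lexicographically smaller endpoint
#' first, rows sorted by endpoint pair) so output is deterministic and
#' `read_signed_edgelist(write_signed_edgelist(net, f))` reproduces `net`
#' exactly, provided `net` has no isolated nodes (isolated nodes are not
#' representable in an edge list).
#'
#' @param net a [signed_network].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_signed_edgelist <- function(net, path) {
  stopifnot(inherits(net, "signed_network"))
  e <- net$edges
  lab <- ifelse(is.na(e$label), "", e$label)
  vtok <- ifelse(e$valence == 1L, "+1", "-1")
  lines <- c("source\ttarget\tvalence\tlabel",
             paste(e$from, e$to, vtok, lab, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Export a signed network to GraphML
#'
#' Writes a GraphML file (for visualisation tools) with a `valence` edge
#' attribute (+1/-1) and a `label` edge attribute where present.
#'
#' @param net a [signed_network].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_signed_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}
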