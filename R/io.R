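#' Read a raw synapse table from a delimited edge-list file
#'
#' Parses a tab- or comma-separated connectivity export into a raw synapse
#' table: one row per recorded (presynaptic cell, postsynaptic cell) pair
#' with a nonnegative synapse count. Direction is taken from the explicit
#' `columns` argument, never guessed from header names, because a silently
#' swapped column order corrupts edge direction. A header row is
#' auto-detected (common column names, or a non-numeric entry in the weight
#' column) and skipped.
#'
#' @param path Path to the file.
#' @param dialect Field separator: `"tsv"` (tab) or `"csv"` (comma).
#' @param columns Character vector giving the role of each file column in
#'   order; must contain `"source"` and `"target"`, optionally `"weight"`.
#'   Rows missing the weight column get a count of 1.
#' @return A data frame of class `raw_synapse_table` with columns `pre`,
#'   `post` (character) and `count` (integer).
#' @seealso [collapse_to_simple()] to turn the table into a simple directed
#'   graph.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("pre\tpost\tcount", "ASEL\tAIYL\t3", "AIYL\tRIA\t1"), f)
#' read_edge_table(f, dialect = "tsv")
#' @export
read_edge_table <- function(path, dialect = c("tsv", "csv"),
                            columns = c("source", "target", "weight")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("edge table file not found: ", path)
  if (!all(c("source", "target") %in% columns))
    stop("`columns` must name both 'source' and 'target'")

  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("empty edge table: ", path)

  fields <- lapply(strsplit(lines, sep, fixed = TRUE), trimws)

  src_i <- match("source", columns)
  tgt_i <- match("target", columns)
  w_i <- match("weight", columns)

  # header heuristics: a recognised column name in a cell-label position,
  # or a non-numeric entry in the declared weight position
  header_words <- c("pre", "post", "source", "target", "from", "to", "weight",
                    "count", "synapses", "pre_cell", "post_cell", "type")
  first <- tolower(fields[[1L]])
  name_pos <- c(src_i, tgt_i)
  is_header <- length(first) >= min(name_pos) &&
    (any(first[name_pos[name_pos <= length(first)]] %in% header_words) ||
       (!is.na(w_i) && length(first) >= w_i &&
          is.na(suppressWarnings(as.numeric(first[w_i])))))
  if (is_header) {
    fields <- fields[-1L]
    line_no <- line_no[-1L]
  }
  if (length(fields) == 0L) stop("no data rows in edge table: ", path)

  nf <- lengths(fields)
  need <- max(src_i, tgt_i)
  bad <- which(nf < need | nf > length(columns))
  if (length(bad))
    stop("malformed row at line ", line_no[bad[1L]], ": expected ", need,
         if (length(columns) > need) paste0("-", length(columns)) else "",
         " fields, found ", nf[bad[1L]])

  pre <- vapply(fields, `[`, character(1L), src_i)
  post <- vapply(fields, `[`, character(1L), tgt_i)
  count <- rep(1L, length(fields))
  if (!is.na(w_i)) {
    has_w <- which(nf >= w_i)
    raw_w <- vapply(fields[has_w], `[`, character(1L), w_i)
    w <- suppressWarnings(as.numeric(raw_w))
    if (anyNA(w)) {
      i <- which(is.na(w))[1L]
      stop("malformed row at line ", line_no[has_w[i]],
           ": non-numeric synapse count '", raw_w[i], "'")
    }
    if (any(w < 0)) {
      i <- which(w < 0)[1L]
      stop("malformed row at line ", line_no[has_w[i]],
           ": negative synapse count ", w[i])
    }
    count[has_w] <- as.integer(round(w))
  }

  structure(
    data.frame(pre = pre, post = post, count = count,
               stringsAsFactors = FALSE, row.names = NULL),
    class = c("raw_synapse_table", "data.frame"))
}

#' Collapse a raw synapse table to a simple directed graph
#'
#' A connection (edge) is a pair of cells joined by one or more chemical
#' synapses: rows with the same (pre, post) pair are merged into one edge
#' whose weight is the summed synapse count. Self-loop rows and rows with a
#' zero count contribute no edge. Every cell mentioned in the table becomes
#' a node, so cells appearing only in dropped rows survive as isolated
#' nodes.
#'
#' @param table A `raw_synapse_table` (or any data frame with columns
#'   `pre`, `post`, `count`).
#' @return A simple directed igraph graph with character vertex names and
#'   an integer `weight` edge attribute.
#' @examples
#' tab <- data.frame(pre = c("A", "A", "B"), post = c("B", "B", "B"),
#'                   count = c(2L, 3L, 1L))
#' g <- collapse_to_simple(tab)
#' igraph::E(g)$weight  # 5: the two A->B rows merged, the B->B loop dropped
#' @export
collapse_to_simple <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("pre", "post", "count") %in% names(table)))
  nodes <- sort(unique(c(as.character(table$pre), as.character(table$post))))
  keep <- table$count > 0 & as.character(table$pre) != as.character(table$post)
  edges <- table[keep, c("pre", "post", "count"), drop = FALSE]
  if (nrow(edges) > 0L)
    edges <- stats::aggregate(count ~ pre + post, data = edges, FUN = sum)
  igraph::graph_from_data_frame(
    d = data.frame(from = as.character(edges$pre),
                   to = as.character(edges$post),
                   weight = as.integer(edges$count),
                   stringsAsFactors = FALSE),
    directed = TRUE, vertices = nodes)
}

# Shared formatter: header plus one sorted "source\ttarget\tweight" line per
# edge. Radix order = C locale, so output is byte-stable across platforms.
edge_list_lines <- function(g) {
  stopifnot(igraph::is_igraph(g), igraph::is_directed(g))
  el <- igraph::as_data_frame(g, what = "edges")
  w <- if ("weight" %in% names(el)) as.integer(round(el$weight))
       else rep(1L, nrow(el))
  ord <- order(el$from, el$to, method = "radix")
  c("source\ttarget\tweight",
    sprintf("%s\t%s\t%d", el$from[ord], el$to[ord], w[ord]))
}

#' Write a directed graph as a sorted edge-list TSV
#'
#' Emits one `source<TAB>target<TAB>weight` line per edge, sorted by
#' (source, target), after a header line. The output round-trips through
#' [read_edge_table()] + [collapse_to_simple()] to an identical graph,
#' except that isolated nodes are not representable in an edge list and are
#' dropped with a warning.
#'
#' @param g A directed igraph graph.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  lines <- edge_list_lines(g)
  if (any(igraph::degree(g, mode = "all") == 0))
    warning("isolated nodes are not representable in an edge list; dropped")
  writeLines(lines, path)
  invisible(path)
}

#' Generate a small toy connectome with hand-computable metrics
#'
#' Deterministic test fixtures: `star_in` has `size - 1` leaves each sending
#' one edge to a hub, `star_out` is its reversal, `ring` is a directed
#' cycle, and `two_stage` is a seeded layered feedforward graph that mimics
#' sensory-to-interneuron-to-motor wiring (the first layer has only
#' out-edges, the last only in-edges, with occasional skip edges creating
#' triangles).
#'
#' @param kind One of `"star_in"`, `"star_out"`, `"ring"`, `"two_stage"`.
#' @param size Number of nodes, at least 3.
#' @param seed Integer seed; only `two_stage` draws random numbers, but the
#'   result is a pure function of `(kind, size, seed)` in every case.
#' @return A simple directed igraph graph with unit edge weights.
#' @examples
#' g <- make_toy_connectome("ring", 5)
#' igraph::degree(g, mode = "in")  # all 1
#' @export
make_toy_connectome <- function(kind = c("star_in", "star_out", "ring", "two_stage"),
                                size, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(size), length(size) == 1L, size >= 3)
  size <- as.integer(size)
  labels <- sprintf("n%02d", seq_len(size))

  edges <- switch(kind,
    star_in = cbind(labels[-1L], labels[1L]),
    star_out = cbind(labels[1L], labels[-1L]),
    ring = cbind(labels, labels[c(seq_len(size)[-1L], 1L)]),
    two_stage = withr::with_seed(as.integer(seed), {
      n_s <- ceiling(size / 3)
      n_m <- floor(size / 3)
      sens <- labels[seq_len(n_s)]
      motor <- labels[(size - n_m + 1L):size]
      inter <- setdiff(labels, c(sens, motor))
      e <- list()
      for (s in sens) {
        k <- sample(seq_len(min(2L, length(inter))), 1L)
        e[[length(e) + 1L]] <- cbind(s, sample(inter, k))
      }
      for (i in inter) {
        k <- sample(seq_len(min(2L, length(motor))), 1L)
        e[[length(e) + 1L]] <- cbind(i, sample(motor, k))
      }
      if (length(inter) >= 2L) {
        pairs <- expand.grid(from = inter, to = inter,
                             stringsAsFactors = FALSE)
        pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
        hit <- stats::runif(nrow(pairs)) < 0.3
        if (any(hit)) e[[length(e) + 1L]] <- as.matrix(pairs[hit, ])
      }
      skip <- expand.grid(from = sens, to = motor, stringsAsFactors = FALSE)
      hit <- stats::runif(nrow(skip)) < 0.2
      if (any(hit)) e[[length(e) + 1L]] <- as.matrix(skip[hit, ])
      all_e <- do.call(rbind, e)
      # every motor cell receives at least one input
      uncovered <- setdiff(motor, all_e[, 2L])
      if (length(uncovered))
        all_e <- rbind(all_e,
                       cbind(sample(inter, length(uncovered), replace = TRUE),
                             uncovered))
      all_e
    }))

  igraph::graph_from_data_frame(
    d = data.frame(from = edges[, 1L], to = edges[, 2L], weight = 1L,
                   stringsAsFactors = FALSE),
    directed = TRUE, vertices = labels)
}
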