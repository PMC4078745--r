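# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compose the node identifier of a process at a time index
#'
#' Time-unrolled graphs index their nodes by (process, time); node names are
#' the serializable form `"<process>@<t>"` with 0-based time indices.
#'
#' @param process character vector of process identifiers.
#' @param t integer vector of time indices (recycled against `process`).
#' @return character vector of node names.
#' @export
#' @examples
#' node_at("X", 0:2)
node_at <- function(process, t) {
  sprintf("%s@%d", process, as.integer(t))
}

# Split "X@3" back into process / time. Returns list(process=, t=).
split_node <- function(node) {
  m <- regmatches(node, regexpr("@[0-9]+$", node))
  if (length(m) != length(node) || any(!nzchar(m))) {
    stop("invalid-argument: node names must have the form '<process>@<t>'")
  }
  list(process = sub("@[0-9]+$", "", node),
       t = as.integer(sub("^@", "", m)))
}

# Canonical unordered pair key.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

# All subsets of x, in increasing cardinality, lexicographic within each
# cardinality; x is sorted first so the order is deterministic.
subsets_in_order <- function(x, max_size = length(x)) {
  x <- sort(x)
  out <- list(character(0))
  max_size <- min(max_size, length(x))
  if (max_size < 1L) return(out)
  for (k in seq_len(max_size)) {
    cmb <- utils::combn(x, k, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

# Kahn topological check on an edge data.frame with columns src, dst.
is_acyclic_edges <- function(nodes, edges) {
  if (nrow(edges) == 0L) return(TRUE)
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  tab <- table(edges$dst)
  indeg[names(tab)] <- as.integer(tab)
  out_by <- split(edges$dst, edges$src)
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    seen <- seen + 1L
    for (w in out_by[[v]] %||% character(0)) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) queue <- c(queue, w)
    }
  }
  seen == length(nodes)
}

#' Build an edge table
#'
#' @param src,dst character vectors of endpoint names.
#' @param ... further columns (`type`, `lag`, ...), recycled by `data.frame`.
#' @return data.frame with columns `src`, `dst` and any extras.
#' @export
edge_frame <- function(src = character(0), dst = character(0), ...) {
  data.frame(src = as.character(src), dst = as.character(dst), ...,
             stringsAsFactors = FALSE)
}

stopifnot_nodes <- function(x, nodes, what = "node") {
  bad <- setdiff(x, nodes)
  if (length(bad)) {
    stop(sprintf("invalid-argument: unknown %s(s): %s", what,
                 paste(bad, collapse = ", ")))
  }
  invisible(TRUE)
}
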