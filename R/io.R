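# Serialization: graph JSON, DOT export, VAR model configs (YAML/JSON).
#
# Graph JSON schema:
#   {"kind": "...",               # optional; inferred when absent
#    "nodes": [...],
#    "edges": [{"src":, "dst":, "lag": int, "type": "directed|undirected|
#               potential|genuine|bidirectional"}],
#    "latent": [...]}

graph_kind <- function(g) {
  switch(class(g)[1L],
         process_graph = "process_graph",
         causal_structure = "causal_structure",
         pattern = "pattern",
         embedded_pattern = "embedded_pattern",
         mixed_macro_graph = "mixed_macro_graph",
         stop("invalid-argument: not a serializable graph object"))
}

#' Write a graph to JSON
#'
#' @param g any graph object of this package.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_graph <- function(g, path) {
  kind <- graph_kind(g)
  e <- graph_edges(g)
  edges <- lapply(seq_len(nrow(e)), function(i) {
    rec <- list(src = e$src[i], dst = e$dst[i])
    if (!is.null(e$lag)) rec$lag <- e$lag[i]
    rec$type <- if (!is.null(e$type)) e$type[i] else "directed"
    rec
  })
  obj <- list(kind = kind, nodes = as.list(graph_nodes(g)), edges = edges)
  if (kind == "process_graph") obj$latent <- as.list(g$latent)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a graph from JSON
#'
#' Accepts the schema written by [write_graph()]; when the `kind` field is
#' absent it is inferred (lagged edges imply a process graph; otherwise the
#' edge-type alphabet decides).  Unknown edge types and non-positive lags
#' are rejected.
#'
#' @param path JSON file path.
#' @return a graph object.
#' @export
read_graph <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop(sprintf(
                    "parse-error: %s: %s", path, conditionMessage(e))))
  nodes <- as.character(unlist(obj$nodes))
  edges <- obj$edges %||% list()
  src <- vapply(edges, function(e) as.character(e$src %||%
    stop("parse-error: edge missing 'src'")), character(1))
  dst <- vapply(edges, function(e) as.character(e$dst %||%
    stop("parse-error: edge missing 'dst'")), character(1))
  type <- vapply(edges, function(e) as.character(e$type %||% "directed"),
                 character(1))
  bad <- setdiff(type, GRAPH_EDGE_TYPES)
  if (length(bad)) {
    stop(sprintf("parse-error: unknown edge type(s): %s",
                 paste(unique(bad), collapse = ", ")))
  }
  lags <- vapply(edges, function(e) as.integer(e$lag %||% NA_integer_),
                 integer(1))
  has_lag <- length(lags) > 0L && any(!is.na(lags))
  kind <- obj$kind %||% NULL
  if (is.null(kind)) {
    kind <- if (has_lag || length(obj$latent %||% list())) "process_graph"
    else if (all(type == "directed")) "causal_structure"
    else if (any(type %in% c("potential", "genuine"))) "embedded_pattern"
    else if (any(type == "bidirectional")) "mixed_macro_graph"
    else "pattern"
  }
  if (kind == "process_graph") {
    if (length(lags) && any(is.na(lags))) {
      stop("parse-error: process-graph edges need a 'lag' field")
    }
    if (length(lags) && any(lags < 1L)) {
      stop("parse-error: edge lag must be a positive integer")
    }
    return(process_graph(nodes, edge_lags(src, dst, lags),
                         latent = as.character(unlist(obj$latent %||% list()))))
  }
  if (has_lag) stop("parse-error: only process graphs carry edge lags")
  edf <- edge_frame(src, dst, type = type)
  switch(kind,
         causal_structure = causal_structure(nodes, edf),
         pattern = pattern(nodes, edf),
         embedded_pattern = embedded_pattern(nodes, edf),
         mixed_macro_graph = mixed_macro_graph(nodes, edf),
         stop(sprintf("parse-error: unknown graph kind '%s'", kind)))
}

#' Export a graph in DOT format
#'
#' Edge styles: directed and genuine causes are solid arrows (genuine in
#' bold), potential causes dashed arrows, common drivers double-headed
#' arrows, undirected links plain lines; latent processes are drawn as
#' dashed circles.
#'
#' @param g any graph object of this package.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dot <- function(g, path) {
  e <- graph_edges(g)
  type <- e$type %||% rep("directed", nrow(e))
  style <- function(tp) {
    switch(tp,
           directed = "[style=solid]",
           genuine = "[style=bold]",
           potential = "[style=dashed]",
           bidirectional = "[dir=both]",
           undirected = "[dir=none]")
  }
  q <- function(x) sprintf("\"%s\"", x)
  lines <- c("digraph G {")
  latent <- if (inherits(g, "process_graph")) g$latent else character(0)
  for (v in graph_nodes(g)) {
    lines <- c(lines, sprintf("  %s%s;", q(v),
                              if (v %in% latent) " [style=dashed]" else ""))
  }
  for (i in seq_len(nrow(e))) {
    lab <- if (!is.null(e$lag)) sprintf(" [label=\"%d\"]", e$lag[i]) else ""
    lines <- c(lines, sprintf("  %s -> %s %s%s;", q(e$src[i]), q(e$dst[i]),
                              style(type[i]), lab))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}

#' Read a VAR model plus observation map from a config file
#'
#' YAML or JSON with fields `names`, `C` (nested rows), optional `Sigma`
#' (default identity) and optional `observation` with `W`, `noise`,
#' `subsample`, `names`.
#'
#' @param path config file path (`.yaml`/`.yml` or `.json`).
#' @return list with `model` and `obs` (identity map when unspecified).
#' @export
read_var_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    # keep YAML 1.1 boolean-looking scalars (Y, N, yes, no, ...) as strings:
    # they are common signal names
    yaml::read_yaml(path, handlers = list("bool#yes" = identity,
                                          "bool#no" = identity))
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  C <- do.call(rbind, lapply(cfg$C, as.numeric))
  Sigma <- if (!is.null(cfg$Sigma)) do.call(rbind, lapply(cfg$Sigma, as.numeric))
  model <- var_model(C, Sigma, names = cfg$names %||% NULL)
  obs <- if (!is.null(cfg$observation)) {
    o <- cfg$observation
    observation_map(do.call(rbind, lapply(o$W, as.numeric)),
                    noise = o$noise %||% 0,
                    subsample = o$subsample %||% 1L,
                    names = o$names %||% NULL)
  } else identity_map(model)
  list(model = model, obs = obs)
}
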