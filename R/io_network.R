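# Network serialization: edge-list JSON and GraphML. Both formats carry the
# node set (label, type, predictability) and the signed weighted edges, and
# round-trip the adjacency to full double precision.

#' Write an estimated network to disk
#'
#' Serializes nodes (label, type, predictability) and edges (endpoints,
#' signed standardized weight, sign-undefined flag) as edge-list JSON or
#' GraphML. Reading the file back with [read_network()] reproduces the node
#' set, edge weights and predictability values.
#'
#' @param model A fitted [estimate_network()] result.
#' @param path Output file path.
#' @param format `"json"` or `"graphml"`; defaults to the file extension.
#' @return Invisibly, `path`.
#' @export
write_network <- function(model, path, format = c("auto", "json", "graphml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE)) "graphml" else "json"
  }
  stopifnot(inherits(model, "network_model"))
  labels <- model$node_labels
  adj <- model$adjacency
  undef <- model$sign_undefined
  ut <- which(upper.tri(adj) & adj != 0, arr.ind = TRUE)

  if (format == "json") {
    nodes <- lapply(seq_along(labels), function(i) {
      list(id = labels[i], type = model$node_types[i],
           predictability = unname(model$predictability[i]))
    })
    edges <- lapply(seq_len(nrow(ut)), function(k) {
      i <- ut[k, 1]; j <- ut[k, 2]
      list(source = labels[i], target = labels[j],
           weight = adj[i, j],
           sign = if (undef[i, j]) "undefined" else
             if (adj[i, j] > 0) "positive" else "negative")
    })
    obj <- list(nodes = nodes, edges = edges,
                smallest_retained_weight = model$smallest_retained_weight,
                n = model$n)
    ok <- tryCatch({
      writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                  null = "null", na = "null"), path)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) stop_noa("cannot write network to '%s': %s", path,
                              conditionMessage(ok))
  } else {
    doc <- xml2::xml_new_root("graphml",
                              xmlns = "http://graphml.graphdrawing.org/xmlns")
    keydefs <- list(
      c("d_type", "node", "type", "string"),
      c("d_pred", "node", "predictability", "double"),
      c("d_weight", "edge", "weight", "double"),
      c("d_sgn", "edge", "sign_undefined", "boolean")
    )
    for (k in keydefs) {
      xml2::xml_add_child(doc, "key", id = k[1], `for` = k[2],
                          attr.name = k[3], attr.type = k[4])
    }
    g <- xml2::xml_add_child(doc, "graph", id = "network", edgedefault = "undirected")
    for (i in seq_along(labels)) {
      nd <- xml2::xml_add_child(g, "node", id = labels[i])
      xml2::xml_add_child(nd, "data", model$node_types[i], key = "d_type")
      xml2::xml_add_child(nd, "data",
                          sprintf("%.17g", unname(model$predictability[i])),
                          key = "d_pred")
    }
    for (k in seq_len(nrow(ut))) {
      i <- ut[k, 1]; j <- ut[k, 2]
      ed <- xml2::xml_add_child(g, "edge", source = labels[i], target = labels[j])
      xml2::xml_add_child(ed, "data", sprintf("%.17g", adj[i, j]), key = "d_weight")
      xml2::xml_add_child(ed, "data", if (undef[i, j]) "true" else "false",
                          key = "d_sgn")
    }
    ok <- tryCatch({ xml2::write_xml(doc, path); TRUE }, error = function(e) e)
    if (!isTRUE(ok)) stop_noa("cannot write network to '%s': %s", path,
                              conditionMessage(ok))
  }
  invisible(path)
}

#' Read a serialized network
#'
#' Parses a file written by [write_network()] and rebuilds the node set and
#' the signed weighted adjacency matrix.
#'
#' @param path Path to a `.json` or `.graphml` file.
#' @param format `"json"` or `"graphml"`; defaults to the file extension.
#' @return A list with `node_labels`, `node_types`, `predictability`,
#'   `adjacency` and `sign_undefined`.
#' @export
read_network <- function(path, format = c("auto", "json", "graphml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE)) "graphml" else "json"
  }
  if (format == "json") {
    obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    labels <- obj$nodes$id
    types <- obj$nodes$type
    pred <- obj$nodes$predictability
    edges <- obj$edges
  } else {
    doc <- xml2::read_xml(path)
    xml2::xml_ns_strip(doc)
    keys <- xml2::xml_find_all(doc, ".//key")
    keymap <- stats::setNames(xml2::xml_attr(keys, "attr.name"),
                              xml2::xml_attr(keys, "id"))
    nodes <- xml2::xml_find_all(doc, ".//node")
    labels <- xml2::xml_attr(nodes, "id")
    get_data <- function(el, name) {
      d <- xml2::xml_find_all(el, "./data")
      v <- xml2::xml_text(d)
      names(v) <- keymap[xml2::xml_attr(d, "key")]
      unname(v[name])
    }
    types <- vapply(nodes, get_data, character(1), "type")
    pred <- as.numeric(vapply(nodes, get_data, character(1), "predictability"))
    eds <- xml2::xml_find_all(doc, ".//edge")
    edges <- data.frame(
      source = xml2::xml_attr(eds, "source"),
      target = xml2::xml_attr(eds, "target"),
      weight = as.numeric(vapply(eds, get_data, character(1), "weight")),
      sign_undefined = vapply(eds, get_data, character(1), "sign_undefined") == "true",
      stringsAsFactors = FALSE
    )
  }

  p1 <- length(labels)
  adj <- matrix(0, p1, p1, dimnames = list(labels, labels))
  undef <- matrix(FALSE, p1, p1, dimnames = list(labels, labels))
  if (!is.null(edges) && NROW(edges) > 0) {
    for (k in seq_len(NROW(edges))) {
      i <- match(edges$source[k], labels)
      j <- match(edges$target[k], labels)
      adj[i, j] <- adj[j, i] <- edges$weight[k]
      su <- if (!is.null(edges$sign_undefined)) edges$sign_undefined[k]
            else identical(edges$sign[k], "undefined")
      undef[i, j] <- undef[j, i] <- isTRUE(su)
    }
  }
  names(pred) <- labels
  list(node_labels = labels, node_types = types, predictability = pred,
       adjacency = adj, sign_undefined = undef)
}
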