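#' Read an XGMML network file
#'
#' Accepts the Cytoscape XGMML dialect: `node` elements with unique `label`
#' (falling back to `id`) and `edge` elements referencing node `id`s or
#' labels. Edges are undirected: `a -> b` and `b -> a` collapse to a single
#' edge. Boolean `att` children named `is_aging_seed` / `is_tsg_seed` are
#' restored onto the node flags.
#'
#' @param path XGMML file path.
#' @return a `ppi_network`.
#' @export
read_xgmml <- function(path) {
  doc <- xml2::read_xml(path)
  node_els <- xml2::xml_find_all(doc, ".//*[local-name()='node']")
  edge_els <- xml2::xml_find_all(doc, ".//*[local-name()='edge']")
  ids <- xml2::xml_attr(node_els, "id")
  labels <- xml2::xml_attr(node_els, "label")
  labels[is.na(labels)] <- ids[is.na(labels)]
  if (anyNA(labels)) stop("XGMML node without label or id")
  labels <- canonical_symbols(labels)
  if (anyDuplicated(labels)) {
    stop("duplicate node labels in XGMML: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  # map both ids and labels to the canonical label
  lut <- c(stats::setNames(labels, ifelse(is.na(ids), labels, ids)),
           stats::setNames(labels, labels))
  flag <- function(els, name) {
    vapply(els, function(el) {
      att <- xml2::xml_find_first(
        el, sprintf(".//*[local-name()='att'][@name='%s']", name))
      if (inherits(att, "xml_missing")) return(FALSE)
      tolower(xml2::xml_attr(att, "value")) %in% c("true", "1")
    }, logical(1))
  }
  aging <- if (length(node_els)) labels[flag(node_els, "is_aging_seed")] else character()
  tsg <- if (length(node_els)) labels[flag(node_els, "is_tsg_seed")] else character()
  src <- xml2::xml_attr(edge_els, "source")
  tgt <- xml2::xml_attr(edge_els, "target")
  unknown <- setdiff(c(src, tgt), names(lut))
  if (length(unknown)) {
    stop("XGMML edge references unknown node(s): ",
         paste(unknown, collapse = ", "))
  }
  ppi_network(
    nodes = labels,
    edges = data.frame(from = unname(lut[src]), to = unname(lut[tgt]),
                       stringsAsFactors = FALSE),
    aging_seeds = aging, tsg_seeds = tsg
  )
}

#' Write a network as XGMML
#'
#' Inverse of [read_xgmml()] on (node set, edge set, seed flags).
#'
#' @param net a `ppi_network`.
#' @param path output file path.
#' @param label graph label attribute.
#' @return invisibly, `path`.
#' @export
write_xgmml <- function(net, path, label = "network") {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub('"', "&quot;", x, fixed = TRUE)
  }
  id_of <- stats::setNames(as.character(seq_len(n_nodes(net))), net$nodes$gene)
  node_lines <- sprintf(
    paste0('  <node id="%s" label="%s">\n',
           '    <att name="is_aging_seed" type="boolean" value="%s"/>\n',
           '    <att name="is_tsg_seed" type="boolean" value="%s"/>\n',
           "  </node>"),
    unname(id_of), esc(net$nodes$gene),
    tolower(as.character(net$nodes$is_aging_seed)),
    tolower(as.character(net$nodes$is_tsg_seed))
  )
  edge_lines <- if (n_edges(net)) {
    sprintf('  <edge source="%s" target="%s"/>',
            unname(id_of[net$edges$from]), unname(id_of[net$edges$to]))
  } else {
    character()
  }
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<graph label="%s" directed="0" xmlns="http://www.cs.rpi.edu/XGMML">',
            esc(label)),
    node_lines, edge_lines, "</graph>"
  ), path)
  invisible(path)
}
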