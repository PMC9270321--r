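#' Export a network to GraphML
#'
#' Writes the estimated network with node attributes (label, type,
#' prevalence, and optionally predictability, community and flow layer) and
#' edge attributes (weight, sign, and bootstrap quantiles when a
#' [bootstrap_edges()] summary is supplied).
#'
#' @param network an `ising_network` or `mgm_network`.
#' @param path output file.
#' @param prevalence optional named numeric: unweighted sample prevalence
#'   (or mean) per node, used downstream as node size.
#' @param predictability optional [node_predictability()] report.
#' @param communities optional [walktrap()] partition.
#' @param flow optional [flow_layers()] layout.
#' @param bootstrap optional [bootstrap_edges()] summary.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(network, path, prevalence = NULL,
                          predictability = NULL, communities = NULL,
                          flow = NULL, bootstrap = NULL) {
  doc <- xml2::xml_new_root("graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  keydefs <- list(
    c("d_label", "node", "label", "string"),
    c("d_type", "node", "type", "string"),
    c("d_prev", "node", "prevalence", "double"),
    c("d_pred", "node", "predictability", "double"),
    c("d_comm", "node", "community", "int"),
    c("d_layer", "node", "layer", "int"),
    c("d_w", "edge", "weight", "double"),
    c("d_sign", "edge", "sign", "int"),
    c("d_q025", "edge", "q025", "double"),
    c("d_q975", "edge", "q975", "double"))
  for (k in keydefs)
    xml2::xml_add_child(doc, "key", id = k[1], `for` = k[2],
                        attr.name = k[3], attr.type = k[4])
  g <- xml2::xml_add_child(doc, "graph", id = "net",
                           edgedefault = "undirected")
  types <- network$node_types
  for (i in seq_along(network$labels)) {
    lab <- network$labels[i]
    nd <- xml2::xml_add_child(g, "node", id = lab)
    add_data <- function(key, value)
      xml2::xml_add_child(nd, "data", as.character(value), key = key)
    add_data("d_label", lab)
    add_data("d_type", types[i])
    if (!is.null(prevalence) && lab %in% names(prevalence))
      add_data("d_prev", format(prevalence[[lab]], digits = 10))
    if (!is.null(predictability)) {
      j <- match(lab, predictability$node)
      if (!is.na(j)) add_data("d_pred",
                              format(predictability$value[j], digits = 10))
    }
    if (!is.null(communities))
      add_data("d_comm", communities$assignment[[lab]])
    if (!is.null(flow))
      add_data("d_layer", flow$layer[[lab]])
  }
  el <- edge_list(network)
  bs <- if (!is.null(bootstrap)) bootstrap$edges else NULL
  for (i in seq_len(nrow(el))) {
    ed <- xml2::xml_add_child(g, "edge", source = el$node_i[i],
                              target = el$node_j[i])
    xml2::xml_add_child(ed, "data", format(el$weight[i], digits = 10),
                        key = "d_w")
    xml2::xml_add_child(ed, "data", as.character(el$sign[i]), key = "d_sign")
    if (!is.null(bs)) {
      j <- which(bs$node_i == el$node_i[i] & bs$node_j == el$node_j[i])
      if (length(j) == 1L) {
        xml2::xml_add_child(ed, "data", format(bs$q025[j], digits = 10),
                            key = "d_q025")
        xml2::xml_add_child(ed, "data", format(bs$q975[j], digits = 10),
                            key = "d_q975")
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Serialise pipeline objects to JSON
#'
#' A small convenience wrapper: writes lists/data frames as pretty JSON with
#' auto-unboxed scalars, the interchange format used for reports, network
#' bundles and the run manifest.
#'
#' @param x object to write.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

# A network as a plain-list JSON bundle (thresholds/intercepts + config).
network_bundle <- function(network) {
  list(labels = network$labels,
       node_types = network$node_types,
       edges = edge_list(network),
       thresholds = as.list(if (!is.null(network$thresholds))
         network$thresholds else network$intercepts),
       n_fit = network$n_fit,
       config = unclass(network$config))
}
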