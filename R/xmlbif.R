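# ---- XMLBIF 0.3 interchange -------------------------------------------------
#
# TABLE convention: probabilities are listed per parent configuration in
# row-major order with the LAST <GIVEN> parent cycling fastest; within each
# configuration, the child's outcomes in declared order. This matches the
# row layout of [cpt()] tables, so a round-trip is the identity.

#' Write a Bayesian network to XMLBIF 0.3
#'
#' @param net a fitted [bayes_net()].
#' @param path output file path.
#' @param name network name written to the NAME element.
#' @export
write_xmlbif <- function(net, path, name = "network") {
  doc <- xml2::xml_new_root("BIF", VERSION = "0.3")
  nw <- xml2::xml_add_child(doc, "NETWORK")
  xml2::xml_add_child(nw, "NAME", name)
  for (v in names(net$variables)) {
    vn <- xml2::xml_add_child(nw, "VARIABLE", TYPE = "nature")
    xml2::xml_add_child(vn, "NAME", v)
    for (s in net$variables[[v]]) xml2::xml_add_child(vn, "OUTCOME", s)
  }
  ord <- topological_order(net)
  for (v in ord) {
    cp <- net$cpts[[v]]
    dn <- xml2::xml_add_child(nw, "DEFINITION")
    xml2::xml_add_child(dn, "FOR", v)
    for (p in cp$parents) xml2::xml_add_child(dn, "GIVEN", p)
    tab <- paste(format(as.vector(t(cp$table)), digits = 17,
                        scientific = FALSE, trim = TRUE),
                 collapse = " ")
    xml2::xml_add_child(dn, "TABLE", tab)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a Bayesian network from XMLBIF 0.3
#'
#' @param path XMLBIF file path.
#' @return a fitted [bayes_net()].
#' @export
read_xmlbif <- function(path) {
  doc <- xml2::read_xml(path)
  nw <- xml2::xml_find_first(doc, ".//NETWORK")
  vnodes <- xml2::xml_find_all(nw, "./VARIABLE")
  variables <- list()
  for (vn in vnodes) {
    nm <- xml2::xml_text(xml2::xml_find_first(vn, "./NAME"))
    outs <- xml2::xml_text(xml2::xml_find_all(vn, "./OUTCOME"))
    variables[[nm]] <- outs
  }
  edges <- matrix(character(0), ncol = 2)
  cpts <- list()
  for (dn in xml2::xml_find_all(nw, "./DEFINITION")) {
    child <- xml2::xml_text(xml2::xml_find_first(dn, "./FOR"))
    parents <- xml2::xml_text(xml2::xml_find_all(dn, "./GIVEN"))
    vals <- as.numeric(strsplit(
      trimws(xml2::xml_text(xml2::xml_find_first(dn, "./TABLE"))),
      "[[:space:]]+")[[1]])
    r <- length(variables[[child]])
    tab <- matrix(vals, ncol = r, byrow = TRUE)
    cpts[[child]] <- cpt(child, parents, variables[parents],
                         variables[[child]], tab)
    if (length(parents)) {
      edges <- rbind(edges, cbind(parents, child))
    }
  }
  net <- bayes_net(variables, edges, cpts)
  bad <- validate_network(net)
  if (length(bad)) {
    stop(sprintf("invalid network in '%s': %s", path,
                 paste(bad, collapse = "; ")), call. = FALSE)
  }
  net
}
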