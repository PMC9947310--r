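# SBML Level 3 Version 1 + fbc version 2 reader/writer built on xml2.
# Identifiers follow the COBRA convention: "M_" / "R_" / "G_" prefixes are
# added on write and stripped on read. Subsystems and gene pathway tags
# travel in <notes> paragraphs ("SUBSYSTEM: ...", "PATHWAY: ...").

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
XHTML_NS <- "http://www.w3.org/1999/xhtml"

sbmlSafeId <- function(id) {
  safe <- gsub("[^A-Za-z0-9_]", "_", id)
  ifelse(grepl("^[A-Za-z_]", safe), safe, paste0("_", safe))
}

writeModelSbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub('"', "&quot;", x, fixed = TRUE)
  }
  num <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)
  con <- character(0)
  w <- function(...) con <<- c(con, paste0(...))

  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<sbml xmlns="', SBML_NS, '" xmlns:fbc="', FBC_NS,
    '" level="3" version="1" fbc:required="false">')
  w('  <model id="', sbmlSafeId(if (length(model@objective)) "model" else "model"),
    '" fbc:strict="true">')

  w('    <listOfCompartments>')
  comps <- unique(c(model@compartments, model@mets$compartment))
  comps <- comps[nzchar(comps)]
  for (cp in comps)
    w('      <compartment id="', sbmlSafeId(cp), '" constant="true"/>')
  w('    </listOfCompartments>')

  w('    <listOfSpecies>')
  for (i in seq_len(nrow(model@mets))) {
    mt <- model@mets[i, ]
    line <- paste0('      <species id="M_', sbmlSafeId(mt$id),
                   '" name="', esc(mt$name),
                   '" compartment="', sbmlSafeId(mt$compartment),
                   '" hasOnlySubstanceUnits="false" boundaryCondition="false"',
                   ' constant="false"')
    if (!is.na(mt$formula) && nzchar(mt$formula))
      line <- paste0(line, ' fbc:chemicalFormula="', esc(mt$formula), '"')
    w(line, "/>")
  }
  w('    </listOfSpecies>')

  # one parameter per distinct bound value
  bvals <- sort(unique(c(model@rxns$lower_bound, model@rxns$upper_bound)))
  bid <- stats::setNames(paste0("b_", seq_along(bvals)), num(bvals))
  w('    <listOfParameters>')
  for (k in seq_along(bvals))
    w('      <parameter id="', bid[[k]], '" value="', num(bvals[k]),
      '" constant="true"/>')
  w('    </listOfParameters>')

  gpaXml <- function(node, indent) {
    pad <- strrep(" ", indent)
    if (node$op == "gene")
      return(paste0(pad, '<fbc:geneProductRef fbc:geneProduct="G_',
                    sbmlSafeId(node$gene), '"/>'))
    tag <- if (node$op == "and") "fbc:and" else "fbc:or"
    c(paste0(pad, "<", tag, ">"),
      unlist(lapply(node$children, gpaXml, indent = indent + 2)),
      paste0(pad, "</", tag, ">"))
  }

  w('    <listOfReactions>')
  for (j in seq_len(nrow(model@rxns))) {
    r <- model@rxns[j, ]
    w('      <reaction id="R_', sbmlSafeId(r$id), '" name="', esc(r$name),
      '" reversible="', tolower(r$lower_bound < 0),
      '" fast="false" fbc:lowerFluxBound="', bid[[num(r$lower_bound)]],
      '" fbc:upperFluxBound="', bid[[num(r$upper_bound)]], '">')
    if (nzchar(r$subsystem) || r$is_exchange) {
      w('        <notes><body xmlns="', XHTML_NS, '">')
      if (nzchar(r$subsystem)) w('          <p>SUBSYSTEM: ', esc(r$subsystem), '</p>')
      if (r$is_exchange) w('          <p>EXCHANGE: true</p>')
      w('        </body></notes>')
    }
    x <- model@S[, j]
    nz <- which(x != 0)
    subs <- nz[x[nz] < 0]
    prods <- nz[x[nz] > 0]
    if (length(subs)) {
      w('        <listOfReactants>')
      for (i in subs)
        w('          <speciesReference species="M_',
          sbmlSafeId(model@mets$id[i]), '" stoichiometry="', num(-x[i]),
          '" constant="true"/>')
      w('        </listOfReactants>')
    }
    if (length(prods)) {
      w('        <listOfProducts>')
      for (i in prods)
        w('          <speciesReference species="M_',
          sbmlSafeId(model@mets$id[i]), '" stoichiometry="', num(x[i]),
          '" constant="true"/>')
      w('        </listOfProducts>')
    }
    tree <- parseGpr(r$gpr)
    if (!is.null(tree)) {
      w('        <fbc:geneProductAssociation>')
      w(gpaXml(tree, 10))
      w('        </fbc:geneProductAssociation>')
    }
    w('      </reaction>')
  }
  w('    </listOfReactions>')

  if (nrow(model@genes)) {
    w('    <fbc:listOfGeneProducts>')
    for (i in seq_len(nrow(model@genes))) {
      gn <- model@genes[i, ]
      w('      <fbc:geneProduct fbc:id="G_', sbmlSafeId(gn$id),
        '" fbc:name="', esc(gn$name), '" fbc:label="', esc(gn$id), '">')
      if (nzchar(gn$pathway))
        w('        <notes><body xmlns="', XHTML_NS, '"><p>PATHWAY: ',
          esc(gn$pathway), '</p></body></notes>')
      w('      </fbc:geneProduct>')
    }
    w('    </fbc:listOfGeneProducts>')
  }

  if (length(model@objective)) {
    w('    <fbc:listOfObjectives fbc:activeObjective="obj">')
    w('      <fbc:objective fbc:id="obj" fbc:type="maximize">')
    w('        <fbc:listOfFluxObjectives>')
    w('          <fbc:fluxObjective fbc:reaction="R_',
      sbmlSafeId(model@objective), '" fbc:coefficient="1"/>')
    w('        </fbc:listOfFluxObjectives>')
    w('      </fbc:objective>')
    w('    </fbc:listOfObjectives>')
  }

  w('  </model>')
  w('</sbml>')
  writeLines(con, path, useBytes = TRUE)
  invisible(path)
}

readModelSbml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("format error: not well-formed XML in '", path, "': ",
         conditionMessage(e)))
  ns <- c(s = SBML_NS, fbc = FBC_NS, x = XHTML_NS)
  modnode <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(modnode, "xml_missing"))
    stop("format error: no <model> element in '", path, "'")

  att <- function(node, a) xml2::xml_attr(node, a)
  stripPre <- function(x, pre) ifelse(startsWith(x, pre),
                                      substring(x, nchar(pre) + 1), x)

  sp <- xml2::xml_find_all(modnode, ".//s:listOfSpecies/s:species", ns)
  mets <- data.frame(
    id = stripPre(att(sp, "id"), "M_"),
    name = ifelse(is.na(att(sp, "name")), stripPre(att(sp, "id"), "M_"),
                  att(sp, "name")),
    compartment = att(sp, "compartment"),
    formula = xml2::xml_attr(sp, "fbc:chemicalFormula", ns),
    stringsAsFactors = FALSE)

  pars <- xml2::xml_find_all(modnode, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(as.numeric(att(pars, "value")), att(pars, "id"))

  notesTag <- function(node, tag) {
    ps <- xml2::xml_find_all(node, "./s:notes//x:p", ns)
    txt <- xml2::xml_text(ps)
    hit <- grep(paste0("^", tag, ":"), txt, value = TRUE)
    if (!length(hit)) return(NA_character_)
    trimws(sub(paste0("^", tag, ":"), "", hit[1]))
  }

  parseGpa <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef")
      return(stripPre(xml2::xml_attr(node, "fbc:geneProduct", ns), "G_"))
    kids <- xml2::xml_children(node)
    parts <- vapply(kids, parseGpa, character(1))
    op <- if (nm == "and") " and " else " or "
    paste0("(", paste(parts, collapse = op), ")")
  }

  rnodes <- xml2::xml_find_all(modnode, ".//s:listOfReactions/s:reaction", ns)
  n <- length(rnodes)
  stoich <- vector("list", n)
  rxns <- data.frame(id = character(n), name = character(n),
                     lower_bound = numeric(n), upper_bound = numeric(n),
                     gpr = character(n), subsystem = character(n),
                     is_exchange = logical(n), stringsAsFactors = FALSE)
  for (j in seq_len(n)) {
    node <- rnodes[[j]]
    rid <- stripPre(att(node, "id"), "R_")
    rxns$id[j] <- rid
    nm <- att(node, "name")
    rxns$name[j] <- if (is.na(nm)) rid else nm
    lbid <- xml2::xml_attr(node, "fbc:lowerFluxBound", ns)
    ubid <- xml2::xml_attr(node, "fbc:upperFluxBound", ns)
    rev <- identical(att(node, "reversible"), "true")
    rxns$lower_bound[j] <- if (!is.na(lbid) && lbid %in% names(pval))
      pval[[lbid]] else if (rev) -1000 else 0
    rxns$upper_bound[j] <- if (!is.na(ubid) && ubid %in% names(pval))
      pval[[ubid]] else 1000
    ss <- notesTag(node, "SUBSYSTEM")
    rxns$subsystem[j] <- if (is.na(ss)) "" else ss
    exn <- notesTag(node, "EXCHANGE")
    st <- numeric(0)
    for (ref in xml2::xml_find_all(node, "./s:listOfReactants/s:speciesReference", ns)) {
      mid <- stripPre(att(ref, "species"), "M_")
      st[mid] <- (if (mid %in% names(st)) st[mid] else 0) -
        as.numeric(att(ref, "stoichiometry"))
    }
    for (ref in xml2::xml_find_all(node, "./s:listOfProducts/s:speciesReference", ns)) {
      mid <- stripPre(att(ref, "species"), "M_")
      st[mid] <- (if (mid %in% names(st)) st[mid] else 0) +
        as.numeric(att(ref, "stoichiometry"))
    }
    stoich[[j]] <- st[st != 0]
    rxns$is_exchange[j] <- if (!is.na(exn)) identical(exn, "true")
      else length(stoich[[j]]) == 1
    gpa <- xml2::xml_find_first(node, "./fbc:geneProductAssociation", ns)
    rxns$gpr[j] <- if (inherits(gpa, "xml_missing")) "" else {
      kids <- xml2::xml_children(gpa)
      if (!length(kids)) "" else parseGpa(kids[[1]])
    }
  }
  names(stoich) <- rxns$id

  gp <- xml2::xml_find_all(modnode, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  genes <- NULL
  if (length(gp)) {
    pw <- vapply(gp, function(g) {
      p <- notesTag(g, "PATHWAY")
      if (is.na(p)) "" else p
    }, character(1))
    gid <- stripPre(xml2::xml_attr(gp, "fbc:id", ns), "G_")
    gname <- xml2::xml_attr(gp, "fbc:name", ns)
    genes <- data.frame(id = gid,
                        name = ifelse(is.na(gname), gid, gname),
                        pathway = pw, stringsAsFactors = FALSE)
  }

  objective <- character(0)
  fo <- xml2::xml_find_first(modnode, ".//fbc:fluxObjective", ns)
  if (!inherits(fo, "xml_missing"))
    objective <- stripPre(xml2::xml_attr(fo, "fbc:reaction", ns), "R_")

  unknown <- setdiff(unique(unlist(lapply(stoich, names))), mets$id)
  if (length(unknown))
    stop("validation error: reactions reference unknown species: ",
         paste(sort(unknown), collapse = ", "))

  comps <- xml2::xml_attr(
    xml2::xml_find_all(modnode, ".//s:listOfCompartments/s:compartment", ns),
    "id")
  MetabolicModel(mets = mets, rxns = rxns, S = stoich, genes = genes,
                 objective = objective, compartments = comps)
}
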