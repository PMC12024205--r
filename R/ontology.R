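# Optional Turtle (RDF/OWL) rendering of the knowledge base: the class
# skeleton (Complaint, FittingParameter and its group subclasses,
# HearingAid, Solution and its category subclasses) plus instances for
# parameters, devices and guide rules. One triple per statement, so the
# emitted statement count equals the parsed triple count. No reasoning is
# performed.

ttl_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub('"', '\\"', x, fixed = TRUE)
  gsub("\n", "\\n", x, fixed = TRUE)
}

ttl_str <- function(x) sprintf('"%s"', ttl_escape(x))
ttl_num <- function(x) {
  if (is.infinite(x)) sprintf('"%s"^^xsd:double', ifelse(x > 0, "INF", "-INF"))
  else format(x, scientific = FALSE)
}

ttl_class_name <- function(x) {
  # "dynamic" -> "Dynamic", "enerFaibl" stays mixed-case
  paste0(toupper(substring(x, 1, 1)), substring(x, 2))
}

ttl_local <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

#' Export a knowledge base as a Turtle ontology
#'
#' Emits an RDF/OWL rendering of the knowledge-base concepts and instances
#' in Turtle: the fixed class skeleton, one subclass of `FittingParameter`
#' per parameter group (e.g. a `Silence` subclass when a silence-detection
#' parameter such as `enerFaibl` is declared), one subclass of `Solution`
#' per solution category, and individuals for parameters, devices and guide
#' rules with their attributes.
#'
#' @param kb a valid `hafes_kb`.
#' @param path destination `.ttl` file.
#' @return Invisibly, the number of triples emitted.
#' @export
export_ontology <- function(kb, path) {
  stopifnot(inherits(kb, "hafes_kb"))
  h <- "hafo:"
  triples <- character()
  add <- function(s, p, o) triples <<- c(triples, sprintf("%s %s %s .", s, p, o))

  # class skeleton
  for (cls in c("Complaint", "FittingParameter", "HearingAid", "Solution",
                "Patient", "FittingConstraint", "FittingRule"))
    add(paste0(h, cls), "a", "owl:Class")
  for (cat_i in seq_len(nrow(.hafes_categories))) {
    label <- .hafes_categories$label[cat_i]
    cls <- ttl_local(gsub(" ", "",
                          gsub("(?:^| )(\\w)", "\\U\\1", label,
                               perl = TRUE)))
    add(paste0(h, cls), "a", "owl:Class")
    add(paste0(h, cls), "rdfs:subClassOf", paste0(h, "Solution"))
    add(paste0(h, cls), "rdfs:label", ttl_str(label))
  }
  groups <- unique(vapply(kb$parameters, function(p) p$group, character(1)))
  for (g in groups) {
    cls <- paste0(h, ttl_class_name(g))
    add(cls, "a", "owl:Class")
    add(cls, "rdfs:subClassOf", paste0(h, "FittingParameter"))
  }

  # parameter individuals
  for (p in kb$parameters) {
    s <- paste0(h, ttl_local(p$name))
    add(s, "a", paste0(h, ttl_class_name(p$group)))
    if (nzchar(p$unit)) add(s, paste0(h, "unit"), ttl_str(p$unit))
    add(s, paste0(h, "minValue"), ttl_num(p$typical_range[1]))
    add(s, paste0(h, "maxValue"), ttl_num(p$typical_range[2]))
    add(s, paste0(h, "defaultValue"), ttl_num(p$default_value))
    add(s, paste0(h, "stepUnit"), ttl_num(p$step_unit))
    if (!is.null(p$manufacturer_alias))
      add(s, paste0(h, "manufacturerAlias"), ttl_str(p$manufacturer_alias))
  }

  # device individuals and their constraints
  for (d in kb$devices) {
    s <- paste0(h, ttl_local(d$model))
    add(s, "a", paste0(h, "HearingAid"))
    add(s, paste0(h, "formFactor"), ttl_str(d$form_factor))
    for (nm in names(d$overrides)) {
      cs <- paste0(h, ttl_local(paste0(d$model, "_", nm, "_constraint")))
      add(cs, "a", paste0(h, "FittingConstraint"))
      add(s, paste0(h, "hasConstraint"), cs)
      add(cs, paste0(h, "constrainsParameter"), paste0(h, ttl_local(nm)))
      add(cs, paste0(h, "minValue"), ttl_num(d$overrides[[nm]][1]))
      add(cs, paste0(h, "maxValue"), ttl_num(d$overrides[[nm]][2]))
    }
  }

  # guide rules
  for (g in kb$guide) {
    s <- paste0(h, sprintf("Rule_%d", g$id))
    add(s, "a", paste0(h, "FittingRule"))
    add(s, paste0(h, "entryId"), ttl_num(g$id))
    first <- g$solutions[[1]]
    add(s, paste0(h, "solutionCategory"), ttl_str(first$category))
    if (!is.null(first$parameter))
      add(s, paste0(h, "adjustsParameter"), paste0(h, ttl_local(first$parameter)))
    if (!is.null(first$command))
      add(s, paste0(h, "command"), ttl_str(format(first$command)))
  }

  header <- c(
    "@prefix hafo: <http://example.org/hafo#> .",
    "@prefix owl: <http://www.w3.org/2002/07/owl#> .",
    "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .",
    "@prefix xsd: <http://www.w3.org/2001/XMLSchema#> .",
    ""
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(c(header, triples)), con = con, useBytes = TRUE)
  invisible(length(triples))
}
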