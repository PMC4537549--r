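SKIN_NS <- "https://sphingokin.r-universe.dev/ns"

#' Read an SBML model
#'
#' Parses SBML Level 2 or Level 3 core documents into a `reaction_network`.
#' Kinetic-law MathML is pattern-matched against the canonical forms (mass
#' action as a product of a rate constant and species powers;
#' Michaelis-Menten as `Vmax*S/(Km+S)`; non-competitive inhibition factors
#' `1/(1 + I/Ki)`); math matching none of these is retained verbatim as an
#' opaque rate expression, so arbitrary models still load and simulate.
#' Local reaction parameters populate the registry as
#' `"<reaction id>.<symbol>"`; global parameters are attached to the
#' reactions that reference them.
#'
#' @param path SBML file.
#' @return a `reaction_network`.
#' @export
read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("not parseable as SBML: ", conditionMessage(e), call. = FALSE)
  })
  ns <- xml2::xml_ns(doc)
  root <- doc
  if (!grepl("sbml", xml2::xml_name(root))) {
    stop("root element is not <sbml>", call. = FALSE)
  }
  lv <- xml2::xml_attr(root, "level")
  xml2::xml_ns_strip(doc)
  model <- xml2::xml_find_first(doc, ".//model")
  if (inherits(model, "xml_missing")) stop("no <model> element", call. = FALSE)

  comp_nodes <- xml2::xml_find_all(model, ".//listOfCompartments/compartment")
  compartments <- tibble(
    id = xml2::xml_attr(comp_nodes, "id"),
    name = dplyr::coalesce(xml2::xml_attr(comp_nodes, "name"),
                           xml2::xml_attr(comp_nodes, "id")),
    volume = as.numeric(dplyr::coalesce(xml2::xml_attr(comp_nodes, "size"),
                                        "1"))
  )

  sp_nodes <- xml2::xml_find_all(model, ".//listOfSpecies/species")
  init <- as.numeric(xml2::xml_attr(sp_nodes, "initialConcentration"))
  amt <- as.numeric(xml2::xml_attr(sp_nodes, "initialAmount"))
  init[is.na(init)] <- amt[is.na(init)]
  derived <- vapply(sp_nodes, function(n) {
    ann <- xml2::xml_find_first(n, ".//annotation/info")
    !inherits(ann, "xml_missing") &&
      identical(xml2::xml_attr(ann, "explicitInitial"), "false")
  }, TRUE)
  species <- tibble(
    id = xml2::xml_attr(sp_nodes, "id"),
    name = dplyr::coalesce(xml2::xml_attr(sp_nodes, "name"),
                           xml2::xml_attr(sp_nodes, "id")),
    compartment = xml2::xml_attr(sp_nodes, "compartment"),
    initial_concentration = dplyr::coalesce(init, 0),
    is_enzyme = FALSE,
    explicit_initial = !is.na(init) & !derived
  )

  gpar_nodes <- xml2::xml_find_all(model, ".//listOfParameters/parameter")
  gpar <- stats::setNames(as.numeric(xml2::xml_attr(gpar_nodes, "value")),
                          xml2::xml_attr(gpar_nodes, "id"))

  rx_nodes <- xml2::xml_find_all(model, ".//listOfReactions/reaction")
  reactions <- lapply(rx_nodes, parse_sbml_reaction, species_ids = species$id,
                      gpar = gpar)

  meta <- list(scenario = xml2::xml_attr(model, "id") %||% "sbml",
               sbml_level = lv)
  reaction_network(species = species, reactions = reactions,
                   compartments = compartments, metadata = meta)
}

parse_sbml_reaction <- function(node, species_ids, gpar) {
  id <- xml2::xml_attr(node, "id")
  name <- xml2::xml_attr(node, "name") %||% id
  if (is.na(name)) name <- id
  side <- function(xp) {
    refs <- xml2::xml_find_all(node, xp)
    if (!length(refs)) return(NULL)
    stats::setNames(
      as.numeric(dplyr::coalesce(xml2::xml_attr(refs, "stoichiometry"), "1")),
      xml2::xml_attr(refs, "species"))
  }
  from <- side(".//listOfReactants/speciesReference")
  to <- side(".//listOfProducts/speciesReference")
  modifiers <- xml2::xml_attr(
    xml2::xml_find_all(node, ".//listOfModifiers/modifierSpeciesReference"),
    "species")

  kl <- xml2::xml_find_first(node, ".//kineticLaw")
  lpar_nodes <- xml2::xml_find_all(
    kl, ".//listOfLocalParameters/localParameter | .//listOfParameters/parameter")
  lpar <- stats::setNames(as.numeric(xml2::xml_attr(lpar_nodes, "value")),
                          xml2::xml_attr(lpar_nodes, "id"))
  math <- xml2::xml_find_first(kl, ".//math/*")
  expr <- mathml_to_expr(math)

  # annotation written by write_sbml(): transport flag + enzyme names
  ann <- xml2::xml_find_first(node, ".//annotation/info")
  transport <- NA
  if (!inherits(ann, "xml_missing")) {
    transport <- identical(xml2::xml_attr(ann, "transport"), "true")
    mods <- xml2::xml_attr(ann, "modifiers")
    if (!is.na(mods) && nzchar(mods)) {
      modifiers <- strsplit(mods, " ", fixed = TRUE)[[1]]
    }
  }

  law <- classify_rate_math(expr, lpar, gpar, species_ids,
                            substrates = names(from))
  if (is.na(transport)) transport <- law$form == "MASS_ACTION"
  rxn(id, from = from, to = to, law = law$law, modifiers = modifiers,
      transport = transport, name = name)
}

# MathML (content markup) -> R expression
mathml_to_expr <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "ci") return(as.name(trimws(xml2::xml_text(node))))
  if (nm == "cn") {
    kids <- xml2::xml_find_all(node, "./*")
    if (length(kids)) { # rationals / e-notation
      parts <- as.numeric(xml2::xml_text(
        xml2::xml_find_all(node, "./text()")))
      ty <- xml2::xml_attr(node, "type")
      if (identical(ty, "e-notation")) return(parts[1] * 10^parts[2])
      if (identical(ty, "rational")) return(parts[1] / parts[2])
    }
    return(as.numeric(xml2::xml_text(node)))
  }
  if (nm != "apply") stop("unsupported MathML node <", nm, ">", call. = FALSE)
  kids <- xml2::xml_find_all(node, "./*")
  op <- xml2::xml_name(kids[[1]])
  args <- lapply(kids[-1], mathml_to_expr)
  fold <- function(f) Reduce(function(a, b) call(f, a, b), args)
  switch(op,
    times = fold("*"), plus = fold("+"), minus = if (length(args) == 1)
      call("-", args[[1]]) else fold("-"),
    divide = fold("/"), power = fold("^"),
    exp = call("exp", args[[1]]), ln = call("log", args[[1]]),
    stop("unsupported MathML operator <", op, ">", call. = FALSE))
}

expr_to_mathml <- function(e) {
  if (is.name(e)) return(paste0("<ci> ", as.character(e), " </ci>"))
  if (is.numeric(e)) return(paste0("<cn> ", format(e, digits = 17), " </cn>"))
  if (is.call(e)) {
    op <- as.character(e[[1]])
    tag <- switch(op, `*` = "times", `+` = "plus", `-` = "minus",
                  `/` = "divide", `^` = "power", exp = "exp", ln = "ln",
                  log = "ln",
                  stop("cannot serialize operator '", op, "' to MathML",
                       call. = FALSE))
    args <- vapply(as.list(e)[-1], expr_to_mathml, "")
    return(paste0("<apply><", tag, "/>", paste(args, collapse = ""),
                  "</apply>"))
  }
  stop("cannot serialize rate expression", call. = FALSE)
}

# flatten a product into factors
product_factors <- function(e) {
  if (is.call(e) && identical(e[[1]], as.name("*"))) {
    c(product_factors(e[[2]]), product_factors(e[[3]]))
  } else list(e)
}

is_one <- function(e) is.numeric(e) && length(e) == 1 && e == 1

# match 1/(1 + I/Ki): returns list(species, ki_sym) or NULL
match_inhibitor_factor <- function(f, species_ids, par_names) {
  if (!(is.call(f) && identical(f[[1]], as.name("/")))) return(NULL)
  if (!is_one(f[[2]])) return(NULL)
  den <- f[[3]]
  if (!(is.call(den) && identical(den[[1]], as.name("+")))) return(NULL)
  a <- den[[2]]; b <- den[[3]]
  if (!is_one(a)) { tmp <- a; a <- b; b <- tmp }
  if (!is_one(a)) return(NULL)
  if (!(is.call(b) && identical(b[[1]], as.name("/")))) return(NULL)
  sp <- b[[2]]; ki <- b[[3]]
  if (is.name(sp) && is.name(ki) &&
      as.character(sp) %in% species_ids &&
      as.character(ki) %in% par_names) {
    list(species = as.character(sp), ki_sym = as.character(ki))
  } else NULL
}

# match Vmax*S/(Km+S)
match_mm_factor <- function(f, species_ids, par_names, substrates) {
  if (!(is.call(f) && identical(f[[1]], as.name("/")))) return(NULL)
  num <- f[[2]]; den <- f[[3]]
  nf <- product_factors(num)
  if (length(nf) != 2) return(NULL)
  syms <- vapply(nf, function(x) if (is.name(x)) as.character(x) else "", "")
  v_i <- which(syms %in% par_names)
  s_i <- which(syms %in% species_ids)
  if (length(v_i) != 1 || length(s_i) != 1) return(NULL)
  s <- syms[s_i]
  if (!(is.call(den) && identical(den[[1]], as.name("+")))) return(NULL)
  d1 <- den[[2]]; d2 <- den[[3]]
  if (is.name(d2) && as.character(d2) %in% par_names) {
    tmp <- d1; d1 <- d2; d2 <- tmp
  }
  if (!(is.name(d1) && as.character(d1) %in% par_names)) return(NULL)
  if (!(is.name(d2) && as.character(d2) == s)) return(NULL)
  if (length(substrates) && !(s %in% substrates)) return(NULL)
  list(vmax_sym = syms[v_i], km_sym = as.character(d1), species = s)
}

classify_rate_math <- function(expr, lpar, gpar, species_ids, substrates) {
  pars <- c(lpar, gpar[setdiff(names(gpar), names(lpar))])
  par_names <- names(pars)
  factors <- product_factors(expr)
  inh <- list(); rest <- list()
  for (f in factors) {
    m <- match_inhibitor_factor(f, species_ids, par_names)
    if (!is.null(m)) inh[[length(inh) + 1]] <- m else
      rest[[length(rest) + 1]] <- f
  }
  inhibitors <- NULL
  if (length(inh)) {
    inhibitors <- stats::setNames(
      vapply(inh, function(m) pars[[m$ki_sym]], 0),
      vapply(inh, `[[`, "", "species"))
  }
  base <- if (length(rest) == 1) rest[[1]] else
    Reduce(function(a, b) call("*", a, b), rest)

  # MM?
  mmf <- if (length(rest) == 1)
    match_mm_factor(base, species_ids, par_names, substrates) else NULL
  if (!is.null(mmf)) {
    return(list(form = "MM",
                law = mm(Vmax = pars[[mmf$vmax_sym]], Km = pars[[mmf$km_sym]],
                         inhibitors = inhibitors)))
  }
  # MAL? product of exactly one parameter and species powers matching nothing
  bf <- product_factors(base)
  k_sym <- NULL; ok <- TRUE
  for (f in bf) {
    if (is.name(f) && as.character(f) %in% par_names && is.null(k_sym)) {
      k_sym <- as.character(f)
    } else if (is.name(f) && as.character(f) %in% species_ids) {
      # first-order species factor
    } else if (is.call(f) && identical(f[[1]], as.name("^")) &&
               is.name(f[[2]]) && as.character(f[[2]]) %in% species_ids &&
               is.numeric(f[[3]])) {
      # species power
    } else ok <- FALSE
  }
  if (ok && !is.null(k_sym)) {
    return(list(form = "MASS_ACTION",
                law = mal(k = pars[[k_sym]], inhibitors = inhibitors)))
  }
  # opaque fallback: whole expression with every referenced parameter
  used <- intersect(all.vars(expr), par_names)
  list(form = "OPAQUE", law = opaque_law(expr, pars[used]))
}

#' Write a network as SBML
#'
#' Serializes to SBML Level 3 Version 1 core. Kinetic-law parameters are
#' written as local parameters (symbol names are unique within each
#' reaction); transport flags and enzyme annotations are carried in a small
#' custom annotation element so [read_sbml()] round-trips the network
#' losslessly. Species with derived (non-tabulated) initial values are
#' marked in the same annotation.
#'
#' @param net a `reaction_network`.
#' @param path output file.
#' @return an `sbml_summary` (level/version and element counts), invisibly.
#' @export
write_sbml <- function(net, path) {
  validate_network(net)
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'level="3" version="1">'),
    sprintf('<model id="%s">',
            esc(net$metadata$scenario %||% "model")),
    "<listOfCompartments>",
    sprintf('<compartment id="%s" name="%s" size="%.17g" constant="true"/>',
            net$compartments$id, esc(net$compartments$name),
            net$compartments$volume),
    "</listOfCompartments>",
    "<listOfSpecies>")
  for (i in seq_len(nrow(net$species))) {
    s <- net$species[i, ]
    ann <- if (!s$explicit_initial) {
      sprintf('><annotation><info xmlns="%s" explicitInitial="false"/></annotation></species>',
              SKIN_NS)
    } else "/>"
    lines <- c(lines, sprintf(
      paste0('<species id="%s" name="%s" compartment="%s" ',
             'initialConcentration="%.17g" hasOnlySubstanceUnits="false" ',
             'boundaryCondition="false" constant="false"%s'),
      s$id, esc(s$name), s$compartment, s$initial_concentration, ann))
  }
  lines <- c(lines, "</listOfSpecies>", "<listOfReactions>")
  for (r in net$reactions) {
    lines <- c(lines, sprintf(
      '<reaction id="%s" name="%s" reversible="false">', r$id, esc(r$name)))
    lines <- c(lines, sprintf(
      '<annotation><info xmlns="%s" transport="%s" modifiers="%s"/></annotation>',
      SKIN_NS, tolower(as.character(r$is_transport)),
      paste(r$modifiers, collapse = " ")))
    if (nrow(r$substrates)) {
      lines <- c(lines, "<listOfReactants>",
                 sprintf('<speciesReference species="%s" stoichiometry="%d" constant="true"/>',
                         r$substrates$species, r$substrates$coef),
                 "</listOfReactants>")
    }
    if (nrow(r$products)) {
      lines <- c(lines, "<listOfProducts>",
                 sprintf('<speciesReference species="%s" stoichiometry="%d" constant="true"/>',
                         r$products$species, r$products$coef),
                 "</listOfProducts>")
    }
    lines <- c(lines, "<kineticLaw>",
               "<math xmlns=\"http://www.w3.org/1998/Math/MathML\">",
               expr_to_mathml(rate_expression(r)),
               "</math>", "<listOfLocalParameters>")
    for (sym in law_symbols(r)) {
      lines <- c(lines, sprintf(
        '<localParameter id="%s" value="%.17g"/>',
        sym, net$params[[paste0(r$id, ".", sym)]]))
    }
    lines <- c(lines, "</listOfLocalParameters>", "</kineticLaw>",
               "</reaction>")
  }
  lines <- c(lines, "</listOfReactions>", "</model>", "</sbml>")
  writeLines(lines, path)
  invisible(sbml_info(path))
}

# canonical symbolic rate expression of a reaction (symbols, not values)
rate_expression <- function(r) {
  law <- r$law
  base <- switch(law$form,
    MASS_ACTION = {
      e <- as.name("k")
      for (i in seq_len(nrow(r$substrates))) {
        f <- if (r$substrates$coef[i] == 1) as.name(r$substrates$species[i])
        else call("^", as.name(r$substrates$species[i]),
                  as.numeric(r$substrates$coef[i]))
        e <- call("*", e, f)
      }
      e
    },
    MICHAELIS_MENTEN = ,
    MM_INHIBITED = {
      s <- as.name(r$substrates$species[1])
      call("/", call("*", as.name("Vmax"), s),
           call("+", as.name("Km"), s))
    },
    OPAQUE = law$expr)
  if (!is.null(law$inhibitors)) {
    for (inh in names(law$inhibitors)) {
      base <- call("*", base,
                   call("/", 1, call("+", 1,
                                     call("/", as.name(inh),
                                          as.name(paste0("Ki_", inh))))))
    }
  }
  base
}

#' Summarize an SBML document
#'
#' @param path SBML file.
#' @return an `sbml_summary`: level, version, element counts and any
#'   unsupported constructs found (events, rules, constraints,
#'   function definitions).
#' @export
sbml_info <- function(path) {
  doc <- xml2::read_xml(path)
  lv <- xml2::xml_attr(doc, "level")
  ver <- xml2::xml_attr(doc, "version")
  xml2::xml_ns_strip(doc)
  count <- function(xp) length(xml2::xml_find_all(doc, xp))
  unsupported <- c(
    if (count(".//listOfEvents/*") > 0) "events",
    if (count(".//listOfRules/*") > 0) "rules",
    if (count(".//listOfConstraints/*") > 0) "constraints",
    if (count(".//listOfFunctionDefinitions/*") > 0) "functionDefinitions")
  structure(list(level = as.integer(lv), version = as.integer(ver),
                 n_compartments = count(".//listOfCompartments/compartment"),
                 n_species = count(".//listOfSpecies/species"),
                 n_reactions = count(".//listOfReactions/reaction"),
                 n_parameters = count(".//listOfParameters/parameter") +
                   count(".//listOfLocalParameters/localParameter"),
                 unsupported = unsupported %||% character()),
            class = "sbml_summary")
}

#' @export
print.sbml_summary <- function(x, ...) {
  cat("<sbml_summary> SBML L", x$level, "V", x$version, ": ",
      x$n_compartments, " compartments, ", x$n_species, " species, ",
      x$n_reactions, " reactions, ", x$n_parameters, " parameters\n",
      sep = "")
  if (length(x$unsupported)) {
    cat("  unsupported constructs:", paste(x$unsupported, collapse = ", "),
        "\n")
  }
  invisible(x)
}
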