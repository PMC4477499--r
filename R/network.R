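#' Constraint-based metabolic network container
#'
#' A `syncol_network` bundles a stoichiometric matrix with flux bounds and a
#' map from the seven physiological roles the column model needs
#' (`co`, `h2`, `co2`, `ethanol`, `acetate`, `growth`, `atp_maintenance`)
#' to reaction identifiers.  Exchange fluxes follow the usual sign
#' convention: negative flux is consumption, positive is secretion.
#'
#' @param reactions character vector of reaction identifiers.
#' @param metabolites character vector of metabolite identifiers.
#' @param S stoichiometric matrix, `length(metabolites)` rows by
#'   `length(reactions)` columns (coerced to a sparse `Matrix`).
#' @param lower,upper numeric flux bounds per reaction (mmol/gDW/h).
#' @param exchange named character vector mapping the seven roles to
#'   reaction ids.
#' @param id model identifier string.
#' @return A validated `syncol_network`.
#' @export
metabolic_network <- function(reactions, metabolites, S, lower, upper,
                              exchange, id = "model") {
  S <- Matrix::Matrix(S, sparse = TRUE)
  net <- structure(
    list(
      id = id,
      reactions = as.character(reactions),
      metabolites = as.character(metabolites),
      S = S,
      lower = stats::setNames(as.numeric(lower), reactions),
      upper = stats::setNames(as.numeric(upper), reactions),
      exchange = exchange
    ),
    class = "syncol_network"
  )
  validate_network(net)
}

#' @export
print.syncol_network <- function(x, ...) {
  cat(sprintf(
    "<syncol_network> %s: %d metabolites, %d reactions (%d exchange roles)\n",
    x$id, length(x$metabolites), length(x$reactions), length(x$exchange)))
  invisible(x)
}

.roles <- c("co", "h2", "co2", "ethanol", "acetate", "growth",
            "atp_maintenance")

validate_network <- function(net) {
  stopifnot(inherits(net, "syncol_network"))
  if (!all(dim(net$S) == c(length(net$metabolites), length(net$reactions))))
    abort("stoichiometric matrix dimensions must be |metabolites| x |reactions|",
          class = "syncol_format_error")
  missing <- setdiff(.roles, names(net$exchange))
  if (length(missing))
    abort(paste0("exchange map is missing roles: ",
                 paste(missing, collapse = ", ")),
          class = "syncol_config_error")
  unresolved <- net$exchange[!net$exchange %in% net$reactions]
  if (length(unresolved))
    abort(paste0("exchange roles map to unknown reactions: ",
                 paste(names(unresolved), collapse = ", ")),
          class = "syncol_config_error")
  dup <- duplicated(net$reactions)
  if (any(dup))
    abort(paste0("duplicated reaction ids: ",
                 paste(unique(net$reactions[dup]), collapse = ", ")),
          class = "syncol_format_error")
  atpm <- net$exchange[["atp_maintenance"]]
  if (!(net$lower[[atpm]] > 0))
    abort("ATP maintenance reaction must have a strictly positive lower bound",
          class = "syncol_config_error")
  net
}

#' Toy lumped Wood-Ljungdahl network
#'
#' A nine-metabolite, thirteen-reaction caricature of acetogen energy
#' metabolism used as the package's test model.  CO and H2 oxidation feed
#' a reducing-equivalent pool (`RED`); carbon is fixed from CO2 into
#' acetyl-CoA (Wood-Ljungdahl lump, 2 CO2 + 8 RED per acetyl-CoA);
#' acetyl-CoA is partitioned between acetate (the sole ATP source, via
#' substrate-level phosphorylation in the acetate kinase lump), ethanol
#' (consuming 4 additional reducing equivalents), and biomass (10
#' acetyl-CoA + 5 ATP).  A mandatory ATP maintenance drain
#' (0.45 mmol/gDW/h) must always be met, and a finite biosynthetic
#' capacity caps the biomass flux at `mu_max`.
#'
#' This energy coupling reproduces the qualitative physiology of
#' CO/H2-fermenting acetogens under the lexicographic flux ordering:
#' acetate secretion is obligatory whenever the cell grows (growth ATP
#' comes from acetate kinase), surplus reducing equivalents at H2-rich,
#' carbon-limited conditions are discharged into ethanol (so H2-rich gas
#' favours ethanol over acetate), H2-poor conditions yield acetate only,
#' and uptake rates too small to cover the maintenance ATP demand are
#' infeasible, giving zero growth.
#'
#' @param mu_max biosynthetic capacity: upper bound on the biomass reaction
#'   flux (h^-1).
#' @param atp_maintenance mandatory ATP drain (mmol/gDW/h).
#' @return A `syncol_network`.
#' @examples
#' net <- toy_wlp_network()
#' solve_lexicographic_fba(net, c(co = 35, h2 = 70, co2 = 0))
#' @export
toy_wlp_network <- function(mu_max = 0.775, atp_maintenance = 0.45) {
  mets <- c("CO", "H2", "CO2", "ACCOA", "ATP", "RED", "ETOH", "AC", "BIOMASS")
  rxn <- list(
    CODH      = c(CO = -1, CO2 = 1, RED = 2),
    HYD       = c(H2 = -1, RED = 2),
    WLP       = c(CO2 = -2, RED = -8, ACCOA = 1),
    PTAACK    = c(ACCOA = -1, AC = 1, ATP = 1),
    ADH       = c(ACCOA = -1, RED = -4, ETOH = 1),
    BIO       = c(ACCOA = -10, ATP = -5, BIOMASS = 1),
    ATPM      = c(ATP = -1),
    EX_CO     = c(CO = -1),
    EX_H2     = c(H2 = -1),
    EX_CO2    = c(CO2 = -1),
    EX_ETOH   = c(ETOH = -1),
    EX_AC     = c(AC = -1),
    EX_BIOMASS = c(BIOMASS = -1)
  )
  S <- matrix(0, length(mets), length(rxn),
              dimnames = list(mets, names(rxn)))
  for (r in names(rxn)) S[names(rxn[[r]]), r] <- rxn[[r]]
  lower <- stats::setNames(rep(0, length(rxn)), names(rxn))
  upper <- stats::setNames(rep(1000, length(rxn)), names(rxn))
  lower[["ATPM"]] <- atp_maintenance
  upper[["BIO"]] <- mu_max
  metabolic_network(
    reactions = names(rxn), metabolites = mets, S = S,
    lower = lower, upper = upper,
    exchange = c(co = "EX_CO", h2 = "EX_H2", co2 = "EX_CO2",
                 ethanol = "EX_ETOH", acetate = "EX_AC",
                 growth = "BIO", atp_maintenance = "ATPM"),
    id = "toy_wlp"
  )
}

#' Default reaction-id patterns for role discovery
#'
#' Regular expressions used to resolve the seven roles against BiGG-style
#' reaction identifiers (e.g. the *C. ljungdahlii* iHN637 reconstruction).
#' Override any entry when a model release spells ids differently.
#' @export
default_role_patterns <- function() {
  c(co = "^EX_co_e$", h2 = "^EX_h2_e$", co2 = "^EX_co2_e$",
    ethanol = "^EX_etoh_e$", acetate = "^EX_ac_e$",
    growth = "^(BIOMASS|Biomass|biomass)", atp_maintenance = "^ATPM$")
}

resolve_roles <- function(reactions, patterns) {
  res <- character(0)
  unresolved <- character(0)
  for (role in .roles) {
    hit <- grep(patterns[[role]], reactions, value = TRUE)
    if (length(hit) == 0) {
      unresolved <- c(unresolved, role)
    } else {
      res[[role]] <- hit[[1]]
    }
  }
  if (length(unresolved))
    abort(paste0("could not resolve exchange roles: ",
                 paste(unresolved, collapse = ", ")),
          class = "syncol_config_error")
  res
}

#' Load a constraint-based model from SBML or COBRA-JSON
#'
#' Reads a genome-scale (or toy) metabolic model and resolves the seven
#' roles the column model needs via configurable reaction-id patterns.
#' SBML input is parsed with a lightweight reader for SBML Level 3 with the
#' FBC flux-bounds package; COBRA-JSON follows the cobrapy schema.
#'
#' @param source path to the model file.
#' @param format `"auto"` (by file extension), `"sbml"` or `"json"`.
#' @param role_patterns named character vector of regular expressions, see
#'   [default_role_patterns()].
#' @return A `syncol_network`; the file's MD5 checksum is attached as
#'   attribute `"checksum"`.
#' @export
load_metabolic_model <- function(source,
                                 format = c("auto", "sbml", "json"),
                                 role_patterns = default_role_patterns()) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", source, ignore.case = TRUE))
      "sbml" else "json"
  }
  if (!file.exists(source))
    abort(paste0("model file not found: ", source),
          class = "syncol_format_error")
  patterns <- default_role_patterns()
  patterns[names(role_patterns)] <- role_patterns
  parsed <- switch(format,
                   sbml = parse_sbml(source),
                   json = parse_cobra_json(source))
  exchange <- resolve_roles(parsed$reactions, patterns)
  net <- metabolic_network(parsed$reactions, parsed$metabolites, parsed$S,
                           parsed$lower, parsed$upper, exchange,
                           id = parsed$id)
  attr(net, "checksum") <- unname(tools::md5sum(source))
  net
}

parse_cobra_json <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e)
                    abort(paste0("failed to parse COBRA-JSON: ",
                                 conditionMessage(e)),
                          class = "syncol_format_error"))
  if (is.null(doc$reactions) || is.null(doc$metabolites))
    abort("COBRA-JSON must contain 'reactions' and 'metabolites'",
          class = "syncol_format_error")
  mets <- vapply(doc$metabolites, function(m) m$id, character(1))
  rids <- vapply(doc$reactions, function(r) r$id, character(1))
  S <- matrix(0, length(mets), length(rids), dimnames = list(mets, rids))
  lower <- upper <- numeric(length(rids))
  for (k in seq_along(doc$reactions)) {
    r <- doc$reactions[[k]]
    st <- unlist(r$metabolites)
    S[names(st), k] <- as.numeric(st)
    lower[k] <- r$lower_bound %||% -1000
    upper[k] <- r$upper_bound %||% 1000
  }
  list(id = doc$id %||% basename(path), reactions = rids,
       metabolites = mets, S = S, lower = lower, upper = upper)
}

parse_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e)
                    abort(paste0("failed to parse SBML: ",
                                 conditionMessage(e)),
                          class = "syncol_format_error"))
  ns <- xml2::xml_ns(doc)
  model <- xml2::xml_find_first(doc, ".//*[local-name()='model']")
  if (is.na(model))
    abort("no <model> element in SBML file", class = "syncol_format_error")
  species <- xml2::xml_find_all(
    model, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  mets <- xml2::xml_attr(species, "id")
  boundary <- xml2::xml_attr(species, "boundaryCondition")
  mets <- mets[is.na(boundary) | boundary != "true"]
  # SBML ids conventionally carry M_/R_ prefixes (BiGG style); strip them
  strip_m <- function(x) sub("^M_", "", x)
  strip_r <- function(x) sub("^R_", "", x)
  mets <- strip_m(mets)
  params <- xml2::xml_find_all(
    model, ".//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))
  rnodes <- xml2::xml_find_all(
    model, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  rids <- strip_r(xml2::xml_attr(rnodes, "id"))
  S <- matrix(0, length(mets), length(rids), dimnames = list(mets, rids))
  lower <- upper <- numeric(length(rids))
  bound_attr <- function(node, which) {
    v <- xml2::xml_attr(node, paste0("fbc:", which), ns = ns)
    if (is.na(v)) v <- xml2::xml_attr(node, which)
    v
  }
  for (k in seq_along(rnodes)) {
    node <- rnodes[[k]]
    add <- function(xpath, sign) {
      refs <- xml2::xml_find_all(node, xpath)
      sp <- strip_m(xml2::xml_attr(refs, "species"))
      coef <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      coef[is.na(coef)] <- 1
      keep <- sp %in% mets
      if (any(keep))
        S[sp[keep], k] <<- S[sp[keep], k] + sign * coef[keep]
    }
    add(".//*[local-name()='listOfReactants']/*[local-name()='speciesReference']", -1)
    add(".//*[local-name()='listOfProducts']/*[local-name()='speciesReference']", +1)
    lb_ref <- bound_attr(node, "lowerFluxBound")
    ub_ref <- bound_attr(node, "upperFluxBound")
    rev <- identical(xml2::xml_attr(node, "reversible"), "true")
    lower[k] <- if (!is.na(lb_ref) && lb_ref %in% names(pval))
      pval[[lb_ref]] else if (rev) -1000 else 0
    upper[k] <- if (!is.na(ub_ref) && ub_ref %in% names(pval))
      pval[[ub_ref]] else 1000
  }
  lower[!is.finite(lower)] <- -1000
  upper[!is.finite(upper)] <- 1000
  list(id = xml2::xml_attr(model, "id") %||% basename(path),
       reactions = rids, metabolites = mets, S = S,
       lower = lower, upper = upper)
}

#' Write a network to COBRA-JSON
#'
#' Serializes a `syncol_network` to the cobrapy JSON schema so models (in
#' particular the toy Wood-Ljungdahl fixture) round-trip through standard
#' constraint-based tooling.
#'
#' @param network a `syncol_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cobra_json <- function(network, path) {
  S <- as.matrix(network$S)
  rx <- purrr::map(seq_along(network$reactions), function(k) {
    col <- S[, k]
    col <- col[col != 0]
    list(id = network$reactions[[k]],
         name = network$reactions[[k]],
         metabolites = as.list(col),
         lower_bound = unname(network$lower[[k]]),
         upper_bound = unname(network$upper[[k]]),
         gene_reaction_rule = "")
  })
  mets <- purrr::map(network$metabolites, function(m)
    list(id = m, name = m, compartment = "c"))
  doc <- list(id = network$id, version = "1",
              metabolites = mets, reactions = rx, genes = list())
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
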