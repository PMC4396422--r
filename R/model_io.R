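#' Read a stoichiometric model from SBML or JSON
#'
#' Reads SBML Level 3 (with `fbc` flux bounds where present) or the
#' package's JSON dialect (see [write_model()]) into a [stoich_model()].
#' Bounds absent from the file default to (-1000, 1000) for reversible and
#' (0, 1000) for irreversible reactions. Exchange reactions are normalized
#' to the convention "single extracellular metabolite, coefficient -1",
#' flipping direction (and bounds) where the file encodes them as pure
#' producers.
#'
#' @param path file to read.
#' @param format `"auto"` (by extension), `"sbml"`, or `"json"`.
#' @param blocked_reactions reaction ids whose bounds are zeroed at load
#'   time (e.g. a lesion such as the metB block applied to a published
#'   reconstruction).
#' @param biomass_reaction_id optional override when the file does not
#'   declare an objective.
#' @return a validated [stoich_model()].
#' @export
read_model <- function(path, format = c("auto", "sbml", "json"),
                       blocked_reactions = character(),
                       biomass_reaction_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  }
  model <- switch(format,
                  json = read_model_json(path),
                  sbml = read_model_sbml(path, biomass_reaction_id))
  for (id in blocked_reactions)
    model <- apply_knockout(model, id)
  bad <- validate_model(model)
  if (length(bad))
    stop("model in ", path, " failed validation: ",
         paste(bad, collapse = "; "))
  model
}

read_model_json <- function(path) {
  x <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                error = function(e)
                  stop("JSON parse failure in ", path, ": ",
                       conditionMessage(e), call. = FALSE))
  need <- c("species_id", "metabolites", "reactions",
            "biomass_reaction_id")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("JSON model ", path, " lacks element(s): ",
         paste(miss, collapse = ", "))
  mets <- do.call(rbind, lapply(x$metabolites, function(m)
    data.frame(id = m$id,
               name = if (is.null(m$name)) m$id else m$name,
               compartment = m$compartment,
               stringsAsFactors = FALSE)))
  stoich_model(species_id = x$species_id,
               metabolites = mets,
               reactions = x$reactions,
               biomass_reaction_id = x$biomass_reaction_id,
               coupled_secretions =
                 if (is.null(x$coupled_secretions)) list()
                 else x$coupled_secretions)
}

#' Write a stoichiometric model to the JSON dialect
#'
#' The dialect has top-level keys `species_id`, `metabolites`,
#' `reactions`, `biomass_reaction_id` and `coupled_secretions`; numbers
#' are written at full precision so that `read_model(write_model(m))`
#' reproduces `m` field by field.
#'
#' @param model a valid [stoich_model()].
#' @param path output file.
#' @param format only `"json"` is supported for writing.
#' @return invisibly, `path`.
#' @export
write_model <- function(model, path, format = "json") {
  format <- match.arg(format, "json")
  bad <- validate_model(model)
  if (length(bad))
    stop("refusing to write invalid model: ",
         paste(bad, collapse = "; "))
  rx <- lapply(unname(model$reactions), function(r) {
    list(id = r$id,
         stoichiometry = as.list(r$stoichiometry),
         lower_bound = r$lower_bound,
         upper_bound = r$upper_bound,
         is_exchange = isTRUE(r$is_exchange),
         exchanged_metabolite =
           if (isTRUE(r$is_exchange)) r$exchanged_metabolite else NULL)
  })
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i)
    list(id = model$metabolites$id[i],
         name = model$metabolites$name[i],
         compartment = model$metabolites$compartment[i]))
  out <- list(species_id = model$species_id,
              metabolites = mets,
              reactions = rx,
              biomass_reaction_id = model$biomass_reaction_id,
              coupled_secretions = model$coupled_secretions)
  json <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  ok <- tryCatch({
    writeLines(json, path)
    TRUE
  }, error = function(e)
    stop("cannot write model to ", path, ": ", conditionMessage(e),
         call. = FALSE))
  invisible(path)
}

## --- SBML level 3 (+fbc) import ------------------------------------------

read_model_sbml <- function(path, biomass_reaction_id = NULL) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e)
                    stop("SBML parse failure in ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  ns <- xml2::xml_ns(doc)
  model_node <- xml2::xml_find_first(doc, ".//*[local-name()='model']")
  if (is.na(model_node) || inherits(model_node, "xml_missing"))
    stop("SBML file ", path, " has no <model> element")

  lname <- function(node, what)
    xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", what))

  ## global parameters (fbc bound values)
  pars <- lname(model_node, "parameter")
  par_val <- stats::setNames(
    as.numeric(xml2::xml_attr(pars, "value")),
    xml2::xml_attr(pars, "id"))

  sp_nodes <- lname(model_node, "species")
  sp_id <- xml2::xml_attr(sp_nodes, "id")
  sp_comp <- xml2::xml_attr(sp_nodes, "compartment")
  sp_bc <- tolower(xml2::xml_attr(sp_nodes, "boundaryCondition")) %in% "true"
  sp_name <- xml2::xml_attr(sp_nodes, "name")
  sp_name[is.na(sp_name)] <- sp_id[is.na(sp_name)]
  extracellular <- sp_comp %in% c("e", "C_e", "extracellular", "ext",
                                  "e0", "Extra_organism") |
    grepl("extracell", sp_comp, ignore.case = TRUE)
  boundary_ids <- sp_id[sp_bc]

  rxn_nodes <- lname(model_node, "reaction")
  if (!length(rxn_nodes))
    stop("SBML file ", path, " defines no reactions")
  reactions <- lapply(rxn_nodes, function(rn) {
    id <- xml2::xml_attr(rn, "id")
    rev <- !(tolower(xml2::xml_attr(rn, "reversible")) %in% "false")
    refs <- function(side, sgn) {
      side_node <- xml2::xml_find_first(
        rn, sprintf("./*[local-name()='%s']", side))
      if (inherits(side_node, "xml_missing")) return(numeric())
      sr <- xml2::xml_find_all(side_node,
                               "./*[local-name()='speciesReference']")
      st <- as.numeric(xml2::xml_attr(sr, "stoichiometry"))
      st[is.na(st)] <- 1
      stats::setNames(sgn * st, xml2::xml_attr(sr, "species"))
    }
    stoich <- c(refs("listOfReactants", -1), refs("listOfProducts", 1))
    ## merge duplicated species, drop boundary species
    if (length(stoich)) {
      stoich <- tapply(stoich, names(stoich), sum)
      stoich <- stats::setNames(as.numeric(stoich), names(stoich))
      stoich <- stoich[!(names(stoich) %in% boundary_ids)]
      stoich <- stoich[abs(stoich) > 0]
    }
    lbid <- xml2::xml_attr(rn, "lowerFluxBound")
    ubid <- xml2::xml_attr(rn, "upperFluxBound")
    lb <- if (!is.na(lbid) && lbid %in% names(par_val)) par_val[[lbid]]
          else if (rev) -1000 else 0
    ub <- if (!is.na(ubid) && ubid %in% names(par_val)) par_val[[ubid]]
          else 1000
    list(id = id, stoichiometry = as.list(stoich),
         lower_bound = lb, upper_bound = ub)
  })

  ## normalize exchanges: single-metabolite reactions become coefficient -1
  reactions <- lapply(reactions, function(r) {
    st <- unlist(r$stoichiometry)
    if (length(st) == 1L) {
      if (st[[1L]] > 0) {      # written as producer; flip direction
        r$stoichiometry <- as.list(-st)
        lb <- r$lower_bound
        r$lower_bound <- -r$upper_bound
        r$upper_bound <- -lb
      } else if (abs(st[[1L]] + 1) > 1e-12) {
        r$stoichiometry <- as.list(st / abs(st[[1L]]))
      }
      r$is_exchange <- abs(unlist(r$stoichiometry)[[1L]] + 1) < 1e-12
    }
    r
  })

  used <- unique(unlist(lapply(reactions,
                               function(r) names(r$stoichiometry))))
  keep <- sp_id %in% used
  mets <- data.frame(id = sp_id[keep], name = sp_name[keep],
                     compartment = ifelse(extracellular[keep],
                                          "extracellular", "cytosol"),
                     stringsAsFactors = FALSE)
  ## any metabolite moved by an exchange is extracellular by definition
  ex_mets <- unlist(lapply(reactions, function(r)
    if (isTRUE(r$is_exchange)) names(r$stoichiometry)[1L]))
  mets$compartment[mets$id %in% ex_mets] <- "extracellular"
  mets$compartment[!(mets$id %in% ex_mets) &
                     mets$compartment == "extracellular"] <- "cytosol"

  if (is.null(biomass_reaction_id)) {
    obj <- xml2::xml_find_first(
      model_node, ".//*[local-name()='fluxObjective']")
    biomass_reaction_id <-
      if (!inherits(obj, "xml_missing"))
        xml2::xml_attr(obj, "reaction")
      else NA_character_
    if (is.na(biomass_reaction_id)) {
      rids <- vapply(reactions, `[[`, "", "id")
      hit <- grep("biomass", rids, ignore.case = TRUE, value = TRUE)
      if (!length(hit))
        stop("SBML file ", path, " declares no objective and no reaction",
             " id contains 'biomass'; supply biomass_reaction_id")
      biomass_reaction_id <- hit[1L]
    }
  }
  sbml_id <- xml2::xml_attr(model_node, "id")
  stoich_model(species_id = if (is.na(sbml_id)) basename(path)
               else sbml_id,
               metabolites = mets, reactions = reactions,
               biomass_reaction_id = biomass_reaction_id)
}
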