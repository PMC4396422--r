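#' Construct a stoichiometric metabolic model
#'
#' A `stoich_model` holds a species' metabolic network: metabolites with
#' compartments, reactions with stoichiometry and flux bounds, the biomass
#' reaction whose flux is the specific growth rate (1/h), and any
#' growth-coupled secretions (mmol secreted per gDW of new biomass).
#'
#' Sign conventions: stoichiometric coefficients are mmol per gDW with
#' negative values for consumption; an exchange reaction carries exactly one
#' extracellular metabolite with coefficient -1, so positive flux secretes
#' into the environment and negative flux takes up from it.
#'
#' @param species_id character scalar naming the species.
#' @param metabolites data.frame with columns `id`, `name`, `compartment`
#'   (`"extracellular"` or `"cytosol"`).
#' @param reactions list of reactions, each a list with elements `id`,
#'   `stoichiometry` (named numeric, names are metabolite ids),
#'   `lower_bound`, `upper_bound` (mmol/gDW/h; 1/h for the biomass
#'   reaction), and optionally `is_exchange` and `exchanged_metabolite`.
#'   Exchange status is inferred when not given.
#' @param biomass_reaction_id id of the biomass reaction.
#' @param coupled_secretions list of `list(metabolite_id=, rate=)` entries;
#'   each forces exchange flux `rate * mu` of that metabolite.
#' @param validate if `TRUE` (default) stop on any invariant violation.
#'
#' @return an object of class `stoich_model`.
#' @seealso [read_model()], [validate_model()], [apply_knockout()]
#' @export
stoich_model <- function(species_id, metabolites, reactions,
                         biomass_reaction_id,
                         coupled_secretions = list(), validate = TRUE) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  reactions <- lapply(reactions, function(r) {
    stoich <- unlist(r$stoichiometry)
    r$stoichiometry <- stats::setNames(as.numeric(stoich), names(stoich))
    if (is.null(r$lower_bound) || is.null(r$upper_bound)) {
      rev <- isTRUE(r$reversible)
      if (is.null(r$lower_bound))
        r$lower_bound <- if (rev) -1000 else 0
      if (is.null(r$upper_bound)) r$upper_bound <- 1000
    }
    r$lower_bound <- as.numeric(r$lower_bound)
    r$upper_bound <- as.numeric(r$upper_bound)
    if (is.null(r$is_exchange)) {
      one <- length(r$stoichiometry) == 1L
      r$is_exchange <- one && abs(r$stoichiometry[[1L]] + 1) < 1e-12
    }
    if (r$is_exchange && is.null(r$exchanged_metabolite))
      r$exchanged_metabolite <- names(r$stoichiometry)[1L]
    r
  })
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  m <- structure(list(species_id = species_id,
                      metabolites = metabolites,
                      reactions = reactions,
                      biomass_reaction_id = biomass_reaction_id,
                      coupled_secretions = coupled_secretions),
                 class = "stoich_model")
  if (validate) {
    bad <- validate_model(m)
    if (length(bad))
      stop("invalid model '", species_id, "': ",
           paste(bad, collapse = "; "))
  }
  m
}

#' Validate a stoichiometric model
#'
#' Checks the structural invariants of a [stoich_model()]: unique ids,
#' stoichiometry keys naming existing metabolites, `lower_bound <=
#' upper_bound`, existence of the biomass reaction, the exchange-reaction
#' sign convention (single extracellular metabolite with coefficient -1),
#' that extracellular metabolites are exactly those touched by exchange
#' reactions, and that coupled secretions reference exchangeable
#' metabolites with non-negative rates.
#'
#' @param model a [stoich_model()].
#' @return character vector of violation descriptions; empty when valid.
#' @export
validate_model <- function(model) {
  v <- character()
  met_ids <- model$metabolites$id
  if (anyDuplicated(met_ids))
    v <- c(v, paste("duplicated metabolite ids:",
                    paste(unique(met_ids[duplicated(met_ids)]),
                          collapse = ", ")))
  rxn_ids <- vapply(model$reactions, `[[`, "", "id")
  if (anyDuplicated(rxn_ids))
    v <- c(v, paste("duplicated reaction ids:",
                    paste(unique(rxn_ids[duplicated(rxn_ids)]),
                          collapse = ", ")))
  if (!length(model$reactions))
    v <- c(v, "model has no reactions")
  exch_mets <- character()
  for (r in model$reactions) {
    unknown <- setdiff(names(r$stoichiometry), met_ids)
    if (length(unknown))
      v <- c(v, paste0("reaction ", r$id, " references unknown metabolite",
                       if (length(unknown) > 1) "s", " ",
                       paste(unknown, collapse = ", ")))
    if (r$lower_bound > r$upper_bound)
      v <- c(v, paste0("reaction ", r$id,
                       ": lower_bound > upper_bound"))
    if (isTRUE(r$is_exchange)) {
      if (length(r$stoichiometry) != 1L ||
          abs(r$stoichiometry[[1L]] + 1) > 1e-12) {
        v <- c(v, paste0("exchange reaction ", r$id,
                         " must have exactly one metabolite with",
                         " coefficient -1"))
      } else {
        met <- names(r$stoichiometry)[1L]
        exch_mets <- c(exch_mets, met)
        comp <- model$metabolites$compartment[match(met, met_ids)]
        if (!is.na(comp) && comp != "extracellular")
          v <- c(v, paste0("exchange reaction ", r$id,
                           " touches non-extracellular metabolite ", met))
      }
    }
  }
  extra <- model$metabolites$id[
    model$metabolites$compartment == "extracellular"]
  orphan <- setdiff(extra, exch_mets)
  if (length(orphan))
    v <- c(v, paste("extracellular metabolites without an exchange",
                    "reaction:", paste(orphan, collapse = ", ")))
  if (!model$biomass_reaction_id %in% rxn_ids)
    v <- c(v, paste0("biomass reaction '", model$biomass_reaction_id,
                     "' not found"))
  for (cs in model$coupled_secretions) {
    if (is.null(cs$rate) || cs$rate < 0)
      v <- c(v, paste0("coupled secretion of ", cs$metabolite_id,
                       ": rate must be >= 0"))
    if (!cs$metabolite_id %in% exch_mets)
      v <- c(v, paste0("coupled secretion metabolite ", cs$metabolite_id,
                       " has no exchange reaction"))
  }
  v
}

#' Knock out one reaction
#'
#' Returns a copy of the model in which the named reaction's flux bounds
#' are set to zero (the reaction is retained in the network), the
#' in-silico equivalent of a loss-of-function mutation. The input model is
#' not modified.
#'
#' @param model a [stoich_model()].
#' @param reaction_id id of the reaction to disable.
#' @return a new `stoich_model`.
#' @export
apply_knockout <- function(model, reaction_id) {
  if (!reaction_id %in% names(model$reactions))
    stop("unknown reaction id: ", reaction_id)
  model$reactions[[reaction_id]]$lower_bound <- 0
  model$reactions[[reaction_id]]$upper_bound <- 0
  model
}

#' Enumerate single-reaction knockout mutants
#'
#' One mutant per reaction, in model order, mirroring a systematic
#' reaction-knockout library.
#'
#' @param model a [stoich_model()].
#' @return character vector of reaction ids, one per mutant.
#' @export
enumerate_knockouts <- function(model) {
  bad <- validate_model(model)
  if (length(bad)) stop("invalid model: ", paste(bad, collapse = "; "))
  unname(vapply(model$reactions, `[[`, "", "id"))
}

#' Attach a growth-coupled secretion to a model
#'
#' Forces the exchange flux of `metabolite_id` to equal `rate * mu` in
#' every FBA solve, i.e. `rate` mmol are secreted per gDW of new biomass.
#' This is how constitutive metabolite excretion (e.g. evolved methionine
#' secretion) is encoded without editing the biomass stoichiometry.
#'
#' @param model a [stoich_model()].
#' @param metabolite_id extracellular metabolite with an exchange reaction.
#' @param rate mmol secreted per gDW of new biomass; must be >= 0.
#' @return the modified `stoich_model`.
#' @export
add_coupled_secretion <- function(model, metabolite_id, rate) {
  model$coupled_secretions <- c(model$coupled_secretions,
                                list(list(metabolite_id = metabolite_id,
                                          rate = rate)))
  bad <- validate_model(model)
  if (length(bad)) stop(paste(bad, collapse = "; "))
  model
}

## named lists of per-reaction bounds, with overrides replacing stored ones
model_bounds <- function(model, overrides = NULL) {
  lb <- vapply(model$reactions, `[[`, 0, "lower_bound")
  ub <- vapply(model$reactions, `[[`, 0, "upper_bound")
  if (!is.null(overrides) && length(overrides)) {
    unknown <- setdiff(names(overrides), names(model$reactions))
    if (length(unknown))
      stop("bounds override for unknown reaction: ",
           paste(unknown, collapse = ", "))
    for (id in names(overrides)) {
      o <- overrides[[id]]
      if (o[1] > o[2]) stop("override for ", id, ": lower > upper")
      lb[id] <- o[1]
      ub[id] <- o[2]
    }
  }
  list(lb = lb, ub = ub)
}

## stoichiometric matrix (metabolites x reactions); augmented = TRUE adds
## the coupled-secretion rate at (metabolite row, biomass column) so that
## mass balance enforces v_exchange = rate * mu
stoich_matrix <- function(model, augmented = FALSE) {
  met_ids <- model$metabolites$id
  rxn_ids <- names(model$reactions)
  S <- matrix(0, length(met_ids), length(rxn_ids),
              dimnames = list(met_ids, rxn_ids))
  for (r in model$reactions)
    S[names(r$stoichiometry), r$id] <- r$stoichiometry
  if (augmented) {
    for (cs in model$coupled_secretions)
      S[cs$metabolite_id, model$biomass_reaction_id] <-
        S[cs$metabolite_id, model$biomass_reaction_id] + cs$rate
  }
  S
}

## ids of exchange reactions and the metabolites they move
exchange_table <- function(model) {
  ex <- Filter(function(r) isTRUE(r$is_exchange), model$reactions)
  data.frame(reaction_id = vapply(ex, `[[`, "", "id"),
             metabolite_id = vapply(ex, `[[`, "", "exchanged_metabolite"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Model content checksum
#'
#' MD5 over the model's canonical JSON serialization, recorded in outputs
#' so that results can be traced to exact model content.
#'
#' @param model a [stoich_model()].
#' @return character MD5 digest.
#' @export
model_checksum <- function(model) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  write_model(model, tf)
  unname(tools::md5sum(tf))
}

#' @export
print.stoich_model <- function(x, ...) {
  n_ex <- sum(vapply(x$reactions, function(r) isTRUE(r$is_exchange), TRUE))
  cat("Stoichiometric model '", x$species_id, "': ",
      length(x$reactions), " reactions (", n_ex, " exchanges), ",
      nrow(x$metabolites), " metabolites\n", sep = "")
  cat("  biomass reaction:", x$biomass_reaction_id, "\n")
  for (cs in x$coupled_secretions)
    cat("  coupled secretion:", cs$metabolite_id, "at", cs$rate,
        "mmol/gDW new biomass\n")
  invisible(x)
}
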