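#' Parameters of the synthetic cross-feeding model pair
#'
#' Stoichiometric yields of the two hand-solvable toy models generated by
#' [make_toy_pair()]. The defaults encode the three mechanisms that
#' structure the real consortium: (i) the carbon consumer ("E-like") is a
#' methionine auxotroph, (ii) it excretes reduced carbon (acetate) that
#' the partner ("S-like") respires, and (iii) biomass per unit oxygen is
#' higher in the E-like model (aerobic sugar catabolism plus a
#' fermentation fallback) than in the acetate respirer, the efficiency
#' asymmetry that shapes competition for oxygen.
#'
#' Both models carry a non-growth-associated ATP maintenance demand
#' (`atp_maintenance_e`, `atp_maintenance_s`, mmol ATP/gDW/h as a forced
#' lower bound). Maintenance makes resting cells catabolize carbon, so a
#' lactose-fed E-like cell secretes acetate even before it can grow —
#' the flux that nucleates the mutualism from a methionine-free medium.
#' The E-like demand must exceed the S-like demand for that byproduct
#' stream to outrun the partner's own maintenance burn.
#'
#' @param atp_per_lactose_aerobic ATP yield of aerobic lactose catabolism.
#' @param atp_per_lactose_fermentative ATP yield of fermentation.
#' @param acetate_per_lactose acetate secreted per lactose catabolized.
#' @param o2_per_lactose oxygen consumed per lactose (aerobic route).
#' @param atp_per_acetate ATP yield of acetate respiration (S-like).
#' @param o2_per_acetate oxygen consumed per acetate respired.
#' @param atp_per_biomass mmol ATP per gDW of new biomass (both species).
#' @param met_per_biomass mmol methionine per gDW of new E-like biomass.
#' @param met_secretion_coupling mmol methionine secreted by the S-like
#'   model per gDW of new biomass.
#' @param atp_maintenance_e,atp_maintenance_s forced maintenance ATP
#'   demand, mmol/gDW/h.
#' @return a list of class `toy_params`.
#' @export
toy_params <- function(atp_per_lactose_aerobic = 6,
                       atp_per_lactose_fermentative = 2,
                       acetate_per_lactose = 2,
                       o2_per_lactose = 2,
                       atp_per_acetate = 3,
                       o2_per_acetate = 2,
                       atp_per_biomass = 10,
                       met_per_biomass = 0.15,
                       met_secretion_coupling = 0.5,
                       atp_maintenance_e = 2,
                       atp_maintenance_s = 1) {
  p <- list(atp_per_lactose_aerobic = atp_per_lactose_aerobic,
            atp_per_lactose_fermentative = atp_per_lactose_fermentative,
            acetate_per_lactose = acetate_per_lactose,
            o2_per_lactose = o2_per_lactose,
            atp_per_acetate = atp_per_acetate,
            o2_per_acetate = o2_per_acetate,
            atp_per_biomass = atp_per_biomass,
            met_per_biomass = met_per_biomass,
            met_secretion_coupling = met_secretion_coupling,
            atp_maintenance_e = atp_maintenance_e,
            atp_maintenance_s = atp_maintenance_s)
  if (any(unlist(p) <= 0))
    stop("all toy parameters must be positive")
  if (atp_per_lactose_aerobic <= atp_per_lactose_fermentative)
    stop("aerobic ATP yield must exceed the fermentative yield")
  ## gDW per mmol O2: E-like aerobic vs S-like respiration
  eff_e <- atp_per_lactose_aerobic / o2_per_lactose / atp_per_biomass
  eff_s <- atp_per_acetate / o2_per_acetate / atp_per_biomass
  if (eff_e <= eff_s)
    stop("E-like biomass per unit O2 must exceed the S-like value")
  structure(p, class = "toy_params")
}

rxn <- function(id, stoich, lb = -1000, ub = 1000) {
  list(id = id, stoichiometry = as.list(stoich),
       lower_bound = lb, upper_bound = ub)
}

#' Generate the synthetic cross-feeding model pair
#'
#' Builds the two small stoichiometric models used as a self-contained
#' stand-in for the published genome-scale pair. The E-like model (12
#' reactions, 10 metabolites) takes up lactose, catabolizes it
#' aerobically (`lcts + 2 O2 -> 6 ATP + 2 ac`) or by fermentation
#' (`lcts -> 2 ATP + 2 ac`), secretes acetate, and needs external
#' methionine for biomass (the metB-lesion analogue: it has no methionine
#' synthesis). The S-like model (8 reactions, 7 metabolites) respires
#' acetate (`ac + 2 O2 -> 3 ATP`) and carries a growth-coupled methionine
#' secretion. Both have a forced ATP maintenance reaction.
#'
#' @param params a [toy_params()].
#' @return list with elements `E` and `S`, both [stoich_model()]s.
#' @export
make_toy_pair <- function(params = toy_params()) {
  if (!inherits(params, "toy_params")) params <- do.call(toy_params, params)
  p <- params

  mets_e <- data.frame(
    id = c("lcts_e", "o2_e", "ac_e", "met_e",
           "lcts_c", "o2_c", "ac_c", "met_c", "atp_c", "adp_c"),
    name = c("lactose (external)", "oxygen (external)",
             "acetate (external)", "methionine (external)",
             "lactose", "oxygen", "acetate", "methionine",
             "ATP", "ADP"),
    compartment = c(rep("extracellular", 4), rep("cytosol", 6)),
    stringsAsFactors = FALSE)
  rx_e <- list(
    rxn("EX_lcts", c(lcts_e = -1)),
    rxn("EX_o2",   c(o2_e = -1)),
    rxn("EX_ac",   c(ac_e = -1)),
    rxn("EX_met",  c(met_e = -1)),
    rxn("T_lcts",  c(lcts_e = -1, lcts_c = 1)),
    rxn("T_o2",    c(o2_e = -1, o2_c = 1)),
    rxn("T_ac",    c(ac_c = -1, ac_e = 1)),
    rxn("T_met",   c(met_e = -1, met_c = 1)),
    rxn("AERO", c(lcts_c = -1, o2_c = -p$o2_per_lactose,
                  adp_c = -p$atp_per_lactose_aerobic,
                  atp_c = p$atp_per_lactose_aerobic,
                  ac_c = p$acetate_per_lactose), lb = 0),
    rxn("FERM", c(lcts_c = -1,
                  adp_c = -p$atp_per_lactose_fermentative,
                  atp_c = p$atp_per_lactose_fermentative,
                  ac_c = p$acetate_per_lactose), lb = 0),
    rxn("ATPM", c(atp_c = -1, adp_c = 1), lb = p$atp_maintenance_e),
    rxn("BIOMASS", c(atp_c = -p$atp_per_biomass,
                     met_c = -p$met_per_biomass,
                     adp_c = p$atp_per_biomass), lb = 0))
  E <- stoich_model("toy_E", mets_e, rx_e, "BIOMASS")

  mets_s <- data.frame(
    id = c("ac_e", "o2_e", "met_e", "ac_c", "o2_c", "atp_c", "adp_c"),
    name = c("acetate (external)", "oxygen (external)",
             "methionine (external)", "acetate", "oxygen", "ATP", "ADP"),
    compartment = c(rep("extracellular", 3), rep("cytosol", 4)),
    stringsAsFactors = FALSE)
  rx_s <- list(
    rxn("EX_ac",  c(ac_e = -1)),
    rxn("EX_o2",  c(o2_e = -1)),
    rxn("EX_met", c(met_e = -1), lb = 0),
    rxn("T_ac",   c(ac_e = -1, ac_c = 1)),
    rxn("T_o2",   c(o2_e = -1, o2_c = 1)),
    rxn("RESP", c(ac_c = -1, o2_c = -p$o2_per_acetate,
                  adp_c = -p$atp_per_acetate,
                  atp_c = p$atp_per_acetate), lb = 0),
    rxn("ATPM", c(atp_c = -1, adp_c = 1), lb = p$atp_maintenance_s),
    rxn("BIOMASS", c(atp_c = -p$atp_per_biomass,
                     adp_c = p$atp_per_biomass), lb = 0))
  S <- stoich_model("toy_S", mets_s, rx_s, "BIOMASS",
                    coupled_secretions = list(
                      list(metabolite_id = "met_e",
                           rate = p$met_secretion_coupling)))
  list(E = E, S = S)
}

#' Standard screening environments
#'
#' The three media of the screen, using the toy metabolite ids. The
#' cooperative medium makes the interaction obligate: lactose (1.2e-5
#' mmol at scale 1) is the limiting resource, oxygen is finite (6.2e-5
#' mmol), and acetate and methionine start absent so each species depends
#' on its partner. Competition (and monoculture essentiality testing)
#' adds unlimited acetate and methionine, making oxygen the contested
#' resource.
#'
#' @param condition `"cooperation"`, `"competition"` or `"monoculture"`
#'   (monoculture uses the competition medium).
#' @param scale positive multiplier on the finite pool amounts.
#' @param box_edge simulation box edge, mm.
#' @return a [community_env()].
#' @export
make_environment <- function(condition = c("cooperation", "competition",
                                           "monoculture"),
                             scale = 1, box_edge = 0.5) {
  condition <- match.arg(condition)
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop("scale must be a positive number")
  pools <- c(lcts_e = 1.2e-5 * scale, o2_e = 6.2e-5 * scale,
             ac_e = 0, met_e = 0)
  unlimited <- if (condition == "cooperation") character()
               else c("ac_e", "met_e")
  community_env(pools, box_edge = box_edge, unlimited = unlimited)
}
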