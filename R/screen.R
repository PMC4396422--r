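#' Configuration of a knockout screen
#'
#' @param focal_species `"E"` or `"S"`: which community member the focal
#'   (mutated) model represents; metrics are always reported in terms of
#'   the E-like and S-like species.
#' @param conditions subset of `"cooperation"`, `"competition"`,
#'   `"monoculture"`. Co-culture conditions produce one record per mutant;
#'   monoculture (the focal species alone in the competition medium, which
#'   supplies everything the partner would) only feeds the
#'   `essential_monoculture` flag.
#' @param essentiality_threshold a mutant growing less than this fraction
#'   of the unperturbed biomass gain is essential (default 0.02).
#' @param substantive_threshold inclusive deviation of a normalized
#'   metric from 1 that counts as a substantive effect (default 0.01).
#' @param simulation a [sim_config()].
#' @param environments optional named list of [community_env()]s keyed by
#'   condition, overriding [make_environment()] defaults (needed when the
#'   models do not use the toy metabolite ids).
#' @param env_scale multiplier passed to [make_environment()].
#' @param inoculum starting biomass per species, gDW.
#' @param r2_include_essential include essential mutants in the
#'   cross-condition effect correlation (default `FALSE`).
#' @return a list of class `screen_config`.
#' @export
screen_config <- function(focal_species = c("E", "S"),
                          conditions = c("cooperation", "competition",
                                         "monoculture"),
                          essentiality_threshold = 0.02,
                          substantive_threshold = 0.01,
                          simulation = sim_config(),
                          environments = NULL,
                          env_scale = 1,
                          inoculum = 3e-7,
                          r2_include_essential = FALSE) {
  focal_species <- match.arg(focal_species)
  conditions <- match.arg(conditions, several.ok = TRUE)
  for (thr in c(essentiality_threshold, substantive_threshold))
    if (thr <= 0 || thr >= 1) stop("thresholds must lie in (0, 1)")
  structure(list(focal_species = focal_species, conditions = conditions,
                 essentiality_threshold = essentiality_threshold,
                 substantive_threshold = substantive_threshold,
                 simulation = simulation, environments = environments,
                 env_scale = env_scale, inoculum = inoculum,
                 r2_include_essential = r2_include_essential),
            class = "screen_config")
}

#' Essentiality call from trajectories
#'
#' A knockout is essential in a condition when the mutant's focal biomass
#' gain over the horizon is less than `threshold` times the unperturbed
#' gain. When the unperturbed strain itself fails to gain biomass, the
#' mutant is essential iff it also fails to gain.
#'
#' @param mutant_traj,unperturbed_traj `community_sim` trajectories from
#'   the same condition and horizon.
#' @param threshold fraction of unperturbed gain (default 0.02).
#' @param species species id or index of the focal species (default
#'   first).
#' @return logical flag.
#' @export
call_essential <- function(mutant_traj, unperturbed_traj,
                           threshold = 0.02, species = 1L) {
  if (length(mutant_traj$times) != length(unperturbed_traj$times) ||
      max(mutant_traj$times) != max(unperturbed_traj$times))
    stop("trajectories have different horizons")
  gain <- function(tr) {
    B <- tr$biomass[, species]
    B[length(B)] - B[1L]
  }
  gm <- gain(mutant_traj)
  gu <- gain(unperturbed_traj)
  if (gu <= 0) return(gm <= 0)
  (gm / gu) < threshold
}

## final biomasses labelled as (E, S) given which model is focal
as_es <- function(focal_final, partner_final, focal_species) {
  if (focal_species == "E")
    c(E = focal_final, S = partner_final)
  else
    c(E = partner_final, S = focal_final)
}

screen_environment <- function(condition, config) {
  if (!is.null(config$environments) &&
      condition %in% names(config$environments))
    return(config$environments[[condition]])
  make_environment(condition, scale = config$env_scale)
}

#' Run a systematic knockout screen
#'
#' Simulates the unperturbed focal/partner pair once per co-culture
#' condition, then every single-reaction knockout mutant of the focal
#' model paired with the unperturbed partner, and (when requested) every
#' mutant alone in the competition medium for monoculture essentiality.
#' Each record carries the final biomasses, the community metrics
#' ([ecd()], [normalized_percent_e()], [normalized_bm()]) relative to the
#' same condition's unperturbed outcome, and essentiality flags. Mutants
#' are independent: the run is deterministic and order-invariant.
#'
#' @param focal [stoich_model()] whose reactions are knocked out.
#' @param partner [stoich_model()] of the unperturbed partner.
#' @param config a [screen_config()].
#' @return an object of class `knockout_screen`: list with `records`
#'   (data.frame, one row per mutant x co-culture condition),
#'   `unperturbed` (data.frame per condition), `focal_species`,
#'   `config`, `provenance`.
#' @export
run_screen <- function(focal, partner, config = screen_config()) {
  for (m in list(focal, partner)) {
    bad <- validate_model(m)
    if (length(bad)) stop("invalid model '", m$species_id, "': ",
                          paste(bad, collapse = "; "))
  }
  if (!length(config$conditions)) stop("no conditions requested")
  cocult <- intersect(config$conditions,
                      c("cooperation", "competition"))
  do_mono <- "monoculture" %in% config$conditions
  mutants <- enumerate_knockouts(focal)
  simc <- config$simulation

  sim_pair <- function(fmodel, env)
    simulate_community(list(fmodel, partner), env, simc,
                       inoculum = config$inoculum)
  sim_alone <- function(fmodel, env)
    simulate_community(list(fmodel), env, simc,
                       inoculum = config$inoculum)

  unp_traj <- list()
  unp <- NULL
  for (cond in cocult) {
    env <- screen_environment(cond, config)
    tr <- sim_pair(focal, env)
    unp_traj[[cond]] <- tr
    es <- as_es(final_biomass(tr, 1L), final_biomass(tr, 2L),
                config$focal_species)
    unp <- rbind(unp, data.frame(condition = cond,
                                 E_final = es[["E"]],
                                 S_final = es[["S"]],
                                 stringsAsFactors = FALSE))
  }
  mono_env <- screen_environment("monoculture", config)
  mono_unp <- if (do_mono) sim_alone(focal, mono_env) else NULL

  ess_mono <- stats::setNames(rep(NA, length(mutants)), mutants)
  ess_cond <- list()
  rec_rows <- vector("list", length(mutants) * length(cocult))
  cond_traj_final <- list()
  for (cond in cocult)
    ess_cond[[cond]] <- stats::setNames(rep(NA, length(mutants)),
                                        mutants)

  k <- 0L
  for (rid in mutants) {
    mut <- apply_knockout(focal, rid)
    if (do_mono) {
      tr_m <- withCallingHandlers(
        sim_alone(mut, mono_env),
        error = function(e)
          stop("monoculture simulation failed for knockout '", rid,
               "': ", conditionMessage(e), call. = FALSE))
      ess_mono[rid] <- call_essential(tr_m, mono_unp,
                                      config$essentiality_threshold)
    }
    for (cond in cocult) {
      tr <- tryCatch(
        sim_pair(mut, screen_environment(cond, config)),
        error = function(e)
          stop("simulation failed for knockout '", rid, "' under ",
               cond, ": ", conditionMessage(e), call. = FALSE))
      ess_cond[[cond]][rid] <-
        call_essential(tr, unp_traj[[cond]],
                       config$essentiality_threshold)
      es <- as_es(final_biomass(tr, 1L), final_biomass(tr, 2L),
                  config$focal_species)
      eu <- unp[unp$condition == cond, ]
      pctE <- tryCatch(normalized_percent_e(es[["E"]], es[["S"]],
                                            eu$E_final, eu$S_final),
                       error = function(e) NA_real_)
      k <- k + 1L
      rec_rows[[k]] <- data.frame(
        reaction_id = rid, condition = cond,
        E_final = es[["E"]], S_final = es[["S"]],
        ECD = ecd(es[["E"]], es[["S"]], eu$E_final, eu$S_final),
        pctE_norm = pctE,
        BM_norm = normalized_bm(es[["E"]], es[["S"]],
                                eu$E_final, eu$S_final),
        stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rec_rows[seq_len(k)])
  if (!is.null(records)) {
    records$essential_monoculture <- unname(ess_mono[records$reaction_id])
    records$essential_cooperation <-
      if ("cooperation" %in% cocult)
        unname(ess_cond[["cooperation"]][records$reaction_id]) else NA
    records$essential_competition <-
      if ("competition" %in% cocult)
        unname(ess_cond[["competition"]][records$reaction_id]) else NA
  }
  provenance <- c(focal_species = config$focal_species,
                  focal_model = focal$species_id,
                  focal_checksum = model_checksum(focal),
                  partner_model = partner$species_id,
                  partner_checksum = model_checksum(partner),
                  conditions = paste(config$conditions, collapse = ","),
                  essentiality_threshold =
                    format(config$essentiality_threshold),
                  substantive_threshold =
                    format(config$substantive_threshold),
                  dt = format(simc$dt), duration = format(simc$duration),
                  Km = format(simc$Km), Vmax = format(simc$Vmax),
                  death_rate = format(simc$death_rate),
                  inoculum = format(config$inoculum))
  structure(list(records = records, unperturbed = unp,
                 essential_monoculture = ess_mono,
                 focal_species = config$focal_species,
                 config = config, provenance = provenance),
            class = "knockout_screen")
}

#' @export
print.knockout_screen <- function(x, ...) {
  nmut <- length(unique(x$records$reaction_id))
  cat("Knockout screen of", x$provenance[["focal_model"]],
      sprintf("(focal %s): %d mutants x %s\n", x$focal_species, nmut,
              paste(unique(x$records$condition), collapse = " + ")))
  if (!is.null(x$unperturbed))
    for (i in seq_len(nrow(x$unperturbed)))
      cat(sprintf("  unperturbed %-12s E = %.4g, S = %.4g gDW\n",
                  x$unperturbed$condition[i], x$unperturbed$E_final[i],
                  x$unperturbed$S_final[i]))
  ess <- x$records$essential_monoculture
  if (any(!is.na(ess)))
    cat("  essential in monoculture:",
        sum(x$essential_monoculture, na.rm = TRUE), "of",
        length(x$essential_monoculture), "reactions\n")
  invisible(x)
}

#' @export
as.data.frame.knockout_screen <- function(x, ...) x$records

#' Write screen records as TSV
#'
#' One row per (mutant, condition) with a `#`-prefixed provenance header
#' (model checksums, parameter echo, unperturbed outcomes).
#'
#' @param screen a `knockout_screen`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_screen <- function(screen, path) {
  con <- file(path, "w")
  on.exit(close(con))
  pv <- screen$provenance
  for (i in seq_along(pv))
    writeLines(paste0("# ", names(pv)[i], ": ", pv[[i]]), con)
  for (i in seq_len(nrow(screen$unperturbed)))
    writeLines(sprintf("# unperturbed_%s: E=%.12g S=%.12g",
                       screen$unperturbed$condition[i],
                       screen$unperturbed$E_final[i],
                       screen$unperturbed$S_final[i]), con)
  df <- screen$records
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], signif, digits = 12)
  utils::write.table(df, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read screen records written by [write_screen()]
#'
#' Rebuilds a `knockout_screen` object (records, unperturbed outcomes and
#' provenance) from its TSV serialization, sufficient for
#' [summarize_screen()].
#'
#' @param path TSV written by [write_screen()].
#' @return a `knockout_screen`.
#' @export
read_screen <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  kv <- sub("^# ([^:]+): (.*)$", "\\1\t\\2", hdr)
  keys <- vapply(strsplit(kv, "\t"), `[`, "", 1L)
  vals <- vapply(strsplit(kv, "\t"), `[`, "", 2L)
  unp <- NULL
  for (i in grep("^unperturbed_", keys)) {
    cond <- sub("^unperturbed_", "", keys[i])
    m <- regmatches(vals[i],
                    regexec("E=([-0-9.eE+]+) S=([-0-9.eE+]+)", vals[i]))[[1]]
    unp <- rbind(unp, data.frame(condition = cond,
                                 E_final = as.numeric(m[2]),
                                 S_final = as.numeric(m[3]),
                                 stringsAsFactors = FALSE))
  }
  records <- utils::read.delim(textConnection(
    lines[!grepl("^# ", lines)]), stringsAsFactors = FALSE)
  ess <- tapply(records$essential_monoculture, records$reaction_id,
                `[`, 1L)
  prov <- stats::setNames(vals[!grepl("^unperturbed_", keys)],
                          keys[!grepl("^unperturbed_", keys)])
  structure(list(records = records, unperturbed = unp,
                 essential_monoculture = ess,
                 focal_species = prov[["focal_species"]],
                 config = NULL, provenance = prov),
            class = "knockout_screen")
}
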