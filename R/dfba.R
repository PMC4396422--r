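#' Shared extracellular environment
#'
#' Metabolite pools (mmol) in a fixed, well-mixed volume. Metabolites
#' listed in `unlimited` behave as an inexhaustible reservoir: uptake is
#' saturated and the pool is never decremented.
#'
#' @param pools named numeric vector of amounts in mmol, keyed by
#'   extracellular metabolite id; all finite amounts must be >= 0.
#' @param box_edge edge length of the cubic simulation box, mm. The
#'   default 0.5 mm gives a volume of 1.25e-7 L for converting pool
#'   amounts to concentrations.
#' @param unlimited character vector of metabolite ids held saturating.
#' @return an object of class `community_env`.
#' @export
community_env <- function(pools, box_edge = 0.5, unlimited = character()) {
  pools <- unlist(pools)
  if (any(!is.finite(pools)) || any(pools < 0))
    stop("finite pool amounts must be >= 0")
  if (box_edge <= 0) stop("box_edge must be > 0")
  structure(list(pools = pools,
                 volume = box_edge^3 * 1e-6,  # mm^3 -> L
                 box_edge = box_edge,
                 unlimited = unlimited),
            class = "community_env")
}

#' @export
print.community_env <- function(x, ...) {
  cat(sprintf("Environment: %.4g L well-mixed box (%g mm edge)\n",
              x$volume, x$box_edge))
  for (m in names(x$pools))
    cat(sprintf("  %-10s %.4g mmol%s\n", m, x$pools[[m]],
                if (m %in% x$unlimited) " (unlimited)" else ""))
  for (m in setdiff(x$unlimited, names(x$pools)))
    cat(sprintf("  %-10s (unlimited)\n", m))
  invisible(x)
}

#' Simulation configuration for community dFBA
#'
#' @param dt time step, h.
#' @param duration horizon, h; must be a positive multiple of `dt`.
#' @param Km Michaelis-Menten half-saturation concentration, micromolar.
#' @param Vmax maximal uptake flux, mmol/gDW/h.
#' @param death_rate first-order biomass death rate, 1/h, applied every
#'   step regardless of growth.
#' @param rescale_iterations maximal number of uptake-rescaling rounds
#'   when species jointly overdraw a finite pool in one step.
#' @param tolerance numeric tolerance for clamping near-zero pools.
#' @param tie_break FBA tie-break, see [solve_fba()].
#' @param update_order `"simultaneous"` (deterministic, default): all
#'   species see the same environment snapshot and pools are updated once
#'   per step; `"random"`: species are updated sequentially in a seeded
#'   random order each step, for comparison with platforms that randomize
#'   calculation order.
#' @param seed integer seed, used only by `update_order = "random"`.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.1, duration = 10, Km = 10, Vmax = 10,
                       death_rate = 0.01, rescale_iterations = 10,
                       tolerance = 1e-15,
                       tie_break = c("flux_min", "none"),
                       update_order = c("simultaneous", "random"),
                       seed = 1L) {
  tie_break <- match.arg(tie_break)
  update_order <- match.arg(update_order)
  if (dt <= 0) stop("dt must be > 0")
  nstep <- duration / dt
  if (duration <= 0 || abs(nstep - round(nstep)) > 1e-9)
    stop("duration must be a positive multiple of dt")
  if (Km < 0 || Vmax < 0 || death_rate < 0)
    stop("Km, Vmax and death_rate must be >= 0")
  structure(list(dt = dt, duration = duration, Km = Km, Vmax = Vmax,
                 death_rate = death_rate,
                 rescale_iterations = rescale_iterations,
                 tolerance = tolerance, tie_break = tie_break,
                 update_order = update_order, seed = as.integer(seed)),
            class = "sim_config")
}

#' Michaelis-Menten uptake bound
#'
#' Maximal uptake flux offered by a pool: `Vmax * c / (Km + c)` with
#' concentration `c = amount / volume`. Unlimited metabolites return
#' `Vmax` (saturation).
#'
#' @param pool_amount amount in mmol (ignored for unlimited metabolites).
#' @param env a [community_env()].
#' @param config a [sim_config()].
#' @param metabolite_id optional id, used to recognize unlimited pools.
#' @return maximal uptake flux, mmol/gDW/h.
#' @export
uptake_bound <- function(pool_amount, env, config, metabolite_id = NULL) {
  if (!is.null(metabolite_id) && metabolite_id %in% env$unlimited)
    return(config$Vmax)
  conc <- max(pool_amount, 0) / env$volume       # mmol/L
  km <- config$Km / 1000                         # uM -> mmol/L
  if (conc <= 0) return(0)
  config$Vmax * conc / (km + conc)
}

## solve one species against an environment snapshot; cap[] imposes
## additional per-metabolite uptake ceilings (overdraw allocation)
species_fba <- function(model, env, config, cap = NULL) {
  ext <- exchange_table(model)
  overrides <- list()
  for (i in seq_len(nrow(ext))) {
    met <- ext$metabolite_id[i]
    rid <- ext$reaction_id[i]
    amt <- if (met %in% names(env$pools)) env$pools[[met]] else 0
    ub_take <- uptake_bound(amt, env, config, metabolite_id = met)
    if (!is.null(cap) && met %in% names(cap) &&
        !(met %in% env$unlimited))
      ub_take <- min(ub_take, cap[[met]])
    r <- model$reactions[[rid]]
    lo <- max(r$lower_bound, -ub_take)
    overrides[[rid]] <- c(min(lo, r$upper_bound), r$upper_bound)
  }
  solve_fba(model, overrides, tie_break = config$tie_break)
}

## exchange fluxes of a solution as a named vector keyed by metabolite
exchange_fluxes <- function(model, sol) {
  ext <- exchange_table(model)
  if (!length(sol$fluxes))
    return(stats::setNames(numeric(nrow(ext)), ext$metabolite_id))
  stats::setNames(as.numeric(sol$fluxes[ext$reaction_id]),
                  ext$metabolite_id)
}

#' Advance a community by one time step
#'
#' All species solve their FBA against the same environment snapshot
#' (Michaelis-Menten uptake bounds from the shared pools). If the joint
#' requested drawdown of a finite pool exceeds its amount, the offending
#' pool's uptake bounds are rescaled proportionally and all species are
#' re-solved, up to `config$rescale_iterations` times. Biomass then
#' follows the forward-Euler update `B * (1 + (mu - d) * dt)` and pools
#' receive `sum_s v_ex,s * B_s * dt`; unlimited pools are unchanged.
#'
#' @param states list of species states, each `list(model=, biomass=)`.
#' @param env a [community_env()].
#' @param config a [sim_config()].
#' @return list with `states`, `env`, `mu` (per-species growth rates) and
#'   `exchange` (per-species exchange flux vectors).
#' @export
step_community <- function(states, env, config) {
  ns <- length(states)
  B <- vapply(states, `[[`, 0, "biomass")
  caps <- replicate(ns, NULL, simplify = FALSE)
  sols <- NULL
  for (it in seq_len(max(1L, config$rescale_iterations))) {
    sols <- lapply(seq_len(ns), function(si)
      species_fba(states[[si]]$model, env, config, caps[[si]]))
    req <- lapply(seq_len(ns), function(si) {
      exf <- exchange_fluxes(states[[si]]$model, sols[[si]])
      -pmin(exf, 0)                       # uptake flux, mmol/gDW/h
    })
    draw <- stats::setNames(numeric(length(env$pools)), names(env$pools))
    for (si in seq_len(ns)) {
      take <- req[[si]] * B[si] * config$dt
      hit <- intersect(names(take), names(draw))
      draw[hit] <- draw[hit] + take[hit]
    }
    limited <- setdiff(names(env$pools), env$unlimited)
    over <- limited[draw[limited] >
                      env$pools[limited] * (1 + 1e-9) + 1e-18]
    if (!length(over)) break
    if (it == max(1L, config$rescale_iterations))
      stop("pool overdraw persists after ", config$rescale_iterations,
           " rescaling rounds for: ", paste(over, collapse = ", "))
    ## allocate the available amount proportionally to realized requests
    for (met in over) {
      frac <- env$pools[[met]] / draw[[met]]
      for (si in seq_len(ns)) {
        if (!met %in% names(req[[si]])) next
        newcap <- req[[si]][[met]] * frac
        old <- caps[[si]][[met]]
        caps[[si]][[met]] <- if (is.null(old)) newcap
                             else min(old, newcap)
      }
    }
  }

  mu <- vapply(sols, `[[`, 0, "growth_rate")
  for (si in seq_len(ns)) {
    exf <- exchange_fluxes(states[[si]]$model, sols[[si]])
    upd <- intersect(names(exf), setdiff(names(env$pools),
                                         env$unlimited))
    env$pools[upd] <- env$pools[upd] + exf[upd] * B[si] * config$dt
    states[[si]]$biomass <-
      B[si] * (1 + (mu[si] - config$death_rate) * config$dt)
  }
  env$pools[abs(env$pools) < config$tolerance] <- 0
  if (any(env$pools < 0)) env$pools[env$pools < 0] <- 0
  list(states = states, env = env, mu = mu,
       exchange = lapply(seq_len(ns), function(si)
         exchange_fluxes(states[[si]]$model, sols[[si]])))
}

## sequential update in randomized order (comparison mode)
step_community_random <- function(states, env, config) {
  ns <- length(states)
  ord <- sample.int(ns)
  mu <- numeric(ns)
  exch <- vector("list", ns)
  for (si in ord) {
    B <- states[[si]]$biomass
    cap <- NULL
    sol <- NULL
    for (it in seq_len(max(1L, config$rescale_iterations))) {
      sol <- species_fba(states[[si]]$model, env, config, cap)
      exf <- exchange_fluxes(states[[si]]$model, sol)
      take <- -pmin(exf, 0) * B * config$dt
      limited <- setdiff(intersect(names(take), names(env$pools)),
                         env$unlimited)
      over <- limited[take[limited] >
                        env$pools[limited] * (1 + 1e-9) + 1e-18]
      if (!length(over)) break
      for (met in over) {
        newcap <- (take[[met]] / (B * config$dt)) *
          env$pools[[met]] / take[[met]]
        cap[[met]] <- if (is.null(cap[[met]])) newcap
                      else min(cap[[met]], newcap)
      }
    }
    exf <- exchange_fluxes(states[[si]]$model, sol)
    upd <- intersect(names(exf), setdiff(names(env$pools),
                                         env$unlimited))
    env$pools[upd] <- env$pools[upd] + exf[upd] * B * config$dt
    mu[si] <- sol$growth_rate
    exch[[si]] <- exf
    states[[si]]$biomass <-
      B * (1 + (mu[si] - config$death_rate) * config$dt)
  }
  env$pools[abs(env$pools) < config$tolerance] <- 0
  env$pools[env$pools < 0] <- 0
  list(states = states, env = env, mu = mu, exchange = exch)
}

#' Simulate a well-mixed co-culture with dynamic FBA
#'
#' Iterates [step_community()] over the configured horizon, recording
#' biomasses, shared metabolite pools and per-step growth rates.
#'
#' @param models a single [stoich_model()] or a list of one or two.
#' @param env a [community_env()].
#' @param config a [sim_config()].
#' @param inoculum starting biomass per species, gDW; recycled to the
#'   number of species. Default 3e-7 g.
#' @return an object of class `community_sim` with elements `times` (h),
#'   `biomass` (time x species matrix, gDW), `pools` (time x metabolite
#'   matrix, mmol), `mu` (step x species matrix, 1/h), `species_ids`,
#'   `env`, `config`.
#' @export
simulate_community <- function(models, env, config = sim_config(),
                               inoculum = 3e-7) {
  if (inherits(models, "stoich_model")) models <- list(models)
  if (!length(models) || length(models) > 2L)
    stop("simulate_community supports one or two species")
  ns <- length(models)
  inoculum <- rep_len(inoculum, ns)
  if (any(inoculum < 0)) stop("inoculum must be >= 0")
  states <- lapply(seq_len(ns), function(i)
    list(model = models[[i]], biomass = inoculum[i]))
  ids <- vapply(models, `[[`, "", "species_id")
  nstep <- round(config$duration / config$dt)

  stepper <- if (config$update_order == "random") {
    set.seed(config$seed)
    step_community_random
  } else step_community

  Bmat <- matrix(NA_real_, nstep + 1L, ns,
                 dimnames = list(NULL, ids))
  Pmat <- matrix(NA_real_, nstep + 1L, length(env$pools),
                 dimnames = list(NULL, names(env$pools)))
  Mmat <- matrix(NA_real_, nstep, ns, dimnames = list(NULL, ids))
  Bmat[1L, ] <- inoculum
  Pmat[1L, ] <- env$pools
  for (k in seq_len(nstep)) {
    out <- stepper(states, env, config)
    states <- out$states
    env <- out$env
    Bmat[k + 1L, ] <- vapply(states, `[[`, 0, "biomass")
    Pmat[k + 1L, ] <- env$pools
    Mmat[k, ] <- out$mu
  }
  structure(list(times = seq(0, config$duration, by = config$dt),
                 biomass = Bmat, pools = Pmat, mu = Mmat,
                 species_ids = ids, env = env, config = config),
            class = "community_sim")
}

#' Final biomass of one species in a simulated trajectory
#' @param sim a `community_sim`.
#' @param species species id or index (default first).
#' @return final biomass, gDW.
#' @export
final_biomass <- function(sim, species = 1L) {
  unname(sim$biomass[nrow(sim$biomass), species])
}

#' @export
print.community_sim <- function(x, ...) {
  nf <- nrow(x$biomass)
  cat(sprintf("Community dFBA trajectory: %d species, %.3g h at dt %.3g h\n",
              ncol(x$biomass), max(x$times), x$config$dt))
  for (j in seq_len(ncol(x$biomass)))
    cat(sprintf("  %-12s %.4g -> %.4g gDW\n", x$species_ids[j],
                x$biomass[1, j], x$biomass[nf, j]))
  invisible(x)
}

#' @export
as.data.frame.community_sim <- function(x, ...) {
  ns <- ncol(x$biomass)
  do.call(rbind, lapply(seq_len(ns), function(j) {
    df <- data.frame(time_h = x$times, species_id = x$species_ids[j],
                     biomass_g = x$biomass[, j],
                     stringsAsFactors = FALSE)
    cbind(df, as.data.frame(x$pools))
  }))
}

#' @export
plot.community_sim <- function(x, log = "y", ...) {
  B <- x$biomass
  B[B <= 0] <- NA
  graphics::matplot(x$times, B, type = "l", lty = 1,
                    col = seq_len(ncol(B)), log = log,
                    xlab = "time (h)", ylab = "biomass (gDW)", ...)
  graphics::legend("bottomright", legend = x$species_ids,
                   col = seq_len(ncol(B)), lty = 1, bty = "n")
  invisible(x)
}

#' Write a trajectory as tidy CSV
#'
#' One row per (time, species) with biomass and one column per tracked
#' pool; a `#`-prefixed provenance header precedes the table.
#'
#' @param sim a `community_sim`.
#' @param path output file.
#' @param provenance optional named character vector echoed as header
#'   comments.
#' @return invisibly, `path`.
#' @export
write_trajectory <- function(sim, path, provenance = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(provenance,
           config = paste0("dt=", sim$config$dt,
                           " duration=", sim$config$duration,
                           " Km=", sim$config$Km,
                           " Vmax=", sim$config$Vmax,
                           " death_rate=", sim$config$death_rate))
  for (i in seq_along(hdr))
    writeLines(paste0("# ", names(hdr)[i], ": ", hdr[i]), con)
  df <- as.data.frame(sim)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], signif, digits = 12)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
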