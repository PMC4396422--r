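#' Solve the flux balance problem for one species
#'
#' Two-stage flux balance analysis. Stage 1 maximizes flux through the
#' biomass reaction subject to steady-state mass balance `S v = 0` and
#' flux bounds. Stage 2 (the default tie-break) fixes the optimal growth
#' rate and minimizes the sum of absolute fluxes, which makes the
#' byproduct secretion spectrum — the currency of cross-feeding — a
#' deterministic function of the inputs rather than an accident of solver
#' pivoting. Growth-coupled secretions are enforced in both stages as
#' `v_exchange = rate * mu`.
#'
#' An infeasible program is reported as `status = "infeasible"` with
#' `growth_rate = 0` and no fluxes: a mutant whose network cannot satisfy
#' its constraints does not grow, it is not an error.
#'
#' @param model a [stoich_model()].
#' @param overrides named list of `c(lower, upper)` bound pairs replacing
#'   the model's stored bounds for this solve (e.g. environmental uptake
#'   limits on exchange reactions).
#' @param tie_break `"flux_min"` (two-stage, default) or `"none"`.
#' @param tol numeric feasibility/optimality tolerance.
#' @return an object of class `fba_solution`: list with `status`
#'   (`"optimal"` or `"infeasible"`), `growth_rate` (1/h), and `fluxes`
#'   (named numeric, mmol/gDW/h).
#' @export
solve_fba <- function(model, overrides = NULL,
                      tie_break = c("flux_min", "none"), tol = 1e-9) {
  tie_break <- match.arg(tie_break)
  S <- stoich_matrix(model, augmented = TRUE)
  bnd <- model_bounds(model, overrides)
  n <- ncol(S)
  m <- nrow(S)
  bio <- match(model$biomass_reaction_id, colnames(S))

  cc <- numeric(n)
  cc[bio] <- -1                      # maximize biomass
  s1 <- lp_solve(cc, S, numeric(m), bnd$lb, bnd$ub, tol = tol)
  if (s1$status == "infeasible")
    return(fba_solution("infeasible", 0, stats::setNames(numeric(0),
                                                         character(0))))
  if (s1$status != "optimal")
    stop("LP solver failure in stage 1: ", s1$status)
  mu <- max(0, s1$x[bio])
  v <- stats::setNames(s1$x, colnames(S))

  if (tie_break == "flux_min") {
    ## min sum |v| at fixed mu, via flux splitting v = p - q
    S2 <- cbind(S, -S)
    fix <- numeric(2 * n)
    fix[bio] <- 1
    fix[n + bio] <- -1
    s2 <- lp_solve(rep(1, 2 * n), rbind(S2, fix), c(numeric(m), mu),
                   c(pmax(bnd$lb, 0), pmax(-bnd$ub, 0)),
                   c(pmax(bnd$ub, 0), pmax(-bnd$lb, 0)), tol = tol)
    if (s2$status == "optimal") {
      v2 <- s2$x[seq_len(n)] - s2$x[n + seq_len(n)]
      if (abs(v2[bio] - mu) > 1e-6 * max(1, abs(mu)))
        stop("flux minimization changed the growth rate (",
             v2[bio], " vs ", mu, ")")
      v <- stats::setNames(v2, colnames(S))
    } else if (s2$status != "infeasible") {
      stop("LP solver failure in stage 2: ", s2$status)
    }
  }
  v[abs(v) < tol] <- 0
  fba_solution("optimal", mu, v)
}

fba_solution <- function(status, growth_rate, fluxes) {
  structure(list(status = status, growth_rate = growth_rate,
                 fluxes = fluxes),
            class = "fba_solution")
}

#' @export
print.fba_solution <- function(x, ...) {
  cat("FBA solution:", x$status,
      sprintf("| growth rate %.6g 1/h\n", x$growth_rate))
  if (length(x$fluxes)) {
    nz <- x$fluxes[x$fluxes != 0]
    cat(" nonzero fluxes (mmol/gDW/h):\n")
    print(round(nz, 6))
  }
  invisible(x)
}
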