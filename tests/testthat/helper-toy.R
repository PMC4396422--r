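## Shared fixtures and independent oracles for the test suite.

toy <- make_toy_pair()

## uptake overrides used by the hand-solved FBA examples
ov_full <- list(EX_lcts = c(-10, 1000), EX_o2 = c(-10, 1000),
                EX_met = c(-10, 1000))
ov_s <- list(EX_ac = c(-10, 1000), EX_o2 = c(-10, 1000))

## the full toy knockout screen is expensive (~40 s); compute once and
## share across test files
.toy_cache <- new.env(parent = emptyenv())
toy_screen_cached <- function() {
  if (is.null(.toy_cache$screen)) {
    t0 <- Sys.time()
    .toy_cache$screen <- run_screen(toy$E, toy$S, screen_config())
    .toy_cache$elapsed <-
      as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }
  .toy_cache$screen
}
toy_screen_elapsed <- function() {
  toy_screen_cached()
  .toy_cache$elapsed
}

## brute-force one-way ANOVA on |x - group mean|, via lm/anova, as the
## independent check of the hand-written Levene statistic
levene_oracle <- function(groups) {
  z <- unlist(lapply(groups, function(g) abs(g - mean(g))))
  f <- factor(rep(seq_along(groups), lengths(groups)))
  a <- stats::anova(stats::lm(z ~ f))
  list(W = a[["F value"]][1], df1 = a[["Df"]][1], df2 = a[["Df"]][2],
       p = a[["Pr(>F)"]][1])
}

## brute-force vertex enumeration for  min c'x, Ax = b, lb <= x <= ub
## with rank(A) = nrow(A); optimum of a bounded LP lies at a vertex,
## i.e. at least n - m variables sit at a bound
lp_vertex_oracle <- function(cc, A, b, lb, ub) {
  n <- ncol(A)
  m <- nrow(A)
  best <- NULL
  for (fix in utils::combn(n, n - m, simplify = FALSE)) {
    free <- setdiff(seq_len(n), fix)
    for (pat in seq_len(2^length(fix)) - 1L) {
      at_ub <- bitwAnd(pat, 2^(seq_along(fix) - 1L)) > 0
      vals <- ifelse(at_ub, ub[fix], lb[fix])
      rhs <- b - A[, fix, drop = FALSE] %*% vals
      xf <- tryCatch(solve(A[, free, drop = FALSE], rhs),
                     error = function(e) NULL)
      if (is.null(xf)) next
      x <- numeric(n)
      x[fix] <- vals
      x[free] <- xf
      if (all(x >= lb - 1e-8) && all(x <= ub + 1e-8)) {
        obj <- sum(cc * x)
        if (is.null(best) || obj < best) best <- obj
      }
    }
  }
  best
}

## stage-1 FBA linear program of a model, for solver cross-checks
fba_lp <- function(model, overrides = NULL) {
  S <- cofba:::stoich_matrix(model, augmented = TRUE)
  bnd <- cofba:::model_bounds(model, overrides)
  bio <- match(model$biomass_reaction_id, colnames(S))
  cc <- numeric(ncol(S))
  cc[bio] <- -1
  list(c = cc, A = unname(S), b = numeric(nrow(S)),
       lb = unname(bnd$lb), ub = unname(bnd$ub))
}
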