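#' Summarize a knockout screen
#'
#' Builds the robustness report for a two-condition screen: per-condition
#' standard deviations of each metric computed twice (over mutants
#' non-essential in every context, and over all mutants), mean-centered
#' Levene tests comparing the cooperative against the competitive
#' distribution of each metric, counts of substantive effects among
#' non-essential mutants, and the cross-condition effect correlation.
#'
#' A reaction is excluded from the "non-essential" analyses when its
#' knockout is essential in any context (monoculture, cooperation or
#' competition); mutants with an extinct community (undefined
#' composition) are excluded from the composition analyses. Degenerate
#' Levene inputs (zero within-group deviation) are reported as `NA` with
#' the error message rather than aborting the summary. Reported p-values
#' are floored at 2.2e-16.
#'
#' @param result a `knockout_screen` from [run_screen()] containing both
#'   co-culture conditions.
#' @param config a [screen_config()]; defaults to the one stored in
#'   `result`.
#' @return an object of class `screen_summary` with data.frame elements
#'   `sigma`, `levene`, `substantive`, `r2`.
#' @export
summarize_screen <- function(result, config = result$config) {
  rec <- result$records
  conds <- c("cooperation", "competition")
  if (!all(conds %in% rec$condition))
    stop("summary requires both cooperation and competition records")
  if (is.null(config))
    config <- screen_config()
  thr <- config$substantive_threshold

  ess_any <- rep(FALSE, nrow(rec))
  for (fld in c("essential_monoculture", "essential_cooperation",
                "essential_competition")) {
    v <- rec[[fld]]
    ess_any <- ess_any | (!is.na(v) & v)
  }
  ess_by_rxn <- tapply(ess_any, rec$reaction_id, any)
  rec$essential_any <- unname(ess_by_rxn[rec$reaction_id])
  nonessential <- rec[!rec$essential_any, ]
  if (length(unique(nonessential$reaction_id)) < 2L)
    stop("insufficient data: fewer than two non-essential mutants")

  metrics <- c("ECD", "pctE_norm", "BM_norm")
  grab <- function(df, metric, cond)
    df[[metric]][df$condition == cond]

  sigma <- do.call(rbind, lapply(metrics, function(mt)
    do.call(rbind, lapply(conds, function(cd)
      do.call(rbind, lapply(c("non_essential", "all"), function(inc) {
        vals <- grab(if (inc == "all") rec else nonessential, mt, cd)
        data.frame(metric = mt, condition = cd, inclusion = inc,
                   sd = stats::sd(vals, na.rm = TRUE),
                   n = sum(!is.na(vals)), stringsAsFactors = FALSE)
      }))))))

  levene <- do.call(rbind, lapply(metrics, function(mt)
    do.call(rbind, lapply(c("non_essential", "all"), function(inc) {
      df <- if (inc == "all") rec else nonessential
      g <- lapply(conds, function(cd) {
        v <- grab(df, mt, cd)
        v[!is.na(v)]
      })
      lt <- tryCatch(levene_mean_centered(g), error = identity)
      if (inherits(lt, "error"))
        data.frame(metric = mt, inclusion = inc, W = NA_real_,
                   df1 = NA_real_, df2 = NA_real_, p = NA_real_,
                   note = conditionMessage(lt), stringsAsFactors = FALSE)
      else
        data.frame(metric = mt, inclusion = inc,
                   W = unname(lt$statistic),
                   df1 = unname(lt$parameter[1]),
                   df2 = unname(lt$parameter[2]),
                   p = max(lt$p.value, 2.2e-16), note = "",
                   stringsAsFactors = FALSE)
    }))))

  substantive <- do.call(rbind, lapply(c("pctE_norm", "BM_norm"),
    function(mt) do.call(rbind, lapply(conds, function(cd) {
      vals <- grab(nonessential, mt, cd)
      data.frame(metric = mt, condition = cd,
                 count = count_substantive(vals, thr),
                 n = sum(!is.na(vals)), stringsAsFactors = FALSE)
    }))))

  r2_pool <- if (isTRUE(config$r2_include_essential)) rec else {
    both_ok <- !(
      (!is.na(rec$essential_cooperation) & rec$essential_cooperation) |
      (!is.na(rec$essential_competition) & rec$essential_competition))
    keep_rxn <- tapply(both_ok, rec$reaction_id, all)
    rec[unname(keep_rxn[rec$reaction_id]), ]
  }
  r2 <- do.call(rbind, lapply(c("pctE_norm", "BM_norm"), function(mt) {
    a <- r2_pool[r2_pool$condition == "cooperation",
                 c("reaction_id", mt)]
    b <- r2_pool[r2_pool$condition == "competition",
                 c("reaction_id", mt)]
    mg <- merge(a, b, by = "reaction_id", suffixes = c("_coop", "_comp"))
    val <- tryCatch(effect_r2(mg[[paste0(mt, "_coop")]],
                              mg[[paste0(mt, "_comp")]]),
                    error = function(e) NA_real_)
    data.frame(metric = mt, r2 = val, n = nrow(mg),
               stringsAsFactors = FALSE)
  }))

  structure(list(sigma = sigma, levene = levene,
                 substantive = substantive, r2 = r2,
                 substantive_threshold = thr,
                 n_mutants = length(unique(rec$reaction_id)),
                 n_nonessential =
                   length(unique(nonessential$reaction_id))),
            class = "screen_summary")
}

#' @export
summary.knockout_screen <- function(object, ...) {
  summarize_screen(object, ...)
}

#' @export
print.screen_summary <- function(x, ...) {
  cat("Screen summary:", x$n_mutants, "mutants,",
      x$n_nonessential, "non-essential in every context\n\n")
  cat("Standard deviations per metric and condition:\n")
  print(x$sigma, row.names = FALSE, digits = 4)
  cat("\nMean-centered Levene tests (cooperation vs competition):\n")
  print(x$levene, row.names = FALSE, digits = 4)
  cat(sprintf("\nSubstantive effects (|metric - 1| >= %g), %s:\n",
              x$substantive_threshold, "non-essential mutants"))
  print(x$substantive, row.names = FALSE)
  cat("\nCross-condition effect correlation:\n")
  print(x$r2, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write report tables
#'
#' Writes the variance table (`<prefix>_sigma.tsv`) and the statistics
#' table (`<prefix>_stats.tsv`: Levene results, substantive counts,
#' cross-condition R squared) of a [summarize_screen()] result.
#'
#' @param summary a `screen_summary`.
#' @param prefix path prefix for the two TSV files.
#' @return invisibly, the two paths.
#' @export
write_report <- function(summary, prefix) {
  p1 <- paste0(prefix, "_sigma.tsv")
  p2 <- paste0(prefix, "_stats.tsv")
  utils::write.table(summary$sigma, p1, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  stats_tab <- merge(summary$levene,
                     stats::aggregate(count ~ metric,
                                      summary$substantive, sum),
                     by = "metric", all.x = TRUE)
  stats_tab <- merge(stats_tab, summary$r2, by = "metric", all.x = TRUE)
  utils::write.table(stats_tab, p2, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(p1, p2))
}
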