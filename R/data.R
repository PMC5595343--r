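# Bundled Gulf of Cadiz study tables (printed raw values used as inputs).

#' Gulf of Cadiz stomach-content diet table (raw columns)
#'
#' Raw prey counts (N), stomachs of occurrence (O) and reconstructed weights
#' (W, g) per prey category for the 13 bottlenose dolphin stomachs analysed
#' in the Gulf of Cadiz, at species, family and class level as published.
#' Percentages and IRIs are deliberately not stored: they are recomputed by
#' [relative_importance()].
#'
#' @return data.frame with columns `class`, `family`, `taxon`, `level`
#'   (`species`/`family`/`class`), `N`, `O`, `W`.
#' @export
cadiz_table1 <- function() {
  utils::read.csv(system.file("extdata", "cadiz_table1.csv",
                              package = "dietmix"),
                  stringsAsFactors = FALSE)
}

#' Gulf of Cadiz isotope summaries (consumer, groups, species)
#'
#' Published d13C / d15N summary statistics for bottlenose dolphin skin
#' (n = 51) and the 12 prey species considered as mixing-model sources,
#' including the printed pooled summaries for the two multi-species groups.
#'
#' @return data.frame with columns `level` (`consumer`/`group`/`species`),
#'   `group`, `taxon`, `n`, and per-isotope `mean`, `sd`, `min`, `max`.
#' @export
cadiz_table2 <- function() {
  utils::read.csv(system.file("extdata", "cadiz_table2.csv",
                              package = "dietmix"),
                  stringsAsFactors = FALSE)
}

#' The four Gulf of Cadiz source groups as a mixing-model source table
#'
#' Groups 1 and 2 use the published pooled summaries; Groups 3 and 4 are
#' single species (*Octopus vulgaris*, *Liza ramada*) whose species rows
#' are the group summaries.
#'
#' @return data.frame with columns `group`, `taxa`, `n`, `mean_d13C`,
#'   `sd_d13C`, `mean_d15N`, `sd_d15N`.
#' @export
cadiz_sources <- function() {
  t2 <- cadiz_table2()
  rows <- lapply(1:4, function(g) {
    sub <- t2[!is.na(t2$group) & t2$group == g, ]
    r <- if (any(sub$level == "group")) sub[sub$level == "group", ][1, ]
         else sub[1, ]
    data.frame(group = g,
               taxa = paste(sub$taxon[sub$level == "species"], collapse = ", "),
               n = r$n, mean_d13C = r$mean_d13C, sd_d13C = r$sd_d13C,
               mean_d15N = r$mean_d15N, sd_d15N = r$sd_d15N)
  })
  do.call(rbind, rows)
}
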