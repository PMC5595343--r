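# Dietary composition indices: %N, %O, %W, IRI, prey-specific abundance for
# Costello-Amundsen diagrams, and stomach-level bootstrap confidence limits.

#' Dietary indices from aggregated counts, occurrences and weights
#'
#' Computes the standard stomach-content composition indices for one or more
#' prey categories given raw totals: numerical percentage
#' \eqn{\%N = 100 N_i/\sum N}, percentage of occurrence
#' \eqn{\%O = 100 O_i/n_{stomachs}}, weight percentage
#' \eqn{\%W = 100 W_i/\sum W}, and the Index of Relative Importance
#' \eqn{IRI = (\%N + \%W) \times \%O} (range 0 to 20000).
#'
#' In `"reporting"` mode each percentage is first rounded to two decimals
#' (half away from zero) and the IRI is computed from — and rounded to — two
#' decimals, matching how published diet tables are typeset; `"analysis"`
#' mode keeps full precision. Categories without a reconstructed weight get
#' no \%W and no IRI.
#'
#' @param N integer vector of prey counts per category.
#' @param O integer vector of stomachs-of-occurrence per category.
#' @param W numeric vector of reconstructed weights (g); `NA` where no
#'   weight could be reconstructed.
#' @param total_n total prey items across the whole diet (defaults to
#'   `sum(N)`; pass the table total when `N` covers only some rows).
#' @param n_stomachs number of stomachs examined.
#' @param total_w total reconstructed weight (defaults to
#'   `sum(W, na.rm = TRUE)`).
#' @param mode `"analysis"` (unrounded) or `"reporting"` (two-decimal).
#' @return data.frame with columns `pctN`, `pctO`, `pctW`, `IRI`.
#' @examples
#' # European conger's family row from a 13-stomach, 1001-prey diet table
#' relative_importance(215, 8, 50603.24, total_n = 1001, n_stomachs = 13,
#'                     total_w = 143842.21, mode = "reporting")
#' @export
relative_importance <- function(N, O, W = NA_real_, total_n = sum(N),
                                n_stomachs, total_w = sum(W, na.rm = TRUE),
                                mode = c("analysis", "reporting")) {
  mode <- match.arg(mode)
  if (n_stomachs < 1) stop("n_stomachs must be >= 1")
  if (total_n < 1) stop("total_n must be >= 1")
  pctN <- 100 * N / total_n
  pctO <- 100 * O / n_stomachs
  pctW <- if (isTRUE(total_w > 0)) 100 * W / total_w else W * NA_real_
  if (mode == "reporting") {
    pctN <- round_half_up(pctN); pctO <- round_half_up(pctO)
    pctW <- round_half_up(pctW)
  }
  iri <- (pctN + pctW) * pctO
  if (mode == "reporting") iri <- round_half_up(iri)
  data.frame(pctN = pctN, pctO = pctO, pctW = pctW, IRI = iri)
}

#' Diet composition table from prey occurrences
#'
#' Aggregates a per-stomach occurrence table (from [reconstruct()]) to the
#' requested taxonomic level and computes N, \%N, O, \%O, W, \%W and IRI per
#' category. The \%W denominator covers only categories with reconstructed
#' weight, so \%W sums to 100 over weighted rows; weightless categories get
#' `NA` for W, \%W and IRI.
#'
#' @param occurrences data.frame with columns `stomach_id`, `taxon`,
#'   `family`, `class`, `n_individuals`, `total_weight_g`.
#' @param n_stomachs number of stomachs examined (may exceed the number of
#'   stomachs containing prey).
#' @param level aggregation level: `"taxon"`, `"family"` or `"class"`.
#' @param mode see [relative_importance()].
#' @return data.frame with columns `taxon` (the category label), `N`,
#'   `pctN`, `O`, `pctO`, `W`, `pctW`, `IRI`, sorted by decreasing IRI.
#' @export
diet_table <- function(occurrences, n_stomachs,
                       level = c("taxon", "family", "class"),
                       mode = c("analysis", "reporting")) {
  level <- match.arg(level); mode <- match.arg(mode)
  stopifnot(is.data.frame(occurrences), nrow(occurrences) >= 1)
  if (n_stomachs < 1) stop("n_stomachs must be >= 1")
  lab <- occurrences[[level]]
  N <- tapply(occurrences$n_individuals, lab, sum)
  O <- tapply(occurrences$stomach_id, lab,
              function(s) length(unique(s)))
  W <- tapply(occurrences$total_weight_g, lab, function(w)
    if (all(is.na(w))) NA_real_ else sum(w, na.rm = TRUE))
  cats <- names(N)
  idx <- relative_importance(as.vector(N), as.vector(O), as.vector(W),
                             total_n = sum(N), n_stomachs = n_stomachs,
                             total_w = sum(W, na.rm = TRUE), mode = mode)
  out <- data.frame(taxon = cats, N = as.vector(N), pctN = idx$pctN,
                    O = as.vector(O), pctO = idx$pctO,
                    W = as.vector(W), pctW = idx$pctW, IRI = idx$IRI)
  out <- out[order(-ifelse(is.na(out$IRI), -Inf, out$IRI), out$taxon), ]
  rownames(out) <- NULL
  out
}

#' Prey-specific abundance
#'
#' The weight share of prey taxon i computed only over the stomachs that
#' contain it:
#' \deqn{\%P_i = 100 \frac{\sum W_i}{\sum W_{ti}}}
#' where the numerator sums taxon i's reconstructed weight and the
#' denominator the total stomach-content weight of those same stomachs.
#' This is the y-axis of the Costello-Amundsen feeding-strategy diagram: a
#' taxon near 100 is dominant wherever it occurs (specialisation), a taxon
#' near 0 is incidental.
#'
#' @param occurrences as in [diet_table()].
#' @param taxon taxon label (matched case-insensitively).
#' @return scalar percentage, or `NA` if the taxon is absent or carries no
#'   weight.
#' @export
prey_specific_abundance <- function(occurrences, taxon) {
  tl <- normalize_label(occurrences$taxon)
  mine <- tl == normalize_label(taxon) & !is.na(occurrences$total_weight_g)
  if (!any(mine)) return(NA_real_)
  stomachs <- unique(occurrences$stomach_id[mine])
  wi <- sum(occurrences$total_weight_g[mine])
  wti <- sum(occurrences$total_weight_g[occurrences$stomach_id %in% stomachs],
             na.rm = TRUE)
  100 * wi / wti
}

#' Costello-Amundsen plot coordinates
#'
#' One (\%O, \%P) pair per weight-bearing taxon; the classic diagram's
#' diagonal axes read prey importance (lower-left rare to upper-right
#' dominant) and niche-width contribution, and the vertical axis reads
#' feeding strategy (specialist top, generalist bottom).
#'
#' @inheritParams diet_table
#' @return data.frame with columns `taxon`, `pctO`, `pctP`.
#' @export
amundsen_points <- function(occurrences, n_stomachs) {
  if (n_stomachs < 1) stop("n_stomachs must be >= 1")
  taxa <- unique(occurrences$taxon[!is.na(occurrences$total_weight_g)])
  pts <- lapply(taxa, function(tx) {
    rows <- normalize_label(occurrences$taxon) == normalize_label(tx)
    data.frame(taxon = tx,
               pctO = 100 * length(unique(occurrences$stomach_id[rows])) /
                 n_stomachs,
               pctP = prey_specific_abundance(occurrences, tx))
  })
  out <- do.call(rbind, pts)
  out[order(out$taxon), , drop = FALSE]
}

#' Bootstrap confidence limits for diet composition
#'
#' Resamples whole stomachs (the sampling unit) with replacement, recomputes
#' \%N, \%O, \%W and IRI per replicate — a taxon absent from a replicate
#' contributes zero — and reports the percentile median and 95\% limits
#' (2.5/50/97.5, linear interpolation between order statistics).
#'
#' @inheritParams diet_table
#' @param n_iter number of bootstrap replicates (default 1000).
#' @param seed integer RNG seed.
#' @return data.frame in long format: `taxon`, `stat` (one of `pctN`,
#'   `pctO`, `pctW`, `IRI`), `median`, `lo95`, `hi95`.
#' @export
bootstrap_diet <- function(occurrences, n_stomachs, n_iter = 1000,
                           seed = .default_seed,
                           level = c("taxon", "family", "class")) {
  level <- match.arg(level)
  if (n_iter < 1) stop("n_iter must be >= 1")
  if (n_stomachs < 1) stop("n_stomachs must be >= 1")
  set.seed(seed)
  lab <- as.character(occurrences[[level]])
  ids <- unique(as.character(occurrences$stomach_id))
  # stomachs examined but empty still belong in the resampling frame
  if (n_stomachs > length(ids))
    ids <- c(ids, sprintf(".empty%d", seq_len(n_stomachs - length(ids))))
  taxa <- sort(unique(lab))
  Nmat <- matrix(0, length(ids), length(taxa), dimnames = list(ids, taxa))
  Wmat <- Nmat
  for (r in seq_len(nrow(occurrences))) {
    i <- as.character(occurrences$stomach_id[r]); j <- lab[r]
    Nmat[i, j] <- Nmat[i, j] + occurrences$n_individuals[r]
    if (!is.na(occurrences$total_weight_g[r]))
      Wmat[i, j] <- Wmat[i, j] + occurrences$total_weight_g[r]
  }
  weighted <- colSums(Wmat) > 0
  draws <- array(0, dim = c(n_iter, length(taxa), 4),
                 dimnames = list(NULL, taxa, c("pctN", "pctO", "pctW", "IRI")))
  for (b in seq_len(n_iter)) {
    pick <- sample.int(length(ids), n_stomachs, replace = TRUE)
    Nb <- colSums(Nmat[pick, , drop = FALSE])
    Ob <- colSums(Nmat[pick, , drop = FALSE] > 0)
    Wb <- colSums(Wmat[pick, , drop = FALSE])
    tn <- sum(Nb); tw <- sum(Wb[weighted])
    pctN <- if (tn > 0) 100 * Nb / tn else Nb * 0
    pctO <- 100 * Ob / n_stomachs
    pctW <- Wb * 0
    if (tw > 0) pctW[weighted] <- 100 * Wb[weighted] / tw
    iri <- ifelse(weighted, (pctN + pctW) * pctO, 0)
    draws[b, , ] <- cbind(pctN, pctO, pctW, iri)
  }
  rows <- lapply(taxa, function(tx) {
    do.call(rbind, lapply(c("pctN", "pctO", "pctW", "IRI"), function(st) {
      if (st %in% c("pctW", "IRI") && !weighted[tx]) return(NULL)
      q <- stats::quantile(draws[, tx, st], c(0.025, 0.5, 0.975),
                           names = FALSE, type = 7)
      data.frame(taxon = tx, stat = st, median = q[2], lo95 = q[1],
                 hi95 = q[3])
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
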