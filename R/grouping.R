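# Source grouping for mixing models: per-species isotope summaries, Ward
# clustering of species means, and exact pooling into group-level summaries.

#' Per-species isotope summary statistics
#'
#' @param measurements data.frame with columns `sample_id`, `role`
#'   (`"consumer"` / `"source"`), `taxon`, `d13C`, `d15N`.
#' @param taxon taxon label (case-insensitive match).
#' @return data.frame with one row per isotope (`d13C`, `d15N`): `n`,
#'   `mean`, `sd` (`NA` when n < 2), `min`, `max`. Values outside typical
#'   marine ranges raise a warning, not an error.
#' @export
summarize_species <- function(measurements, taxon) {
  rows <- normalize_label(measurements$taxon) == normalize_label(taxon)
  if (!any(rows)) stop("no measurements for taxon '", taxon, "'")
  m <- measurements[rows, ]
  if (any(m$d13C < -35 | m$d13C > -5) || any(m$d15N < 0 | m$d15N > 25))
    warning("isotope values outside typical marine ranges for '", taxon, "'")
  do.call(rbind, lapply(c("d13C", "d15N"), function(iso) {
    x <- m[[iso]]
    data.frame(isotope = iso, n = length(x), mean = mean(x),
               sd = if (length(x) >= 2) stats::sd(x) else NA_real_,
               min = min(x), max = max(x))
  }))
}

#' Ward clustering of species mean isotope values
#'
#' Agglomerative hierarchical clustering of species in the (d13C, d15N)
#' plane, Euclidean distance, Ward minimum-variance linkage, cut at `k`
#' groups. Rows are sorted by taxon before clustering so the partition does
#' not depend on input order; group numbers follow the order of first
#' appearance in the sorted list.
#'
#' @param species_means data.frame with columns `taxon`, `d13C`, `d15N`
#'   (mean values, permil).
#' @param k number of clusters, `1 <= k <= nrow(species_means)`.
#' @param linkage `"ward.D2"` (distances squared inside the update — the
#'   modern convention, default) or the legacy `"ward.D"`.
#' @param standardize scale each isotope axis to unit sd before clustering
#'   (default `FALSE`: the two axes' spreads are typically comparable in
#'   permil).
#' @return list with `partition` (named integer vector of group ids per
#'   taxon), `tree` (the `hclust` object), `heights` (merge heights) and
#'   `newick` (the dendrogram as a Newick string, for external inspection).
#' @export
ward_cluster <- function(species_means, k, linkage = c("ward.D2", "ward.D"),
                         standardize = FALSE) {
  linkage <- match.arg(linkage)
  stopifnot(is.data.frame(species_means))
  n <- nrow(species_means)
  if (k < 1 || k > n) stop("k must be between 1 and the number of species")
  sm <- species_means[order(species_means$taxon), ]
  xy <- as.matrix(sm[, c("d13C", "d15N")])
  rownames(xy) <- sm$taxon
  if (standardize) xy <- scale(xy)
  tree <- stats::hclust(stats::dist(xy), method = linkage)
  cut <- stats::cutree(tree, k = k)
  # renumber groups by first appearance over the sorted taxa
  part <- match(cut, unique(cut))
  names(part) <- sm$taxon
  newick <- if (n >= 3) ape::write.tree(ape::as.phylo(tree)) else NA_character_
  list(partition = part, tree = tree, heights = tree$height, newick = newick)
}

#' Pool species summaries into source-group summaries
#'
#' Exact pooling of per-species means and standard deviations, equivalent to
#' recomputing the statistics from the concatenated raw values:
#' pooled mean \eqn{m = \sum n_i m_i / \sum n_i} and pooled variance
#' \deqn{s^2 = \frac{\sum (n_i - 1) s_i^2 + \sum n_i (m_i - m)^2}
#'   {\sum n_i - 1}.}
#'
#' @param species_summaries data.frame with columns `taxon`, `n`,
#'   `mean_d13C`, `sd_d13C`, `mean_d15N`, `sd_d15N` (sd may be `NA` for
#'   n = 1 species).
#' @param partition named integer vector mapping taxon to group id (e.g.
#'   from [ward_cluster()]).
#' @return data.frame with one row per group: `group`, `taxa`
#'   (comma-separated members), `n`, `mean_d13C`, `sd_d13C`, `mean_d15N`,
#'   `sd_d15N`; sd is `NA` when the pooled n < 2.
#' @export
pool_groups <- function(species_summaries, partition) {
  stopifnot(all(species_summaries$taxon %in% names(partition)))
  g <- partition[species_summaries$taxon]
  pool1 <- function(n, m, s) {
    N <- sum(n); M <- sum(n * m) / N
    if (N < 2) return(c(M, NA_real_))
    s2 <- ifelse(n >= 2, s^2, 0)
    V <- (sum((n - 1) * s2) + sum(n * (m - M)^2)) / (N - 1)
    c(M, sqrt(V))
  }
  out <- lapply(sort(unique(g)), function(gid) {
    rows <- species_summaries[g == gid, ]
    c13 <- pool1(rows$n, rows$mean_d13C, rows$sd_d13C)
    n15 <- pool1(rows$n, rows$mean_d15N, rows$sd_d15N)
    data.frame(group = gid, taxa = paste(rows$taxon, collapse = ", "),
               n = sum(rows$n), mean_d13C = c13[1], sd_d13C = c13[2],
               mean_d15N = n15[1], sd_d15N = n15[2])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
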