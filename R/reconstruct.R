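# Prey reconstruction: identified hard-part measurements -> per-stomach prey
# counts, lengths and allometrically reconstructed weights.

# Bone elements treated as paired (two per fish) unless overridden.
.paired_elements <- c("premaxilla", "maxilla", "dentary", "opercula", "cleitrum")

# Measurement kinds each structure can carry.
.structure_kinds <- list(
  otolith    = c("otolith_length", "otolith_width"),
  upper_beak = c("rostral_length", "hood_length"),
  lower_beak = c("rostral_length", "hood_length"))

#' Minimum number of fish individuals evidenced by hard parts
#'
#' Applies the standard counting rule: each otolith represents half a fish,
#' and each diagnostic bone likewise half a fish if the element is paired
#' (one fish otherwise); the estimate is the highest count implied by any
#' structure type, rounded up, so any detected hard part evidences at least
#' one individual.
#'
#' @param otolith_count nonnegative otolith count.
#' @param bone_counts named nonnegative integer vector of counts per bone
#'   element (e.g. `c(premaxilla = 4)`); may be empty.
#' @param paired character vector of elements counted as paired; defaults to
#'   premaxilla, maxilla, dentary, opercula and cleitrum.
#' @return positive integer.
#' @examples
#' count_individuals(4)                       # 2
#' count_individuals(3, c(premaxilla = 4))    # 2
#' count_individuals(1)                       # 1
#' @export
count_individuals <- function(otolith_count = 0, bone_counts = integer(),
                              paired = .paired_elements) {
  if (otolith_count < 0 || any(bone_counts < 0))
    stop("counts must be nonnegative")
  if (otolith_count == 0 && (length(bone_counts) == 0 || all(bone_counts == 0)))
    stop("no hard parts: cannot evidence an individual")
  cand <- ceiling(0.5 * otolith_count)
  if (length(bone_counts)) {
    halve <- names(bone_counts) %in% paired
    cand <- c(cand, ifelse(halve, ceiling(0.5 * bone_counts), bone_counts))
  }
  as.integer(max(cand))
}

#' Reconstruct prey length and weight from a hard-part measurement
#'
#' Length follows the entry's length model (`linear`: \eqn{a + b x};
#' `power`: \eqn{a x^b}); weight is always a power law of the reconstructed
#' length, \eqn{W = c L^d} (grams).
#'
#' @param measurement structure measurement in mm.
#' @param entry one row of a regression table (list or single-row
#'   data.frame) with fields `length_form`, `length_a`, `length_b`,
#'   `weight_c`, `weight_d`.
#' @return list with `length_mm` and `weight_g`.
#' @export
estimate_size <- function(measurement, entry) {
  if (!is.finite(measurement) || measurement <= 0)
    stop("measurement must be a positive number of mm")
  len <- if (entry$length_form == "linear") {
    entry$length_a + entry$length_b * measurement
  } else if (entry$length_form == "power") {
    entry$length_a * measurement^entry$length_b
  } else stop("unknown length_form: ", entry$length_form)
  if (!is.finite(len) || len <= 0)
    stop("length model produced a non-positive length")
  list(length_mm = len, weight_g = entry$weight_c * len^entry$weight_d)
}

# Resolve a taxon to its regression entry: species-scope match beats
# group-scope (family) match beats nothing (NULL = no-weight outcome).
# Optionally restrict to entries consuming a given structure.
resolve_regression <- function(taxon, family, regressions, structure = NULL) {
  if (is.null(regressions) || nrow(regressions) == 0) return(NULL)
  rt <- normalize_label(regressions$taxon)
  ok_struct <- if (is.null(structure)) rep(TRUE, nrow(regressions))
               else regressions$input_structure == structure
  hit <- which(regressions$scope == "species" & rt == normalize_label(taxon) & ok_struct)
  if (!length(hit) && !is.na(family))
    hit <- which(regressions$scope == "group" & rt == normalize_label(family) & ok_struct)
  if (!length(hit)) return(NULL)
  as.list(regressions[hit[1], ])
}

#' Reconstruct per-stomach prey occurrences from hard-part records
#'
#' Groups records by stomach and taxon, counts individuals (otolith/bone
#' rule for fish via [count_individuals()]; for cephalopods the larger of
#' the upper- and lower-beak counts), reconstructs individual lengths and
#' weights through the regression table, and totals weight per occurrence as
#' the mean reconstructed individual weight times the individual count
#' (structures usually outnumber individuals, e.g. two otoliths per fish).
#'
#' Regression resolution is deterministic: a species-scope entry beats a
#' group-scope (family) entry, and a taxon resolving to neither yields an
#' occurrence with the weight left `NA` (a "no-weight" outcome, not an
#' error).
#'
#' @param records data.frame with columns `stomach_id`, `taxon`, `family`,
#'   `class`, `structure` (`otolith`, `bone`, `upper_beak`, `lower_beak`),
#'   `bone_element` (required when `structure == "bone"`), `measurement_mm`
#'   (optional per row), `count` (positive integer).
#' @param regressions data.frame with columns `taxon`, `scope` (`species` /
#'   `group`), `input_structure`, `measurement_kind`, `length_form`,
#'   `length_a`, `length_b`, `weight_c`, `weight_d`.
#' @param paired passed to [count_individuals()].
#' @param beak_preference which beak's measurements to use when both are
#'   measured and regressions exist for both; default `"lower_beak"`.
#' @return data.frame with one row per (stomach, taxon): `stomach_id`,
#'   `taxon`, `family`, `class`, `n_individuals`, `total_weight_g`.
#' @export
reconstruct <- function(records, regressions, paired = .paired_elements,
                        beak_preference = "lower_beak") {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  if (any(records$count < 1)) stop("record counts must be >= 1")
  bad_bone <- records$structure == "bone" &
    (is.na(records$bone_element) | records$bone_element == "")
  if (any(bad_bone))
    stop("bone records must name a bone_element (rows ",
         paste(which(bad_bone), collapse = ", "), ")")
  key <- interaction(records$stomach_id, normalize_label(records$taxon),
                     drop = TRUE)
  out <- lapply(split(records, key), function(g) {
    is_ceph <- any(g$structure %in% c("upper_beak", "lower_beak"))
    if (is_ceph) {
      n_up <- sum(g$count[g$structure == "upper_beak"])
      n_lo <- sum(g$count[g$structure == "lower_beak"])
      n <- max(n_up, n_lo, 1L)
    } else {
      oto <- sum(g$count[g$structure == "otolith"])
      bones <- g[g$structure == "bone", ]
      bc <- if (nrow(bones)) tapply(bones$count, bones$bone_element, sum)
            else integer()
      n <- count_individuals(oto, unlist(bc), paired = paired)
    }
    # weight: prefer the structure the resolved regression consumes
    structs <- unique(g$structure[!is.na(g$measurement_mm)])
    if (is_ceph && beak_preference %in% structs &&
        !is.null(resolve_regression(g$taxon[1], g$family[1], regressions,
                                    beak_preference)))
      structs <- beak_preference
    entry <- NULL; meas <- numeric()
    for (st in structs) {
      e <- resolve_regression(g$taxon[1], g$family[1], regressions, st)
      if (!is.null(e)) {
        if (!e$measurement_kind %in% .structure_kinds[[st]])
          stop("regression for '", g$taxon[1], "' pairs structure '", st,
               "' with incompatible measurement kind '", e$measurement_kind,
               "' (stomach ", g$stomach_id[1], ")")
        entry <- e
        meas <- g$measurement_mm[g$structure == st & !is.na(g$measurement_mm)]
        break
      }
    }
    w <- NA_real_
    if (!is.null(entry) && length(meas)) {
      wts <- vapply(meas, function(m) estimate_size(m, entry)$weight_g,
                    numeric(1))
      w <- mean(wts) * n
    }
    data.frame(stomach_id = g$stomach_id[1], taxon = g$taxon[1],
               family = g$family[1], class = g$class[1],
               n_individuals = n, total_weight_g = w)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$stomach_id, res$taxon), , drop = FALSE]
}
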