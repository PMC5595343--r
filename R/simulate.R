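# Synthetic-data generators with known ground truth for both analysis
# streams: hard-part stomach records and consumer/source isotope tables.

#' Configuration for the stomach-content simulator
#'
#' Describes a predator population whose stomachs are filled by drawing a
#' per-stomach prey composition from a Dirichlet distribution and prey counts
#' from a multinomial, then materialising each individual prey as hard parts
#' (two otoliths for fish, one lower beak for cephalopods) whose measurements
#' are consistent with a supplied allometric regression table.
#'
#' @param taxa data.frame with columns `taxon`, `family`, `class`
#'   (`"Teleost"` or `"Cephalopod"`), `structure` (`"otolith"` or `"beak"`),
#'   `length_mean_mm`, `length_sd_mm`, and optionally logical `no_weight`
#'   marking taxa that deliberately lack a regression entry.
#' @param regressions regression table in the [reconstruct()] schema; every
#'   taxon must either resolve against it or be flagged `no_weight`.
#' @param n_stomachs number of stomachs to simulate.
#' @param individuals_per_stomach integer scalar or length-`n_stomachs`
#'   vector of prey individuals per stomach.
#' @param concentration positive Dirichlet concentration (per taxon)
#'   governing across-stomach heterogeneity; small values give the
#'   heavy-tailed, few-taxa-dominate stomachs typical of opportunistic
#'   predators. Default 0.3.
#' @param seed integer RNG seed.
#' @return a list of class `"stomach_sim_config"`.
#' @seealso [simulate_stomach_dataset()]
#' @export
stomach_sim_config <- function(taxa, regressions, n_stomachs,
                               individuals_per_stomach,
                               concentration = 0.3,
                               seed = .default_seed) {
  stopifnot(is.data.frame(taxa), nrow(taxa) >= 1)
  if (n_stomachs < 1) stop("n_stomachs must be >= 1")
  if (concentration <= 0) stop("concentration must be > 0")
  n_ind <- rep_len(as.integer(individuals_per_stomach), n_stomachs)
  if (any(n_ind <= 0)) stop("individuals_per_stomach must be positive")
  if (is.null(taxa$no_weight)) taxa$no_weight <- FALSE
  # every taxon needs a regression entry or an explicit opt-out
  resolvable <- vapply(seq_len(nrow(taxa)), function(i) {
    !is.null(resolve_regression(taxa$taxon[i], taxa$family[i], regressions))
  }, logical(1))
  if (any(!resolvable & !taxa$no_weight))
    stop("taxa without a regression entry must set no_weight = TRUE: ",
         paste(taxa$taxon[!resolvable & !taxa$no_weight], collapse = ", "))
  structure(list(taxa = taxa, regressions = regressions,
                 n_stomachs = as.integer(n_stomachs),
                 individuals_per_stomach = n_ind,
                 concentration = concentration, seed = as.integer(seed)),
            class = "stomach_sim_config")
}

#' Simulate a hard-part stomach dataset with known composition
#'
#' Per stomach, a composition is drawn from Dirichlet(concentration) and the
#' configured number of individuals is allocated to taxa by a multinomial
#' draw. Each fish contributes two otolith rows, each cephalopod one
#' lower-beak row; the hard-part measurement is the taxon's drawn body length
#' back-transformed through its length regression, so reconstruction with the
#' same regression table recovers lengths (and hence weights) exactly.
#'
#' @param config a [stomach_sim_config()].
#' @return list with elements `records` (a hard-part table in the
#'   [reconstruct()] input schema), `truth` (per-stomach, per-taxon
#'   `truth_n` and `truth_weight_g`), and `config`.
#' @export
simulate_stomach_dataset <- function(config) {
  stopifnot(inherits(config, "stomach_sim_config"))
  set.seed(config$seed)
  taxa <- config$taxa
  K <- nrow(taxa)
  rec <- vector("list", config$n_stomachs)
  tru <- vector("list", config$n_stomachs)
  for (s in seq_len(config$n_stomachs)) {
    p <- rdirichlet1(K, config$concentration)
    counts <- as.vector(stats::rmultinom(1, config$individuals_per_stomach[s], p))
    rows <- list(); truths <- list()
    for (k in which(counts > 0)) {
      len <- rpositive_norm(counts[k], taxa$length_mean_mm[k], taxa$length_sd_mm[k])
      entry <- resolve_regression(taxa$taxon[k], taxa$family[k], config$regressions)
      if (!is.null(entry)) {
        meas <- invert_length_model(len, entry)
        w <- sum(entry$weight_c * len^entry$weight_d)
      } else {
        meas <- len  # emitted but unusable downstream (no-weight taxon)
        w <- NA_real_
      }
      is_fish <- taxa$structure[k] == "otolith"
      reps <- if (is_fish) 2L else 1L
      rows[[length(rows) + 1L]] <- data.frame(
        stomach_id = sprintf("S%02d", s),
        taxon = taxa$taxon[k], family = taxa$family[k], class = taxa$class[k],
        structure = if (is_fish) "otolith" else "lower_beak",
        bone_element = NA_character_,
        measurement_mm = rep(meas, each = reps),
        count = 1L)
      truths[[length(truths) + 1L]] <- data.frame(
        stomach_id = sprintf("S%02d", s), taxon = taxa$taxon[k],
        truth_n = counts[k], truth_weight_g = w)
    }
    rec[[s]] <- do.call(rbind, rows)
    tru[[s]] <- do.call(rbind, truths)
  }
  list(records = do.call(rbind, rec), truth = do.call(rbind, tru),
       config = config)
}

# positive-support normal draws by resampling the non-positive ones
rpositive_norm <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

# invert the length model: measurement that reconstructs to body length L
invert_length_model <- function(len, entry) {
  if (entry$length_form == "linear") (len - entry$length_a) / entry$length_b
  else (len / entry$length_a)^(1 / entry$length_b)
}

#' Configuration for the isotope-data simulator
#'
#' @param true_p diet proportion vector over the K source groups (sums to 1).
#' @param sources data.frame with columns `group`, `mean_d13C`, `sd_d13C`,
#'   `mean_d15N`, `sd_d15N`, `n`.
#' @param tdf diet-to-tissue discrimination factors: data.frame with columns
#'   `isotope` (`"d13C"`, `"d15N"`), `mean`, `sd`, optionally `group` for
#'   per-source factors.
#' @param n_consumers number of consumer samples to draw.
#' @param residual_sd length-2 nonnegative vector of additional residual
#'   standard deviations (permil), one per isotope. Default `c(0, 0)`.
#' @param seed integer RNG seed.
#' @return a list of class `"isotope_sim_config"`.
#' @export
isotope_sim_config <- function(true_p, sources, tdf, n_consumers,
                               residual_sd = c(0, 0), seed = .default_seed) {
  stopifnot(is.data.frame(sources))
  if (abs(sum(true_p) - 1) > 1e-12 || any(true_p < 0))
    stop("true_p must be a probability vector summing to 1 (within 1e-12)")
  if (length(true_p) != nrow(sources))
    stop("length(true_p) must equal the number of source groups")
  if (any(residual_sd < 0)) stop("residual_sd must be nonnegative")
  if (n_consumers < 1) stop("n_consumers must be >= 1")
  structure(list(true_p = true_p, sources = sources, tdf = tdf,
                 n_consumers = as.integer(n_consumers),
                 residual_sd = rep_len(residual_sd, 2),
                 seed = as.integer(seed)),
            class = "isotope_sim_config")
}

#' Simulate consumer isotope values from a known diet
#'
#' Draws consumer values from the same mass-balance likelihood the mixing
#' model fits: per isotope j, independently,
#' \deqn{x_j \sim N\big(\sum_k p_k(\mu_{kj}+\lambda_{kj}),\;
#'   \sqrt{\sum_k p_k^2(\sigma_{kj}^2+\tau_{kj}^2) + \xi_j^2}\big)}
#' where \eqn{\lambda, \tau} are the discrimination-factor mean and sd and
#' \eqn{\xi_j} the configured residual sd.
#'
#' @param config an [isotope_sim_config()].
#' @return list with `consumers` (data.frame `sample_id`, `d13C`, `d15N`),
#'   `truth` (the generating proportion vector) and `config`.
#' @export
simulate_isotope_dataset <- function(config) {
  stopifnot(inherits(config, "isotope_sim_config"))
  stopifnot_simplex(config$true_p, tol = 1e-12)
  set.seed(config$seed)
  mo <- mixture_moments(config$true_p,
                        mixing_data_from_tables(config$sources, config$tdf))
  n <- config$n_consumers
  x <- vapply(1:2, function(j) {
    stats::rnorm(n, mo$mean[j], sqrt(mo$var[j] + config$residual_sd[j]^2))
  }, numeric(n))
  x <- matrix(x, nrow = n)
  list(consumers = data.frame(sample_id = sprintf("C%03d", seq_len(n)),
                              d13C = x[, 1], d15N = x[, 2]),
       truth = config$true_p, config = config)
}

#' Default Gulf of Cadiz isotope configuration
#'
#' Returns an [isotope_sim_config()] describing the Gulf of Cadiz bottlenose
#' dolphin study system: the four prey source groups with their published
#' isotope summaries (Sparidae-dominated Group 1; the hake / mackerel /
#' conger / red bandfish / pilchard Group 2; *Octopus vulgaris*; *Liza
#' ramada*) and 51 consumers. Diet-to-tissue discrimination factors are a
#' required user input — no published value ships with the package.
#'
#' @param tdf discrimination-factor table (see [isotope_sim_config()]);
#'   required, no default.
#' @param true_p generating diet proportions; defaults to the study's
#'   rounded posterior means for Groups 1 and 2 (0.52, 0.22) with the
#'   remainder split evenly over Groups 3 and 4.
#' @param n_consumers default 51.
#' @param residual_sd default `c(0, 0)`.
#' @param seed integer RNG seed.
#' @return an [isotope_sim_config()].
#' @export
default_gulf_config <- function(tdf, true_p = c(0.52, 0.22, 0.13, 0.13),
                                n_consumers = 51, residual_sd = c(0, 0),
                                seed = .default_seed) {
  if (missing(tdf))
    stop("tdf is required: discrimination factors are study-specific and ",
         "no default is provided")
  isotope_sim_config(true_p, cadiz_sources(), tdf, n_consumers,
                     residual_sd, seed)
}
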