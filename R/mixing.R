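# Bayesian mass-balance stable-isotope mixing model: Dirichlet prior on the
# diet-proportion simplex, Gaussian mass-balance likelihood with source and
# discrimination-factor uncertainty, optional residual error, sampled by
# additive-log-ratio random-walk Metropolis.

.isotopes <- c("d13C", "d15N")

# Assemble the internal model-data list from a source table and a TDF table.
# mu/sigma/lambda/tau are K x 2 matrices (columns d13C, d15N); a TDF without
# a group column is broadcast to every source.
mixing_data_from_tables <- function(sources, tdf) {
  stopifnot(is.data.frame(sources), nrow(sources) >= 1)
  K <- nrow(sources)
  mu <- cbind(sources$mean_d13C, sources$mean_d15N)
  sigma <- cbind(sources$sd_d13C, sources$sd_d15N)
  sigma[is.na(sigma)] <- 0
  lambda <- matrix(0, K, 2); tau <- matrix(0, K, 2)
  if (!is.null(tdf)) {
    stopifnot(all(c("isotope", "mean", "sd") %in% names(tdf)))
    for (j in 1:2) {
      rows <- tdf[tdf$isotope == .isotopes[j], ]
      if (nrow(rows) == 0) next
      if (!is.null(rows$group) && !all(is.na(rows$group))) {
        i <- match(sources$group, rows$group)
        lambda[, j] <- rows$mean[i]; tau[, j] <- rows$sd[i]
      } else {
        lambda[, j] <- rows$mean[1]; tau[, j] <- rows$sd[1]
      }
    }
  }
  if (any(sigma < 0) || any(tau < 0)) stop("sds must be nonnegative")
  list(K = K, groups = as.character(sources$group), mu = mu, sigma = sigma,
       lambda = lambda, tau = tau)
}

#' Mixture mean and variance implied by a diet proportion vector
#'
#' The mass-balance moments per isotope j:
#' \deqn{m_j = \sum_k p_k(\mu_{kj} + \lambda_{kj}), \quad
#'       v_j = \sum_k p_k^2(\sigma_{kj}^2 + \tau_{kj}^2)}
#' with source means/sds \eqn{\mu, \sigma} and discrimination-factor
#' means/sds \eqn{\lambda, \tau}.
#'
#' @param p diet proportions on the simplex.
#' @param data either a source table plus `tdf` (as in [isomix()]), or the
#'   internal list built by `mixing_data_from_tables()`.
#' @param tdf discrimination-factor table when `data` is a source table.
#' @return list with `mean` and `var`, each length 2 (d13C, d15N).
#' @export
mixture_moments <- function(p, data, tdf = NULL) {
  if (is.data.frame(data)) data <- mixing_data_from_tables(data, tdf)
  stopifnot_simplex(p)
  list(mean = as.vector(crossprod(p, data$mu + data$lambda)),
       var = as.vector(crossprod(p^2, data$sigma^2 + data$tau^2)))
}

# Log posterior density (up to a constant) at (p, xi).
# x: n x 2 consumer matrix. alpha: Dirichlet concentration (length K).
# xi_upper: upper bounds of the uniform priors on the residual sds.
mixing_log_posterior <- function(p, xi, x, data, alpha, xi_upper) {
  if (any(p <= 0) || abs(sum(p) - 1) > 1e-10) return(-Inf)
  if (any(xi < 0) || any(xi > xi_upper)) return(-Inf)
  mo <- mixture_moments(p, data)
  s <- sqrt(mo$var + xi^2)
  if (any(s <= 0)) return(-Inf)
  ll <- sum(stats::dnorm(x[, 1], mo$mean[1], s[1], log = TRUE)) +
        sum(stats::dnorm(x[, 2], mo$mean[2], s[2], log = TRUE))
  ll + sum((alpha - 1) * log(p))
}

# additive-log-ratio transform and inverse (last component is the reference)
alr <- function(p) log(p[-length(p)] / p[length(p)])
alr_inv <- function(z) {
  e <- exp(c(z, 0) - max(c(z, 0)))
  e / sum(e)
}

#' Fit a Bayesian stable-isotope mixing model
#'
#' Estimates the diet proportions `p` of a consumer population from d13C and
#' d15N values, a source-group summary table, and diet-to-tissue
#' discrimination factors (TDF). Consumer values are modelled per isotope as
#' \eqn{x_{ij} \sim N(m_j(p),\, \sqrt{v_j(p) + \xi_j^2})} with the
#' mass-balance moments of [mixture_moments()], a Dirichlet(\eqn{\alpha})
#' prior on `p`, and (optionally) a residual error sd \eqn{\xi_j} with a
#' Uniform(0, upper) prior.
#'
#' Sampling is random-walk Metropolis on the additive-log-ratio transform of
#' `p` (so every retained draw lies exactly on the simplex) and on
#' \eqn{\log \xi}; the proposal scales adapt toward a 20-40\% acceptance
#' rate during the first half of burn-in (50-draw batches, scale
#' multiplied/divided by 1.1) and are frozen afterwards. Chains use distinct
#' sub-seeds and are summarised with split-chain Gelman-Rubin diagnostics.
#'
#' @param consumers data.frame (or matrix) with columns `d13C`, `d15N`; may
#'   have zero rows, in which case the posterior is the prior.
#' @param sources data.frame with columns `group`, `mean_d13C`, `sd_d13C`,
#'   `mean_d15N`, `sd_d15N` (e.g. from [pool_groups()] or
#'   [cadiz_sources()]).
#' @param tdf discrimination factors: data.frame with columns `isotope`
#'   (`"d13C"`, `"d15N"`), `mean`, `sd`, and optionally `group` for
#'   per-source factors. Required (pass sds of 0 for a known-exact TDF).
#' @param chains number of MCMC chains (default 3).
#' @param burnin burn-in draws per chain (default 5000).
#' @param samples retained draws per chain before thinning (default 5000).
#' @param thin thinning interval (default 1).
#' @param prior_alpha Dirichlet concentration, scalar or length-K
#'   (default 1, uninformative).
#' @param residual include the residual error term \eqn{\xi_j}
#'   (default `TRUE`).
#' @param residual_sd_upper upper bound of the Uniform prior on
#'   \eqn{\xi_j}; default twice the consumer sd on each isotope.
#' @param proposal_scale initial random-walk step (default 0.5).
#' @param seed integer RNG seed.
#' @return an object of class `"isomix"`: list with `draws` (array
#'   `samples/thin` x parameters x chains), `accept` (per-chain acceptance
#'   rates), `rhat`, `data`, `consumers` and the call settings. Methods:
#'   [print.isomix()], [summary.isomix()], [coef.isomix()],
#'   [plot.isomix()], [simulate.isomix()].
#' @examples
#' tdf <- data.frame(isotope = c("d13C", "d15N"), mean = c(1, 1.6),
#'                   sd = c(0.4, 0.5))
#' sim <- simulate_isotope_dataset(default_gulf_config(tdf, seed = 1))
#' \donttest{
#' fit <- isomix(sim$consumers, cadiz_sources(), tdf, seed = 1)
#' summary(fit)
#' }
#' @export
isomix <- function(consumers, sources, tdf, chains = 3, burnin = 5000,
                   samples = 5000, thin = 1, prior_alpha = 1,
                   residual = TRUE, residual_sd_upper = NULL,
                   proposal_scale = 0.5, seed = .default_seed) {
  data <- mixing_data_from_tables(sources, tdf)
  K <- data$K
  if (K < 2) stop("at least 2 source groups are required")
  if (burnin < 1 || samples < 1) stop("burnin and samples must be >= 1")
  x <- as.matrix(as.data.frame(consumers)[, .isotopes, drop = FALSE])
  storage.mode(x) <- "double"
  alpha <- rep_len(prior_alpha, K)
  if (any(alpha <= 0)) stop("prior_alpha must be positive")
  if (is.null(residual_sd_upper)) {
    residual_sd_upper <- if (nrow(x) >= 2) 2 * apply(x, 2, stats::sd)
                         else c(5, 5)  # no consumer spread to scale from
  }
  xi_upper <- rep_len(residual_sd_upper, 2)
  n_keep <- samples %/% thin
  pn <- c(paste0("p_", data$groups), if (residual) paste0("xi_", .isotopes))
  draws <- array(NA_real_, c(n_keep, length(pn), chains),
                 dimnames = list(NULL, pn, NULL))
  accept <- matrix(NA_real_, chains, 2, dimnames = list(NULL, c("p", "xi")))

  lp_fun <- function(z, eta) {
    p <- alr_inv(z)
    xi <- if (residual) exp(eta) else c(0, 0)
    lp <- mixing_log_posterior(p, xi, x, data, alpha, xi_upper)
    # change of variables: ALR Jacobian, and log-scale Jacobian for xi
    lp + sum(log(p)) + if (residual) sum(eta) else 0
  }

  for (ch in seq_len(chains)) {
    set.seed(seed + 1000L * (ch - 1L))
    z <- rep(0, K - 1)
    eta <- if (residual) log(xi_upper / 4) else numeric(0)
    lp <- lp_fun(z, eta)
    tries <- 0
    while (!is.finite(lp) && tries < 100) {
      z <- alr(rdirichlet1(K, alpha))
      if (residual) eta <- log(stats::runif(2, 0, xi_upper))
      lp <- lp_fun(z, eta); tries <- tries + 1
    }
    if (!is.finite(lp)) stop("could not initialise chain ", ch,
                             ": posterior is non-finite everywhere tried")
    s_z <- proposal_scale; s_e <- proposal_scale
    acc_z <- 0L; acc_e <- 0L; bat_z <- 0L; bat_e <- 0L; n_post <- 0L
    total <- burnin + samples
    adapt_until <- burnin %/% 2
    kept <- 0L
    for (it in seq_len(total)) {
      zp <- z + s_z * stats::rnorm(K - 1)
      lpp <- lp_fun(zp, eta)
      if (is.finite(lpp) && log(stats::runif(1)) < lpp - lp) {
        z <- zp; lp <- lpp; bat_z <- bat_z + 1L
        if (it > burnin) acc_z <- acc_z + 1L
      }
      if (residual) {
        ep <- eta + s_e * stats::rnorm(2)
        lpp <- lp_fun(z, ep)
        if (is.finite(lpp) && log(stats::runif(1)) < lpp - lp) {
          eta <- ep; lp <- lpp; bat_e <- bat_e + 1L
          if (it > burnin) acc_e <- acc_e + 1L
        }
      }
      if (it <= adapt_until && it %% 50 == 0) {
        if (bat_z / 50 < 0.20) s_z <- s_z / 1.1
        else if (bat_z / 50 > 0.40) s_z <- s_z * 1.1
        if (residual) {
          if (bat_e / 50 < 0.20) s_e <- s_e / 1.1
          else if (bat_e / 50 > 0.40) s_e <- s_e * 1.1
        }
        bat_z <- 0L; bat_e <- 0L
      }
      if (it > burnin) {
        n_post <- n_post + 1L
        if (n_post %% thin == 0 && kept < n_keep) {
          kept <- kept + 1L
          draws[kept, seq_len(K), ch] <- alr_inv(z)
          if (residual) draws[kept, K + 1:2, ch] <- exp(eta)
        }
      }
    }
    accept[ch, ] <- c(acc_z, if (residual) acc_e else NA) / samples
  }

  out <- list(draws = draws, accept = accept, data = data, consumers = x,
              residual = residual, prior_alpha = alpha, xi_upper = xi_upper,
              chains = chains, burnin = burnin, samples = samples,
              thin = thin, seed = seed)
  out$rhat <- gelman_rubin(draws)
  class(out) <- "isomix"
  out
}

#' Split-chain Gelman-Rubin potential scale reduction factor
#'
#' Each chain is split in half, and R-hat is computed from the between- and
#' within-half variances; values near 1 indicate the chains agree. Chains
#' with zero variance (a parameter stuck at a constant) report 1 with a
#' warning.
#'
#' @param x an [isomix()] fit or a draws array (iterations x parameters x
#'   chains) with at least 2 chains and 4 draws each.
#' @return named numeric vector of R-hat values per parameter.
#' @export
gelman_rubin <- function(x) {
  if (inherits(x, "isomix")) x <- x$draws
  stopifnot(length(dim(x)) == 3)
  n <- dim(x)[1]; P <- dim(x)[2]; C <- dim(x)[3]
  if (C < 2 || n < 4) stop("need >= 2 chains with >= 4 draws each")
  half <- n %/% 2
  out <- vapply(seq_len(P), function(p) {
    segs <- list()
    for (ch in seq_len(C)) {
      segs[[2 * ch - 1]] <- x[1:half, p, ch]
      segs[[2 * ch]] <- x[(half + 1):(2 * half), p, ch]
    }
    m <- vapply(segs, mean, 0); v <- vapply(segs, stats::var, 0)
    W <- mean(v)
    if (W <= .Machine$double.eps * max(1, abs(mean(m)))^2) {
      warning("zero within-chain variance; R-hat reported as 1")
      return(1)
    }
    B_over_n <- stats::var(m)
    sqrt((half - 1) / half + B_over_n / W)
  }, numeric(1))
  names(out) <- dimnames(x)[[2]]
  out
}

#' Posterior summaries with nested central credible intervals
#'
#' @param object an [isomix()] fit (or a draws array).
#' @return data.frame per parameter: `mean`, `median`, and central 50, 75
#'   and 95\% interval bounds (`lo50` ... `hi95`).
#' @export
summarize_posterior <- function(object) {
  x <- if (inherits(object, "isomix")) object$draws else object
  flat <- apply(x, 2, c)
  out <- data.frame(parameter = colnames(flat),
                    mean = colMeans(flat),
                    median = apply(flat, 2, stats::median))
  for (lev in c(50, 75, 95)) {
    ci <- apply(flat, 2, central_interval, level = lev / 100)
    out[[paste0("lo", lev)]] <- ci[1, ]
    out[[paste0("hi", lev)]] <- ci[2, ]
  }
  rownames(out) <- NULL
  out
}

#' @export
print.isomix <- function(x, ...) {
  cat("Bayesian stable-isotope mixing model (", x$data$K, " sources, ",
      nrow(x$consumers), " consumers)\n", sep = "")
  cat(x$chains, "chains x", x$samples, "draws after", x$burnin,
      "burn-in; residual error:", if (x$residual) "yes" else "no", "\n")
  cat("Posterior mean diet proportions:\n")
  print(round(coef(x), 3))
  cat("Max split R-hat:", round(max(x$rhat), 3), "\n")
  invisible(x)
}

#' @export
summary.isomix <- function(object, ...) {
  s <- summarize_posterior(object)
  s$rhat <- object$rhat[s$parameter]
  class(s) <- c("summary.isomix", "data.frame")
  s
}

#' @export
print.summary.isomix <- function(x, ...) {
  print.data.frame(cbind(x["parameter"],
                         round(x[, setdiff(names(x), "parameter")], 4)),
                   row.names = FALSE)
  invisible(x)
}

#' @export
coef.isomix <- function(object, ...) {
  p <- colMeans(apply(object$draws, 2, c))
  p[seq_len(object$data$K)]
}

#' Credible-interval plot of estimated source contributions
#'
#' Draws the 95, 75 and 50\% central credible intervals (thin to thick
#' segments) and the posterior median per source group.
#'
#' @param x an [isomix()] fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.isomix <- function(x, ...) {
  s <- summarize_posterior(x)
  s <- s[seq_len(x$data$K), ]
  k <- nrow(s)
  graphics::plot(NA, xlim = c(0.5, k + 0.5), ylim = c(0, 1), xaxt = "n",
                 xlab = "source group", ylab = "diet proportion", ...)
  graphics::axis(1, at = seq_len(k), labels = sub("^p_", "", s$parameter))
  for (i in seq_len(k)) {
    graphics::segments(i, s$lo95[i], i, s$hi95[i], lwd = 1)
    graphics::segments(i, s$lo75[i], i, s$hi75[i], lwd = 3)
    graphics::segments(i, s$lo50[i], i, s$hi50[i], lwd = 6)
    graphics::points(i, s$median[i], pch = 19)
  }
  invisible(s)
}

#' Posterior-predictive simulation of consumer isotope values
#'
#' For each requested replicate, one retained posterior draw of `(p, xi)` is
#' selected at random and a consumer dataset of the original size is drawn
#' from the model likelihood.
#'
#' @param object an [isomix()] fit.
#' @param nsim number of replicate datasets.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return list of `nsim` data.frames with columns `d13C`, `d15N`.
#' @export
simulate.isomix <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  flat <- apply(object$draws, 2, c)
  n <- max(1L, nrow(object$consumers))
  K <- object$data$K
  lapply(seq_len(nsim), function(i) {
    d <- flat[sample.int(nrow(flat), 1), ]
    p <- d[seq_len(K)] / sum(d[seq_len(K)])
    xi <- if (object$residual) d[K + 1:2] else c(0, 0)
    mo <- mixture_moments(p, object$data)
    data.frame(d13C = stats::rnorm(n, mo$mean[1], sqrt(mo$var[1] + xi[1]^2)),
               d15N = stats::rnorm(n, mo$mean[2], sqrt(mo$var[2] + xi[2]^2)))
  })
}
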