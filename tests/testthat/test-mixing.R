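two_sources <- function(mu1 = c(-14, -14), mu2 = c(-22, -22),
                        sd1 = c(0.1, 0.1), sd2 = c(0.1, 0.1)) {
  data.frame(group = 1:2, mean_d13C = c(mu1[1], mu2[1]),
             sd_d13C = c(sd1[1], sd2[1]), mean_d15N = c(mu1[2], mu2[2]),
             sd_d15N = c(sd1[2], sd2[2]), n = 10)
}

test_that("mixture moments follow the mass-balance formulas", {
  src <- two_sources(c(-16, -16), c(-18, -18), c(0, 0), c(0, 0))
  mo <- mixture_moments(c(0.5, 0.5), src, NULL)
  expect_equal(mo$mean, c(-17, -17))
  expect_equal(mo$var, c(0, 0))

  # hand evaluation of the quadratic form: p=(0.25,0.75), mu=(0,4), sigma=2
  src2 <- data.frame(group = 1:2, mean_d13C = c(0, 4), sd_d13C = 2,
                     mean_d15N = c(0, 4), sd_d15N = 2, n = 5)
  mo2 <- mixture_moments(c(0.25, 0.75), src2, NULL)
  expect_equal(mo2$mean[1], 3)
  expect_equal(mo2$var[1], (0.0625 + 0.5625) * 4)

  # degenerate single source: moments are the corrected source's own
  src1 <- data.frame(group = 1, mean_d13C = -16, sd_d13C = 0.3,
                     mean_d15N = 12, sd_d15N = 0.4, n = 5)
  mo1 <- mixture_moments(1, src1, tdf_fixture())
  expect_equal(mo1$mean, c(-15, 13.6))
  expect_equal(mo1$var, c(0.3^2 + 0.4^2, 0.4^2 + 0.5^2))

  expect_error(mixture_moments(c(0.7, 0.7), src, NULL), "simplex")
})

test_that("log posterior equals an independent Gaussian density sum", {
  src <- two_sources(c(-15, 10), c(-20, 14), c(0.5, 0.3), c(0.4, 0.6))
  data <- dietmix:::mixing_data_from_tables(src, NULL)
  x <- rbind(c(-16.2, 11.1), c(-17.5, 12.0), c(-18.9, 13.4))
  p <- c(0.3, 0.7); xi <- c(0.2, 0.1)
  got <- dietmix:::mixing_log_posterior(p, xi, x, data,
                                        alpha = c(1, 1), xi_upper = c(5, 5))
  # oracle: write the two mixture moments and densities out longhand
  m1 <- 0.3 * -15 + 0.7 * -20; v1 <- 0.09 * 0.25 + 0.49 * 0.16
  m2 <- 0.3 * 10 + 0.7 * 14;  v2 <- 0.09 * 0.09 + 0.49 * 0.36
  oracle <- sum(dnorm(x[, 1], m1, sqrt(v1 + 0.04), log = TRUE)) +
    sum(dnorm(x[, 2], m2, sqrt(v2 + 0.01), log = TRUE))
  expect_equal(got, oracle, tolerance = 1e-12)

  # a flat Dirichlet prior leaves only likelihood differences
  p2 <- c(0.6, 0.4)
  got2 <- dietmix:::mixing_log_posterior(p2, xi, x, data,
                                         alpha = c(1, 1), xi_upper = c(5, 5))
  m1b <- 0.6 * -15 + 0.4 * -20; v1b <- 0.36 * 0.25 + 0.16 * 0.16
  m2b <- 0.6 * 10 + 0.4 * 14;  v2b <- 0.36 * 0.09 + 0.16 * 0.36
  oracle2 <- sum(dnorm(x[, 1], m1b, sqrt(v1b + 0.04), log = TRUE)) +
    sum(dnorm(x[, 2], m2b, sqrt(v2b + 0.01), log = TRUE))
  expect_equal(got - got2, oracle - oracle2, tolerance = 1e-10)

  # single observation at the mixture mean with unit total variance
  src0 <- two_sources(c(0, 0), c(0, 0), c(1, 1), c(1, 1))
  d0 <- dietmix:::mixing_data_from_tables(src0, NULL)
  p0 <- c(sqrt(0.5), 1 - sqrt(0.5))  # p1^2 + p2^2 gives v slightly < 1
  v0 <- sum(p0^2)
  ll <- dietmix:::mixing_log_posterior(p0, c(sqrt(1 - v0), 2),
                                       matrix(c(0, 2), 1, 2), d0,
                                       alpha = c(1, 1), xi_upper = c(5, 5))
  # isotope 1 sits exactly at its mean with total sd 1
  expect_equal(ll - dnorm(2, 0, sqrt(v0 + 4), log = TRUE),
               -0.5 * log(2 * pi), tolerance = 1e-12)

  expect_identical(dietmix:::mixing_log_posterior(c(0.5, 0.5), c(6, 0.1), x,
                                                  data, c(1, 1), c(5, 5)),
                   -Inf)
})

test_that("exchangeable sources share the posterior equally", {
  src <- two_sources(c(-17, 12), c(-17, 12), c(0.5, 0.5), c(0.5, 0.5))
  set.seed(5)
  cons <- data.frame(d13C = rnorm(20, -17, 0.5), d15N = rnorm(20, 12, 0.5))
  fit <- isomix(cons, src, NULL, chains = 3, burnin = 4000, samples = 4000,
                residual = FALSE, seed = 2)
  expect_lt(abs(coef(fit)[["p_1"]] - 0.5), 0.05)
})

test_that("with no consumers the posterior is the Dirichlet prior", {
  src <- two_sources()
  empty <- data.frame(d13C = numeric(0), d15N = numeric(0))
  fit <- isomix(empty, src, NULL, chains = 2, burnin = 2000, samples = 4000,
                prior_alpha = c(2, 6), residual = FALSE, seed = 3)
  expect_lt(abs(coef(fit)[["p_1"]] - 0.25), 0.03)  # alpha_1 / sum(alpha)
  expect_lt(abs(coef(fit)[["p_2"]] - 0.75), 0.03)
})

test_that("an uninformative isotope leaves the proportion posterior unchanged", {
  # isotope 2 identical across sources with zero source spread: its
  # likelihood depends only on the residual sd, so it factorises away from p
  src <- two_sources(c(-14, 12), c(-22, 12), c(0.8, 0), c(0.8, 0))
  set.seed(9)
  p_true <- 0.7
  cons <- data.frame(d13C = rnorm(40, p_true * -14 + 0.3 * -22,
                                  sqrt(p_true^2 + 0.3^2) * 0.8),
                     d15N = rnorm(40, 12, 0.2))
  fit <- isomix(cons, src, NULL, chains = 3, burnin = 4000, samples = 4000,
                residual = TRUE, residual_sd_upper = c(1, 1), seed = 4)
  # oracle: grid over (p1, xi1) using isotope 1 alone
  gr <- grid_posterior_p1_resid(cons$d13C, mu = c(-14, -22),
                                sigma = c(0.8, 0.8), xi_upper = 1)
  expect_lt(abs(coef(fit)[["p_1"]] - gr), 0.02)
})

test_that("every retained draw lies exactly on the simplex", {
  src <- two_sources()
  set.seed(1)
  cons <- data.frame(d13C = rnorm(10, -17, 1), d15N = rnorm(10, -17, 1))
  fit <- isomix(cons, src, NULL, chains = 2, burnin = 500, samples = 500,
                seed = 6)
  sums <- apply(fit$draws[, 1:2, ], c(1, 3), sum)
  expect_true(all(abs(sums - 1) < 1e-10))
  expect_true(all(fit$draws[, 1:2, ] >= 0))
  xi <- fit$draws[, 3:4, ]
  expect_true(all(xi >= 0))
})

test_that("split R-hat separates agreeing from disagreeing chains", {
  set.seed(77)
  agree <- array(rnorm(4000 * 2 * 3), c(4000, 2, 3),
                 dimnames = list(NULL, c("a", "b"), NULL))
  r <- gelman_rubin(agree)
  expect_true(all(r < 1.05))
  expect_named(r, c("a", "b"))

  apart <- agree
  apart[, 1, 2] <- apart[, 1, 2] + 10  # one chain centred elsewhere
  expect_gt(gelman_rubin(apart)[["a"]], 2)

  flat <- array(1, c(100, 1, 3), dimnames = list(NULL, "p", NULL))
  expect_warning(r0 <- gelman_rubin(flat), "zero")
  expect_equal(unname(r0), 1)
  expect_error(gelman_rubin(agree[, , 1, drop = FALSE]), "2 chains")
})

test_that("split R-hat agrees with an independent implementation", {
  skip_if_not_installed("coda")
  set.seed(123)
  x <- array(rnorm(3000 * 1 * 3, sd = 2), c(3000, 1, 3),
             dimnames = list(NULL, "p", NULL))
  mine <- gelman_rubin(x)[["p"]]
  cl <- coda::mcmc.list(lapply(1:3, function(ch) coda::mcmc(x[, 1, ch])))
  ref <- coda::gelman.diag(cl, autoburnin = FALSE)$psrf[1, 1]
  expect_lt(abs(mine - ref), 0.02)
})

test_that("posterior summaries give nested central intervals", {
  const <- array(0.4, c(50, 1, 2), dimnames = list(NULL, "p_1", NULL))
  s <- summarize_posterior(const)
  expect_equal(s$lo95, 0.4); expect_equal(s$hi50, 0.4)

  set.seed(8)
  unif <- array(runif(20000), c(10000, 1, 2),
                dimnames = list(NULL, "p_1", NULL))
  su <- summarize_posterior(unif)
  expect_lt(abs(su$lo95 - 0.025), 0.01)
  expect_lt(abs(su$hi95 - 0.975), 0.01)
  expect_true(su$lo95 <= su$lo75 && su$lo75 <= su$lo50)
  expect_true(su$hi50 <= su$hi75 && su$hi75 <= su$hi95)
})

test_that("constructor rejects invalid inputs", {
  src <- two_sources()
  cons <- data.frame(d13C = -17, d15N = -17)
  expect_error(isomix(cons, src[1, ], NULL), "2 source groups")
  expect_error(isomix(cons, src, NULL, prior_alpha = 0), "positive")
  expect_error(isomix(cons, src, NULL, burnin = 0), "burnin")
})
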