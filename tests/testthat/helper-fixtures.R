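# Shared fixtures and independent oracles, all built in code.

# Three-stomach toy for prey-specific abundance (hand-computable):
# stomach 1 holds A (10 g) and B (30 g); stomach 2 holds A (5 g);
# stomach 3 holds B (20 g).
toy_occurrences <- function() {
  data.frame(stomach_id = c("s1", "s1", "s2", "s3"),
             taxon = c("A", "B", "A", "B"),
             family = c("fA", "fB", "fA", "fB"),
             class = "Teleost",
             n_individuals = c(1L, 1L, 1L, 1L),
             total_weight_g = c(10, 30, 5, 20))
}

# Minimal regression table: identity-ish linear length model and a cubic
# weight law, at species and group scope, plus a beak entry.
toy_regressions <- function() {
  data.frame(
    taxon = c("sprat", "fishfam", "squidsp"),
    scope = c("species", "group", "species"),
    input_structure = c("otolith", "otolith", "lower_beak"),
    measurement_kind = c("otolith_length", "otolith_length", "hood_length"),
    length_form = "linear",
    length_a = c(0, 5, 0),
    length_b = c(10, 8, 20),
    weight_c = c(0.01, 0.02, 0.05),
    weight_d = c(3, 3, 2.5))
}

toy_taxa <- function() {
  data.frame(taxon = c("sprat", "gobby", "squidsp"),
             family = c("fishfam", "fishfam", "squidfam"),
             class = c("Teleost", "Teleost", "Cephalopod"),
             structure = c("otolith", "otolith", "beak"),
             length_mean_mm = c(120, 60, 80),
             length_sd_mm = c(15, 8, 10))
}

tdf_fixture <- function() {
  data.frame(isotope = c("d13C", "d15N"), mean = c(1.0, 1.6),
             sd = c(0.4, 0.5))
}

# Independent 1-D grid integration of the K = 2 mixing posterior over p1
# (flat prior, no residual term). Returns posterior mean and sd of p1.
grid_posterior_p1 <- function(x, mu, sigma, lambda = matrix(0, 2, 2),
                              tau = matrix(0, 2, 2), ngrid = 1e4) {
  p1 <- (seq_len(ngrid) - 0.5) / ngrid
  ll <- numeric(ngrid)
  for (j in 1:2) {
    m <- p1 * (mu[1, j] + lambda[1, j]) + (1 - p1) * (mu[2, j] + lambda[2, j])
    v <- p1^2 * (sigma[1, j]^2 + tau[1, j]^2) +
      (1 - p1)^2 * (sigma[2, j]^2 + tau[2, j]^2)
    for (i in seq_len(nrow(x)))
      ll <- ll + dnorm(x[i, j], m, sqrt(v), log = TRUE)
  }
  w <- exp(ll - max(ll))
  w <- w / sum(w)
  mean <- sum(w * p1)
  list(mean = mean, sd = sqrt(sum(w * (p1 - mean)^2)))
}

# 2-D grid integration over (p1, xi1) for a K = 2, single-isotope mixing
# posterior with flat Dirichlet prior and Uniform(0, xi_upper) residual
# prior. Returns the marginal posterior mean of p1.
grid_posterior_p1_resid <- function(x1, mu, sigma, xi_upper, ngrid = 300) {
  p1 <- (seq_len(ngrid) - 0.5) / ngrid
  xi <- xi_upper * (seq_len(ngrid) - 0.5) / ngrid
  m <- p1 * mu[1] + (1 - p1) * mu[2]
  v <- p1^2 * sigma[1]^2 + (1 - p1)^2 * sigma[2]^2
  lw <- matrix(0, ngrid, ngrid)  # rows p1, cols xi
  for (j in seq_len(ngrid)) {
    s <- sqrt(v + xi[j]^2)
    for (i in seq_along(x1)) lw[, j] <- lw[, j] + dnorm(x1[i], m, s, log = TRUE)
  }
  w <- exp(lw - max(lw))
  sum(rowSums(w) * p1) / sum(w)
}

# Gift-wrapping (Jarvis march) convex hull, an O(n h) oracle independent of
# grDevices::chull. Returns the vertex set (unordered matrix of rows).
jarvis_hull <- function(pts) {
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  if (n <= 2) return(pts)
  start <- which.min(pts[, 2] + 1e-9 * pts[, 1])
  hull <- integer(0)
  cur <- start
  repeat {
    hull <- c(hull, cur)
    cand <- if (cur == 1) 2 else 1
    for (i in seq_len(n)) {
      if (i == cur) next
      cr <- (pts[cand, 1] - pts[cur, 1]) * (pts[i, 2] - pts[cur, 2]) -
        (pts[cand, 2] - pts[cur, 2]) * (pts[i, 1] - pts[cur, 1])
      d_i <- sum((pts[i, ] - pts[cur, ])^2)
      d_c <- sum((pts[cand, ] - pts[cur, ])^2)
      if (cand == cur || cr < 0 || (abs(cr) < 1e-12 && d_i > d_c)) cand <- i
    }
    cur <- cand
    if (cur == start) break
    if (length(hull) > n) stop("jarvis march failed to terminate")
  }
  pts[hull, , drop = FALSE]
}

# canonical form for comparing hull vertex sets
sorted_rows <- function(m) {
  m <- round(as.matrix(m), 9)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}
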