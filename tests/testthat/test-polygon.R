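tri_sources <- function(sd = 0) {
  data.frame(group = 1:3, mean_d13C = c(-20, -14, -17),
             sd_d13C = sd, mean_d15N = c(10, 10, 16), sd_d15N = sd, n = 10)
}

test_that("corrected source draws honour means, seeds and combined scatter", {
  src <- tri_sources(0)
  tdf0 <- data.frame(isotope = c("d13C", "d15N"), mean = c(1, 2), sd = 0)
  d1 <- corrected_source_draw(src, tdf0)
  expect_equal(unname(d1[, 1]), src$mean_d13C + 1)
  expect_equal(unname(d1[, 2]), src$mean_d15N + 2)

  set.seed(42); a <- corrected_source_draw(tri_sources(0.5), tdf_fixture())
  set.seed(42); b <- corrected_source_draw(tri_sources(0.5), tdf_fixture())
  expect_identical(a, b)

  # empirical sd of one source's draws matches sqrt(sigma^2 + tau^2)
  set.seed(7)
  draws <- replicate(1e4,
    corrected_source_draw(tri_sources(0.5), tdf_fixture())[1, 1])
  target <- sqrt(0.5^2 + 0.4^2)
  se <- target / sqrt(2 * (1e4 - 1))
  expect_lt(abs(sd(draws) - target), 3 * se)

  # standard-error option shrinks the scatter by sqrt(n)
  set.seed(7)
  draws_sem <- replicate(1e3,
    corrected_source_draw(tri_sources(0.5), NULL, use_sem = TRUE)[1, 1])
  expect_lt(sd(draws_sem), 0.5)
})

test_that("convex hull handles triangles, interior points and degeneracies", {
  tri <- rbind(c(0, 0), c(4, 0), c(0, 3))
  h <- convex_hull(tri)
  expect_equal(nrow(h), 3L)
  expect_equal(sorted_rows(h), sorted_rows(tri))

  sq <- rbind(tri, c(1, 1))  # fourth point inside the triangle
  expect_equal(nrow(convex_hull(sq)), 3L)

  seg <- convex_hull(rbind(c(0, 0), c(1, 1), c(2, 2)))
  expect_equal(nrow(seg), 2L)
  expect_equal(sorted_rows(seg), sorted_rows(rbind(c(0, 0), c(2, 2))))

  pt <- convex_hull(rbind(c(1, 2), c(1, 2)))
  expect_equal(nrow(pt), 1L)

  # counter-clockwise orientation: positive signed area
  h2 <- convex_hull(matrix(rnorm(40), ncol = 2))
  i2 <- c(seq_len(nrow(h2))[-1], 1)
  area2 <- sum(h2[, 1] * h2[i2, 2] - h2[i2, 1] * h2[, 2])
  expect_gt(area2, 0)
})

test_that("convex hull matches a gift-wrapping oracle on random instances", {
  for (s in 1:5) {
    set.seed(s)
    pts <- matrix(rnorm(200), ncol = 2)
    expect_equal(sorted_rows(convex_hull(pts)),
                 sorted_rows(jarvis_hull(pts)),
                 info = paste("seed", s))
  }
})

test_that("point-in-polygon counts boundaries as inside", {
  tri <- convex_hull(rbind(c(0, 0), c(4, 0), c(0, 3)))
  expect_true(point_in_polygon(c(4 / 3, 1), tri))      # centroid
  expect_true(point_in_polygon(c(4, 0), tri))          # vertex
  expect_true(point_in_polygon(c(2, 0), tri))          # edge midpoint
  expect_false(point_in_polygon(c(5, 0), tri))         # beyond max x
  expect_equal(point_in_polygon(rbind(c(1, 1), c(9, 9)), tri),
               c(TRUE, FALSE))
  seg <- convex_hull(rbind(c(0, 0), c(2, 2)))
  expect_true(point_in_polygon(c(1, 1), seg))
  expect_false(point_in_polygon(c(1, 1.1), seg))
})

test_that("polygon probabilities hit the trivial extremes", {
  src <- tri_sources(1e-6)
  tdf0 <- data.frame(isotope = c("d13C", "d15N"), mean = 0, sd = 1e-6)
  centroid <- data.frame(sample_id = "c", d13C = -17, d15N = 12)
  pg <- mixing_polygon(centroid, src, tdf0, n_iter = 200, seed = 1)
  expect_equal(pg$probabilities$probability, 1)
  expect_true(pg$overall_pass)

  far <- data.frame(sample_id = "f", d13C = -4, d15N = 26)
  pg2 <- mixing_polygon(far, src, tdf0, n_iter = 200, seed = 1)
  expect_equal(pg2$probabilities$probability, 0)
  expect_false(pg2$overall_pass)
})

test_that("probability estimates behave like binomial proportions", {
  src <- tri_sources(0.8)
  # a consumer near the hull edge so its inclusion probability is moderate
  edge <- data.frame(sample_id = "e", d13C = -17, d15N = 9.8)
  probs <- vapply(1:25, function(s)
    mixing_polygon(edge, src, NULL, n_iter = 150,
                   seed = s)$probabilities$probability, numeric(1))
  q <- mean(probs)
  expect_true(q > 0.1 && q < 0.9)  # genuinely intermediate
  expect_lt(abs(sd(probs) - sqrt(q * (1 - q) / 150)),
            3 * sqrt(q * (1 - q) / 150))
})

test_that("inflating source scatter cannot strand an outside consumer", {
  base <- tri_sources(0.3)
  outside <- data.frame(sample_id = "o", d13C = -17, d15N = 8.8)
  p_small <- mean(vapply(1:10, function(s)
    mixing_polygon(outside, base, NULL, n_iter = 300,
                   seed = s)$probabilities$probability, numeric(1)))
  wide <- tri_sources(0.9)
  p_large <- mean(vapply(1:10, function(s)
    mixing_polygon(outside, wide, NULL, n_iter = 300,
                   seed = s)$probabilities$probability, numeric(1)))
  expect_gte(p_large, p_small)
})

test_that("design validation reports failing consumers and vacuous passes", {
  src <- tri_sources(1e-6)
  two <- data.frame(sample_id = c("in", "out"), d13C = c(-17, -4),
                    d15N = c(12, 26))
  pg <- mixing_polygon(two, src, NULL, n_iter = 100, seed = 2)
  v <- validate_design(pg)
  expect_false(v$pass)
  expect_equal(v$failing$sample_id, "out")

  none <- data.frame(sample_id = character(0), d13C = numeric(0),
                     d15N = numeric(0))
  pg0 <- mixing_polygon(none, src, NULL, n_iter = 50, seed = 3)
  expect_warning(v0 <- validate_design(pg0), "vacuous")
  expect_true(v0$pass)

  expect_error(mixing_polygon(two, src, NULL, n_iter = 0), "n_iter")
  expect_error(mixing_polygon(two, src, NULL, threshold = 1.5), "threshold")
})

test_that("probability surface is populated on request", {
  src <- tri_sources(0.3)
  cons <- data.frame(sample_id = "c", d13C = -17, d15N = 12)
  pg <- mixing_polygon(cons, src, NULL, n_iter = 60, seed = 4,
                       surface = TRUE, grid_res = 40)
  expect_equal(dim(pg$surface), c(40L, 40L))
  expect_true(all(pg$surface >= 0 & pg$surface <= 1))
  # the surface peaks inside the source triangle
  expect_gt(max(pg$surface), 0.9)
})
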