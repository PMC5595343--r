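# Mixing-polygon simulation: Monte-Carlo hulls of TDF-corrected source
# draws, per-consumer inside probability, 10%-level contour surface, and the
# 95%-mixing-region pass/fail rule.

#' One Monte-Carlo draw of the TDF-corrected source locations
#'
#' Each source k is drawn independently per isotope j from
#' \eqn{N(\mu_{kj} + \lambda_{kj}, \sqrt{\sigma_{kj}^2 + \tau_{kj}^2})},
#' i.e. the combined source + discrimination-factor uncertainty. With
#' `use_sem = TRUE` the source sd is replaced by its standard error
#' \eqn{\sigma/\sqrt{n}} (requires an `n` column in the source table).
#'
#' @param data source table plus `tdf` as in [isomix()], or the internal
#'   list from `mixing_data_from_tables()`.
#' @param tdf discrimination-factor table when `data` is a source table.
#' @param use_sem draw source scatter from standard errors instead of sds.
#' @param n per-source sample sizes (needed only with `use_sem` and an
#'   internal-list `data`).
#' @return K x 2 matrix of (d13C, d15N) points.
#' @export
corrected_source_draw <- function(data, tdf = NULL, use_sem = FALSE,
                                  n = NULL) {
  if (is.data.frame(data)) {
    n <- data$n
    data <- mixing_data_from_tables(data, tdf)
  }
  sigma <- data$sigma
  if (use_sem) {
    if (is.null(n)) stop("use_sem requires per-source sample sizes")
    sigma <- sigma / sqrt(n)
  }
  sd <- sqrt(sigma^2 + data$tau^2)
  m <- data$mu + data$lambda
  matrix(stats::rnorm(length(m), m, sd), nrow = data$K,
         dimnames = list(data$groups, .isotopes))
}

#' Convex hull of 2-D points, counter-clockwise
#'
#' Returns the hull vertices in counter-clockwise order with collinear
#' interior points removed. Degenerate inputs are handled: identical points
#' give a single-point "hull", collinear points the two extreme endpoints.
#'
#' @param points matrix (or data.frame) with 2 columns.
#' @return matrix of hull vertices (2 columns), counter-clockwise.
#' @export
convex_hull <- function(points) {
  pts <- unique(as.matrix(points))
  if (nrow(pts) == 1) return(pts)
  # collinearity check: cross products against the longest chord ~ 0
  d <- sweep(pts, 2, pts[1, ])
  span <- max(abs(d))
  dirv <- d[which.max(rowSums(d^2)), ]
  cr <- d[, 1] * dirv[2] - d[, 2] * dirv[1]
  if (all(abs(cr) <= 1e-12 * max(1, span^2))) {
    proj <- d %*% dirv
    return(pts[c(which.min(proj), which.max(proj)), , drop = FALSE])
  }
  h <- grDevices::chull(pts[, 1], pts[, 2])  # clockwise order
  pts[rev(h), , drop = FALSE]
}

#' Point-in-convex-polygon test (boundary counts as inside)
#'
#' Orientation-test based: a point is inside a counter-clockwise convex
#' polygon iff it lies on the left of (or on) every edge, within a 1e-12
#' relative tolerance. Degenerate hulls (segment or single point) test
#' distance to the segment/point.
#'
#' @param point length-2 numeric, or an n x 2 matrix of points.
#' @param polygon hull vertices from [convex_hull()].
#' @return logical (vector).
#' @export
point_in_polygon <- function(point, polygon) {
  pts <- if (is.null(dim(point))) matrix(point, ncol = 2) else as.matrix(point)
  poly <- as.matrix(polygon)
  m <- nrow(poly)
  scale <- max(1, abs(poly))
  tol <- 1e-12 * scale^2
  if (m == 1)
    return(sqrt((pts[, 1] - poly[1, 1])^2 + (pts[, 2] - poly[1, 2])^2) <=
             1e-12 * scale)
  if (m == 2) {
    a <- poly[1, ]; b <- poly[2, ]
    ab <- b - a
    t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / sum(ab^2)
    t <- pmin(1, pmax(0, t))
    dx <- pts[, 1] - (a[1] + t * ab[1]); dy <- pts[, 2] - (a[2] + t * ab[2])
    return(sqrt(dx^2 + dy^2) <= 1e-12 * scale)
  }
  inside <- rep(TRUE, nrow(pts))
  for (i in seq_len(m)) {
    a <- poly[i, ]; b <- poly[if (i == m) 1 else i + 1, ]
    cr <- (b[1] - a[1]) * (pts[, 2] - a[2]) - (b[2] - a[2]) * (pts[, 1] - a[1])
    inside <- inside & (cr >= -tol)
  }
  inside
}

#' Mixing-polygon simulation
#'
#' Validates a mixing-model design: over `n_iter` Monte-Carlo iterations a
#' polygon (convex hull) is built from TDF-corrected source draws and every
#' consumer is tested for inclusion; a consumer's probability is the
#' fraction of polygons containing it. A consumer passes the 95\%
#' mixing-region rule iff its probability is at least `threshold`
#' (default 0.05), i.e. it is excluded from fewer than 95\% of simulated
#' polygons; the design passes iff every consumer passes.
#'
#' @param consumers data.frame with columns `d13C`, `d15N` (and optionally
#'   `sample_id`).
#' @param sources source table as in [isomix()].
#' @param tdf discrimination-factor table as in [isomix()].
#' @param n_iter Monte-Carlo iterations (default 1500; at least 100 for
#'   stable contours).
#' @param threshold inclusion probability defining the mixing region
#'   (default 0.05).
#' @param seed integer RNG seed.
#' @param use_sem see [corrected_source_draw()].
#' @param surface also evaluate the probability surface on a regular grid
#'   spanning the data extent plus 1 permil (for 10\%-level contours).
#' @param grid_res grid resolution per axis (default 200).
#' @return object of class `"mixing_polygon"`: list with `probabilities`
#'   (data.frame `sample_id`, `probability`, `pass`), `overall_pass`,
#'   `threshold`, and if requested `grid_x`, `grid_y`, `surface` (matrix of
#'   inside probabilities).
#' @seealso [validate_design()], [plot.mixing_polygon()]
#' @export
mixing_polygon <- function(consumers, sources, tdf, n_iter = 1500,
                           threshold = 0.05, seed = .default_seed,
                           use_sem = FALSE, surface = FALSE,
                           grid_res = 200) {
  if (n_iter < 1) stop("n_iter must be >= 1")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  cons <- as.data.frame(consumers)
  ids <- if (!is.null(cons$sample_id)) as.character(cons$sample_id)
         else sprintf("C%03d", seq_len(nrow(cons)))
  pts <- as.matrix(cons[, .isotopes, drop = FALSE])
  data <- mixing_data_from_tables(sources, tdf)
  set.seed(seed)
  hits <- rep(0L, nrow(pts))
  grid <- NULL; ghits <- NULL
  if (surface) {
    ext <- rbind(data$mu + data$lambda, pts)
    gx <- seq(min(ext[, 1]) - 1, max(ext[, 1]) + 1, length.out = grid_res)
    gy <- seq(min(ext[, 2]) - 1, max(ext[, 2]) + 1, length.out = grid_res)
    grid <- cbind(rep(gx, times = grid_res), rep(gy, each = grid_res))
    ghits <- rep(0L, nrow(grid))
  }
  for (it in seq_len(n_iter)) {
    hull <- convex_hull(corrected_source_draw(data, use_sem = use_sem,
                                              n = sources$n))
    if (nrow(pts)) hits <- hits + point_in_polygon(pts, hull)
    if (surface) ghits <- ghits + point_in_polygon(grid, hull)
  }
  prob <- if (nrow(pts)) hits / n_iter else numeric(0)
  out <- list(probabilities = data.frame(sample_id = ids, probability = prob,
                                         pass = prob >= threshold),
              overall_pass = all(prob >= threshold),
              threshold = threshold, n_iter = n_iter,
              sources = sources, tdf = tdf, consumers = cons)
  if (surface) {
    out$grid_x <- gx; out$grid_y <- gy
    out$surface <- matrix(ghits / n_iter, grid_res, grid_res)
  }
  class(out) <- "mixing_polygon"
  out
}

#' Pass/fail report for a mixing-polygon simulation
#'
#' The design is accepted iff every consumer's inside probability reaches
#' the inclusion threshold; failing consumers are listed. An empty consumer
#' set passes vacuously, with a warning.
#'
#' @param result a [mixing_polygon()] result.
#' @return list with `pass` (logical), `n_fail`, and `failing` (data.frame
#'   of failing consumers).
#' @export
validate_design <- function(result) {
  stopifnot(inherits(result, "mixing_polygon"))
  pr <- result$probabilities
  if (nrow(pr) == 0) {
    warning("no consumers: design passes vacuously")
    return(list(pass = TRUE, n_fail = 0L, failing = pr))
  }
  failing <- pr[!pr$pass, , drop = FALSE]
  list(pass = nrow(failing) == 0, n_fail = nrow(failing), failing = failing)
}

#' @export
print.mixing_polygon <- function(x, ...) {
  pr <- x$probabilities
  cat("Mixing-polygon simulation:", x$n_iter, "iterations,",
      nrow(pr), "consumers\n")
  if (nrow(pr)) {
    cat(sprintf("inside probability: min %.3f, median %.3f, max %.3f\n",
                min(pr$probability), stats::median(pr$probability),
                max(pr$probability)))
    cat(sum(!pr$pass), " consumer(s) outside the ",
        100 * (1 - x$threshold), "% mixing region\n", sep = "")
  }
  cat("overall:", if (x$overall_pass) "PASS" else "FAIL", "\n")
  invisible(x)
}

#' Contour plot of the mixing-polygon probability surface
#'
#' Consumers as points, TDF-corrected source means as crosses, probability
#' contours every 10\% level (requires the fit to have been run with
#' `surface = TRUE`).
#'
#' @param x a [mixing_polygon()] result.
#' @param ... passed to [graphics::contour()].
#' @export
plot.mixing_polygon <- function(x, ...) {
  if (is.null(x$surface))
    stop("re-run mixing_polygon() with surface = TRUE to plot contours")
  graphics::contour(x$grid_x, x$grid_y, x$surface,
                    levels = seq(0.1, 0.9, 0.1),
                    xlab = expression(delta^13 * C),
                    ylab = expression(delta^15 * N), ...)
  pts <- as.matrix(x$consumers[, .isotopes])
  graphics::points(pts, pch = 16, cex = 0.6)
  d <- mixing_data_from_tables(x$sources, x$tdf)
  graphics::points(d$mu + d$lambda, pch = 4, lwd = 2)
  invisible(x)
}
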