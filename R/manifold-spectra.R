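#' Laplace-Beltrami spectrum of the unit-circumference circle
#'
#' Builds the spectral description of the circle parameterized by
#' `theta` in `[0, 1)` (circumference 1, volume `V = 1`).  Eigenvalues of
#' the (negative) Laplace-Beltrami operator come in levels indexed by the
#' frequency `l`: `lambda_l = 4 * pi^2 * l^2`, with multiplicity 1 at
#' `l = 0` and 2 for `l >= 1` (sine and cosine eigenfunctions).  The
#' level-`l` addition kernel, the sum of products of the eigenfunctions
#' within the level, depends only on the geodesic separation `t`:
#' `A_0(t) = 1` and `A_l(t) = 2 * cos(2 * pi * l * t)` for `l >= 1`, so
#' that `A_l(0) = m_l / V`.
#'
#' @param max_level largest level (frequency) to tabulate; non-negative
#'   integer.
#' @return an object of class `manifold_spectrum` with elements
#'   `manifold`, `d`, `volume`, `level`, `lambda`, `mult`, `max_level`.
#' @examples
#' sp <- circle_spectrum(4)
#' sp$lambda / (4 * pi^2)  # 0, 1, 4, 9, 16
#' @seealso [sphere_spectrum()], [addition_kernels()]
#' @export
circle_spectrum <- function(max_level) {
  max_level <- check_count(max_level, "max_level")
  l <- 0:max_level
  structure(
    list(
      manifold = "circle", d = 1L, volume = 1,
      level = l,
      lambda = 4 * pi^2 * l^2,
      mult = ifelse(l == 0L, 1L, 2L),
      max_level = max_level
    ),
    class = "manifold_spectrum"
  )
}

#' Laplace-Beltrami spectrum of the unit 2-sphere
#'
#' Spectral description of the unit sphere (radius 1, volume
#' `V = 4 * pi`).  Level `l` has eigenvalue `lambda_l = l * (l + 1)` and
#' multiplicity `m_l = 2 * l + 1` (the spherical harmonics of degree
#' `l`).  By the addition theorem the level-`l` addition kernel is
#' `A_l(t) = (2 * l + 1) * P_l(cos(t)) / (4 * pi)` where `P_l` is the
#' Legendre polynomial of degree `l`, so `A_l(0) = m_l / V`.
#'
#' @inheritParams circle_spectrum
#' @return an object of class `manifold_spectrum`; see
#'   [circle_spectrum()].
#' @export
sphere_spectrum <- function(max_level) {
  max_level <- check_count(max_level, "max_level")
  l <- 0:max_level
  structure(
    list(
      manifold = "sphere", d = 2L, volume = 4 * pi,
      level = l,
      lambda = l * (l + 1),
      mult = 2L * l + 1L,
      max_level = max_level
    ),
    class = "manifold_spectrum"
  )
}

#' @export
print.manifold_spectrum <- function(x, ...) {
  cat(sprintf(
    "<manifold_spectrum> %s (d = %d, V = %.6g), levels 0..%d, lambda up to %.6g\n",
    x$manifold, x$d, x$volume, x$max_level, max(x$lambda)
  ))
  invisible(x)
}

# Shared spectrum constructor from a manifold name.
spectrum_for <- function(manifold, max_level) {
  switch(manifold,
    circle = circle_spectrum(max_level),
    sphere = sphere_spectrum(max_level),
    stop("unknown manifold: ", manifold)
  )
}

#' Legendre polynomials by the three-term recurrence
#'
#' Evaluates `P_0(z), ..., P_lmax(z)` by the stable Bonnet recurrence
#' `(l + 1) P_{l+1} = (2l + 1) z P_l - l P_{l-1}`.
#'
#' @param z numeric vector in `[-1, 1]`.
#' @param lmax largest degree.
#' @param max_degree guard on the recurrence depth; degrees above it are
#'   refused with an error (raise it explicitly for deep truncation
#'   studies).
#' @return a `length(z)` by `lmax + 1` matrix, column `l + 1` holding
#'   `P_l(z)`.
#' @export
legendre_poly <- function(z, lmax, max_degree = 512L) {
  lmax <- check_count(lmax, "lmax")
  if (lmax > max_degree) {
    stop("Legendre degree ", lmax, " exceeds max_degree = ", max_degree,
         "; raise `max_degree` if the recurrence depth is intended")
  }
  if (any(abs(z) > 1 + 1e-12)) stop("Legendre argument must lie in [-1, 1]")
  z <- pmin(1, pmax(-1, z))
  out <- matrix(0, length(z), lmax + 1L)
  out[, 1L] <- 1
  if (lmax >= 1L) out[, 2L] <- z
  if (lmax >= 2L) {
    for (l in 1:(lmax - 1L)) {
      out[, l + 2L] <- ((2 * l + 1) * z * out[, l + 1L] - l * out[, l]) / (l + 1)
    }
  }
  out
}

#' Addition kernels of a manifold spectrum
#'
#' Evaluates the level-wise addition kernels `A_l(t)` at geodesic
#' separations `t`.  Circle: `A_0 = 1`, `A_l(t) = 2 cos(2 pi l t)`.
#' Sphere: `A_l(t) = (2l + 1) P_l(cos t) / (4 pi)`.  In both cases
#' `A_l(0) = m_l / V`.
#'
#' @param spectrum a [circle_spectrum()] or [sphere_spectrum()] object.
#' @param t numeric vector of geodesic separations (circle: `[0, 1/2]`,
#'   values in `[0, 1)` are folded; sphere: `[0, pi]`).
#' @param max_degree passed to [legendre_poly()] for the sphere.
#' @return a `length(t)` by `max_level + 1` matrix of kernel values.
#' @export
addition_kernels <- function(spectrum, t, max_degree = 512L) {
  stopifnot(inherits(spectrum, "manifold_spectrum"))
  if (spectrum$manifold == "circle") {
    out <- 2 * cos(2 * pi * outer(t, spectrum$level))
    out[, 1L] <- 1
    out
  } else {
    P <- legendre_poly(cos(t), spectrum$max_level, max_degree = max_degree)
    sweep(P, 2L, (2 * spectrum$level + 1) / (4 * pi), "*")
  }
}

#' Geodesic distance on the circle or sphere
#'
#' Circle points are angles `theta` in `[0, 1)`; the distance is
#' `min(D, 1 - D)` with `D = |theta_x - theta_y| mod 1`, so it lies in
#' `[0, 1/2]`.  Sphere points are unit 3-vectors; the distance is the
#' arc length `acos(<x, y>)` in `[0, pi]`.
#'
#' @param manifold `"circle"`, `"sphere"`, or a `manifold_spectrum`.
#' @param x,y circle: numeric vectors of angles; sphere: unit 3-vectors
#'   (or matrices with one point per row).
#' @return vector (or matrix, if `x` and `y` have several points) of
#'   geodesic distances.
#' @examples
#' geodesic_distance("circle", 0.9, 0.1)  # wrap-around: 0.2
#' @export
geodesic_distance <- function(manifold, x, y) {
  name <- manifold_name(manifold)
  if (name == "circle") {
    delta <- abs(outer(as.numeric(x), as.numeric(y), "-")) %% 1
    drop(pmin(delta, 1 - delta))
  } else {
    x <- as_sphere_points(x)
    y <- as_sphere_points(y)
    ip <- tcrossprod(x, y)
    drop(acos(pmin(pmax(ip, -1), 1)))
  }
}

manifold_name <- function(manifold) {
  if (inherits(manifold, "manifold_spectrum")) return(manifold$manifold)
  match.arg(manifold, c("circle", "sphere"))
}

as_sphere_points <- function(x, tol = 1e-8) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != 3L) stop("sphere points must be unit 3-vectors")
  nrm <- sqrt(rowSums(x^2))
  if (any(abs(nrm - 1) > tol)) {
    stop("sphere points must have unit norm (largest deviation ",
         format(max(abs(nrm - 1))), ")")
  }
  x / nrm
}

check_count <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 0 || x != floor(x)) {
    stop("`", name, "` must be a single non-negative integer")
  }
  as.integer(x)
}

#' Construct a design set on a manifold
#'
#' A design set is an ordered collection of points together with its
#' geodesic distance matrix and minimal separation `q` (the smallest
#' off-diagonal distance; `Inf` for a single point).  Row order matters:
#' experiments treat prefixes of a design as earlier observation sets
#' (the increasing-sequence assumption).
#'
#' @param manifold `"circle"` or `"sphere"`.
#' @param points circle: numeric vector of angles in `[0, 1)`; sphere:
#'   matrix of unit 3-vectors, one per row.
#' @return an object of class `design_set` with elements `manifold`,
#'   `points`, `n`, `dist`, `q`.
#' @export
design_set <- function(manifold, points) {
  name <- manifold_name(manifold)
  if (name == "circle") {
    points <- as.numeric(points)
    if (any(points < 0 | points >= 1)) stop("circle angles must lie in [0, 1)")
    n <- length(points)
  } else {
    points <- as_sphere_points(points)
    dimnames(points) <- NULL
    n <- nrow(points)
  }
  if (n < 1L) stop("a design needs at least one point")
  d <- geodesic_distance(name, points, points)
  d <- matrix(d, n, n)
  q <- if (n == 1L) Inf else min(d[upper.tri(d)])
  structure(
    list(manifold = name, points = points, n = n, dist = d, q = q),
    class = "design_set"
  )
}

#' @export
print.design_set <- function(x, ...) {
  cat(sprintf("<design_set> %d point(s) on the %s, min separation q = %.6g\n",
              x$n, x$manifold, x$q))
  invisible(x)
}

#' Nested dyadic design on the circle
#'
#' The dyadic grid `{j / 2^level}` ordered by refinement: level 1
#' contributes `(0, 1/2)`, and each subsequent level appends its new
#' midpoints `(2j - 1) / 2^k`.  Prefixes of the point sequence are
#' therefore themselves valid designs, realizing an increasing sequence
#' of observation sets that becomes dense in the circle.  The minimal
#' separation is `q = 2^-level`.
#'
#' @param level refinement depth, a positive integer.
#' @param drop_zero if `TRUE`, omit the point 0 (useful when predicting
#'   at 0, which the remaining points still accumulate towards).
#' @return a [design_set()].
#' @export
dyadic_circle_design <- function(level, drop_zero = FALSE) {
  level <- check_count(level, "level")
  if (level < 1L) stop("`level` must be >= 1")
  pts <- c(0, 0.5)
  if (level >= 2L) {
    for (k in 2:level) pts <- c(pts, (2 * seq_len(2^(k - 1L)) - 1) / 2^k)
  }
  if (drop_zero) pts <- pts[pts != 0]
  design_set("circle", pts)
}

#' Fibonacci lattice design on the sphere
#'
#' Deterministic quasi-uniform point set: point `i` (0-based) has
#' colatitude `acos(1 - 2 (i + 1/2) / n)` and longitude
#' `2 pi i / phi` with `phi` the golden ratio.  The minimal separation
#' scales like the uniform packing distance `sqrt(4 pi / n)`.
#'
#' @param n number of points, a positive integer.
#' @return a [design_set()] on the sphere.
#' @export
fibonacci_sphere_design <- function(n) {
  n <- check_count(n, "n")
  if (n < 1L) stop("`n` must be >= 1")
  i <- seq_len(n) - 1
  z <- 1 - 2 * (i + 0.5) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- (1 + sqrt(5)) / 2
  theta <- 2 * pi * i / phi
  design_set("sphere", cbind(r * cos(theta), r * sin(theta), z))
}

#' Minimal separation of a design
#'
#' The smallest off-diagonal geodesic distance; duplicated points (zero
#' separation) are refused because downstream truncation certificates
#' and covariance factorizations require `q > 0`.
#'
#' @param design a [design_set()].
#' @return a positive number.
#' @export
min_separation <- function(design) {
  stopifnot(inherits(design, "design_set"))
  if (design$n < 2L) stop("minimal separation needs at least two points")
  if (design$q <= 0) stop("design contains duplicated points (q = 0)")
  design$q
}

#' Read or write a design from delimited text
#'
#' One point per row.  Circle files have a single column `theta` with
#' angles in `[0, 1)`.  Sphere files have either `lon,lat` in degrees or
#' `x,y,z` unit vectors; the header decides.  Row order is the design
#' order (prefix = earlier observations).
#'
#' @param path file path.
#' @return a [design_set()].
#' @export
read_design <- function(path) {
  tab <- utils::read.csv(path)
  cols <- tolower(names(tab))
  if (identical(cols, "theta")) {
    design_set("circle", tab[[1L]])
  } else if (setequal(cols, c("lon", "lat"))) {
    lon <- tab[[which(cols == "lon")]] * pi / 180
    lat <- tab[[which(cols == "lat")]] * pi / 180
    design_set("sphere", cbind(cos(lat) * cos(lon), cos(lat) * sin(lon), sin(lat)))
  } else if (setequal(cols, c("x", "y", "z"))) {
    design_set("sphere", as.matrix(tab[, order(match(cols, c("x", "y", "z")))]))
  } else {
    stop("unrecognized design header: expected 'theta', 'lon,lat' or 'x,y,z'")
  }
}

#' @rdname read_design
#' @param design a [design_set()] to serialize.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "design_set"))
  tab <- if (design$manifold == "circle") {
    data.frame(theta = design$points)
  } else {
    data.frame(x = design$points[, 1L], y = design$points[, 2L],
               z = design$points[, 3L])
  }
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
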