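# Independent oracles used across the suite. These deliberately avoid the
# package's own distance/optics code paths: closed forms, parametric
# surface minimisation and plain-R vector algebra only.

# minimise |p - f(u, v)| over a 2D parameter rectangle by iterated grid
# refinement; f maps (u, v) -> a 3-column matrix of surface points
refine_min_dist <- function(p, f, lo, hi, n = 48L, iters = 4L) {
  for (it in seq_len(iters)) {
    u <- seq(lo[1], hi[1], length.out = n)
    v <- seq(lo[2], hi[2], length.out = n)
    gr <- as.matrix(expand.grid(u = u, v = v))
    pts <- f(gr[, 1], gr[, 2])
    d2 <- (pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2 + (pts[, 3] - p[3])^2
    i <- which.min(d2)
    du <- (hi[1] - lo[1]) / (n - 1)
    dv <- (hi[2] - lo[2]) / (n - 1)
    best <- gr[i, ]
    lo <- c(max(lo[1], best[1] - du), max(lo[2], best[2] - dv))
    hi <- c(min(hi[1], best[1] + du), min(hi[2], best[2] + dv))
  }
  sqrt(min(d2))
}

# unsigned distance from p to a sphere surface (trivial closed form kept
# separate from the package's signed formula)
oracle_dist_sphere <- function(p, r, center = c(0, 0, 0)) {
  abs(sqrt(sum((p - center)^2)) - r)
}

oracle_dist_box <- function(p, he) {
  # minimise over the six faces parametrically
  faces <- list(
    function(u, v) cbind(he[1], u, v), function(u, v) cbind(-he[1], u, v),
    function(u, v) cbind(u, he[2], v), function(u, v) cbind(u, -he[2], v),
    function(u, v) cbind(u, v, he[3]), function(u, v) cbind(u, v, -he[3]))
  doms <- list(c(2, 3), c(2, 3), c(1, 3), c(1, 3), c(1, 2), c(1, 2))
  min(vapply(seq_along(faces), function(i) {
    ax <- doms[[i]]
    refine_min_dist(p, faces[[i]], lo = -he[ax], hi = he[ax])
  }, numeric(1)))
}

oracle_dist_capsule <- function(p, a, b, r) {
  ab <- b - a
  # orthonormal frame perpendicular to the axis
  e1 <- if (abs(ab[1]) < 0.9 * sqrt(sum(ab^2))) c(1, 0, 0) else c(0, 1, 0)
  e1 <- e1 - ab * sum(e1 * ab) / sum(ab^2)
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(ab[2] * e1[3] - ab[3] * e1[2], ab[3] * e1[1] - ab[1] * e1[3],
          ab[1] * e1[2] - ab[2] * e1[1])
  e2 <- e2 / sqrt(sum(e2^2))
  lateral <- function(t, th)
    cbind(a[1] + t * ab[1] + r * (cos(th) * e1[1] + sin(th) * e2[1]),
          a[2] + t * ab[2] + r * (cos(th) * e1[2] + sin(th) * e2[2]),
          a[3] + t * ab[3] + r * (cos(th) * e1[3] + sin(th) * e2[3]))
  cap <- function(center, axsign) function(th, ph) {
    # hemisphere pointing away from the segment (th = polar from outward axis)
    axn <- axsign * ab / sqrt(sum(ab^2))
    dx <- cos(th) %o% axn + (sin(th) * cos(ph)) %o% e1 +
      (sin(th) * sin(ph)) %o% e2
    sweep(r * dx, 2, center, "+")
  }
  min(refine_min_dist(p, lateral, c(0, 0), c(1, 2 * pi)),
      refine_min_dist(p, cap(a, -1), c(0, 0), c(pi / 2, 2 * pi)),
      refine_min_dist(p, cap(b, +1), c(0, 0), c(pi / 2, 2 * pi)))
}

oracle_dist_cylinder <- function(p, hh, r) {
  lateral <- function(th, z) cbind(r * cos(th), r * sin(th), z)
  disk <- function(zs) function(rr, th) cbind(rr * cos(th), rr * sin(th),
                                              rep(zs, length(rr)))
  min(refine_min_dist(p, lateral, c(0, -hh), c(2 * pi, hh)),
      refine_min_dist(p, disk(hh), c(0, 0), c(r, 2 * pi)),
      refine_min_dist(p, disk(-hh), c(0, 0), c(r, 2 * pi)))
}

# smallest positive t with |o + t d - c| = r, or NA
oracle_ray_sphere <- function(o, d, c, r) {
  oc <- o - c
  b <- sum(oc * d)
  disc <- b^2 - (sum(oc^2) - r^2)
  if (disc < 0) return(NA_real_)
  ts <- c(-b - sqrt(disc), -b + sqrt(disc))
  ts <- ts[ts > 1e-12]
  if (length(ts) == 0) NA_real_ else min(ts)
}

# plain-R vector Snell refraction (n oriented against incidence)
oracle_refract <- function(d, n, n1, n2) {
  eta <- n1 / n2
  cosi <- -sum(d * n)
  k <- 1 - eta^2 * (1 - cosi^2)
  if (k < 0) return(NULL)
  t <- eta * d + (eta * cosi - sqrt(k)) * n
  t / sqrt(sum(t^2))
}

# trace a downward ray through a refractive sphere: two refractions,
# no reflections; returns list(entry, exit, direction)
oracle_glass_sphere_ray <- function(x0, center, r, n_glass, z_start = 1.5) {
  o <- c(x0, 0, z_start)
  d <- c(0, 0, -1)
  t1 <- oracle_ray_sphere(o, d, center, r)
  p1 <- o + t1 * d
  nrm <- (p1 - center) / r
  d1 <- oracle_refract(d, nrm, 1, n_glass)
  t2 <- oracle_ray_sphere(p1 + 1e-9 * d1, d1, center, r)
  p2 <- p1 + 1e-9 * d1 + t2 * d1
  nrm2 <- -(p2 - center) / r  # oriented against incidence (leaving)
  d2 <- oracle_refract(d1, nrm2, n_glass, 1)
  list(entry = p1, exit = p2, direction = d2)
}

# analytic Henyey-Greenstein CDF of the scattering cosine
hg_cdf <- function(c, g) {
  if (abs(g) < 1e-6) return((c + 1) / 2)
  (1 - g^2) / (2 * g) * (1 / sqrt(1 + g^2 - 2 * g * c) - 1 / (1 + g))
}

angle_between <- function(a, b) {
  cc <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(max(-1, min(1, cc)))
}

# deterministic pseudo-random points without touching the global RNG stream
# beyond a local seed
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
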