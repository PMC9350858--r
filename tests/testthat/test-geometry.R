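# SDF primitives, CSG algebra, transforms, normals and scene queries.

test_that("primitive signed distances match their closed forms", {
  expect_equal(sdf_distance(sdf_sphere(0.5), c(0, 0, 0)), -0.5)
  expect_equal(sdf_distance(sdf_sphere(0.5), c(0.5, 0, 0)), 0)
  expect_equal(sdf_distance(sdf_sphere(1), c(3, 4, 0)), 4)

  expect_equal(sdf_distance(sdf_box(c(1, 1, 1)), c(0, 0, 0)), -1)
  expect_equal(sdf_distance(sdf_box(c(1, 1, 1)), c(2, 0, 0)), 1)
  expect_equal(sdf_distance(sdf_box(c(1, 1, 1)), c(2, 2, 0)), sqrt(2))

  a <- c(-0.3, 0, 0); b <- c(0.4, 0.2, 0.1)
  expect_equal(sdf_distance(sdf_capsule(a, b, 0.1), a), -0.1)
  expect_equal(sdf_distance(sdf_capsule(a, b, 0.1), (a + b) / 2), -0.1)

  expect_equal(sdf_distance(sdf_cylinder(2, 0.5), c(0, 0, 0)), -0.5)
  expect_equal(sdf_distance(sdf_cylinder(0.3, 2), c(0, 0, 0)), -0.3)
  expect_equal(sdf_distance(sdf_cylinder(1, 0.5), c(0.5, 0, 0.2)), 0)
})

test_that("invalid primitive parameters are rejected", {
  expect_error(sdf_sphere(-1), "positive")
  expect_error(sdf_box(c(1, 0, 1)), "positive")
  expect_error(sdf_capsule(c(0, 0, 0), c(0, 0, 0), 0.1), "degenerate")
  expect_error(sdf_capsule(c(0, 0, 0), c(1, 0, 0), 0), "positive")
  expect_error(sdf_cylinder(0, 1), "positive")
  expect_error(sdf_smooth_union(sdf_sphere(1), sdf_sphere(1), k = 0), "positive")
})

test_that("primitive distances agree with the surface-minimisation oracle", {
  shapes <- list(
    list(node = sdf_sphere(0.5),
         oracle = function(p) oracle_dist_sphere(p, 0.5)),
    list(node = sdf_box(c(0.6, 0.4, 0.8)),
         oracle = function(p) oracle_dist_box(p, c(0.6, 0.4, 0.8))),
    list(node = sdf_capsule(c(-0.4, 0, 0), c(0.3, 0.3, 0.2), 0.15),
         oracle = function(p) oracle_dist_capsule(p, c(-0.4, 0, 0),
                                                  c(0.3, 0.3, 0.2), 0.15)),
    list(node = sdf_cylinder(0.5, 0.35),
         oracle = function(p) oracle_dist_cylinder(p, 0.5, 0.35))
  )
  pts <- with_seed(11, matrix(runif(3 * 12, -1.2, 1.2), ncol = 3))
  for (sh in shapes) {
    for (i in seq_len(nrow(pts))) {
      p <- pts[i, ]
      expect_lt(abs(abs(sdf_distance(sh$node, p)) - sh$oracle(p)), 1e-4)
    }
  }
})

test_that("sign convention: inside negative, surface zero, outside positive", {
  cases <- list(
    list(node = sdf_sphere(0.7), surf = c(0.7, 0, 0)),
    list(node = sdf_box(c(0.5, 0.6, 0.7)), surf = c(0.5, 0, 0)),
    list(node = sdf_capsule(c(0, 0, -0.3), c(0, 0, 0.3), 0.2),
         surf = c(0.2, 0, 0.1)),
    list(node = sdf_cylinder(0.4, 0.3), surf = c(0.3, 0, 0.1))
  )
  for (cs in cases) {
    expect_lt(abs(sdf_distance(cs$node, cs$surf)), 1e-9)
    expect_lt(sdf_distance(cs$node, 0.5 * cs$surf), 0)
    expect_gt(sdf_distance(cs$node, 2.5 * cs$surf), 0)
  }
})

test_that("all node types are 1-Lipschitz", {
  nodes <- list(
    sdf_sphere(0.5), sdf_box(c(0.5, 0.7, 0.3)),
    sdf_capsule(c(-0.3, 0, 0), c(0.3, 0.1, 0), 0.2), sdf_cylinder(0.5, 0.3),
    sdf_subtraction(sdf_box(c(0.5, 0.5, 0.5)), sdf_sphere(0.4)),
    sdf_union(sdf_sphere(0.3, center = c(0.4, 0, 0)), sdf_sphere(0.3)),
    sdf_smooth_union(sdf_sphere(0.3, center = c(0.4, 0, 0)), sdf_sphere(0.3),
                     k = 0.1),
    sdf_transform(sdf_box(c(0.3, 0.3, 0.6)),
                  rotation = matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3),
                  translation = c(0.2, -0.1, 0))
  )
  pq <- with_seed(7, matrix(runif(6 * 200, -1.5, 1.5), ncol = 6))
  for (nd in nodes) {
    dp <- sdf_distance(nd, pq[, 1:3])
    dq <- sdf_distance(nd, pq[, 4:6])
    sep <- sqrt(rowSums((pq[, 1:3] - pq[, 4:6])^2))
    expect_true(all(abs(dp - dq) <= sep + 1e-6))
  }
})

test_that("eikonal property |grad D| = 1 off the medial axis", {
  h <- 1e-5
  nodes <- list(sdf_sphere(0.5), sdf_box(c(0.5, 0.7, 0.3)),
                sdf_capsule(c(-0.3, 0, 0), c(0.3, 0.1, 0), 0.2),
                sdf_cylinder(0.5, 0.3))
  pts <- with_seed(5, matrix(runif(3 * 40, -1.2, 1.2), ncol = 3))
  for (nd in nodes) {
    for (i in seq_len(nrow(pts))) {
      p <- pts[i, ]
      if (abs(sdf_distance(nd, p)) < 0.05) next  # keep clear of surface kinks
      g <- vapply(1:3, function(ax) {
        e <- c(0, 0, 0); e[ax] <- h
        (sdf_distance(nd, p + e) - sdf_distance(nd, p - e)) / (2 * h)
      }, numeric(1))
      expect_lt(abs(sqrt(sum(g^2)) - 1), 1e-4)
    }
  }
})

test_that("CSG combine follows min/max algebra and bounds", {
  expect_equal(csg_combine("union", -1, 2), -1)
  expect_equal(csg_combine("intersection", -1, 2), 2)
  expect_equal(csg_combine("subtraction", -1, -2), 2)
  expect_error(csg_combine("frobnicate", 0, 0), "unknown")

  # smooth union dips strictly below min at equality, reduces to min apart
  expect_lt(csg_combine("smooth_union", 0.5, 0.5, k = 0.1), 0.5)
  expect_equal(csg_combine("smooth_union", 0.5, 0.5, k = 0.1),
               0.5 - 0.1 / 4)  # h = 1 at equality
  expect_equal(csg_combine("smooth_union", 0.2, 0.5, k = 0.1), 0.2)

  d <- with_seed(3, matrix(runif(2 * 100, -1, 1), ncol = 2))
  su <- csg_combine("smooth_union", d[, 1], d[, 2], k = 0.2)
  expect_true(all(su <= pmin(d[, 1], d[, 2]) + 1e-12))
  expect_true(all(csg_combine("intersection", d[, 1], d[, 2]) >= d[, 1]))

  # tree evaluation consistent with the scalar algebra
  s1 <- sdf_sphere(0.4, center = c(0.3, 0, 0)); s2 <- sdf_sphere(0.4)
  pts <- with_seed(4, matrix(runif(3 * 50, -1, 1), ncol = 3))
  d1 <- sdf_distance(s1, pts); d2 <- sdf_distance(s2, pts)
  expect_equal(sdf_distance(sdf_union(s1, s2), pts),
               csg_combine("union", d1, d2))
  expect_equal(sdf_distance(sdf_smooth_union(s1, s2, k = 0.15), pts),
               csg_combine("smooth_union", d1, d2, k = 0.15))
  expect_equal(sdf_distance(sdf_subtraction(s1, s2), pts),
               csg_combine("subtraction", d1, d2))
})

test_that("rigid transforms preserve distances and follow the convention", {
  p <- c(0.3, -0.2, 0.5)
  expect_equal(transform_point(p), p)
  t <- c(0.1, 0.2, -0.3)
  expect_equal(sdf_distance(sdf_transform(sdf_sphere(0.5), translation = t), p),
               sdf_distance(sdf_sphere(0.5), p - t))

  # right-handed 90 degree rotation about z maps local +x to world +y
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  expect_equal(det(Rz), 1)
  expect_equal(as.numeric(Rz %*% c(1, 0, 0)), c(0, 1, 0))
  expect_equal(transform_point(c(0, 1, 0), rotation = Rz), c(1, 0, 0))

  # a rotated box measured against a manually rotated oracle
  box <- sdf_transform(sdf_box(c(0.5, 0.2, 0.3)), rotation = Rz)
  pts <- with_seed(9, matrix(runif(3 * 20, -1, 1), ncol = 3))
  for (i in seq_len(nrow(pts))) {
    local <- as.numeric(crossprod(Rz, pts[i, ]))
    expect_equal(sdf_distance(box, pts[i, ]),
                 sdf_distance(sdf_box(c(0.5, 0.2, 0.3)), local))
  }

  expect_error(sdf_transform(sdf_sphere(1), rotation = diag(3) * 2),
               "orthonormal")
  flip <- diag(c(-1, 1, 1))
  expect_error(sdf_transform(sdf_sphere(1), rotation = flip), "proper")
})

test_that("surface normals are unit central-difference gradients", {
  n1 <- surface_normal(sdf_sphere(1), c(1, 0, 0))
  expect_equal(n1, c(1, 0, 0), tolerance = 1e-6)
  expect_lt(abs(sqrt(sum(n1^2)) - 1), 1e-12)
  expect_equal(surface_normal(sdf_sphere(1), c(0, -1, 0)), c(0, -1, 0),
               tolerance = 1e-6)

  nb <- surface_normal(sdf_box(c(0.5, 0.5, 0.5)), c(0.5, 0.1, -0.2))
  expect_lt(max(abs(nb - c(1, 0, 0))), 1e-6)

  # analytic capsule normals: radial from the closest axis point
  a <- c(0, 0, -0.3); b <- c(0, 0, 0.3)
  nc <- surface_normal(sdf_capsule(a, b, 0.2), c(0.2, 0, 0.1))
  expect_lt(max(abs(nc - c(1, 0, 0))), 1e-5)
  ncap <- surface_normal(sdf_capsule(a, b, 0.2), c(0, 0, 0.5))
  expect_lt(max(abs(ncap - c(0, 0, 1))), 1e-5)

  # random sphere points against the analytic radial normal
  dirs <- with_seed(13, matrix(rnorm(3 * 25), ncol = 3))
  dirs <- dirs / sqrt(rowSums(dirs^2))
  for (i in seq_len(nrow(dirs))) {
    nn <- surface_normal(sdf_sphere(0.7), 0.7 * dirs[i, ])
    expect_lt(max(abs(nn - dirs[i, ])), 1e-5)
    expect_lt(abs(sqrt(sum(nn^2)) - 1), 1e-12)
  }

  expect_error(surface_normal(sdf_box(c(1, 1, 1)), c(0, 0, 0)), "degenerate")
})

test_that("scene_distance returns the nearest surface magnitude", {
  m <- optical_medium(mu_s = 1)
  sc <- scene(sdf_region(sdf_sphere(0.5), m), bbox_half = c(3, 3, 3))
  expect_equal(scene_distance(sc, c(2, 0, 0)),
               list(distance = 1.5, region = 1L))
  expect_equal(scene_distance(sc, c(0, 0, 0)),
               list(distance = 0.5, region = 1L))

  sc2 <- scene(sdf_region(sdf_sphere(0.5, center = c(-1, 0, 0)), m),
               sdf_region(sdf_sphere(0.2, center = c(1, 0, 0)), m),
               bbox_half = c(3, 3, 3))
  got <- scene_distance(sc2, c(0.5, 0, 0))
  expect_equal(got$region, 2L)
  expect_equal(got$distance, 0.3)

  sc0 <- scene(list(), bbox_half = c(1, 1, 1))
  expect_error(scene_distance(sc0, c(0, 0, 0)), "no regions")
})

test_that("medium_at resolves overlaps by layer then declaration order", {
  tissue <- optical_medium(mu_s = 100, mu_a = 0.5, g = 0.9, n = 1.38)
  vessel <- optical_medium(mu_s = 94, mu_a = 231, g = 0.9, n = 1.38)
  sc <- scene(
    sdf_region(sdf_box(c(0.5, 0.5, 0.5)), tissue, layer = 1L),
    sdf_region(sdf_capsule(c(-0.3, 0, 0), c(0.3, 0, 0), 0.1), vessel,
               layer = 2L),
    bbox_half = c(1, 1, 1)
  )
  expect_equal(medium_at(sc, c(0, 0, 0))$mu_a, 231)      # vessel wins inside
  expect_equal(medium_at(sc, c(0, 0, 0.4))$mu_a, 0.5)    # tissue elsewhere
  expect_equal(medium_at(sc, c(0, 0, 0.9))$mu_a, 0)      # ambient in the gap
  expect_error(medium_at(sc, c(5, 0, 0)), "outside")

  # equal layers: earlier declaration wins
  sc2 <- scene(
    sdf_region(sdf_sphere(0.5), optical_medium(mu_a = 1), layer = 0L),
    sdf_region(sdf_sphere(0.5), optical_medium(mu_a = 2), layer = 0L),
    bbox_half = c(1, 1, 1)
  )
  expect_equal(medium_at(sc2, c(0, 0, 0))$mu_a, 1)
})

test_that("rasterize labels voxels like medium_at and conserves volume", {
  m <- optical_medium(mu_s = 1)
  sc <- scene(sdf_region(sdf_sphere(0.5), m), bbox_half = c(1, 1, 1))
  g <- fluence_grid(c(-1, -1, -1), c(1, 1, 1), c(100, 100, 100))
  lab <- rasterize(sc, g)
  vol <- sum(lab == 1L) * prod(g$spacing)
  expect_lt(abs(vol - 4 / 3 * pi * 0.5^3) / (4 / 3 * pi * 0.5^3), 0.01)

  expect_true(all(rasterize(scene(list(), bbox_half = c(1, 1, 1)), g) == 0L))

  # nested shapes follow the layer rule
  sc2 <- scene(
    sdf_region(sdf_box(c(0.8, 0.8, 0.8)), m, layer = 1L),
    sdf_region(sdf_sphere(0.3), optical_medium(mu_a = 1), layer = 2L),
    bbox_half = c(1, 1, 1)
  )
  lab2 <- rasterize(sc2, fluence_grid(c(-1, -1, -1), c(1, 1, 1), c(40, 40, 40)))
  expect_equal(lab2[20, 20, 20], 2L)  # centre voxel: sphere (higher layer)
  expect_equal(lab2[6, 20, 20], 1L)   # x = -0.725: box only

  gbig <- fluence_grid(c(-2, -2, -2), c(2, 2, 2), c(10, 10, 10))
  expect_error(rasterize(sc, gbig), "exceeds")
})
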