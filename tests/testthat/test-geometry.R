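# Planar geometry primitives: closed-form checks, independent brute-force
# oracles, and rigid-motion invariance.

test_that("angle_at_vertex handles canonical and degenerate configurations", {
  expect_equal(angle_at_vertex(c(1, 0), c(0, 0), c(0, 1)), 90)
  expect_equal(angle_at_vertex(c(1, 0), c(0, 0), c(-1, 0)), 180)
  expect_equal(angle_at_vertex(c(2, 2), c(1, 1), c(3, 3)), 0,
               tolerance = 1e-5)
  expect_error(angle_at_vertex(c(0, 0), c(0, 0), c(1, 1)), "zero-length")
})

test_that("angle_at_vertex matches a law-of-cosines oracle on random triangles", {
  set.seed(11)
  for (i in 1:200) {
    a <- random_point(); v <- random_point(); b <- random_point()
    la <- sqrt(sum((a - v)^2)); lb <- sqrt(sum((b - v)^2))
    lc <- sqrt(sum((a - b)^2))
    if (la < 1e-6 || lb < 1e-6) next
    oracle <- acos(min(1, max(-1, (la^2 + lb^2 - lc^2) / (2 * la * lb)))) *
      180 / pi
    expect_equal(angle_at_vertex(a, v, b), oracle, tolerance = 1e-9)
  }
})

test_that("angle_between_lines respects acute/obtuse conventions", {
  l1 <- ceph_line(c(0, 0), c(1, 0))
  expect_equal(angle_between_lines(l1, ceph_line(c(5, 7), c(2, 0))), 0)
  expect_equal(angle_between_lines(l1, ceph_line(c(0, 0), c(0, 3)),
                                   "obtuse"), 90)
  # oracle: folded atan2 difference
  set.seed(12)
  for (i in 1:200) {
    d1 <- random_point(); d2 <- random_point()
    if (sum(d1^2) < 1e-8 || sum(d2^2) < 1e-8) next
    diff <- abs(atan2(d1[2], d1[1]) - atan2(d2[2], d2[1])) * 180 / pi
    diff <- diff %% 180
    oracle <- min(diff, 180 - diff)
    got <- angle_between_lines(ceph_line(c(0, 0), d1), ceph_line(c(0, 0), d2))
    expect_equal(got, oracle, tolerance = 1e-9)
  }
})

test_that("inclination_difference uses the y-down sign convention", {
  h <- ceph_line(c(0, 0), c(1, 0))
  expect_equal(inclination_difference(h, h), 0)
  # a line sloping downward-anteriorly has positive atan2 inclination in the
  # y-down frame, so the reference-minus-line difference is -45
  expect_equal(inclination_difference(h, ceph_line(c(0, 0), c(1, 1))), -45)
  expect_equal(inclination_difference(ceph_line(c(0, 0), c(1, -1)), h), -45)
  expect_error(inclination_difference(h, ceph_line(c(0, 0), c(-1, 0))),
               "anteriorly")
})

test_that("signed distances have the documented signs and an oracle match", {
  down <- ceph_line(c(0, 0), c(0, 1))    # cranial -> caudal
  expect_equal(signed_point_line_distance(c(0, 5), down), 0)
  expect_equal(signed_point_line_distance(c(3, 1), down), 3)  # anterior side
  expect_equal(signed_point_line_distance(c(-2, 1), down), -2)
  fwd <- ceph_line(c(0, 0), c(1, 0))     # posterior -> anterior
  expect_equal(signed_point_line_distance(c(1, 4), fwd, "inferior_positive"),
               4)
  expect_equal(signed_point_line_distance(c(1, -4), fwd, "inferior_positive"),
               -4)
  # magnitude oracle: residual of the orthogonal projection
  set.seed(13)
  for (i in 1:200) {
    o <- random_point(); d <- random_point(); p <- random_point()
    if (sum(d^2) < 1e-8) next
    u <- d / sqrt(sum(d^2))
    res <- (p - o) - sum((p - o) * u) * u
    oracle <- sqrt(sum(res^2))
    expect_equal(abs(signed_point_line_distance(p, ceph_line(o, d))), oracle,
                 tolerance = 1e-9)
  }
})

test_that("project_along matches the cosine oracle", {
  ax <- ceph_line(c(0, 0), c(1, 0))
  expect_equal(project_along(c(0, 0), c(0, 0), ax), 0)
  expect_equal(project_along(c(3, 4), c(0, 0), ax), 3)
  set.seed(14)
  for (i in 1:100) {
    o <- random_point(); p <- random_point(); d <- random_point()
    if (sum(d^2) < 1e-8 || sum((p - o)^2) < 1e-8) next
    ang <- angle_at_vertex(o + d, o, p) * pi / 180
    oracle <- sqrt(sum((p - o)^2)) * cos(ang)
    expect_equal(project_along(p, o, ceph_line(o, d)), oracle,
                 tolerance = 1e-8)
  }
})

test_that("line_intersection solves the 2x2 system and rejects parallels", {
  xaxis <- ceph_line(c(0, 0), c(1, 0))
  yaxis <- ceph_line(c(0, 0), c(0, 1))
  expect_equal(line_intersection(xaxis, yaxis), c(0, 0))
  expect_error(line_intersection(xaxis, ceph_line(c(0, 1), c(2, 0))),
               "parallel")
  set.seed(15)
  for (i in 1:100) {
    o1 <- random_point(); d1 <- random_point()
    o2 <- random_point(); d2 <- random_point()
    cross <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(cross) / sqrt(sum(d1^2) * sum(d2^2)) < 1e-3) next
    ts <- solve(cbind(d1, -d2), o2 - o1)   # independent linear solve
    oracle <- o1 + ts[1] * d1
    expect_equal(line_intersection(ceph_line(o1, d1), ceph_line(o2, d2)),
                 oracle, tolerance = 1e-9)
  }
})

test_that("construct_xi is the FH-aligned rectangle centre", {
  sq <- list(r1 = c(0, 5), r2 = c(10, 5), r3 = c(5, 0), r4 = c(5, 10))
  fh <- ceph_line(c(0, 0), c(1, 0))
  expect_equal(construct_xi(sq$r1, sq$r2, sq$r3, sq$r4, fh), c(5, 5))
  # oracle: rotate everything into the FH frame, average, rotate back
  set.seed(16)
  for (i in 1:100) {
    pts <- replicate(4, random_point(), simplify = FALSE)
    d <- random_point()
    if (sum(d^2) < 1e-8) next
    th <- atan2(d[2], d[1])
    rot <- function(p, a) c(cos(a) * p[1] - sin(a) * p[2],
                            sin(a) * p[1] + cos(a) * p[2])
    loc <- lapply(pts, rot, a = -th)
    mid <- c((loc[[1]][1] + loc[[2]][1]) / 2, (loc[[3]][2] + loc[[4]][2]) / 2)
    oracle <- rot(mid, th)
    got <- construct_xi(pts[[1]], pts[[2]], pts[[3]], pts[[4]],
                        ceph_line(c(0, 0), d))
    expect_equal(got, oracle, tolerance = 1e-9)
  }
})

test_that("angles are invariant and constructions equivariant under rigid motion", {
  set.seed(17)
  for (i in 1:50) {
    a <- random_point(); v <- random_point(); b <- random_point()
    if (sqrt(sum((a - v)^2)) < 1e-3 || sqrt(sum((b - v)^2)) < 1e-3) next
    deg <- runif(1, -180, 180); shift <- runif(2, -30, 30)
    scale <- runif(1, 0.5, 3)
    tr <- function(p) rigid_point(p, deg, shift, scale)
    expect_equal(angle_at_vertex(tr(a), tr(v), tr(b)),
                 angle_at_vertex(a, v, b), tolerance = 1e-9)
    # signed distance scales linearly and flips under reflection
    l <- ceph_line(v, b - v)
    d0 <- signed_point_line_distance(a, l)
    l_tr <- ceph_line(tr(v), tr(b) - tr(v))
    expect_equal(signed_point_line_distance(tr(a), l_tr), scale * d0,
                 tolerance = 1e-8)
    refl <- function(p) c(p[1], -p[2])   # reflection flips orientation
    l_re <- ceph_line(refl(v), refl(b) - refl(v))
    expect_equal(signed_point_line_distance(refl(a), l_re), -d0,
                 tolerance = 1e-9)
    # intersection commutes with the rigid motion
    o2 <- random_point(); d2 <- random_point()
    l2 <- ceph_line(o2, d2)
    cross <- (b - v)[1] * d2[2] - (b - v)[2] * d2[1]
    if (abs(cross) / sqrt(sum((b - v)^2) * sum(d2^2)) < 1e-3) next
    p0 <- line_intersection(l, l2)
    p1 <- line_intersection(l_tr, ceph_line(tr(o2), tr(o2 + d2) - tr(o2)))
    expect_equal(p1, tr(p0), tolerance = 1e-7)
  }
})
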