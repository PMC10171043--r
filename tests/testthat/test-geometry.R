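test_that("parameter validation enforces physical bounds", {
  expect_s3_class(leaflet_params(H1 = 15, Rin = 10, T = 0.2), "leaflet_params")
  expect_error(leaflet_params(H1 = -1, Rin = 10, T = 0.2), "H1")
  expect_error(leaflet_params(H1 = 15, Rin = 0, T = 0.2), "Rin")
  expect_error(leaflet_params(H1 = 15, Rin = 10, T = 0), "thickness")
  expect_error(leaflet_params(H1 = 15, Rin = 10, T = 0.2, R = 101), "sag")
  expect_error(leaflet_params(H1 = 15, Rin = 10, T = 0.2, phi = 90), "phi")
  expect_error(leaflet_params(H1 = 15, Rin = 10, T = 0.2, Sec = 121), "Sec")
  expect_error(leaflet_params(H1 = NaN, Rin = 10, T = 0.2), "finite")
})

test_that("published 19-mm design meshes with the documented counts and tips", {
  p <- leaflet_params(H1 = 15.22, phi = 5.17, R = 40, Rin = 9.38, T = 0.14,
                      Sec = 119)
  m <- generate_leaflet_mesh(p, nu = 11, ntheta = 21)
  expect_equal(nrow(m$nodes), 11 * (21 - 2) + 2)
  expect_equal(nrow(m$triangles), 2 * (11 - 1) * (21 - 2))
  # commissure tips at the full leaflet height
  expect_equal(m$nodes[1, 3], 15.22, tolerance = 1e-9)
  expect_equal(m$nodes[2, 3], 15.22, tolerance = 1e-9)
  expect_equal(max(sqrt(m$nodes[, 1]^2 + m$nodes[, 2]^2)), 9.38,
               tolerance = 1e-9)
  expect_true(validate_mesh(m))
})

test_that("triangle-count law holds across resolutions", {
  p <- leaflet_params(H1 = 15, Rin = 10, T = 0.2)
  for (res in list(c(3, 5), c(5, 9), c(8, 13), c(11, 21))) {
    m <- generate_leaflet_mesh(p, nu = res[1], ntheta = res[2])
    expect_equal(nrow(m$triangles), 2 * (res[1] - 1) * (res[2] - 2))
    expect_equal(nrow(m$nodes), res[1] * (res[2] - 2) + 2)
  }
  expect_error(generate_leaflet_mesh(p, nu = 2, ntheta = 9), "nu")
  expect_error(generate_leaflet_mesh(p, nu = 5, ntheta = 4), "ntheta")
  expect_error(generate_leaflet_mesh(p, nu = 5, ntheta = 10), "odd")
})

test_that("flat design (no sag, no tilt) puts the free edge at z = H1", {
  p <- leaflet_params(H1 = 14, phi = 0, R = 0, Rin = 9, T = 0.2)
  m <- generate_leaflet_mesh(p, nu = 9, ntheta = 17)
  expect_equal(max(abs(m$nodes[m$free_edge_nodes, 3] - 14)), 0,
               tolerance = 1e-12)
  expect_true(min(m$nodes[, 3]) > -1e-6)
})

test_that("mesh generation is deterministic", {
  p <- leaflet_params(H1 = 17.3, phi = -12, R = 63, Rin = 11.2, T = 0.4)
  m1 <- generate_leaflet_mesh(p, nu = 11, ntheta = 21)
  m2 <- generate_leaflet_mesh(p, nu = 11, ntheta = 21)
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$triangles, m2$triangles)
})

test_that("mesh nodes match direct evaluation of the surface equations", {
  # Independent oracle: the closed-form surface evaluated on the grid.
  p <- leaflet_params(H1 = 16, phi = 8, R = 100, Rin = 10, T = 0.2, Sec = 118)
  nu <- 7; ntheta <- 11
  m <- generate_leaflet_mesh(p, nu = nu, ntheta = ntheta)
  half <- p$Sec / 2
  surf <- function(u, th) {
    phir <- p$phi * pi / 180
    att <- c(p$Rin * cos(th * pi / 180), p$Rin * sin(th * pi / 180),
             p$H1 * (1 - cos(pi * th / half)) / 2)
    rf <- p$Rin * abs(th) / half
    af <- sign(th) * half * pi / 180
    fre <- c(rf * cos(af), rf * sin(af), p$H1 - tan(phir) * (p$Rin - rf))
    pt <- (1 - u) * att + u * fre
    pt[3] <- pt[3] - (p$R / 100) * 0.25 * p$Rin * sin(pi * u) *
      cos(pi * th / p$Sec)
    pt
  }
  us <- seq(0, 1, length.out = nu)
  ths <- seq(-half, half, length.out = ntheta)
  # interior columns (welded commissures are columns 1 and ntheta)
  for (j in c(2, 5, 10)) {
    for (i in c(1, 4, 7)) {
      id <- 2L + (j - 2L) * nu + i
      expect_equal(m$nodes[id, ], unname(surf(us[i], ths[j])),
                   tolerance = 1e-12)
    }
  }
  # deepest sag point matches the direct grid minimum of the closed form
  grid_min <- min(outer(us, ths[2:(ntheta - 1)],
                        Vectorize(function(u, th) surf(u, th)[3])))
  expect_equal(min(m$nodes[, 3]), grid_min, tolerance = 1e-12)
})

test_that("undeformed projected area is invariant to phi and R", {
  base <- projected_covered_area(
    generate_leaflet_mesh(leaflet_params(H1 = 15, phi = 0, R = 0, Rin = 10,
                                         T = 0.2), 9, 17), Rin = 10)
  for (par in list(c(20, 0), c(-15, 50), c(5, 100))) {
    a <- projected_covered_area(
      generate_leaflet_mesh(leaflet_params(H1 = 15, phi = par[1], R = par[2],
                                           Rin = 10, T = 0.2), 9, 17),
      Rin = 10)
    expect_equal(a, base, tolerance = 1e-12)
  }
})

test_that("closed leaflet covers its sector (projection closure)", {
  m120 <- generate_leaflet_mesh(
    leaflet_params(H1 = 15, phi = 0, R = 0, Rin = 10, T = 0.2, Sec = 120),
    nu = 11, ntheta = 21)
  cov <- projected_covered_area(m120, Rin = 10, resolution = 0.05)
  expect_equal(cov, sector_area(10), tolerance = 0.015)
  m119 <- generate_leaflet_mesh(
    leaflet_params(H1 = 15, phi = 0, R = 0, Rin = 10, T = 0.2, Sec = 119),
    nu = 11, ntheta = 21)
  cov119 <- projected_covered_area(m119, Rin = 10, resolution = 0.05)
  expect_equal(cov119, (119 / 120) * sector_area(10), tolerance = 0.015)
})

test_that("reference orifice area is one third of the circle", {
  expect_equal(sector_area(10), 104.7198, tolerance = 1e-6)
  expect_equal(sector_area(0), 0)
  expect_equal(sector_area(9.38), 92.137048, tolerance = 1e-6) # pinned
  expect_error(sector_area(-1), "Rin")
})

test_that("projected area handles single triangles and degenerate planes", {
  nodes <- rbind(c(0, 0, 3), c(1, 0, 3), c(0, 1, 3))
  tri <- rbind(c(1L, 2L, 3L))
  a <- projected_covered_area(nodes, Rin = 5, resolution = 0.02,
                              triangles = tri)
  expect_equal(a, 0.5, tolerance = 2 * 0.02 * (2 + sqrt(2)) / 0.5)
  # triangle in the XZ plane projects to a line: zero area
  xz <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1))
  expect_equal(projected_covered_area(xz, Rin = 5, triangles = tri), 0)
  expect_error(projected_covered_area(nodes, Rin = 5, resolution = 0,
                                      triangles = tri), "resolution")
  expect_error(projected_covered_area(nodes, Rin = 5), "triangles")
})
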