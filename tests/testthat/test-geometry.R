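test_that("hexagonal lattice has unit-spacing six-neighbor structure", {
  g <- hex_grid(300, 300, 0.0375)
  ctr <- hex_centers(g)
  expect_equal(max(ctr$x) - min(ctr$x), (300 - 1 + 0.5) * 0.0375)
  expect_equal(max(ctr$y) - min(ctr$y), 299 * 0.0375 * sqrt(3) / 2,
               tolerance = 1e-12)

  nb <- hex_neighbors(g)
  set.seed(3)
  for (i in sample(which(rowSums(is.na(nb)) == 0), 20)) {
    d <- sqrt((ctr$x[nb[i, ]] - ctr$x[i])^2 + (ctr$y[nb[i, ]] - ctr$y[i])^2)
    expect_equal(d, rep(0.0375, 6), tolerance = 1e-12)
  }

  g1 <- hex_grid(1, 1, 0.5)
  expect_true(all(is.na(hex_neighbors(g1))))
  expect_error(hex_grid(0, 10, 1), "positive")
})

test_that("disc rasterization round-trips through the contour within 3%", {
  g <- hex_grid(150, 150, 0.0375)
  for (R in c(0.5, 1, 1.5, 2)) {
    cs <- disc_section(R, media = 0.15, adv = 0.1, grid = g)
    ct <- lumen_contour(cs)
    a <- polygon_area(ct)
    expect_gt(a, 0)  # counter-clockwise
    expect_lt(abs(a - pi * R^2) / (pi * R^2), 0.03)
  }
  # single-site lumen: area of one hexagonal cell
  cs1 <- disc_section(0.02, media = 0.2, adv = 0.1)
  expect_equal(lumen_site_area(cs1), sqrt(3) / 2 * 0.0375^2)
  lab <- cs1$label
  lab[lab == LABELS["lumen"]] <- LABELS["media"]
  expect_error(lumen_contour(cross_section(cs1$grid, lab)), "no lumen")
})

test_that("shoelace area agrees with a fan-triangulation oracle", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(polygon_area(sq), 1)
  hexagon <- cbind(cos(pi / 3 * (0:5)), sin(pi / 3 * (0:5)))
  expect_equal(polygon_area(hexagon), 3 * sqrt(3) / 2, tolerance = 1e-12)
  expect_equal(round(polygon_area(hexagon), 4), 2.5981)

  # circle of diameter 3.3 mm: the target lumen area
  expect_equal(polygon_area(circle_contour(1.65)), 8.55, tolerance = 1e-3)

  set.seed(9)
  for (k in 1:8) {
    n <- sample(5:12, 1)
    th <- sort(runif(n, -pi, pi))
    r <- runif(n, 0.5, 2)
    poly <- cbind(r * cos(th), r * sin(th))  # star-shaped, CCW
    # oracle: sum of signed triangle areas fanned from the origin
    oracle <- sum(vapply(seq_len(n), function(i) {
      j <- if (i == n) 1 else i + 1
      (poly[i, 1] * poly[j, 2] - poly[j, 1] * poly[i, 2]) / 2
    }, numeric(1)))
    expect_equal(polygon_area(poly), oracle, tolerance = 1e-12)
  }

  bowtie <- cbind(c(0, 1, 0, 1), c(0, 1, 1, 0))
  expect_error(polygon_area(bowtie), "self-intersect")
})

test_that("hydraulic diameter reduces to the closed forms", {
  ct <- circle_contour(0.7)
  expect_equal(hydraulic_diameter(polygon_area(ct), polygon_perimeter(ct)),
               1.4, tolerance = 1e-4)
  expect_equal(hydraulic_diameter(1, 4), 1)
  expect_equal(hydraulic_diameter(2, 6), 4 / 3)
  expect_error(hydraulic_diameter(1, 0), "perimeter")
})

test_that("distance to the lumen wall is zero on the wall and Lipschitz", {
  cs <- disc_section(0.8, media = 0.3, adv = 0.2)
  df <- distance_to_lumen(cs)
  lab <- cs$label
  nb <- hex_neighbors(cs$grid)
  lum <- lab == LABELS["lumen"]
  wall <- matrix(lab %in% TISSUE_CODES, nrow(lab), ncol(lab)) &
    matrix(neighbor_count(lum, nb) > 0, nrow(lab), ncol(lab))
  expect_true(all(df[wall] == 0))
  expect_true(all(is.infinite(df[lab == LABELS["exterior"]])))
  # one ring in: distance equals the site spacing
  ring1 <- which(!wall & matrix(lab %in% TISSUE_CODES, nrow(lab),
                                ncol(lab)) &
                   matrix(neighbor_count(wall, nb) > 0, nrow(lab),
                          ncol(lab)))
  expect_true(all(abs(df[ring1] - 0.0375) < 1e-9))
  # 1-Lipschitz across neighboring tissue sites
  ti <- which(matrix(lab %in% TISSUE_CODES, nrow(lab), ncol(lab)))
  for (k in 1:6) {
    v <- nb[ti, k]
    ok <- !is.na(v) & lab[v] %in% TISSUE_CODES & is.finite(df[ti])
    expect_true(all(abs(df[ti[ok]] - df[v[ok]]) <= 0.0375 + 1e-9))
  }
})

test_that("contour smoothing is identity at window 1 and damps spikes", {
  ct <- circle_contour(1, n = 180)
  expect_identical(smooth_contour(ct, 1), ct)
  sm <- smooth_contour(ct, 9)
  expect_equal(max(abs(sm - ct)), 0, tolerance = 1e-9)  # circle fixed point

  spiky <- ct
  spiky[90, ] <- spiky[90, ] * 1.5  # radial spike
  amp <- function(x) {
    r <- sqrt(rowSums((x - rep(colMeans(x), each = nrow(x)))^2))
    max(r) - stats::median(r)
  }
  a0 <- amp(spiky)
  a5 <- amp(smooth_contour(spiky, 5))
  a11 <- amp(smooth_contour(spiky, 11))
  expect_lt(a5, a0)
  expect_lt(a11, a5)
  # area guard
  a_in <- abs(polygon_area(spiky, check = FALSE))
  a_out <- abs(polygon_area(smooth_contour(spiky, 21), check = FALSE))
  expect_lt(abs(a_out - a_in) / a_in, 0.02 + 1e-9)
  expect_error(smooth_contour(ct, 4), "odd")
})

test_that("3D nodes map onto plane sites with max-damage aggregation", {
  g <- hex_grid(41, 41, 0.0375)
  s <- 0.0375
  nodes <- data.frame(
    x = c(0, 0.075, 0.075, -2 * s),
    y = c(0, 0, 0, 0),
    z = c(0, 0, 0.4, 0),
    layer = c("media", "media", "plaque", "adventitia"),
    damage = c(0.3, 0.3, 0.9, 0.1))
  out <- map_nodes_to_plane(nodes, origin = c(0, 0, 0),
                            normal = c(0, 0, 1), grid = g,
                            slab_half_width = 1, center = c(0, 0))
  ctr_r <- round(g$n_rows / 2); ctr_c <- round(g$n_cols / 2)
  # node at the plane origin lands at the grid center
  expect_equal(unname(out$label[ctr_r, ctr_c]), unname(LABELS["media"]))
  # a node 0.075 mm along x sits exactly 2 sites away
  expect_equal(unname(out$label[ctr_r, ctr_c + 2]),
               unname(LABELS["plaque"]))
  # two nodes on one site: the maximum damage wins
  expect_equal(out$damage[ctr_r, ctr_c + 2], 0.9)
  expect_equal(unname(out$label[ctr_r, ctr_c - 2]),
               unname(LABELS["adventitia"]))
  expect_error(map_nodes_to_plane(nodes, origin = c(0, 0, 50),
                                  normal = c(0, 0, 1), grid = g),
               "empty slab")
})

test_that("cross-sections round-trip through CSV", {
  cs <- disc_section(0.5, media = 0.2, adv = 0.15,
                     grid = hex_grid(60, 60, 0.0375))
  dmg <- matrix(0, 60, 60)
  dmg[cs$label == LABELS["media"]] <- 0.4
  path <- withr::local_tempfile(fileext = ".csv")
  write_cross_section_csv(cs, path, damage = dmg)
  back <- read_cross_section_csv(path, cs$grid)
  expect_identical(back$cs$label, cs$label)
  expect_equal(back$damage, dmg)
})

test_that("damage JSON maps and laceration mask CSVs round-trip", {
  g <- hex_grid(40, 40, 0.0375)
  set.seed(2)
  dmg <- matrix(0, 40, 40)
  dmg[sample(1600, 50)] <- runif(50)
  pj <- withr::local_tempfile(fileext = ".json")
  write_damage_json(dmg, pj, plane_id = 3)
  expect_equal(read_damage_json(pj), dmg, tolerance = 1e-12)

  mask <- dmg >= 0.5
  pm <- withr::local_tempfile(fileext = ".csv")
  write_mask_csv(mask, pm, plane_id = 3)
  expect_identical(read_mask_csv(pm, g), mask)
  # empty mask round-trips too
  write_mask_csv(matrix(FALSE, 40, 40), pm)
  expect_false(any(read_mask_csv(pm, g)))
})
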