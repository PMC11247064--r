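test_that("isochoric invariants match direct tensor arithmetic", {
  id <- deformation_state(diag(3))
  expect_equal(unlist(isochoric_invariants(id)),
               c(I1bar = 3, I4bar = 1, I6bar = 1))

  # uniaxial circumferential stretch 1.2
  d <- uniaxial_stretch_state(1.2)
  inv <- isochoric_invariants(d)
  expect_equal(inv$I1bar, 1.44 + 2 / 1.2, tolerance = 1e-12)
  expect_equal(inv$I4bar, 1.44)
  expect_equal(inv$I6bar, 1 / 1.2)

  # equibiaxial (1.1, 1.1, 1.1^-2)
  eb <- deformation_state(diag(c(1.1^2, 1.1^2, 1.1^-4)))
  expect_equal(isochoric_invariants(eb)$I1bar, 2 * 1.21 + 1.1^-4,
               tolerance = 1e-12)

  expect_error(deformation_state(diag(c(2, 1, 1))), "det")
})

test_that("fiber strain measures follow the dispersion formula", {
  inv0 <- list(I1bar = 3, I4bar = 1, I6bar = 1)
  expect_equal(unlist(fiber_strains(inv0, 0.2)), c(E4bar = 0, E6bar = 0))

  inv <- isochoric_invariants(uniaxial_stretch_state(1.2))
  es <- fiber_strains(inv, kappa = 0)
  expect_equal(es$E4bar, 0.44, tolerance = 1e-12)
  expect_equal(es$E6bar, 1 / 1.2 - 1, tolerance = 1e-12)

  # kappa = 1/3 is the isotropic limit: E4 = E6 = (I1 - 3)/3
  es3 <- fiber_strains(inv, kappa = 1 / 3)
  expect_equal(es3$E4bar, (inv$I1bar - 3) / 3)
  expect_equal(es3$E6bar, es3$E4bar)

  expect_error(fiber_strains(inv, kappa = 0.4), "kappa")
})

test_that("kappa = 1/3 makes the energy independent of fiber orientation", {
  set.seed(11)
  for (i in 1:5) {
    a <- matrix(rnorm(9), 3)
    C <- crossprod(a) + diag(3) * 0.5
    C <- C / det(C)^(1 / 3)
    p <- layer_params(c10 = 0.1, k1 = 0.2, k2 = 0.3, k3 = 0.15, k4 = 0.2,
                      kappa = 1 / 3, layer = "media")
    w1 <- damaged_sef(deformation_state(C, n_c = c(1, 0, 0),
                                        n_l = c(0, 0, 1)), p)
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    u <- c(-v[2], v[1], 0); u <- u / sqrt(sum(u^2))
    w2 <- damaged_sef(deformation_state(C, n_c = v, n_l = u), p)
    expect_equal(w1, w2, tolerance = 1e-9)
  }
})

test_that("matrix and fiber energies evaluate the stated forms", {
  expect_equal(matrix_energy(3, 0.183), 0)
  expect_equal(matrix_energy(3.5, 0.183), 0.0915)
  expect_equal(matrix_energy(5, 0), 0)

  mp <- media_params()
  fe <- fiber_energy(0.44, -0.1667, mp)
  expect_equal(fe$energy_A1,
               0.080 / (2 * 0.253) * (exp(0.253 * 0.44^2) - 1),
               tolerance = 1e-12)
  expect_equal(fe$energy_A2, 0)  # compressed family excluded
  expect_equal(unlist(fiber_energy(0, 0, mp), use.names = FALSE), c(0, 0))

  # vanishing exponent falls back to the quadratic limit
  q <- layer_params(c10 = 0.1, k1 = 0.2, k2 = 0, k3 = 0.3, k4 = 0,
                    layer = "adventitia")
  fq <- fiber_energy(0.5, 0.2, q)
  expect_equal(fq$energy_A1, 0.2 / 2 * 0.25)
  expect_equal(fq$energy_A2, 0.3 / 2 * 0.04)
})

test_that("damage norm, driver and smoothstep behave as specified", {
  expect_equal(damage_norm(0), 0)
  expect_equal(damage_norm(0.0915), sqrt(2 * 0.0915))
  expect_equal(damage_norm(0.5 * 0.497^2), 0.497)
  expect_error(damage_norm(-1), "negative")

  expect_equal(reduction_factor(0.3, 0.497, 0.808), 0)
  expect_equal(reduction_factor(0.808, 0.497, 0.808), 1)
  expect_equal(reduction_factor(0.6525, 0.497, 0.808), 0.5)
  expect_error(reduction_factor(0.5, 0.8, 0.8), "XiF")

  expect_equal(smoothstep_damage(0), 0)
  expect_equal(smoothstep_damage(1), 1)
  expect_equal(smoothstep_damage(0.5), 0.5)
  # C1 smoothness at onset: difference quotient vanishes
  eps <- 1e-5
  expect_lt(smoothstep_damage(eps) / eps, 1e-8)
  expect_warning(smoothstep_damage(1.2), "clamp")
  s <- seq(0, 1, by = 0.01)
  expect_true(all(diff(smoothstep_damage(s)) >= 0))
})

test_that("damaged energy is a linear reduction of the undamaged one", {
  mp <- media_params()
  d <- uniaxial_stretch_state(1.3)
  w0 <- damaged_sef(d, mp)  # all damage zero
  dm <- damage_state()
  dm$d_m <- 1; dm$d_fA1 <- 1; dm$d_fA2 <- 1
  expect_equal(damaged_sef(d, mp, dm), 0)
  dm2 <- damage_state()
  dm2$d_m <- 0.5
  inv <- isochoric_invariants(d)
  wm <- matrix_energy(inv$I1bar, mp$c10)
  expect_equal(damaged_sef(d, mp, dm2), w0 - 0.5 * wm)
  expect_equal(damaged_sef(d, mp, dm2) <= w0, TRUE)
})

test_that("damage evolution is irreversible along arbitrary histories", {
  mp <- media_params()
  expect_identical(evolve_damage(list(), mp), list())

  # monotone ramp through onset and saturation
  tr <- evolve_damage(seq(1, 2.2, length.out = 15), mp)
  dms <- vapply(tr, function(s) s$d_m, numeric(1))
  expect_equal(dms[1], 0)
  expect_equal(dms[15], 1)
  expect_true(all(diff(dms) >= 0))

  # load-unload: damage at the end equals damage at the peak
  lu <- evolve_damage(c(1, 1.4, 1.8, 1.4, 1), mp)
  expect_equal(lu[[5]]$d_m, lu[[3]]$d_m)

  # property: random walks in stretch never decrease any damage variable
  set.seed(42)
  for (k in 1:10) {
    lam <- pmax(0.75, cumprod(c(1, exp(rnorm(12, 0, 0.12)))))
    tr <- evolve_damage(lam, mp)
    for (f in c("d_m", "d_fA1", "d_fA2", "ximax_m", "ximax_fA1",
                "ximax_fA2")) {
      v <- vapply(tr, `[[`, numeric(1), f)
      expect_true(all(diff(v) >= -1e-12))
    }
    # damaged energy never exceeds the undamaged one
    last <- tr[[length(tr)]]
    def <- uniaxial_stretch_state(lam[length(lam)])
    expect_lte(damaged_sef(def, mp, last), damaged_sef(def, mp) + 1e-12)
  }

  # adventitia has damage disabled
  tra <- evolve_damage(c(1, 1.8, 2.4), adventitia_params())
  expect_equal(tra[[3]]$d_m, 0)
  expect_equal(tra[[3]]$d_fA1, 0)
})

test_that("plaque ductile surrogate yields, initiates and saturates", {
  pp <- plaque_params()
  expect_equal(plaque_damage_1d(1), 0)
  expect_equal(plaque_damage_1d(c(1, 1.3, 1.74)), 0)   # below yield 1.75
  expect_equal(plaque_damage_1d(c(1, 1.75 * exp(0.09))), 0)  # below uf_pl
  expect_gt(plaque_damage_1d(c(1, 2.5)), 0)
  expect_gt(plaque_damage_1d(seq(1, 12, length.out = 30)), 0.99)
  lams <- seq(1.5, 6, by = 0.5)
  dmg <- vapply(lams, function(l) plaque_damage_1d(c(1, l)), numeric(1))
  expect_true(all(diff(dmg) >= 0))
  expect_error(plaque_damage_1d(c(1, -0.5)), "stretch")
})

test_that("element deletion thresholds the damage field monotonically", {
  expect_equal(element_deletion(c(0.79, 0.80, 0.95)),
               c(FALSE, TRUE, TRUE))
  expect_false(any(element_deletion(rep(0, 10))))
  expect_true(all(element_deletion(rep(1, 10))))
  set.seed(7)
  f <- matrix(runif(100), 10)
  m_hi <- element_deletion(f, 0.9)
  m_lo <- element_deletion(f, 0.5)
  expect_true(all(m_lo[m_hi]))  # lowering the threshold only adds sites
})
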