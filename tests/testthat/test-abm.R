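test_that("agent seeding reproduces the layer composition ratios", {
  cs <- disc_section(0.6, media = 0.55, adv = 0.45,
                     grid = hex_grid(120, 120, 0.0375))
  n_med <- sum(cs$label == LABELS["media"])
  n_adv <- sum(cs$label == LABELS["adventitia"])
  expect_gt(n_med, 2000)
  expect_gt(n_adv, 2000)
  rs <- sapply(1:5, function(s) {
    ag <- initialize_agents(cs, seed = s)
    k <- ag$kind
    med <- cs$label == LABELS["media"]
    adv <- cs$label == LABELS["adventitia"]
    c(smc_ecm = sum(k[med] == KINDS["smc"]) / sum(k[med] %in% ECM_CODES),
      col_ela = sum(k[med] == KINDS["collagen"]) /
        sum(k[med] == KINDS["elastin"]),
      fib_col = sum(k[adv] == KINDS["fibroblast"]) /
        sum(k[adv] == KINDS["collagen"]))
  })
  expect_equal(mean(rs["smc_ecm", ]), 0.72, tolerance = 0.05)
  expect_equal(mean(rs["col_ela", ]), 0.63, tolerance = 0.05)
  expect_equal(mean(rs["fib_col", ]), 0.43, tolerance = 0.05)

  # clocks are desynchronized over their cycles
  ag <- initialize_agents(cs, seed = 1)
  cc <- ag$clock_cell[!is.na(ag$clock_cell)]
  expect_true(all(cc >= 0 & cc < 24))
  expect_gt(stats::sd(cc), 5)

  # degenerate composition: all media sites become SMCs
  ag2 <- initialize_agents(cs, abm_composition(smc_ecm = Inf), seed = 1)
  expect_true(all(ag2$kind[cs$label == LABELS["media"]] == KINDS["smc"]))
})

test_that("event probabilities follow the published rule set", {
  r <- abm_rates(beta_med = 1.85)
  p0 <- event_probabilities("smc", "media", 0, 0, r)
  expect_equal(p0$division, 0.05)
  expect_equal(p0$apoptosis, 0.05)
  expect_equal(p0$production, 0.008)
  p1 <- event_probabilities("smc", "media", 1, 1, r)
  expect_equal(p1$division, 0.05 + 0.11 + 0.66)
  expect_equal(p1$production, 0.008 + 0.0413 + 0.21)
  pe <- event_probabilities("collagen", "media", 1, 1, r)
  expect_equal(pe$degradation, 0.008 / 1.85, tolerance = 1e-12)
  expect_equal(pe$division, 0)
  pf <- event_probabilities("fibroblast", "adventitia", 1, 1, r)
  expect_equal(pf$division, 0.05)
  expect_equal(pf$production, 0.008)
  pa <- event_probabilities("collagen", "adventitia", 0, 0, r)
  expect_equal(pa$degradation, 0.008 / 2.5)
  pp <- event_probabilities("plaque_matrix", "plaque", 1, 1, r)
  expect_equal(unlist(pp, use.names = FALSE), rep(0, 4))
  # clamped at 1
  big <- event_probabilities("smc", "media", 5, 5, r)
  expect_equal(big$division, 1)
})

test_that("media events shift the lumen by one site, adventitia by none", {
  cs <- disc_section(0.5, media = 0.25, adv = 0.25,
                     grid = hex_grid(70, 70, 0.0375))
  st <- abm_init(cs, wss_field = flat_wss(10), seed = 5)
  base <- abm_summary(st)
  lab <- st$label
  nb <- hex_neighbors(st$grid)
  wall <- which(lab == LABELS["media"] & st$kind == KINDS["smc"] &
                  matrix(neighbor_count(lab == LABELS["lumen"], nb) > 0,
                         nrow(lab), ncol(lab)))
  site <- wall[1]
  expect_true(apply_event(st, site, "division"))
  s1 <- abm_summary(st)
  expect_equal(s1$n_lumen, base$n_lumen - 1)
  expect_equal(s1$n_media, base$n_media + 1)
  expect_equal(s1$n_adventitia, base$n_adventitia)
  # apoptosis on the same chain restores the counts
  expect_true(apply_event(st, site, "apoptosis"))
  s2 <- abm_summary(st)
  expect_equal(s2$n_lumen, base$n_lumen)
  expect_equal(s2$n_media, base$n_media)

  adv_site <- which(st$label == LABELS["adventitia"] &
                      st$kind == KINDS["fibroblast"])[1]
  expect_true(apply_event(st, adv_site, "production"))
  s3 <- abm_summary(st)
  expect_equal(s3$n_lumen, base$n_lumen)
  expect_equal(s3$n_adventitia, base$n_adventitia + 1)

  expect_true(apply_event(st, adv_site, "degradation"))
  s4 <- abm_summary(st)
  expect_equal(s4$n_adventitia, base$n_adventitia)
  expect_error(apply_event(st, site, "metamorphosis"), "unknown")
})

test_that("site labels always partition the grid", {
  spec <- small_vessel()
  vs <- generate_vessel(spec)
  dm <- generate_damage(vs, seed = 2)
  st <- abm_init(dm[[1]]$cs, damage = dm[[1]]$damage,
                 deleted_plaque = dm[[1]]$deleted_plaque,
                 laceration = dm[[1]]$deleted, seed = 3)
  n_total <- st$grid$n_rows * st$grid$n_cols
  for (k in 1:24) {
    abm_step(st)
    if (k %% 12 == 0) smooth_abm(st)
    s <- abm_summary(st)
    n_ext <- n_total - s$n_lumen - s$n_media - s$n_adventitia -
      s$n_plaque - s$n_void
    expect_equal(s$n_lumen + s$n_media + s$n_adventitia + s$n_plaque +
                   s$n_void + n_ext, n_total)
    expect_true(all(st$label %in% LABELS))
    # agents sit exactly on tissue sites
    expect_true(all((st$kind > 0) == (st$label %in% TISSUE_CODES)))
  }
})

test_that("lumen bookkeeping matches the applied media event balance", {
  cs <- disc_section(0.7, media = 0.3, adv = 0.2,
                     grid = hex_grid(90, 90, 0.0375))
  st <- abm_init(cs, wss_field = flat_wss(10), seed = 11, log_events = TRUE)
  n0 <- sum(st$label == LABELS["lumen"])
  for (k in 1:60) abm_step(st)  # no smoothing: pure event accounting
  ev <- event_log(st)
  media_ev <- ev$layer == LABELS["media"]
  ins <- sum(ev$type %in% c("division", "production") & media_ev)
  rem <- sum(ev$type %in% c("apoptosis", "degradation") & media_ev)
  dn <- sum(st$label == LABELS["lumen"]) - n0
  # every applied media event moves the open boundary by one site;
  # skipped (blocked/non-tissue) events bound the discrepancy
  expect_lte(abs(dn - (rem - ins)), st$counts[["skipped"]])
})

test_that("migration fires by inverse distance and halts on targets", {
  cs <- disc_section(0.5, media = 0.3, adv = 0.2,
                     grid = hex_grid(70, 70, 0.0375))
  st <- abm_init(cs, composition = abm_composition(smc_ecm = Inf),
                 wss_field = flat_wss(10), seed = 2)
  # no laceration: no targets
  pairs <- find_migration_pairs(st)
  expect_length(pairs$targets, 0)

  # mark a small deleted-plaque pocket inside the lumen region
  lab <- st$label
  lum_idx <- which(lab == LABELS["lumen"])
  ctr <- hex_centers(st$grid)
  far <- lum_idx[which.max(ctr$x[lum_idx])]  # lumen site at the wall
  del <- matrix(FALSE, nrow(lab), ncol(lab))
  del[far] <- TRUE
  st$deleted_plaque <- del
  migration_targets(st)
  # damage below threshold: no candidates
  pairs <- find_migration_pairs(st)
  expect_length(pairs$candidates, 0)
  expect_gt(length(pairs$targets), 0)

  st$damage[st$label == LABELS["media"]] <- 0.9
  pairs <- find_migration_pairs(st)
  expect_gt(length(pairs$candidates), 0)
  n_targets0 <- length(pairs$targets)
  expect_gt(length(pairs$candidates), n_targets0)
  # more candidates than targets: migration halts after exactly
  # |targets| moves (repeated passes let distant candidates fire)
  for (i in 1:40) migration_step(st)
  expect_equal(st$counts[["migrations"]], n_targets0)
  expect_true(all(st$label[pairs$targets] == LABELS["media"]))

  # firing probability 1/d: candidates far from the target rarely fire
  d <- 5
  p_hat <- mean(replicate(400, stats::runif(1) < min(1, 1 / d)))
  expect_lt(abs(p_hat - 0.2), 0.08)
})

test_that("fixed seeds give bit-identical trajectories and event logs", {
  spec <- small_vessel()
  vs <- generate_vessel(spec)
  dm <- generate_damage(vs, seed = 4)
  w <- generate_wss(dm)
  r1 <- run_plane(dm[[1]]$cs, damage = dm[[1]]$damage, wss_field = w[[1]],
                  duration_days = 3, coupling_days = 3, seed = 99,
                  deleted_plaque = dm[[1]]$deleted_plaque,
                  laceration = dm[[1]]$deleted, log_events = TRUE)
  r2 <- run_plane(dm[[1]]$cs, damage = dm[[1]]$damage, wss_field = w[[1]],
                  duration_days = 3, coupling_days = 3, seed = 99,
                  deleted_plaque = dm[[1]]$deleted_plaque,
                  laceration = dm[[1]]$deleted, log_events = TRUE)
  expect_identical(r1$daily, r2$daily)
  expect_identical(event_log(r1$state), event_log(r2$state))
  expect_identical(r1$state$label, r2$state$label)
  r3 <- run_plane(dm[[1]]$cs, damage = dm[[1]]$damage, wss_field = w[[1]],
                  duration_days = 3, coupling_days = 3, seed = 100,
                  deleted_plaque = dm[[1]]$deleted_plaque,
                  laceration = dm[[1]]$deleted, log_events = TRUE)
  expect_false(identical(r1$daily, r3$daily))
})

test_that("a lone maximally stimulated cell divides once per cell cycle", {
  # alpha1 = 0 removes baseline division and apoptosis; the shear input is
  # zeroed everywhere except one wall site, whose SMC then divides exactly
  # when its 24-h clock wraps: two mitoses over 48 hours, each certain
  cs <- disc_section(0.4, media = 0.2, adv = 0.15,
                     grid = hex_grid(60, 60, 0.0375))
  rates <- abm_rates(alpha1 = 0, alpha2 = 1e3, alpha4 = 0, alpha5 = 0,
                     alpha6 = 0)
  st <- abm_init(cs, composition = abm_composition(smc_ecm = Inf),
                 wss_field = flat_wss(10), rates = rates, seed = 8,
                 log_events = TRUE)
  st$stim$wssinput[] <- 0
  h <- which(st$label == LABELS["media"] & st$kind == KINDS["smc"] &
               st$stim$dist_field == 0)[1]
  st$stim$wssinput[h] <- 1
  n0 <- sum(st$label == LABELS["lumen"])
  for (k in 1:24) abm_step(st)  # 48 hours
  ev <- event_log(st)
  expect_equal(nrow(ev), 2)
  expect_true(all(ev$type == "division"))
  expect_true(all(ev$p == 1))
  expect_true(all(ev$site == h))
  expect_equal(sum(st$label == LABELS["lumen"]), n0 - 2)
})

test_that("paired boundary smoothing conserves the lumen site count", {
  spec <- small_vessel()
  vs <- generate_vessel(spec)
  dm <- generate_damage(vs, seed = 6)
  st <- abm_init(dm[[1]]$cs, damage = dm[[1]]$damage,
                 deleted_plaque = dm[[1]]$deleted_plaque, seed = 13)
  for (k in 1:36) abm_step(st)
  n_before <- sum(st$label == LABELS["lumen"])
  smooth_abm(st)
  expect_equal(sum(st$label == LABELS["lumen"]), n_before)
})
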