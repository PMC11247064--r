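#' Agent kind codes
#'
#' Integer codes used in the agent kind matrix: none 0, smc 1,
#' fibroblast 2, collagen 3, elastin 4, plaque_matrix 5.
#'
#' @format Named integer vector.
#' @export
KINDS <- c(none = 0L, smc = 1L, fibroblast = 2L, collagen = 3L,
           elastin = 4L, plaque_matrix = 5L)
CELL_CODES <- c(1L, 2L)   # smc, fibroblast
ECM_CODES <- c(3L, 4L)    # collagen, elastin

#' Seed agents onto a cross-section
#'
#' Media sites become smooth muscle cells with probability
#' `smc_ecm / (1 + smc_ecm)` and matrix agents otherwise; matrix agents are
#' collagen with probability `collagen_elastin / (1 + collagen_elastin)`
#' and elastin otherwise.  Adventitia sites are fibroblasts with
#' probability `fibroblast_collagen / (1 + fibroblast_collagen)` and
#' collagen otherwise.  Plaque sites carry inert plaque-matrix agents.
#' Cell clocks are drawn uniformly over the cell cycle and matrix clocks
#' over the matrix cycle, desynchronizing the population.
#'
#' @param cs a [cross_section()].
#' @param composition an [abm_composition()]; `Inf` ratios give degenerate
#'   single-kind layers.
#' @param seed optional integer; when supplied the RNG is seeded here,
#'   otherwise the current RNG stream is used.
#' @param T_cell,T_ecm cell and matrix cycle lengths, hours.
#' @return List of class `agent_grid` with integer `kind` matrix and
#'   numeric clock matrices `clock_cell`, `clock_ecm` (NA where undefined).
#' @export
initialize_agents <- function(cs, composition = abm_composition(),
                              seed = NULL, T_cell = 24, T_ecm = 4) {
  if (!is.null(seed)) set.seed(seed)
  ratio_p <- function(r) if (is.infinite(r)) 1 else r / (1 + r)
  lab <- cs$label
  kind <- matrix(KINDS["none"], nrow(lab), ncol(lab))
  med <- which(lab == LABELS["media"])
  adv <- which(lab == LABELS["adventitia"])
  plq <- which(lab == LABELS["plaque"])
  if (length(med)) {
    is_smc <- stats::runif(length(med)) < ratio_p(composition$smc_ecm)
    is_col <- stats::runif(length(med)) < ratio_p(composition$collagen_elastin)
    kind[med] <- ifelse(is_smc, KINDS["smc"],
                        ifelse(is_col, KINDS["collagen"], KINDS["elastin"]))
  }
  if (length(adv)) {
    is_fib <- stats::runif(length(adv)) <
      ratio_p(composition$fibroblast_collagen)
    kind[adv] <- ifelse(is_fib, KINDS["fibroblast"], KINDS["collagen"])
  }
  kind[plq] <- KINDS["plaque_matrix"]
  cell <- kind %in% CELL_CODES
  host <- kind %in% c(CELL_CODES, ECM_CODES)  # matrix-clock carriers
  clock_cell <- matrix(NA_real_, nrow(lab), ncol(lab))
  clock_ecm <- matrix(NA_real_, nrow(lab), ncol(lab))
  clock_cell[cell] <- stats::runif(sum(cell), 0, T_cell)
  clock_ecm[host] <- stats::runif(sum(host), 0, T_ecm)
  structure(list(kind = kind, clock_cell = clock_cell, clock_ecm = clock_ecm,
                 T_cell = T_cell, T_ecm = T_ecm),
            class = "agent_grid")
}

#' Per-agent event probabilities
#'
#' Media smooth muscle cells divide with probability
#' `alpha1 + alpha2 * WSSinput + alpha3 * Dinput` (clamped to `[0, 1]`) and
#' die with baseline probability `alpha1`; they also host matrix production
#' with probability `alpha4 + alpha5 * WSSinput + alpha6 * Dinput` on the
#' matrix clock.  Media matrix agents degrade with probability
#' `alpha4 / beta_med`.  Adventitia fibroblasts keep baseline rates
#' (`alpha1` division/apoptosis, `alpha4` production) and adventitia
#' collagen degrades at `alpha4 / beta_adv`.  Plaque matrix is inert.
#'
#' @param kind agent kind name (`"smc"`, `"fibroblast"`, `"collagen"`,
#'   `"elastin"`, `"plaque_matrix"`).
#' @param layer `"media"`, `"adventitia"` or `"plaque"`.
#' @param Dinput,WSSinput local stimulus values, `>= 0`.
#' @param rates an [abm_rates()].
#' @return Named list with `division`, `apoptosis`, `production`,
#'   `degradation` (zero where the event does not apply to the agent).
#' @export
event_probabilities <- function(kind, layer, Dinput = 0, WSSinput = 0,
                                rates = abm_rates()) {
  stopifnot(Dinput >= 0, WSSinput >= 0)
  cl <- function(p) pmin(1, pmax(0, p))
  p <- list(division = 0, apoptosis = 0, production = 0, degradation = 0)
  if (layer == "media") {
    if (kind == "smc") {
      p$division <- cl(rates$alpha1 + rates$alpha2 * WSSinput +
                         rates$alpha3 * Dinput)
      p$apoptosis <- cl(rates$alpha1)
      p$production <- cl(rates$alpha4 + rates$alpha5 * WSSinput +
                           rates$alpha6 * Dinput)
    } else if (kind %in% c("collagen", "elastin")) {
      p$degradation <- cl(rates$alpha4 / rates$beta_med)
    }
  } else if (layer == "adventitia") {
    if (kind == "fibroblast") {
      p$division <- cl(rates$alpha1)
      p$apoptosis <- cl(rates$alpha1)
      p$production <- cl(rates$alpha4)
    } else if (kind == "collagen") {
      p$degradation <- cl(rates$alpha4 / rates$beta_adv)
    }
  }
  p
}

#' Initialize an agent-based simulation state for one plane
#'
#' Bundles the cross-section labels, the static post-intervention damage
#' field, the agents, the stimulus fields and the bookkeeping needed by
#' [abm_step()].  The state is an environment, mutated in place by the
#' stepping functions (use [clone_abm_state()] for an independent copy).
#' The shear-input field is computed here and refreshed only at
#' hemodynamic coupling boundaries (see [run_plane()]).
#'
#' @param cs a [cross_section()].
#' @param damage static site damage field in `[0, 1]` (matrix); defaults to
#'   zero (homeostatic run).
#' @param wss_field per-plane shear samples (`angle`, `wss` data frame), or
#'   `NULL` to use [wss_surrogate()] on the current lumen contour.
#' @param composition an [abm_composition()].
#' @param rates an [abm_rates()].
#' @param sparams a [stimulus_params()].
#' @param seed integer RNG seed.
#' @param deleted_plaque optional logical matrix marking plaque sites that
#'   were removed by element deletion (defines the migration target region).
#' @param laceration optional logical matrix of all deleted sites (defines
#'   the recovery-tracking region; defaults to `deleted_plaque`).
#' @param flow_rate,viscosity surrogate hemodynamics settings.
#' @param T_cell,T_ecm,dt_hours clock settings, hours.
#' @param log_events keep a per-event log (site, type, probability, uniform
#'   draw); needed for audit tests, off by default for speed.
#' @return Environment of class `abm_state`.
#' @export
abm_init <- function(cs, damage = NULL, wss_field = NULL,
                     composition = abm_composition(), rates = abm_rates(),
                     sparams = stimulus_params(), seed = 1L,
                     deleted_plaque = NULL, laceration = NULL,
                     flow_rate = 100, viscosity = 0.0035,
                     T_cell = 24, T_ecm = 4, dt_hours = 2,
                     log_events = FALSE) {
  stopifnot(dt_hours > 0, T_cell %% dt_hours == 0, T_ecm %% dt_hours == 0)
  set.seed(seed)
  nr <- cs$grid$n_rows; nc <- cs$grid$n_cols
  if (is.null(damage)) damage <- matrix(0, nr, nc)
  if (is.null(deleted_plaque)) deleted_plaque <- matrix(FALSE, nr, nc)
  if (is.null(laceration)) laceration <- deleted_plaque
  ag <- initialize_agents(cs, composition, seed = NULL,
                          T_cell = T_cell, T_ecm = T_ecm)
  st <- new.env(parent = emptyenv())
  st$grid <- cs$grid
  st$plane_id <- cs$plane_id
  st$axial_mm <- cs$axial_mm
  st$label <- cs$label
  st$kind <- ag$kind
  st$clock_cell <- ag$clock_cell
  st$clock_ecm <- ag$clock_ecm
  st$T_cell <- T_cell
  st$T_ecm <- T_ecm
  st$damage <- damage
  st$deleted_plaque <- deleted_plaque
  st$laceration <- laceration
  st$rates <- rates
  st$sparams <- sparams
  st$composition <- composition
  st$flow_rate <- flow_rate
  st$viscosity <- viscosity
  st$dt_hours <- dt_hours
  st$t_hours <- 0
  st$centers <- hex_centers(cs$grid)
  st$nb <- cs_neighbors(cs)
  st$log_events <- log_events
  st$log <- list()
  st$counts <- c(applied = 0L, skipped = 0L, migrations = 0L)
  class(st) <- "abm_state"
  migration_targets(st)
  refresh_stimulus(st, wss_field)
  st
}

#' Recompute the migration target set from the deleted-plaque mask
#'
#' Targets are the open (lumen/void) sites inside or adjacent to the
#' laceration-deleted plaque region of the post-intervention
#' configuration.  The set is fixed when the state is created: a target,
#' once occupied by a migrating cell, is spent and never re-enters the
#' pool, so migration halts after at most the initial target count.
#'
#' @param st an `abm_state` (mutated in place).
#' @return The state, invisibly.
#' @export
migration_targets <- function(st) {
  lab <- st$label
  nr <- nrow(lab); nc <- ncol(lab)
  open <- matrix(lab %in% OPEN_CODES, nr, nc)
  near_del <- st$deleted_plaque |
    matrix(neighbor_count(st$deleted_plaque, st$nb) > 0, nr, nc)
  st$mig_targets <- which(open & near_del)
  invisible(st)
}

#' Cross-section view of a simulation state
#'
#' @param st an `abm_state`.
#' @return The current [cross_section()].
#' @export
state_cross_section <- function(st) {
  cross_section(st$grid, st$label, plane_id = st$plane_id,
                axial_mm = st$axial_mm)
}

#' Deep copy of a simulation state
#'
#' @param st an `abm_state`.
#' @return An independent `abm_state` environment.
#' @export
clone_abm_state <- function(st) {
  out <- new.env(parent = emptyenv())
  for (nm in ls(st, all.names = TRUE)) assign(nm, get(nm, envir = st), out)
  class(out) <- "abm_state"
  out
}

#' @export
print.abm_state <- function(x, ...) {
  cat(sprintf("<abm_state> plane %s, t = %.1f d, lumen %.3f mm^2\n",
              x$plane_id, x$t_hours / 24,
              sum(x$label == LABELS["lumen"]) * hex_site_area(x$grid)))
  invisible(x)
}

# Recompute the shear-input field for the current configuration (coupling
# boundaries only); mutates the state.
refresh_stimulus <- function(st, wss_field = NULL) {
  cs <- state_cross_section(st)
  ct <- lumen_contour(cs)
  if (is.null(wss_field))
    wss_field <- wss_surrogate(ct, st$flow_rate, st$viscosity)
  dist_field <- distance_to_lumen(cs, max_dist = 3 * st$sparams$dist)
  dwall <- wall_dysfunction(cs, wss_field, st$sparams)
  st$stim <- list(
    wssinput = propagate_wssinput(dwall, cs, st$sparams, dist_field),
    dwall = dwall, dist_field = dist_field,
    wss_field = wss_field, contour = ct)
  invisible(st)
}

# Walk site-by-site from `from` toward (inward = lumen/void) or away from
# (outward = exterior) the reference point, returning the tissue path and
# the terminal open site; NULL when blocked.
walk_chain <- function(label, nb, x, y, cx, cy, from, outward = FALSE) {
  path <- integer(256); n <- 0L; cur <- from
  d2cur <- (x[cur] - cx)^2 + (y[cur] - cy)^2
  repeat {
    n <- n + 1L
    if (n > length(path)) return(NULL)
    path[n] <- cur
    nbrs <- nb[cur, ]
    nbrs <- nbrs[!is.na(nbrs)]
    if (!length(nbrs)) return(NULL)
    d2 <- (x[nbrs] - cx)^2 + (y[nbrs] - cy)^2
    k <- if (outward) which.max(d2) else which.min(d2)
    if ((!outward && d2[k] >= d2cur) || (outward && d2[k] <= d2cur))
      return(NULL)  # blocked: no strict progress toward the open region
    cur <- nbrs[k]; d2cur <- d2[k]
    lb <- label[cur]
    if (!outward && lb %in% OPEN_CODES)
      return(list(path = path[seq_len(n)], terminal = cur))
    if (outward && lb == LABELS["exterior"])
      return(list(path = path[seq_len(n)], terminal = cur))
  }
}

# Insert a new agent at `site`, displacing the radial chain one site toward
# the open region.  Mutates the state; returns TRUE on success.
chain_insert <- function(st, site, new_kind, outward, cx, cy) {
  w <- walk_chain(st$label, st$nb, st$centers$x, st$centers$y, cx, cy, site,
                  outward = outward)
  if (is.null(w)) return(FALSE)
  p <- w$path; tm <- w$terminal
  dst <- c(p[-1], tm)
  st$label[dst] <- st$label[p]
  st$kind[dst] <- st$kind[p]
  st$clock_cell[dst] <- st$clock_cell[p]
  st$clock_ecm[dst] <- st$clock_ecm[p]
  st$kind[p[1]] <- new_kind
  st$clock_cell[p[1]] <- if (new_kind %in% CELL_CODES) 0 else NA_real_
  st$clock_ecm[p[1]] <- 0
  if (new_kind %in% CELL_CODES && length(p) > 1)
    st$clock_cell[p[2]] <- 0  # parent clock also restarts after mitosis
  TRUE
}

# Remove the agent at `site`; the chain between the site and the open
# region collapses one site, opening the innermost (media) or outermost
# (adventitia) tissue site.  Mutates the state; returns TRUE on success.
chain_remove <- function(st, site, outward, cx, cy) {
  w <- walk_chain(st$label, st$nb, st$centers$x, st$centers$y, cx, cy, site,
                  outward = outward)
  if (is.null(w)) return(FALSE)
  p <- w$path; tm <- w$terminal
  if (length(p) > 1) {
    src <- p[-1]; dst <- p[-length(p)]
    st$kind[dst] <- st$kind[src]
    st$clock_cell[dst] <- st$clock_cell[src]
    st$clock_ecm[dst] <- st$clock_ecm[src]
    st$label[dst] <- st$label[src]
  }
  last <- p[length(p)]
  st$kind[last] <- KINDS["none"]
  st$clock_cell[last] <- NA_real_
  st$clock_ecm[last] <- NA_real_
  st$label[last] <- st$label[tm]  # joins the adjacent open region
  TRUE
}

lumen_centroid <- function(st) {
  lum <- st$label == LABELS["lumen"]
  c(mean(st$centers$x[lum]), mean(st$centers$y[lum]))
}

#' Apply a single biological event to a simulation state
#'
#' Media (and plaque-region) insertions displace the radial agent chain one
#' site toward the lumen, turning the innermost open site into tissue
#' (lumen area decreases by one site); removals collapse the chain, opening
#' one wall site (lumen area increases by one site).  Adventitia events
#' displace the chain through the outer boundary and leave the lumen
#' untouched.  Events whose chain is blocked by the grid edge are skipped
#' and counted.
#'
#' @param st an `abm_state` (mutated in place).
#' @param site linear site index of the hosting agent.
#' @param type one of `"division"`, `"apoptosis"`, `"production"`,
#'   `"degradation"`.
#' @param new_kind agent kind code for insertions; defaults to the host
#'   kind for division and to collagen for production.
#' @param centroid optional precomputed lumen centroid `c(x, y)`.
#' @return `TRUE` if the event was applied, `FALSE` if skipped.
#' @export
apply_event <- function(st, site, type, new_kind = NULL, centroid = NULL) {
  if (is.null(centroid)) centroid <- lumen_centroid(st)
  outward <- st$label[site] == LABELS["adventitia"]
  ok <- switch(type,
    division = chain_insert(st, site, new_kind %||% st$kind[site],
                            outward, centroid[1], centroid[2]),
    production = chain_insert(st, site, new_kind %||% KINDS["collagen"],
                              outward, centroid[1], centroid[2]),
    apoptosis = ,
    degradation = chain_remove(st, site, outward, centroid[1], centroid[2]),
    stop("unknown event type: ", type, call. = FALSE))
  st$counts[if (ok) "applied" else "skipped"] <-
    st$counts[if (ok) "applied" else "skipped"] + 1L
  ok
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Migration candidates and target sites
#'
#' Candidates are smooth muscle cells on media sites that line the lumen
#' and carry post-intervention damage at or above the migration threshold;
#' targets are the still-open, not-yet-occupied sites of the fixed
#' post-intervention target pool (see [migration_targets()]).
#'
#' @param st an `abm_state`.
#' @return List with integer vectors `candidates` and `targets` (linear
#'   site indices).
#' @export
find_migration_pairs <- function(st) {
  lab <- st$label
  nr <- nrow(lab); nc <- ncol(lab)
  targets <- st$mig_targets[lab[st$mig_targets] %in% OPEN_CODES]
  if (!length(targets))
    return(list(candidates = integer(0), targets = integer(0)))
  lum <- lab == LABELS["lumen"]
  cand <- which(lab == LABELS["media"] &
                  st$kind == KINDS["smc"] &
                  st$damage >= st$rates$migration_threshold &
                  matrix(neighbor_count(lum, st$nb) > 0, nr, nc))
  list(candidates = cand, targets = targets)
}

#' One migration pass
#'
#' Each candidate fires with probability `min(1, 1 / d_min)` where `d_min`
#' is its distance (in site-spacing units) to the nearest free target; a
#' firing candidate moves to that target (ties broken by lowest site
#' index), which becomes media tissue, while the vacated wall site joins
#' the lumen.  The pass halts when candidates or free targets are
#' exhausted.
#'
#' @param st an `abm_state` (mutated in place).
#' @param pairs optional precomputed [find_migration_pairs()] result.
#' @return The state, invisibly.
#' @export
migration_step <- function(st, pairs = find_migration_pairs(st)) {
  cand <- pairs$candidates; targ <- pairs$targets
  if (!length(cand) || !length(targ)) return(invisible(st))
  x <- st$centers$x; y <- st$centers$y; s <- st$grid$spacing
  free <- targ
  ord <- if (length(cand) > 1) sample(length(cand)) else 1L
  for (i in ord) {
    if (!length(free)) break
    ci <- cand[i]
    d <- sqrt((x[free] - x[ci])^2 + (y[free] - y[ci])^2) / s
    j <- which.min(d)  # which.min takes the lowest index on ties
    p <- min(1, 1 / max(1, d[j]))
    u <- stats::runif(1)
    if (u >= p) next
    t1 <- free[j]
    st$label[t1] <- LABELS["media"]
    st$kind[t1] <- KINDS["smc"]
    st$clock_cell[t1] <- 0
    st$clock_ecm[t1] <- 0
    st$label[ci] <- LABELS["lumen"]
    st$kind[ci] <- KINDS["none"]
    st$clock_cell[ci] <- NA_real_
    st$clock_ecm[ci] <- NA_real_
    st$counts["migrations"] <- st$counts["migrations"] + 1L
    st$mig_targets <- setdiff(st$mig_targets, t1)  # target spent for good
    free <- free[-j]
  }
  invisible(st)
}

#' Advance the simulation by one time step
#'
#' Order within a step: a migration pass (while laceration targets remain),
#' then clock advancement; agents whose cycle wraps are tested for their
#' events.  Competing events on one agent (division vs apoptosis,
#' production vs degradation host roles) are decided by independent uniform
#' draws; a division and an apoptosis firing together on one cell cancel,
#' keeping the homeostatic expectation exactly balanced.  Accepted events
#' are applied in random site order.
#'
#' @param st an `abm_state` (mutated in place).
#' @param dt time step, hours (default the state's `dt_hours`).
#' @return The state, invisibly.
#' @export
abm_step <- function(st, dt = st$dt_hours) {
  t_days <- st$t_hours / 24
  pairs <- find_migration_pairs(st)
  if (length(pairs$targets) && length(pairs$candidates))
    migration_step(st, pairs)
  # clocks
  st$clock_cell <- st$clock_cell + dt
  st$clock_ecm <- st$clock_ecm + dt
  act_cell <- which(!is.na(st$clock_cell) & st$clock_cell >= st$T_cell)
  act_ecm <- which(!is.na(st$clock_ecm) & st$clock_ecm >= st$T_ecm)
  st$clock_cell[act_cell] <- st$clock_cell[act_cell] - st$T_cell
  st$clock_ecm[act_ecm] <- st$clock_ecm[act_ecm] - st$T_ecm
  lab <- st$label
  r <- st$rates
  infl <- inflammation(t_days, st$sparams)
  W <- st$stim$wssinput
  events <- list()
  if (length(act_cell)) {
    ac <- act_cell[st$kind[act_cell] %in% CELL_CODES]
    if (length(ac)) {
      med <- lab[ac] == LABELS["media"]
      p_div <- ifelse(med,
                      pmin(1, r$alpha1 + r$alpha2 * W[ac] +
                             r$alpha3 * st$damage[ac] * infl),
                      r$alpha1)
      p_apo <- rep(r$alpha1, length(ac))
      u1 <- stats::runif(length(ac)); u2 <- stats::runif(length(ac))
      div <- u1 < p_div; apo <- u2 < p_apo
      cancel <- div & apo
      div <- div & !cancel; apo <- apo & !cancel
      if (any(div))
        events$division <- data.frame(site = ac[div], type = "division",
                                      kind = st$kind[ac[div]],
                                      layer = lab[ac[div]],
                                      p = p_div[div], u = u1[div])
      if (any(apo))
        events$apoptosis <- data.frame(site = ac[apo], type = "apoptosis",
                                       kind = st$kind[ac[apo]],
                                       layer = lab[ac[apo]],
                                       p = p_apo[apo], u = u2[apo])
    }
  }
  if (length(act_ecm)) {
    ph <- act_ecm[st$kind[act_ecm] %in% CELL_CODES]
    dh <- act_ecm[st$kind[act_ecm] %in% ECM_CODES]
    if (length(ph)) {
      med <- lab[ph] == LABELS["media"]
      p_pr <- ifelse(med,
                     pmin(1, r$alpha4 + r$alpha5 * W[ph] +
                            r$alpha6 * st$damage[ph] * infl),
                     r$alpha4)
      u3 <- stats::runif(length(ph))
      pr <- u3 < p_pr
      if (any(pr))
        events$production <- data.frame(site = ph[pr], type = "production",
                                        kind = st$kind[ph[pr]],
                                        layer = lab[ph[pr]],
                                        p = p_pr[pr], u = u3[pr])
    }
    if (length(dh)) {
      med <- lab[dh] == LABELS["media"]
      p_dg <- ifelse(med, r$alpha4 / r$beta_med, r$alpha4 / r$beta_adv)
      u4 <- stats::runif(length(dh))
      dg <- u4 < p_dg
      if (any(dg))
        events$degradation <- data.frame(site = dh[dg], type = "degradation",
                                         kind = st$kind[dh[dg]],
                                         layer = lab[dh[dg]],
                                         p = p_dg[dg], u = u4[dg])
    }
  }
  if (length(events)) {
    ev <- do.call(rbind, events)
    if (nrow(ev) > 1) ev <- ev[sample(nrow(ev)), , drop = FALSE]
    pc <- if (is.infinite(st$composition$collagen_elastin)) 1 else
      st$composition$collagen_elastin / (1 + st$composition$collagen_elastin)
    ctr <- lumen_centroid(st)
    for (i in seq_len(nrow(ev))) {
      site <- ev$site[i]; type <- ev$type[i]
      # the hosting agent may have been displaced by an earlier chain in
      # this step; the drawn event count stays faithful as long as the
      # site is still tissue, so only non-tissue sites are skipped
      if (!(st$label[site] %in% TISSUE_CODES)) {
        st$counts["skipped"] <- st$counts["skipped"] + 1L
        next
      }
      nk <- NULL
      if (type == "division") {
        nk <- ev$kind[i]
      } else if (type == "production") {
        nk <- if (lab[site] == LABELS["media"]) {
          if (stats::runif(1) < pc) KINDS["collagen"] else KINDS["elastin"]
        } else KINDS["collagen"]
      }
      apply_event(st, site, type, new_kind = nk, centroid = ctr)
    }
    if (st$log_events)
      st$log[[length(st$log) + 1L]] <- cbind(t_hours = st$t_hours, ev)
  }
  st$t_hours <- st$t_hours + dt
  invisible(st)
}

#' Boundary smoothing of the lattice state
#'
#' Removes single-site irregularities at the lumen-tissue interface by a
#' majority vote: a lumen site with more than four tissue neighbors (a
#' pit) is a fill candidate, and a media site with more than four open
#' neighbors (a spike) is a carve candidate.  Fills and carves are applied
#' in matched pairs -- the deepest pits become media tissue seeded with a
#' fresh smooth muscle cell while the sharpest spikes dissolve into the
#' lumen -- so a smoothing pass never changes the lumen site count.  On
#' the hexagonal lattice pits are detected more readily than spikes, and
#' an unpaired pass would steadily push the wall inward; pairing removes
#' that bias (and satisfies the area guard by construction).
#'
#' @param st an `abm_state` (mutated in place).
#' @param max_area_change relative lumen-area guard retained for interface
#'   compatibility; the paired pass always meets it.
#' @return The state, invisibly.
#' @export
smooth_abm <- function(st, max_area_change = 0.02) {
  lab <- st$label
  nr <- nrow(lab); nc <- ncol(lab)
  lum <- lab == LABELS["lumen"]
  n_lum <- sum(lum)
  if (n_lum == 0) return(invisible(st))
  tis <- matrix(lab %in% TISSUE_CODES, nr, nc)
  n_tis_nb <- matrix(neighbor_count(tis, st$nb), nr, nc)
  n_open_nb <- matrix(neighbor_count(matrix(lab %in% OPEN_CODES, nr, nc),
                                     st$nb), nr, nc)
  fill <- which(lum & n_tis_nb > 4)
  carve <- which(lab == LABELS["media"] & n_open_nb > 4)
  k <- min(length(fill), length(carve), ceiling(max_area_change * n_lum))
  if (k == 0) return(invisible(st))
  fill <- fill[order(-n_tis_nb[fill], fill)][seq_len(k)]
  carve <- carve[order(-n_open_nb[carve], carve)][seq_len(k)]
  if (length(fill)) {
    # inherit the kind of a random adjacent media agent so smoothing does
    # not perturb the local composition
    for (f in fill) {
      nbs <- st$nb[f, ]
      nbs <- nbs[!is.na(nbs)]
      nbs <- nbs[st$label[nbs] == LABELS["media"] &
                   st$kind[nbs] %in% c(CELL_CODES, ECM_CODES)]
      nk <- if (length(nbs)) {
        st$kind[if (length(nbs) > 1) nbs[sample.int(length(nbs), 1)] else nbs]
      } else KINDS["smc"]
      st$label[f] <- LABELS["media"]
      st$kind[f] <- nk
      st$clock_cell[f] <- if (nk %in% CELL_CODES) 0 else NA_real_
      st$clock_ecm[f] <- 0
    }
  }
  if (length(carve)) {
    st$label[carve] <- LABELS["lumen"]
    st$kind[carve] <- KINDS["none"]
    st$clock_cell[carve] <- NA_real_
    st$clock_ecm[carve] <- NA_real_
  }
  invisible(st)
}

#' Composition and area summary of a state
#'
#' @param st an `abm_state`.
#' @return One-row data frame of site counts by label, agent counts by
#'   kind, the lumen area (mm^2) and the laceration void fraction (share of
#'   initially deleted sites still open).
#' @export
abm_summary <- function(st) {
  lab <- st$label
  kind <- st$kind
  lac <- st$laceration
  lvf <- if (any(lac)) mean(lab[lac] %in% OPEN_CODES) else NA_real_
  data.frame(
    t_days = st$t_hours / 24,
    lumen_area_mm2 = sum(lab == LABELS["lumen"]) * hex_site_area(st$grid),
    n_lumen = sum(lab == LABELS["lumen"]),
    n_media = sum(lab == LABELS["media"]),
    n_adventitia = sum(lab == LABELS["adventitia"]),
    n_plaque = sum(lab == LABELS["plaque"]),
    n_void = sum(lab == LABELS["void"]),
    n_smc = sum(kind == KINDS["smc"]),
    n_fibroblast = sum(kind == KINDS["fibroblast"]),
    n_collagen = sum(kind == KINDS["collagen"]),
    n_elastin = sum(kind == KINDS["elastin"]),
    n_media_smc = sum(kind == KINDS["smc"] & lab == LABELS["media"]),
    n_media_ecm = sum(kind %in% ECM_CODES & lab == LABELS["media"]),
    lac_void_fraction = lvf)
}

#' Run the agent-based model on one plane
#'
#' Advances a plane for `duration_days` with (by default) 2-hour steps,
#' daily boundary smoothing and daily checkpoints.  The inflammatory input
#' follows the static damage field and the inflammation clock at every
#' step, while the shear input is recomputed from the remodeled lumen
#' contour only at hemodynamic coupling boundaries.
#'
#' @param cs a [cross_section()].
#' @param damage static damage field matrix (default zero).
#' @param wss_field external shear samples for the first cycle (`angle`,
#'   `wss` data frame) or `NULL` for the built-in surrogate; after a
#'   coupling boundary the surrogate is applied to the remodeled contour.
#' @param duration_days,coupling_days simulation horizon and hemodynamic
#'   update period, days.
#' @param seed integer RNG seed.
#' @param smooth_every_hours boundary-smoothing cadence (default daily).
#' @param ... further arguments passed to [abm_init()].
#' @return List of class `plane_run` with `daily` (checkpoint data frame),
#'   `contours` (named by day: start, coupling boundaries, end) and the
#'   final `state`.
#' @export
run_plane <- function(cs, damage = NULL, wss_field = NULL,
                      duration_days = 60, coupling_days = 30, seed = 1L,
                      smooth_every_hours = 24, ...) {
  st <- abm_init(cs, damage = damage, wss_field = wss_field, seed = seed, ...)
  run_plane_from(st, duration_days = duration_days,
                 coupling_days = coupling_days,
                 smooth_every_hours = smooth_every_hours)
}

#' Continue a simulation state for a further period
#'
#' Used directly by the multi-plane pipeline to continue replicates from a
#' selected representative configuration.
#'
#' @param st an `abm_state` (mutated in place).
#' @inheritParams run_plane
#' @return A `plane_run` list (see [run_plane()]).
#' @export
run_plane_from <- function(st, duration_days, coupling_days = 30,
                           smooth_every_hours = 24) {
  dt <- st$dt_hours
  n_steps <- round(duration_days * 24 / dt)
  steps_per_day <- round(24 / dt)
  smooth_every <- max(1L, round(smooth_every_hours / dt))
  daily <- vector("list", duration_days + 1)
  daily[[1]] <- abm_summary(st)
  t0_days <- st$t_hours / 24
  contours <- stats::setNames(list(st$stim$contour), as.character(t0_days))
  for (k in seq_len(n_steps)) {
    abm_step(st, dt)
    if (k %% smooth_every == 0) smooth_abm(st)
    if (k %% steps_per_day == 0)
      daily[[k / steps_per_day + 1]] <- abm_summary(st)
    el_days <- k * dt / 24
    if (k < n_steps && el_days %% coupling_days == 0) {
      refresh_stimulus(st)  # hemodynamic coupling update
      contours[[as.character(t0_days + el_days)]] <- st$stim$contour
    }
  }
  contours[[as.character(t0_days + duration_days)]] <-
    lumen_contour(state_cross_section(st))
  structure(list(daily = do.call(rbind, daily), contours = contours,
                 state = st),
            class = "plane_run")
}

#' Event log of a run
#'
#' @param st an `abm_state` run with `log_events = TRUE`.
#' @return Data frame of time-stamped event records (site, type, firing
#'   probability and uniform draw).
#' @export
event_log <- function(st) {
  if (!length(st$log))
    return(data.frame(t_hours = numeric(0), site = integer(0),
                      type = character(0), kind = integer(0),
                      layer = integer(0), p = numeric(0), u = numeric(0)))
  out <- do.call(rbind, st$log)
  rownames(out) <- NULL
  out
}
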