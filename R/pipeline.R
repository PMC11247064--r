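#' Radii of a closed contour at equally spaced angles
#'
#' Samples the polygon radius about `center` at `n_angles` equal angles by
#' linear interpolation between vertices ordered by angle.
#'
#' @param contour matrix `n x 2`.
#' @param center optional `c(x, y)`; defaults to the vertex centroid.
#' @param n_angles number of samples.
#' @return Numeric vector of radii at angles `-pi + (k - 1/2) * 2*pi / n`.
#' @export
contour_radii <- function(contour, center = NULL, n_angles = 360) {
  if (is.null(center)) center <- c(mean(contour[, 1]), mean(contour[, 2]))
  th <- atan2(contour[, 2] - center[2], contour[, 1] - center[1])
  r <- sqrt((contour[, 1] - center[1])^2 + (contour[, 2] - center[2])^2)
  o <- order(th)
  th <- th[o]; r <- r[o]
  # periodic padding for interpolation across the -pi/pi seam
  th2 <- c(th[length(th)] - 2 * pi, th, th[1] + 2 * pi)
  r2 <- c(r[length(r)], r, r[1])
  ang <- -pi + (seq_len(n_angles) - 0.5) * 2 * pi / n_angles
  stats::approx(th2, r2, xout = ang, ties = mean)$y
}

#' Select the representative replicate by contour RMSD
#'
#' The replicate contours are resampled to a common angular
#' parameterization about the shared centroid (mean of all vertices); the
#' average contour is the pointwise mean radius, and the replicate
#' minimizing the root-mean-square deviation of its radii from the average
#' is returned (ties broken by lowest index).
#'
#' @param contours list of contour matrices (>= 2).
#' @param n_angles angular resolution of the comparison.
#' @return Integer index of the representative replicate (1-based), with
#'   attribute `rmsd` giving all deviations.
#' @export
select_replicate <- function(contours, n_angles = 360) {
  if (length(contours) < 2)
    stop("need at least two replicate contours", call. = FALSE)
  allv <- do.call(rbind, contours)
  center <- c(mean(allv[, 1]), mean(allv[, 2]))
  rad <- vapply(contours, contour_radii, numeric(n_angles),
                center = center, n_angles = n_angles)
  avg <- rowMeans(rad)
  rmsd <- sqrt(colMeans((rad - avg)^2))
  # ties (within numerical noise) break toward the lowest index
  best <- which(rmsd <= min(rmsd) + 1e-8 * max(1, min(rmsd)))[1]
  structure(best, rmsd = rmsd)
}

# Deterministic sub-seed for (plane, cycle, replicate); kept below 2^31.
derive_seed <- function(seed, plane, cycle, replicate) {
  as.integer((as.double(seed) + 7919 * plane + 104729 * cycle +
                1299709 * replicate) %% 2147483647)
}

#' Run the coupled multi-plane remodeling framework
#'
#' For each plane and each hemodynamic coupling cycle, `replicates`
#' stochastic simulations are advanced for `coupling_days`; the replicate
#' whose lumen contour is closest (RMSD of radii) to the replicate average
#' is selected as representative, all replicates restart from its state,
#' and the shear field is recomputed on its remodeled contour before the
#' next cycle.  Lofted lumen surfaces are assembled at the start and at
#' every cycle boundary.
#'
#' @param damaged per-plane list from [generate_damage()] (or a list with
#'   fields `cs`, `damage`, `deleted`, `deleted_plaque` per plane).
#' @param wss_fields optional per-plane list of (`angle`, `wss`) data
#'   frames for the first cycle (e.g. [generate_wss()] or
#'   [read_wss_csv()]); `NULL` uses the surrogate throughout.
#' @param replicates stochastic replicates per plane per cycle.
#' @param horizon_days,coupling_days simulation horizon and coupling
#'   period, days (`horizon_days` must be a multiple of `coupling_days`).
#' @param seed base seed; every replicate derives its own stream from
#'   (plane, cycle, replicate).
#' @param axial_positions plane positions for lofting, mm; defaults to the
#'   sections' `axial_mm`.
#' @param resume a previous `framework_run` to continue from (its final
#'   states and elapsed cycles are reused; `damaged` is ignored then).
#' @param verbose print per-cycle progress.
#' @param ... further arguments passed to [abm_init()] (rates, stimulus
#'   parameters, composition, flow settings, ...).
#' @return List of class `framework_run`: `daily` (selected-replicate
#'   checkpoint series, all planes), `areas` (plane x day matrix, mm^2),
#'   `contours` (per plane, per checkpoint), `selected` (replicate
#'   indices), `surfaces` (lofted meshes per checkpoint) and `states`
#'   (final per-plane states).
#' @export
run_framework <- function(damaged, wss_fields = NULL, replicates = 3,
                          horizon_days = 60, coupling_days = 30, seed = 1L,
                          axial_positions = NULL, resume = NULL,
                          verbose = FALSE, ...) {
  if (horizon_days %% coupling_days != 0)
    stop("horizon_days must be a multiple of coupling_days", call. = FALSE)
  n_cycles <- horizon_days %/% coupling_days
  if (is.null(resume)) {
    n_planes <- length(damaged)
    states <- vector("list", n_planes)
    daily <- vector("list", n_planes)
    contours <- lapply(seq_len(n_planes), function(i) list())
    selected <- matrix(NA_integer_, n_planes, 0)
    cycle0 <- 0L
  } else {
    n_planes <- length(resume$states)
    states <- resume$states
    daily <- resume$.daily_list
    contours <- resume$contours
    selected <- resume$selected
    cycle0 <- ncol(resume$selected)
  }
  for (cyc in seq_len(n_cycles)) {
    sel_col <- rep(NA_integer_, n_planes)
    for (p in seq_len(n_planes)) {
      reps <- vector("list", replicates)
      runs <- vector("list", replicates)
      for (r in seq_len(replicates)) {
        sd <- derive_seed(seed, p, cycle0 + cyc, r)
        if (is.null(states[[p]])) {
          st <- tryCatch(
            abm_init(damaged[[p]]$cs, damage = damaged[[p]]$damage,
                     wss_field = if (!is.null(wss_fields))
                       wss_fields[[p]] else NULL,
                     deleted_plaque = damaged[[p]]$deleted_plaque,
                     laceration = damaged[[p]]$deleted,
                     seed = sd, ...),
            error = function(e) stop("plane ", p, ": ", conditionMessage(e),
                                     call. = FALSE))
        } else {
          st <- clone_abm_state(states[[p]])
          set.seed(sd)
        }
        runs[[r]] <- run_plane_from(st, duration_days = coupling_days,
                                    coupling_days = coupling_days)
        reps[[r]] <- st
      }
      cts <- lapply(runs, function(x) x$contours[[length(x$contours)]])
      sel <- select_replicate(cts)
      sel_col[p] <- sel
      states[[p]] <- reps[[sel]]
      if (is.null(daily[[p]])) {
        daily[[p]] <- cbind(plane = p, runs[[sel]]$daily)
        contours[[p]][["0"]] <- runs[[sel]]$contours[[1]]
      } else {
        daily[[p]] <- rbind(daily[[p]], cbind(plane = p,
                                              runs[[sel]]$daily[-1, ]))
      }
      contours[[p]][[as.character((cycle0 + cyc) * coupling_days)]] <-
        cts[[sel]]
      if (verbose)
        message(sprintf("cycle %d plane %d: replicate %d selected",
                        cycle0 + cyc, p, sel))
    }
    selected <- cbind(selected, sel_col)
  }
  all_daily <- do.call(rbind, daily)
  days <- sort(unique(all_daily$t_days))
  areas <- matrix(NA_real_, n_planes, length(days),
                  dimnames = list(NULL, days))
  for (p in seq_len(n_planes)) {
    dd <- daily[[p]]
    areas[p, as.character(dd$t_days)] <- dd$lumen_area_mm2
  }
  if (is.null(axial_positions))
    axial_positions <- vapply(states, function(s) s$axial_mm, numeric(1))
  surfaces <- NULL
  if (n_planes >= 2) {
    cps <- names(contours[[1]])
    surfaces <- lapply(cps, function(cp)
      loft_surface(lapply(contours, `[[`, cp), axial_positions))
    names(surfaces) <- cps
  }
  structure(list(daily = all_daily, areas = areas, contours = contours,
                 selected = selected, surfaces = surfaces, states = states,
                 .daily_list = daily),
            class = "framework_run")
}

#' Loft a triangle-mesh surface through stacked contours
#'
#' Each contour is resampled to `n_vertices` radii at equal angles about
#' its own centroid (start vertex at angle zero) and consecutive rings are
#' joined by a ruled band of triangles, giving an open tube (Euler
#' characteristic zero).
#'
#' @param contours list of contour matrices, ordered along the axis.
#' @param axial_positions axial coordinate of each contour, mm.
#' @param n_vertices vertices per ring (default 200).
#' @return List of class `loft_mesh` with `vertices` (`N x 3`) and `faces`
#'   (`M x 3`, 1-based).
#' @export
loft_surface <- function(contours, axial_positions, n_vertices = 200) {
  np <- length(contours)
  if (np < 2) stop("need at least two planes to loft", call. = FALSE)
  if (length(axial_positions) != np)
    stop("one axial position per contour is required", call. = FALSE)
  ang <- -pi + (seq_len(n_vertices) - 0.5) * 2 * pi / n_vertices
  verts <- vector("list", np)
  for (i in seq_len(np)) {
    ct <- contours[[i]]
    ctr <- c(mean(ct[, 1]), mean(ct[, 2]))
    r <- contour_radii(ct, ctr, n_vertices)
    verts[[i]] <- cbind(ctr[1] + r * cos(ang), ctr[2] + r * sin(ang),
                        axial_positions[i])
  }
  vertices <- do.call(rbind, verts)
  faces <- vector("list", np - 1)
  for (i in seq_len(np - 1)) {
    a <- (i - 1) * n_vertices + seq_len(n_vertices)
    b <- i * n_vertices + seq_len(n_vertices)
    a2 <- c(a[-1], a[1]); b2 <- c(b[-1], b[1])
    faces[[i]] <- rbind(cbind(a, a2, b), cbind(a2, b2, b))
  }
  structure(list(vertices = vertices,
                 faces = do.call(rbind, faces),
                 n_vertices = n_vertices, n_planes = np),
            class = "loft_mesh")
}

#' Cross-sectional ring area of a lofted mesh
#'
#' @param mesh a [loft_surface()] result.
#' @param plane ring index.
#' @return Polygon area of the ring, mm^2.
#' @export
mesh_ring_area <- function(mesh, plane) {
  i <- (plane - 1) * mesh$n_vertices + seq_len(mesh$n_vertices)
  abs(polygon_area(mesh$vertices[i, 1:2], check = FALSE))
}

#' Write a mesh as ASCII PLY
#'
#' @param mesh a [loft_surface()] result.
#' @param path output path.
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nv),
               "property float x", "property float y", "property float z",
               paste("element face", nf),
               "property list uchar int vertex_indices", "end_header"), con)
  utils::write.table(format(mesh$vertices, trim = TRUE, digits = 7),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  utils::write.table(cbind(3L, mesh$faces - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a mesh as Wavefront OBJ
#'
#' @param mesh a [loft_surface()] result.
#' @param path output path.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("v", apply(format(mesh$vertices, trim = TRUE,
                                     digits = 7), 1, paste,
                              collapse = " ")), con)
  writeLines(paste("f", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]),
             con)
  invisible(path)
}
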