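#' Site label codes
#'
#' Integer codes used in every cross-section label matrix: exterior 0,
#' lumen 1, media 2, adventitia 3, plaque 4, void 5.
#'
#' @format Named integer vector.
#' @export
LABELS <- c(exterior = 0L, lumen = 1L, media = 2L, adventitia = 3L,
            plaque = 4L, void = 5L)
TISSUE_CODES <- c(2L, 3L, 4L)   # media, adventitia, plaque
OPEN_CODES <- c(1L, 5L)         # lumen, void

#' Hexagonal site lattice
#'
#' Pointy-top hexagonal lattice in odd-row offset layout: site `(r, c)`
#' (1-based) has center `x = (c - 1 + 0.5 * ((r - 1) %% 2)) * spacing`,
#' `y = (r - 1) * spacing * sqrt(3) / 2`.  Every interior site has six
#' neighbors at distance `spacing`.
#'
#' @param n_rows,n_cols site counts (default 300 x 300).
#' @param spacing center-to-center distance, mm per site (default 0.0375,
#'   i.e. 1.5 cells per site at a 25 um cell diameter).
#' @return Object of class `hex_grid`.
#' @export
hex_grid <- function(n_rows = 300, n_cols = 300, spacing = 0.0375) {
  if (n_rows < 1 || n_cols < 1 || spacing <= 0)
    stop("grid dimensions and spacing must be positive", call. = FALSE)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 spacing = spacing),
            class = "hex_grid")
}

#' Site-center coordinates of a hexagonal grid
#'
#' @param grid a [hex_grid()].
#' @return List of two `n_rows x n_cols` matrices `x`, `y` (mm).
#' @export
hex_centers <- function(grid) {
  r <- matrix(seq_len(grid$n_rows), grid$n_rows, grid$n_cols)
  cc <- matrix(seq_len(grid$n_cols), grid$n_rows, grid$n_cols, byrow = TRUE)
  list(x = (cc - 1 + 0.5 * ((r - 1) %% 2)) * grid$spacing,
       y = (r - 1) * grid$spacing * sqrt(3) / 2)
}

#' Neighbor index table of a hexagonal grid
#'
#' @param grid a [hex_grid()].
#' @return Integer matrix `N x 6` (N = number of sites, column-major linear
#'   indices); off-grid neighbors are `NA`.
#' @export
hex_neighbors <- function(grid) {
  nr <- grid$n_rows; nc <- grid$n_cols
  r <- rep(seq_len(nr), nc)
  cc <- rep(seq_len(nc), each = nr)
  odd <- ((r - 1) %% 2) == 1  # shifted rows
  # (dr, dc) per parity: even rows (not shifted) vs odd (shifted right)
  drs <- c(0, 0, -1, -1, 1, 1)
  dcs_even <- c(-1, 1, -1, 0, -1, 0)
  dcs_odd <- c(-1, 1, 0, 1, 0, 1)
  out <- matrix(NA_integer_, nr * nc, 6)
  for (k in 1:6) {
    rr <- r + drs[k]
    ccs <- cc + ifelse(odd, dcs_odd[k], dcs_even[k])
    ok <- rr >= 1 & rr <= nr & ccs >= 1 & ccs <= nc
    idx <- rep(NA_integer_, nr * nc)
    idx[ok] <- (ccs[ok] - 1L) * nr + rr[ok]
    out[, k] <- idx
  }
  out
}

# Count, per site, how many of its neighbors satisfy a logical mask.
neighbor_count <- function(mask, nb) {
  m <- matrix(FALSE, nrow(nb), 6)
  for (k in 1:6) {
    v <- nb[, k]
    ok <- !is.na(v)
    m[ok, k] <- mask[v[ok]]
  }
  rowSums(m)
}

#' Tissue-labelled cross-section on a hexagonal grid
#'
#' @param grid a [hex_grid()].
#' @param label integer matrix (`n_rows x n_cols`) of site labels coded as
#'   in `LABELS` (exterior 0, lumen 1, media 2, adventitia 3, plaque 4,
#'   void 5), or a character matrix of label names.
#' @param plane_id identifier of the plane.
#' @param axial_mm axial position along the vessel, mm.
#' @return Object of class `cross_section`.
#' @export
cross_section <- function(grid, label, plane_id = 1L, axial_mm = 0) {
  if (is.character(label)) {
    lb <- matrix(LABELS[label], nrow(label), ncol(label))
  } else lb <- label
  stopifnot(nrow(lb) == grid$n_rows, ncol(lb) == grid$n_cols)
  if (!all(lb %in% LABELS))
    stop("unknown label code in cross-section", call. = FALSE)
  structure(list(grid = grid, label = lb, plane_id = plane_id,
                 axial_mm = axial_mm),
            class = "cross_section")
}

#' @export
print.cross_section <- function(x, ...) {
  cnt <- table(factor(x$label, levels = LABELS, labels = names(LABELS)))
  cat(sprintf("<cross_section> plane %s at %.1f mm, %d x %d grid (%.4f mm/site)\n",
              x$plane_id, x$axial_mm, x$grid$n_rows, x$grid$n_cols,
              x$grid$spacing))
  print(cnt)
  invisible(x)
}

# Site area of the hex cell (mm^2).
hex_site_area <- function(grid) sqrt(3) / 2 * grid$spacing^2

#' Lumen area from the site count
#'
#' Number of lumen-labelled sites times the hexagonal cell area; the exact
#' area measure used by the remodeling loop.
#'
#' @param cs a [cross_section()].
#' @return Area, mm^2.
#' @export
lumen_site_area <- function(cs) {
  sum(cs$label == LABELS["lumen"]) * hex_site_area(cs$grid)
}

#' Map labelled 3D nodes onto a cross-section grid
#'
#' Nodes within `slab_half_width` of the plane are projected onto it,
#' expressed in in-plane coordinates, and rasterized to the nearest site.
#' When several nodes land on one site the maximum damage is kept
#' (a partially failed site behaves as failed).
#'
#' @param nodes data frame with columns `x`, `y`, `z` (mm), `layer`
#'   (label name) and `damage`.
#' @param origin,normal plane definition (3-vectors); `normal` need not be
#'   unit length.
#' @param grid a [hex_grid()].
#' @param slab_half_width half-thickness of the slab captured by the plane,
#'   mm (half the inter-plane distance; default 1 for 2 mm-spaced planes).
#' @param center in-plane coordinates are shifted so this point maps to the
#'   grid center; defaults to the projected node centroid.
#' @return List with `label` and `damage` matrices plus the in-plane node
#'   coordinates.
#' @export
map_nodes_to_plane <- function(nodes, origin, normal, grid,
                               slab_half_width = 1, center = NULL) {
  n <- normal / sqrt(sum(normal^2))
  d <- as.matrix(nodes[, c("x", "y", "z")])
  d <- sweep(d, 2, origin)
  dist <- drop(d %*% n)
  keep <- abs(dist) <= slab_half_width
  if (!any(keep))
    stop("empty slab: no nodes within ", slab_half_width,
         " mm of the plane at ", paste(round(origin, 3), collapse = ","),
         call. = FALSE)
  # orthonormal in-plane basis
  a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * n) * n; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  p <- d[keep, , drop = FALSE]
  u <- drop(p %*% e1); v <- drop(p %*% e2)
  if (is.null(center)) center <- c(mean(u), mean(v))
  ctr <- hex_centers(grid)
  gx <- ctr$x[round(grid$n_rows / 2), round(grid$n_cols / 2)]
  gy <- ctr$y[round(grid$n_rows / 2), round(grid$n_cols / 2)]
  u <- u - center[1] + gx
  v <- v - center[2] + gy
  s <- grid$spacing
  r <- round(v / (s * sqrt(3) / 2)) + 1L
  cc <- round(u / s - 0.5 * ((r - 1) %% 2)) + 1L
  ok <- r >= 1 & r <= grid$n_rows & cc >= 1 & cc <= grid$n_cols
  lab <- matrix(LABELS["exterior"], grid$n_rows, grid$n_cols)
  dmg <- matrix(0, grid$n_rows, grid$n_cols)
  idx <- (cc[ok] - 1L) * grid$n_rows + r[ok]
  layer <- LABELS[as.character(nodes$layer[keep][ok])]
  dval <- nodes$damage[keep][ok]
  o <- order(dval)  # later (larger) damage wins on collisions
  lab[idx[o]] <- layer[o]
  dmg[idx[o]] <- dval[o]
  list(label = lab, damage = dmg, u = u, v = v)
}

#' Closed lumen contour of a cross-section
#'
#' Star-shaped envelope of the lumen about the lumen-site centroid: the
#' boundary lumen sites are binned by angle, the largest site-center radius
#' per bin is kept, empty bins are filled by circular interpolation, and
#' half a site spacing is added to account for the finite site extent.
#' The result is a simple, closed, counter-clockwise polyline with vertex
#' spacing below the grid spacing for lumens larger than a few sites.
#'
#' @param cs a [cross_section()].
#' @param n_angles number of angular bins/vertices (default 360).
#' @return Matrix `n_angles x 2` of (x, y) vertices in mm, class `contour`.
#' @export
lumen_contour <- function(cs, n_angles = 360) {
  lum <- cs$label == LABELS["lumen"]
  if (!any(lum)) stop("cross-section has no lumen sites", call. = FALSE)
  ctr <- hex_centers(cs$grid)
  cx <- mean(ctr$x[lum]); cy <- mean(ctr$y[lum])
  nb <- cs_neighbors(cs)
  # boundary = lumen sites with at least one non-lumen (or off-grid) neighbor
  nonlum_nb <- neighbor_count(!lum, nb)
  edge <- matrix(rowSums(is.na(nb)) > 0, cs$grid$n_rows, cs$grid$n_cols)
  bnd <- lum & (matrix(nonlum_nb, cs$grid$n_rows, cs$grid$n_cols) > 0 | edge)
  if (!any(bnd)) bnd <- lum
  bx <- ctr$x[bnd] - cx; by <- ctr$y[bnd] - cy
  th <- atan2(by, bx)
  rr <- sqrt(bx^2 + by^2)
  bins <- pmin(n_angles, floor((th + pi) / (2 * pi) * n_angles) + 1L)
  rmax <- rep(NA_real_, n_angles)
  agg <- tapply(rr, bins, max)
  rmax[as.integer(names(agg))] <- agg
  if (anyNA(rmax)) {
    if (all(is.na(rmax))) rmax[] <- max(rr)
    rmax <- fill_circular(rmax)
  }
  rmax <- rmax + cs$grid$spacing / 2  # finite site extent
  ang <- (seq_len(n_angles) - 0.5) / n_angles * 2 * pi - pi
  out <- cbind(x = cx + rmax * cos(ang), y = cy + rmax * sin(ang))
  structure(out, class = c("contour", class(out)))
}

# Circularly interpolate NA runs in a periodic numeric vector.
fill_circular <- function(v) {
  n <- length(v)
  idx <- which(!is.na(v))
  if (!length(idx)) return(v)
  for (i in which(is.na(v))) {
    lo <- idx[which.min((i - idx) %% n)]
    hi <- idx[which.min((idx - i) %% n)]
    dl <- (i - lo) %% n; dh <- (hi - i) %% n
    v[i] <- (v[lo] * dh + v[hi] * dl) / (dl + dh)
  }
  v
}

#' Shoelace area of a closed polygon
#'
#' Positive for counter-clockwise orientation.  With `check = TRUE` the
#' polygon is verified to be simple (no two non-adjacent edges intersect)
#' and an error is raised otherwise.
#'
#' @param contour matrix `n x 2` of vertices (closing edge implied).
#' @param check verify simplicity (O(n^2); default `TRUE`).
#' @return Signed area, mm^2.
#' @export
polygon_area <- function(contour, check = TRUE) {
  x <- contour[, 1]; y <- contour[, 2]
  n <- length(x)
  if (n < 3) stop("polygon needs at least 3 vertices", call. = FALSE)
  if (check && is_self_intersecting(x, y))
    stop("self-intersecting contour", call. = FALSE)
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

# Segment-intersection test over all non-adjacent edge pairs (vectorized).
is_self_intersecting <- function(x, y) {
  n <- length(x)
  if (n < 4) return(FALSE)
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  pr <- utils::combn(n, 2)
  i <- pr[1, ]; j <- pr[2, ]
  adj <- (j - i) == 1 | (i == 1 & j == n)
  i <- i[!adj]; j <- j[!adj]
  if (!length(i)) return(FALSE)
  cr <- function(ax, ay, bx, by) ax * by - ay * bx
  d1 <- cr(x2[i] - x[i], y2[i] - y[i], x[j] - x[i], y[j] - y[i])
  d2 <- cr(x2[i] - x[i], y2[i] - y[i], x2[j] - x[i], y2[j] - y[i])
  d3 <- cr(x2[j] - x[j], y2[j] - y[j], x[i] - x[j], y[i] - y[j])
  d4 <- cr(x2[j] - x[j], y2[j] - y[j], x2[i] - x[j], y2[i] - y[j])
  any(d1 * d2 < 0 & d3 * d4 < 0)
}

#' Perimeter of a closed polygon
#' @param contour matrix `n x 2` of vertices.
#' @return Perimeter length, mm.
#' @export
polygon_perimeter <- function(contour) {
  x <- contour[, 1]; y <- contour[, 2]
  sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
}

#' Hydraulic diameter
#'
#' `4 * area / perimeter`; equals the geometric diameter for a circle.
#'
#' @param area cross-sectional area, mm^2.
#' @param perimeter wetted perimeter, mm (> 0).
#' @return Diameter, mm.
#' @export
hydraulic_diameter <- function(area, perimeter) {
  if (any(perimeter <= 0)) stop("perimeter must be positive", call. = FALSE)
  4 * area / perimeter
}

#' Distance of each tissue site from the lumen wall
#'
#' Wall sites (tissue sites adjacent to the lumen) are at distance zero;
#' every other tissue site gets the Euclidean distance from its center to
#' the nearest wall-site center.  Exterior, lumen and void sites carry an
#' infinite sentinel and are excluded from stimulus computations.
#'
#' @param cs a [cross_section()].
#' @param max_dist distances are exact up to this value (mm); farther sites
#'   keep the sentinel `Inf`.  Bounding the search keeps the cost linear in
#'   the wall length.
#' @return Numeric matrix of distances (mm) with `Inf` sentinels.
#' @export
distance_to_lumen <- function(cs, max_dist = Inf) {
  lab <- cs$label
  tissue <- matrix(lab %in% TISSUE_CODES, nrow(lab), ncol(lab))
  lum <- lab == LABELS["lumen"]
  if (!any(lum)) stop("cross-section has no lumen sites", call. = FALSE)
  nb <- cs_neighbors(cs)
  wall <- tissue & matrix(neighbor_count(lum, nb) > 0, nrow(lab), ncol(lab))
  out <- matrix(Inf, nrow(lab), ncol(lab))
  if (!any(wall)) return(out)
  ctr <- hex_centers(cs$grid)
  wx <- ctr$x[wall]; wy <- ctr$y[wall]
  ti <- which(tissue)
  tx <- ctr$x[ti]; ty <- ctr$y[ti]
  if (is.finite(max_dist)) {
    keep <- tx >= min(wx) - max_dist & tx <= max(wx) + max_dist &
      ty >= min(wy) - max_dist & ty <= max(wy) + max_dist
    ti <- ti[keep]; tx <- tx[keep]; ty <- ty[keep]
  }
  # chunked nearest-neighbor distances (wall sets are a few hundred sites)
  step <- max(1L, as.integer(2e6 / max(1, length(wx))))
  for (s0 in seq(1L, length(ti), by = step)) {
    s1 <- min(length(ti), s0 + step - 1L)
    d2 <- outer(tx[s0:s1], wx, "-")^2 + outer(ty[s0:s1], wy, "-")^2
    out[ti[s0:s1]] <- sqrt(do.call(pmin, asplit(d2, 2)))
  }
  out[wall] <- 0
  out
}

#' Smooth a contour by a circular moving average of vertex radii
#'
#' Vertex radii about the contour centroid are filtered with a circular
#' moving average of odd window length.  If the smoothed contour's area
#' departs from the original by more than `max_area_change`, the result is
#' blended back toward the input until the bound holds.  `window = 1` is
#' the identity; a circle is a fixed point.
#'
#' @param contour matrix `n x 2`.
#' @param window odd window length `>= 1`.
#' @param max_area_change relative area-change guard (default 0.02).
#' @return Smoothed contour.
#' @export
smooth_contour <- function(contour, window = 5, max_area_change = 0.02) {
  if (window %% 2 != 1 || window < 1)
    stop("window must be odd and >= 1", call. = FALSE)
  if (window == 1) return(contour)
  x <- contour[, 1]; y <- contour[, 2]
  cx <- mean(x); cy <- mean(y)
  r <- sqrt((x - cx)^2 + (y - cy)^2)
  th <- atan2(y - cy, x - cx)
  h <- (window - 1) / 2
  n <- length(r)
  rext <- c(r[(n - h + 1):n], r, r[1:h])
  rs <- stats::filter(rext, rep(1 / window, window), sides = 2)
  rs <- as.numeric(rs)[(h + 1):(h + n)]
  a0 <- abs(polygon_area(contour, check = FALSE))
  build <- function(lam) {
    rb <- (1 - lam) * r + lam * rs
    cbind(x = cx + rb * cos(th), y = cy + rb * sin(th))
  }
  lam <- 1
  cand <- build(lam)
  for (k in 1:20) {
    if (abs(abs(polygon_area(cand, check = FALSE)) - a0) / a0 <=
        max_area_change) break
    lam <- lam / 2
    cand <- build(lam)
  }
  structure(cand, class = c("contour", class(cand)))
}

# Cached neighbor tables keyed by grid dimensions (per-session memoization).
.nb_cache <- new.env(parent = emptyenv())
cs_neighbors <- function(cs) {
  key <- paste(cs$grid$n_rows, cs$grid$n_cols, sep = "x")
  nb <- .nb_cache[[key]]
  if (is.null(nb)) {
    nb <- hex_neighbors(cs$grid)
    .nb_cache[[key]] <- nb
  }
  nb
}

#' Serialize a cross-section (and optional damage field) to CSV
#'
#' Columns: `plane_id`, `row`, `col`, `label`, `damage`.
#'
#' @param cs a [cross_section()].
#' @param path output path.
#' @param damage optional damage matrix matching the grid.
#' @export
write_cross_section_csv <- function(cs, path, damage = NULL) {
  idx <- which(cs$label != LABELS["exterior"])
  r <- ((idx - 1L) %% cs$grid$n_rows) + 1L
  cc <- ((idx - 1L) %/% cs$grid$n_rows) + 1L
  df <- data.frame(plane_id = cs$plane_id, row = r, col = cc,
                   label = names(LABELS)[match(cs$label[idx], LABELS)],
                   damage = if (is.null(damage)) 0 else damage[idx])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a cross-section CSV written by [write_cross_section_csv()]
#'
#' @param path input path.
#' @param grid the [hex_grid()] the sites index into.
#' @return List with the `cross_section` and the damage matrix.
#' @export
read_cross_section_csv <- function(path, grid) {
  df <- utils::read.csv(path)
  need <- c("plane_id", "row", "col", "label", "damage")
  if (!all(need %in% names(df)))
    stop("cross-section CSV must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  lab <- matrix(LABELS["exterior"], grid$n_rows, grid$n_cols)
  dmg <- matrix(0, grid$n_rows, grid$n_cols)
  idx <- (df$col - 1L) * grid$n_rows + df$row
  lab[idx] <- LABELS[df$label]
  dmg[idx] <- df$damage
  list(cs = cross_section(grid, lab, plane_id = df$plane_id[1]),
       damage = dmg)
}

#' Damage fields as JSON site maps
#'
#' Sparse JSON serialization of a per-site damage field: only non-zero
#' sites are stored, as parallel `row`/`col`/`damage` arrays.
#'
#' @param damage numeric damage matrix.
#' @param path output path.
#' @param plane_id identifier stored with the map.
#' @export
write_damage_json <- function(damage, path, plane_id = 1L) {
  idx <- which(damage > 0)
  nr <- nrow(damage)
  jsonlite::write_json(
    list(plane_id = plane_id, n_rows = nr, n_cols = ncol(damage),
         row = ((idx - 1L) %% nr) + 1L,
         col = ((idx - 1L) %/% nr) + 1L,
         damage = damage[idx]),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_damage_json
#' @export
read_damage_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- matrix(0, j$n_rows, j$n_cols)
  out[(j$col - 1L) * j$n_rows + j$row] <- j$damage
  out
}

#' Laceration masks as boolean CSVs
#'
#' Columns `plane_id`, `row`, `col`, `deleted`; only `TRUE` sites are
#' written.
#'
#' @param mask logical matrix.
#' @param path output path.
#' @param plane_id identifier stored with the mask.
#' @export
write_mask_csv <- function(mask, path, plane_id = 1L) {
  idx <- which(mask)
  nr <- nrow(mask)
  utils::write.csv(
    data.frame(plane_id = rep(plane_id, length(idx)),
               row = ((idx - 1L) %% nr) + 1L,
               col = ((idx - 1L) %/% nr) + 1L,
               deleted = rep(TRUE, length(idx))),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mask_csv
#' @param grid the [hex_grid()] the sites index into.
#' @export
read_mask_csv <- function(path, grid) {
  df <- utils::read.csv(path)
  out <- matrix(FALSE, grid$n_rows, grid$n_cols)
  if (nrow(df)) out[(df$col - 1L) * grid$n_rows + df$row] <- df$deleted
  out
}
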