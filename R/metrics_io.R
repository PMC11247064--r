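#' Median and interquartile range
#'
#' Quartiles by linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' @param values numeric vector, `n >= 1`.
#' @return Named vector `median`, `q1`, `q3`.
#' @export
median_iqr <- function(values) {
  if (!length(values)) stop("empty input", call. = FALSE)
  q <- stats::quantile(values, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' Percent lumen-area increase from the intervention
#'
#' `100 * (a_post - a_pre) / a_pre`.
#'
#' @param a_pre,a_post lumen areas before/after the intervention, mm^2.
#' @param digits rounding of the report (default 0, whole percent).
#' @return Percent change.
#' @export
lumen_increase_pct <- function(a_pre, a_post, digits = 0) {
  if (any(a_pre <= 0)) stop("pre-intervention area must be positive",
                            call. = FALSE)
  round(100 * (a_post - a_pre) / a_pre, digits)
}

#' Percent restenosis relative to the post-intervention lumen
#'
#' `100 * (1 - a_t / a_post)`.
#'
#' @param a_post post-intervention lumen area, mm^2.
#' @param a_t follow-up lumen area, mm^2.
#' @param digits rounding of the report (default 0).
#' @return Percent restenosis.
#' @export
restenosis_pct <- function(a_post, a_t, digits = 0) {
  if (any(a_post <= 0)) stop("post-intervention area must be positive",
                             call. = FALSE)
  round(100 * (1 - a_t / a_post), digits)
}

#' Percent residual stenosis relative to the target lumen
#'
#' `100 * (1 - a_min / a_target)`.
#'
#' @param a_min minimum lumen area after the intervention, mm^2.
#' @param a_target target (reference) lumen area, mm^2.
#' @param digits rounding of the report (default 1).
#' @return Percent residual stenosis.
#' @export
residual_stenosis_pct <- function(a_min, a_target, digits = 1) {
  if (any(a_target <= 0)) stop("target area must be positive", call. = FALSE)
  round(100 * (1 - a_min / a_target), digits)
}

#' Two-sided Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples.  For pooled sizes up to
#' `exact_max` the permutation distribution of U is enumerated exactly
#' (valid under ties); beyond that a tie-corrected normal approximation
#' with continuity correction is used.  The two-sided p-value is
#' `min(1, 2 * min(P(U <= u), P(U >= u)))`.
#'
#' @param x,y numeric samples, each non-empty.
#' @param exact_max maximum pooled size for exact enumeration (default 12,
#'   covering the 11-plane comparisons).
#' @return List with `U` (statistic of `x`), `p_value` and `method`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 12) {
  nx <- length(x); ny <- length(y)
  if (!nx || !ny) stop("both samples must be non-empty", call. = FALSE)
  u_stat <- function(xs, ys) {
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u <- u_stat(x, y)
  if (nx + ny <= exact_max) {
    pool <- c(x, y)
    idx <- utils::combn(nx + ny, nx)
    us <- apply(idx, 2, function(i) u_stat(pool[i], pool[-i]))
    p <- min(1, 2 * min(mean(us <= u), mean(us >= u)))
    list(U = u, p_value = p, method = "exact enumeration")
  } else {
    n <- nx + ny
    tie_tab <- table(c(x, y))
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sd_u <- sqrt(nx * ny / 12 * (n + 1 - tie_term))
    mu <- nx * ny / 2
    if (sd_u == 0) return(list(U = u, p_value = 1,
                               method = "normal approximation"))
    z <- (u - mu - sign(u - mu) * 0.5) / sd_u
    list(U = u, p_value = min(1, 2 * stats::pnorm(-abs(z))),
         method = "normal approximation")
  }
}

#' Restenosis report from per-plane area series
#'
#' Summarizes a `framework_run` (or any plane-by-day area matrix) into the
#' standard follow-up metrics: median [IQR] lumen area per checkpoint,
#' minimum lumen area, percent increase from a pre-intervention reference,
#' percent restenosis at follow-up checkpoints and percent residual
#' stenosis against a target area.
#'
#' @param areas plane-by-day numeric matrix (columns named by day) or a
#'   `framework_run`.
#' @param a_pre optional per-plane pre-intervention areas, mm^2.
#' @param a_target optional target lumen area, mm^2 (e.g. the area of the
#'   fully expanded balloon).
#' @param days checkpoints to report (default first and last plus day 30
#'   when present).
#' @return Data frame, one row per checkpoint.
#' @export
restenosis_report <- function(areas, a_pre = NULL, a_target = NULL,
                              days = NULL) {
  if (inherits(areas, "framework_run")) areas <- areas$areas
  all_days <- as.numeric(colnames(areas))
  if (is.null(days)) {
    days <- unique(c(0, intersect(30, all_days), max(all_days)))
  }
  day0 <- areas[, which.min(abs(all_days - 0))]
  rows <- lapply(days, function(d) {
    a <- areas[, which.min(abs(all_days - d))]
    mi <- median_iqr(a)
    data.frame(
      day = d,
      median_area_mm2 = mi["median"],
      q1_mm2 = mi["q1"], q3_mm2 = mi["q3"],
      min_area_mm2 = min(a),
      increase_pct = if (!is.null(a_pre))
        lumen_increase_pct(stats::median(a_pre), mi["median"]) else NA_real_,
      restenosis_pct = restenosis_pct(stats::median(day0), mi["median"]),
      residual_stenosis_pct = if (!is.null(a_target))
        residual_stenosis_pct(min(a), a_target) else NA_real_,
      row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Write a deterministic run manifest
#'
#' Records the configuration hash, seed and package version next to the
#' outputs of a run, so results can be traced to their inputs.
#'
#' @param cfg configuration list.
#' @param seed seed used.
#' @param dir output directory.
#' @return Manifest path, invisibly.
#' @export
write_manifest <- function(cfg, seed, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  manifest <- list(
    config_md5 = hash, seed = seed,
    package_version = as.character(utils::packageVersion("restenosim")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE)
  invisible(path)
}

#' Plot per-plane lumen area over time
#'
#' @param run a `framework_run` (or plane-by-day area matrix).
#' @param normalized divide each plane by its day-0 area.
#' @param ... passed to [graphics::matplot()].
#' @export
plot_area_series <- function(run, normalized = TRUE, ...) {
  areas <- if (inherits(run, "framework_run")) run$areas else run
  days <- as.numeric(colnames(areas))
  y <- if (normalized) areas / areas[, 1] else areas
  graphics::matplot(days, t(y), type = "l", lty = 1,
                    xlab = "time (days)",
                    ylab = if (normalized) "normalized lumen area"
                    else "lumen area (mm^2)", ...)
  invisible(run)
}
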