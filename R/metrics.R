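#' Swarming index of a single frame
#'
#' A per-frame statistic of how cells are organised relative to the
#' tumouroid, anchored at -1 when all cells sit on the well perimeter, 0 in
#' expectation when cells are uniformly distributed outside the tumouroid,
#' and +1 when all cells are inside the tumouroid. Each cell scores
#' `c = +1` if inside; otherwise `c = 1 - 2u` where
#' `u = (rho^2 - R_t^2) / (R_w^2 - R_t^2)` is the area-fraction coordinate
#' of the annulus (uniform on `[0, 1]` for spatially uniform cells). The
#' index is the mean score, invariant under rotations about the arena
#' centre and non-decreasing when any cell moves inward.
#'
#' @param frame A data frame (or matrix) of cell positions with columns
#'   `x`, `y` (um); one imaging frame.
#' @param arena An [arena_config()].
#' @return The swarming index, a number in `[-1, 1]`.
#' @examples
#' arena <- arena_config()
#' th <- seq(0, 2 * pi, length.out = 101)[-101]
#' rim <- data.frame(x = 3400 * cos(th), y = 3400 * sin(th))
#' swarming_index(rim, arena) # -1
#' @export
swarming_index <- function(frame, arena) {
  stopifnot(inherits(arena, "arena_config"))
  p <- as_xy_matrix(frame)
  if (nrow(p) == 0L)
    stop("swarming index is undefined for an empty frame")
  rho2 <- (p[, 1] - arena$centre[1])^2 + (p[, 2] - arena$centre[2])^2
  rt2 <- tumouroid_radius(arena)^2
  rw2 <- well_radius(arena)^2
  # small relative slack: positions may have round-tripped through
  # fixed-precision text formats
  if (any(rho2 > rw2 * (1 + 1e-4)))
    stop("all cells must lie within the well")
  u <- pmin((rho2 - rt2) / (rw2 - rt2), 1)
  score <- ifelse(rho2 < rt2, 1, 1 - 2 * u)
  mean(score)
}

#' Swarming index over time
#'
#' @param frames A `frame_table` (columns `t`, `x`, `y`).
#' @param arena An [arena_config()].
#' @return A `swarming_series` data frame with columns `t` (min) and `M`.
#' @export
swarming_series <- function(frames, arena) {
  stopifnot(is.data.frame(frames),
            all(c("t", "x", "y") %in% names(frames)))
  times <- sort(unique(frames$t))
  M <- vapply(times, function(tt)
    swarming_index(frames[frames$t == tt, c("x", "y")], arena), numeric(1))
  structure(data.frame(t = times, M = M),
            class = c("swarming_series", "data.frame"))
}

unit_vector <- function(u) {
  u <- as.numeric(u)
  if (length(u) == 2L) u <- c(u, 0)
  if (length(u) != 3L || !all(is.finite(u)))
    stop("direction must be a finite 2- or 3-vector")
  nrm <- sqrt(sum(u^2))
  if (nrm < 1e-30) stop("direction must be nonzero")
  u / nrm
}

#' Forward migration index of one track
#'
#' The net displacement projected on the target direction `u`, divided by
#' the net displacement magnitude: the cosine of the angle between the
#' displacement vector and the direction toward the target (classically the
#' x axis toward the tumouroid, hence "FMI = Dx / D"). The target direction
#' is always passed explicitly; no sign convention is hidden.
#'
#' @param positions Matrix or data frame of track positions in time order,
#'   with columns `x`, `y`, `z` (a `z` of 0 is assumed if absent).
#' @param u Target direction (2- or 3-vector; normalised internally).
#' @return The FMI, in `[-1, 1]`.
#' @export
fmi <- function(positions, u) {
  u <- unit_vector(u)
  if (is.data.frame(positions)) {
    if (!"z" %in% names(positions)) positions$z <- 0
    positions <- as.matrix(positions[, c("x", "y", "z")])
  }
  if (ncol(positions) == 2L) positions <- cbind(positions, 0)
  if (nrow(positions) < 2L) stop("a track needs at least 2 points")
  d <- positions[nrow(positions), ] - positions[1L, ]
  nd <- sqrt(sum(d^2))
  if (nd < 1e-30)
    stop("FMI undefined for zero net displacement")
  sum(d * u) / nd
}

#' Per-track motility summary
#'
#' For each track: net displacement `D` (straight-line distance between
#' first and last position), its projection `D_proj` on the target
#' direction, `fmi = D_proj / D`, `mean_speed` (total path length divided
#' by track duration) and `duration`. Single-point tracks are excluded and
#' reported in the `"excluded"` attribute; tracks with zero net
#' displacement get `fmi = NA`.
#'
#' @param tracks A `track_table`.
#' @param u Target direction (2- or 3-vector).
#' @return Data frame with one row per track, attribute `"excluded"`
#'   naming any dropped tracks.
#' @export
track_summary <- function(tracks, u) {
  stopifnot(is.data.frame(tracks))
  u <- unit_vector(u)
  per <- split_tracks(tracks)
  excluded <- names(per)[vapply(per, nrow, integer(1)) < 2L]
  per <- per[setdiff(names(per), excluded)]
  if (length(excluded))
    message(length(excluded), " single-point track(s) excluded")
  rows <- lapply(names(per), function(id) {
    tr <- per[[id]]
    p <- as.matrix(tr[, c("x", "y", "z")])
    d <- p[nrow(p), ] - p[1L, ]
    D <- sqrt(sum(d^2))
    dproj <- sum(d * u)
    path <- sum(sqrt(rowSums(diff(p)^2)))
    dur <- tr$t[nrow(tr)] - tr$t[1L]
    data.frame(track_id = id, duration = dur, D = D, D_proj = dproj,
               fmi = if (D < 1e-30) NA_real_ else dproj / D,
               mean_speed = path / dur, n_points = nrow(tr),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(track_id = character(0))
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Infiltration statistics for one frame
#'
#' @param frame Data frame/matrix of positions with columns `x`, `y`.
#' @param arena An [arena_config()].
#' @return List with `fraction_infiltrated` (cells strictly inside the
#'   tumouroid over all cells), `depths` (shortest distance from the
#'   tumouroid edge for each infiltrated cell, um) and `mean_depth`
#'   (`NA` when no cell is infiltrated).
#' @export
infiltration_stats <- function(frame, arena) {
  rd <- radial_distance(frame, arena)
  if (!length(rd)) stop("empty frame")
  depths <- -rd[rd < 0]
  list(fraction_infiltrated = length(depths) / length(rd),
       depths = unname(depths),
       mean_depth = if (length(depths)) mean(depths) else NA_real_)
}

#' Radial density kymograph
#'
#' For each frame, the cumulative count `N(r)` of cells residing within
#' signed radial distance `r` of the tumouroid interface (`0 <= d <= r`;
#' infiltrated cells are excluded) is evaluated on `r_grid`, smoothed with
#' a penalised cubic smoothing spline (penalty chosen by generalised
#' cross-validation unless `spar` is given), and differentiated with
#' respect to `r`. The derivative is reported both per unit `r`
#' (`density_per_r`, cells/um) and per unit area after dividing by the
#' circumference at that radius (`density`, cells/um^2). Negative smoothed
#' densities are clipped to zero and counted in attribute
#' `"n_clipped_negative"`.
#'
#' @param frames A `frame_table` (columns `t`, `x`, `y`).
#' @param arena An [arena_config()].
#' @param r_grid Increasing grid of distances from the tumouroid edge (um);
#'   defaults to 100 points spanning the tumouroid-to-wall gap.
#' @param spar Optional smoothing parameter passed to
#'   [stats::smooth.spline()]; `NULL` selects the penalty by GCV.
#' @return A `kymograph_grid`: list with `r`, `t`, `density`,
#'   `density_per_r` and `cumulative` (exact pre-smoothing counts), each
#'   grid a `length(r) x length(t)` matrix.
#' @export
density_kymograph <- function(frames, arena, r_grid = NULL, spar = NULL) {
  stopifnot(is.data.frame(frames),
            all(c("t", "x", "y") %in% names(frames)),
            inherits(arena, "arena_config"))
  gap <- well_radius(arena) - tumouroid_radius(arena)
  if (is.null(r_grid)) r_grid <- seq(0, gap, length.out = 100L)
  r_grid <- as.numeric(r_grid)
  if (length(r_grid) < 4L || any(diff(r_grid) <= 0))
    stop("`r_grid` must be increasing with at least 4 points")
  times <- sort(unique(frames$t))
  if (!length(times)) stop("no frames")
  nr <- length(r_grid)
  cum <- dens_r <- dens <- matrix(NA_real_, nr, length(times))
  n_clipped <- 0L
  for (j in seq_along(times)) {
    fr <- frames[frames$t == times[j], c("x", "y")]
    d <- radial_distance(fr, arena)
    d <- sort(d[d >= 0])
    N <- findInterval(r_grid, d)
    cum[, j] <- N
    fit <- if (is.null(spar)) stats::smooth.spline(r_grid, N) else
      stats::smooth.spline(r_grid, N, spar = spar)
    deriv <- stats::predict(fit, r_grid, deriv = 1)$y
    neg <- deriv < 0
    n_clipped <- n_clipped + sum(neg)
    deriv[neg] <- 0
    dens_r[, j] <- deriv
    dens[, j] <- deriv / (2 * pi * (tumouroid_radius(arena) + r_grid))
  }
  structure(list(r = r_grid, t = times, density = dens,
                 density_per_r = dens_r, cumulative = cum),
            n_clipped_negative = n_clipped,
            class = "kymograph_grid")
}

#' @export
print.kymograph_grid <- function(x, ...) {
  cat("<kymograph_grid>", length(x$r), "radial x", length(x$t),
      "time bins; r in [", min(x$r), ",", max(x$r), "] um\n")
  invisible(x)
}

#' Instantaneous FMI kymograph
#'
#' Scores every step displacement of every track against the local
#' toward-tumouroid direction (the xy unit vector from the step's start
#' position toward the arena centre): the score is the cosine of the angle
#' between the 3D step and that direction. Scores are averaged in bins of
#' (distance from the tumouroid edge at step start, time at step start).
#' Empty bins are `NA`, distinguishable from bins whose mean is 0.
#'
#' @param tracks A `track_table` (apply [filter_tracks()] first).
#' @param arena An [arena_config()].
#' @param r_bins Bin edges for distance from the tumouroid edge (um).
#' @param t_bins Bin edges for time (min).
#' @return List with `r_mid`, `t_mid`, `mean_fmi` (matrix, `NA` where
#'   empty) and `n` (observations per bin).
#' @export
instantaneous_fmi_kymograph <- function(tracks, arena,
                                        r_bins = NULL, t_bins = NULL) {
  stopifnot(is.data.frame(tracks), inherits(arena, "arena_config"))
  if (is.null(r_bins))
    r_bins <- seq(0, well_radius(arena) - tumouroid_radius(arena),
                  length.out = 11L)
  if (is.null(t_bins))
    t_bins <- seq(min(tracks$t), max(tracks$t) + 1e-9, length.out = 11L)
  per <- split_tracks(tracks)
  score <- rstart <- tstart <- list()
  for (id in names(per)) {
    tr <- per[[id]]
    if (nrow(tr) < 2L) next
    p <- as.matrix(tr[, c("x", "y", "z")])
    d <- diff(p)
    nd <- sqrt(rowSums(d^2))
    ux <- arena$centre[1] - p[-nrow(p), 1]
    uy <- arena$centre[2] - p[-nrow(p), 2]
    un <- sqrt(ux^2 + uy^2)
    ok <- nd > 1e-30 & un > 1e-30
    sc <- (d[, 1] * ux + d[, 2] * uy) / (nd * un)
    score[[id]] <- sc[ok]
    rstart[[id]] <- radial_distance(p[-nrow(p), 1:2, drop = FALSE],
                                    arena)[ok]
    tstart[[id]] <- tr$t[-nrow(tr)][ok]
  }
  score <- unlist(score, use.names = FALSE)
  rstart <- unlist(rstart, use.names = FALSE)
  tstart <- unlist(tstart, use.names = FALSE)
  ri <- cut(rstart, r_bins, include.lowest = TRUE, labels = FALSE)
  ti <- cut(tstart, t_bins, include.lowest = TRUE, labels = FALSE)
  keep <- !is.na(ri) & !is.na(ti)
  nrb <- length(r_bins) - 1L
  ntb <- length(t_bins) - 1L
  mean_fmi <- matrix(NA_real_, nrb, ntb)
  nobs <- matrix(0L, nrb, ntb)
  if (any(keep)) {
    idx <- (ti[keep] - 1L) * nrb + ri[keep]
    sums <- tapply(score[keep], idx, sum)
    cnts <- tapply(score[keep], idx, length)
    cells <- as.integer(names(sums))
    mean_fmi[cells] <- sums / cnts
    nobs[cells] <- as.integer(cnts)
  }
  list(r_mid = (r_bins[-1] + r_bins[-length(r_bins)]) / 2,
       t_mid = (t_bins[-1] + t_bins[-length(t_bins)]) / 2,
       mean_fmi = mean_fmi, n = nobs)
}

#' Transwell transmigration index
#'
#' Ratio of cells transmigrated toward the sample medium over cells
#' transmigrated toward control medium.
#'
#' @param n_sample Cells transmigrated in the sample condition.
#' @param n_control Cells transmigrated in the control condition; must be
#'   positive.
#' @return The transmigration index (dimensionless).
#' @export
transmigration_index <- function(n_sample, n_control) {
  stopifnot(is.numeric(n_sample), is.numeric(n_control),
            n_sample >= 0)
  if (!all(n_control > 0))
    stop("`n_control` must be positive: the index is undefined otherwise")
  n_sample / n_control
}

#' Cytotoxicity index
#'
#' Killing of cognate target cells relative to non-cognate bystanders
#' between 0 h and 2 h of co-culture:
#' `[1 - (cog_2h/noncog_2h) / (cog_0h/noncog_0h)] * 100` percent.
#'
#' @param cog_0h,noncog_0h Cognate / non-cognate target counts at 0 h.
#' @param cog_2h,noncog_2h Counts at 2 h.
#' @return Cytotoxicity index in percent.
#' @export
cytotoxicity_index <- function(cog_0h, noncog_0h, cog_2h, noncog_2h) {
  if (!all(noncog_0h > 0, noncog_2h > 0, cog_0h > 0))
    stop("denominator counts must be positive")
  (1 - (cog_2h / noncog_2h) / (cog_0h / noncog_0h)) * 100
}
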