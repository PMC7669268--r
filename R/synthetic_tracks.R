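#' Parameters for the synthetic 3D persistent-random-walk generator
#'
#' The generator emulates the two motility pools the bootstrap draws from:
#' an undirected pool (`drift_weight = 0`) standing in for CTLs migrating
#' randomly in the absence of a tumouroid, and a directionally biased pool
#' (`drift_weight > 0` toward `drift_direction`) standing in for CTLs
#' chemotaxing toward a tumouroid. Each step direction is the normalised
#' convex mixture of the previous direction (weight `persistence`), the
#' drift direction (weight `drift_weight`) and an isotropic random unit
#' vector (the remaining weight); step lengths are positive draws from a
#' normal truncated at zero.
#'
#' @param n_tracks Number of tracks.
#' @param duration Track duration (minutes).
#' @param dt Sampling interval (minutes); default 1/3 min (20 s).
#' @param speed_mean Mean instantaneous speed (um/min).
#' @param speed_sd SD of instantaneous speed (um/min).
#' @param persistence Directional correlation weight in `[0, 1]`.
#' @param drift_direction Unit 3-vector of the bias, or `NULL` when
#'   `drift_weight = 0`.
#' @param drift_weight Bias weight in `[0, 1]`;
#'   `persistence + drift_weight` must not exceed 1.
#' @param seed Integer seed; identical parameters give byte-identical
#'   tables.
#' @return An object of class `walk_params`.
#' @export
walk_params <- function(n_tracks, duration, dt = 1 / 3,
                        speed_mean = 8, speed_sd = 2,
                        persistence = 0.5,
                        drift_direction = NULL, drift_weight = 0,
                        seed = 1L) {
  stopifnot(n_tracks >= 1, duration > 0, dt > 0,
            speed_mean >= 0, speed_sd >= 0)
  if (persistence < 0 || persistence > 1)
    stop("`persistence` must be in [0, 1]")
  if (drift_weight < 0 || drift_weight > 1)
    stop("`drift_weight` must be in [0, 1]")
  if (persistence + drift_weight > 1 + 1e-12)
    stop("`persistence` + `drift_weight` must not exceed 1")
  if (speed_mean == 0 && speed_sd == 0)
    stop("degenerate walk: `speed_mean` and `speed_sd` both zero")
  if (drift_weight > 0) {
    if (is.null(drift_direction))
      stop("`drift_direction` required when `drift_weight` > 0")
    drift_direction <- as.numeric(drift_direction)
    if (length(drift_direction) != 3L || !all(is.finite(drift_direction)))
      stop("`drift_direction` must be a finite 3-vector")
    nrm <- sqrt(sum(drift_direction^2))
    if (abs(nrm - 1) > 1e-6)
      stop("`drift_direction` must be unit-norm")
    drift_direction <- drift_direction / nrm
  } else {
    drift_direction <- NULL
  }
  structure(list(n_tracks = as.integer(n_tracks), duration = duration,
                 dt = dt, speed_mean = speed_mean, speed_sd = speed_sd,
                 persistence = persistence,
                 drift_direction = drift_direction,
                 drift_weight = drift_weight, seed = as.integer(seed)),
            class = "walk_params")
}

random_unit_rows <- function(n) {
  # isotropic directions: normalised standard-normal triples
  m <- matrix(stats::rnorm(3 * n), ncol = 3L)
  nrm <- sqrt(rowSums(m^2))
  bad <- nrm < 1e-12
  while (any(bad)) {
    m[bad, ] <- stats::rnorm(3 * sum(bad))
    nrm <- sqrt(rowSums(m^2))
    bad <- nrm < 1e-12
  }
  m / nrm
}

positive_truncnorm <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  v <- stats::rnorm(n, mean, sd)
  bad <- v < 0
  while (any(bad)) {
    v[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- v < 0
  }
  v
}

#' Generate synthetic 3D motility tracks
#'
#' @param params A [walk_params()] object.
#' @return A `track_table` with `n_tracks` tracks starting at the origin,
#'   sampled every `dt` minutes.
#' @examples
#' p <- walk_params(n_tracks = 3, duration = 10, seed = 7)
#' tr <- generate_walks(p)
#' @export
generate_walks <- function(params) {
  stopifnot(inherits(params, "walk_params"))
  n <- params$n_tracks
  n_steps <- round(params$duration / params$dt)
  if (abs(n_steps * params$dt - params$duration) > 1e-6 * params$dt)
    stop("`duration` must be a multiple of `dt`")
  w_p <- params$persistence
  w_d <- params$drift_weight
  w_n <- 1 - w_p - w_d
  drift <- if (is.null(params$drift_direction)) c(0, 0, 0) else
    params$drift_direction
  withr::with_seed(params$seed, {
    dir <- random_unit_rows(n)
    xs <- matrix(0, n_steps + 1L, n)
    ys <- matrix(0, n_steps + 1L, n)
    zs <- matrix(0, n_steps + 1L, n)
    for (s in seq_len(n_steps)) {
      v <- w_p * dir + w_n * random_unit_rows(n)
      v[, 1] <- v[, 1] + w_d * drift[1]
      v[, 2] <- v[, 2] + w_d * drift[2]
      v[, 3] <- v[, 3] + w_d * drift[3]
      nrm <- sqrt(rowSums(v^2))
      bad <- nrm < 1e-12
      if (any(bad)) { # cancelling mixture: fall back to a fresh direction
        v[bad, ] <- random_unit_rows(sum(bad))
        nrm[bad] <- 1
      }
      dir <- v / nrm
      len <- positive_truncnorm(n, params$speed_mean * params$dt,
                                params$speed_sd * params$dt)
      xs[s + 1L, ] <- xs[s, ] + dir[, 1] * len
      ys[s + 1L, ] <- ys[s, ] + dir[, 2] * len
      zs[s + 1L, ] <- zs[s, ] + dir[, 3] * len
    }
  })
  ids <- sprintf("walk_%04d", seq_len(n))
  df <- data.frame(
    track_id = rep(ids, each = n_steps + 1L),
    t = rep((0:n_steps) * params$dt, times = n),
    x = as.vector(xs), y = as.vector(ys), z = as.vector(zs),
    stringsAsFactors = FALSE)
  as_track_table(df)
}
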