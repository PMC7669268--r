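#' Build a pool of 10-minute motility blocks from tracks
#'
#' Cuts every track into all unique consecutive windows of
#' `block_duration` minutes, advancing one sample at a time (maximal
#' overlap): a track with `n` position samples and `k = block_duration/dt`
#' steps per block contributes `max(0, n - k)` blocks. Each block stores the
#' window's consecutive displacement vectors together with the pool's
#' reference direction — the xy direction toward the attraction target in
#' the source data (by experimental convention the tumouroid lies toward
#' -x, hence the default `c(-1, 0)`). Agents later re-enact blocks after a
#' z-axis rotation carrying this reference onto their own target direction.
#'
#' @param tracks A `track_table`, uniformly sampled.
#' @param kind `"undirected"` or `"chemotactic"`; which behavioural pool the
#'   blocks feed.
#' @param block_duration Block length (minutes); must be a multiple of the
#'   sampling interval.
#' @param reference_direction Unit xy 2-vector toward the attraction target
#'   in the source data.
#' @return An object of class `block_pool` with elements `steps` (an
#'   `n_blocks x 3k` matrix, columns `dx1, dy1, dz1, dx2, ...`), `kind`,
#'   `dt` (min), `block_duration`, `reference_direction` and `source`
#'   (data frame of source track id and window offset).
#' @export
build_block_pool <- function(tracks, kind = c("undirected", "chemotactic"),
                             block_duration = 10,
                             reference_direction = c(-1, 0)) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(tracks), block_duration > 0)
  reference_direction <- as.numeric(reference_direction)
  if (length(reference_direction) != 2L ||
      abs(sqrt(sum(reference_direction^2)) - 1) > 1e-6)
    stop("`reference_direction` must be a unit xy 2-vector")
  per_track <- split_tracks(tracks)
  dts <- unlist(lapply(per_track, function(tr)
    if (nrow(tr) > 1L) diff(tr$t) else numeric(0)))
  if (!length(dts)) stop("no track has more than one sample")
  dt <- stats::median(dts)
  if (max(dts) - min(dts) > 0.01 * dt)
    stop("tracks are not uniformly sampled at a common interval")
  k <- round(block_duration / dt)
  if (abs(k * dt - block_duration) > 0.01 * dt)
    stop("`block_duration` (", block_duration,
         " min) is not a multiple of the sampling interval (",
         signif(dt, 4), " min)")
  steps_list <- list()
  src_track <- character(0)
  src_offset <- integer(0)
  for (id in names(per_track)) {
    tr <- per_track[[id]]
    n <- nrow(tr)
    n_blocks <- max(0L, n - k)
    if (n_blocks == 0L) next
    d <- cbind(diff(tr$x), diff(tr$y), diff(tr$z)) # (n-1) x 3 step vectors
    for (j in seq_len(n_blocks)) {
      w <- d[j:(j + k - 1L), , drop = FALSE]
      steps_list[[length(steps_list) + 1L]] <- as.vector(t(w))
      src_track <- c(src_track, id)
      src_offset <- c(src_offset, j)
    }
  }
  if (!length(steps_list))
    stop("empty block pool: no track is at least ", block_duration,
         " min long (cannot bootstrap)")
  steps <- do.call(rbind, steps_list)
  structure(list(steps = steps, kind = kind, dt = dt,
                 block_duration = block_duration,
                 reference_direction = reference_direction,
                 source = data.frame(track_id = src_track,
                                     offset = src_offset,
                                     stringsAsFactors = FALSE)),
            class = "block_pool")
}

#' @export
print.block_pool <- function(x, ...) {
  cat("<block_pool>", nrow(x$steps), x$kind, "blocks of",
      x$block_duration, "min (", ncol(x$steps) / 3, "steps of",
      signif(x$dt, 4), "min )\n")
  invisible(x)
}

block_steps_matrix <- function(pool, i) {
  matrix(pool$steps[i, ], ncol = 3L, byrow = TRUE)
}

#' Sample a motility block uniformly with replacement
#'
#' Draws from R's random stream, so wrap in [withr::with_seed()] (or call
#' `set.seed()`) for reproducibility.
#'
#' @param pool A [build_block_pool()] result.
#' @return A `motility_block`: list with `steps` (k x 3 displacement
#'   matrix, um), `reference_direction`, `source_track`, `source_offset`.
#' @export
sample_block <- function(pool) {
  stopifnot(inherits(pool, "block_pool"))
  n <- nrow(pool$steps)
  if (n < 1L) stop("empty block pool")
  i <- sample.int(n, 1L)
  structure(list(steps = block_steps_matrix(pool, i),
                 reference_direction = pool$reference_direction,
                 source_track = pool$source$track_id[i],
                 source_offset = pool$source$offset[i]),
            class = "motility_block")
}

#' Rotate a block's steps toward a new target direction
#'
#' Rotates every displacement about the z axis by the angle that carries the
#' block's reference direction onto `target_direction`. "Up" is maintained:
#' z components and step lengths are unchanged, and the rotation preserves
#' handedness (no reflection).
#'
#' @param block A `motility_block` from [sample_block()], or any list with
#'   `steps` (k x 3) and `reference_direction` (unit xy 2-vector).
#' @param target_direction xy 2-vector pointing toward the new target; must
#'   be nonzero (it is normalised internally).
#' @return A k x 3 matrix of rotated displacements.
#' @export
reorient_block <- function(block, target_direction) {
  stopifnot(is.list(block), is.matrix(block$steps), ncol(block$steps) == 3L)
  tgt <- as.numeric(target_direction)
  if (length(tgt) != 2L || !all(is.finite(tgt)))
    stop("`target_direction` must be a finite xy 2-vector")
  nrm <- sqrt(sum(tgt^2))
  if (nrm < 1e-30) stop("`target_direction` must be nonzero")
  ref <- block$reference_direction
  theta <- atan2(tgt[2], tgt[1]) - atan2(ref[2], ref[1])
  ct <- cos(theta); st <- sin(theta)
  s <- block$steps
  cbind(ct * s[, 1] - st * s[, 2],
        st * s[, 1] + ct * s[, 2],
        s[, 3])
}

#' Replay blocks end-to-end from a start position
#'
#' Convenience used for identity-bootstrap checks: accumulates the step
#' displacements of a sequence of (optionally reoriented) blocks.
#'
#' @param blocks List of k x 3 step matrices.
#' @param start Numeric 3-vector start position.
#' @return Matrix of positions, one row per sample including the start.
#' @export
replay_blocks <- function(blocks, start = c(0, 0, 0)) {
  steps <- do.call(rbind, blocks)
  pos <- apply(steps, 2L, cumsum)
  if (is.null(dim(pos))) pos <- matrix(pos, nrow = 1L)
  rbind(start, sweep(pos, 2L, start, `+`))
}
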