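#' Create an empty chemokine field
#'
#' The field is an append-only log of secretion events; concentration and
#' gradient queries are answered by superposing the free-space heat kernel
#' of the diffusion equation over all prior events,
#' \deqn{C(x,t) = \sum_e q_e (4\pi D (t-t_e))^{-3/2}
#'   \exp\left(-\frac{|x-x_e|^2}{4 D (t-t_e)}\right),}
#' with no degradation and no wall reflections. Time is in seconds here
#' (the dynamics time base), lengths in um, concentration in
#' molecules/um^3.
#'
#' @param D Diffusion coefficient (um^2/s). The default 250 um^2/s
#'   corresponds to a ~10 kDa chemokine such as CCL3/CCL4.
#' @param coalescing_window Window (minutes) within which successive events
#'   from one source are merged; 0 disables merging, making superposition
#'   exact.
#' @param merge_radius Maximum distance (um) between merged events; one
#'   agent radius by default.
#' @return An object of class `chemokine_field`.
#' @export
chemokine_field <- function(D = 250, coalescing_window = 5,
                            merge_radius = 6) {
  stopifnot(D > 0, coalescing_window >= 0, merge_radius >= 0)
  structure(list(events = empty_events(), D = D,
                 coalescing_window = coalescing_window,
                 merge_radius = merge_radius,
                 last_event = integer(0)),
            class = "chemokine_field")
}

empty_events <- function() {
  data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
             t = numeric(0), q = numeric(0), source = character(0),
             stringsAsFactors = FALSE)
}

#' @export
print.chemokine_field <- function(x, ...) {
  cat("<chemokine_field> D =", x$D, "um^2/s,", nrow(x$events),
      "secretion event(s), total", sum(x$events$q), "molecules\n")
  invisible(x)
}

#' Record a secretion event
#'
#' Appends an event to the field log. If the most recent event from the
#' same `source` lies within the coalescing window and within
#' `merge_radius`, the two are merged instead (quantities summed,
#' quantity-weighted mean position and time), which keeps the
#' O(agents x events) superposition tractable over long runs.
#'
#' @param field A [chemokine_field()].
#' @param position Numeric 3-vector (um).
#' @param time Event time (seconds).
#' @param quantity Molecules secreted; must be positive.
#' @param source Optional source identifier used for coalescing.
#' @return The updated `chemokine_field`.
#' @export
record_secretion <- function(field, position, time, quantity,
                             source = "src") {
  stopifnot(inherits(field, "chemokine_field"))
  position <- as.numeric(position)
  if (length(position) != 3L || !all(is.finite(position)))
    stop("`position` must be a finite 3-vector")
  if (!is.finite(time) || time < 0) stop("`time` must be >= 0 (seconds)")
  if (!is.finite(quantity) || quantity <= 0)
    stop("`quantity` must be positive")
  ev <- field$events
  le <- field$last_event[source]
  win_s <- field$coalescing_window * 60
  if (!is.na(le) && length(le) && win_s > 0) {
    prev <- ev[le, ]
    d <- sqrt(sum((position - c(prev$x, prev$y, prev$z))^2))
    if ((time - prev$t) <= win_s && d <= field$merge_radius) {
      tot <- prev$q + quantity
      ev$x[le] <- (prev$q * prev$x + quantity * position[1]) / tot
      ev$y[le] <- (prev$q * prev$y + quantity * position[2]) / tot
      ev$z[le] <- (prev$q * prev$z + quantity * position[3]) / tot
      ev$t[le] <- (prev$q * prev$t + quantity * time) / tot
      ev$q[le] <- tot
      field$events <- ev
      return(field)
    }
  }
  field$events <- rbind(ev, data.frame(
    x = position[1], y = position[2], z = position[3],
    t = time, q = quantity, source = source, stringsAsFactors = FALSE))
  field$last_event[source] <- nrow(field$events)
  field
}

events_matrix <- function(field) {
  as.matrix(field$events[c("x", "y", "z", "t", "q")])
}

#' Chemokine concentration at points in space and time
#'
#' @param field A [chemokine_field()].
#' @param x A 3-vector or an n x 3 matrix of query points (um).
#' @param t Query time (seconds); events at or after `t` contribute
#'   nothing.
#' @return Numeric vector of concentrations (molecules/um^3).
#' @export
concentration <- function(field, x, t) {
  stopifnot(inherits(field, "chemokine_field"), is.finite(t), t >= 0)
  if (!is.matrix(x)) x <- matrix(as.numeric(x), ncol = 3L)
  storage.mode(x) <- "double"
  cpp_concentration(events_matrix(field), x, t, field$D)
}

#' Six-point gradient probe
#'
#' Evaluates the concentration at the six points where a sphere of the
#' given radius around `centre` meets the +/-x, +/-y, +/-z axes, forms the
#' gradient by central differences, and reports its direction together with
#' the maximum of the six probe values (the agent's perceived peak
#' concentration). A gradient of numerically zero norm (ties, symmetric
#' sources, empty field) yields direction `NULL`.
#'
#' @param field A [chemokine_field()].
#' @param centre Numeric 3-vector, the agent centre (um).
#' @param radius Probe radius (um); the agent radius in the simulator.
#' @param t Query time (seconds).
#' @return List with `direction` (unit 3-vector or `NULL`),
#'   `max_concentration`, and `gradient` (the raw central-difference
#'   vector, molecules/um^4).
#' @export
gradient_probe <- function(field, centre, radius, t) {
  stopifnot(inherits(field, "chemokine_field"), radius > 0)
  centre <- as.numeric(centre)
  if (length(centre) != 3L || !all(is.finite(centre)))
    stop("`centre` must be a finite 3-vector")
  res <- cpp_gradient_probe(events_matrix(field), centre, radius, t,
                            field$D)
  g <- res$gradient
  nrm <- sqrt(sum(g^2))
  list(direction = if (nrm > 1e-30) g / nrm else NULL,
       max_concentration = res$max_concentration,
       gradient = g)
}

#' Sample agent-specific sensing thresholds
#'
#' Each threshold is its median times `exp(sigma_log * Z)` with `Z` standard
#' normal (a log-normal with the given median); pairs violating
#' `actuation < desensitisation` are resampled. Draws come from R's random
#' stream.
#'
#' @param params A [threshold_params()] object.
#' @param n Number of agent threshold pairs.
#' @return Data frame with columns `actuation`, `desensitisation`
#'   (molecules/um^3).
#' @export
sample_thresholds <- function(params, n = 1L) {
  stopifnot(inherits(params, "threshold_params"), n >= 1)
  a <- params$actuation_median *
    exp(params$sigma_log * stats::rnorm(n))
  d <- params$desensitisation_median *
    exp(params$sigma_log * stats::rnorm(n))
  bad <- !(a < d)
  while (any(bad)) {
    nb <- sum(bad)
    a[bad] <- params$actuation_median *
      exp(params$sigma_log * stats::rnorm(nb))
    d[bad] <- params$desensitisation_median *
      exp(params$sigma_log * stats::rnorm(nb))
    bad <- !(a < d)
  }
  data.frame(actuation = a, desensitisation = d)
}

#' Serialise a field's event log to a delimited file
#'
#' @param field A [chemokine_field()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_field_events <- function(field, path) {
  stopifnot(inherits(field, "chemokine_field"))
  utils::write.csv(field$events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
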