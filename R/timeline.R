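#' Piecewise-constant value-input timeline
#'
#' A `value_timeline` maps session time (ms) to the length-`N` vector of
#' value inputs `V(t)` driving the network. Values are piecewise
#' constant on half-open intervals `[t_k, t_{k+1})`; the timeline is
#' defined (and zero by default) everywhere on `[0, duration]`.
#'
#' @param onsets Numeric vector of event onset times, ms (strictly
#'   increasing, non-overlapping events).
#' @param durations Event durations, ms (positive; recycled if scalar).
#' @param values Matrix with one row per event and one column per option
#'   (or a vector for a single event), nonnegative.
#' @param total_duration Total timeline duration, ms; defaults to the end
#'   of the last event.
#' @return An object of class `value_timeline`.
#' @examples
#' tl <- value_timeline(onsets = c(0, 4), durations = 3,
#'                      values = rbind(c(20, 40), c(60, 40)),
#'                      total_duration = 8)
#' timeline_value(tl, c(1, 3.5, 5))
#' @export
value_timeline <- function(onsets, durations, values,
                           total_duration = NULL) {
  if (is.null(dim(values))) values <- matrix(values, nrow = 1)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  k <- length(onsets)
  durations <- rep_len(as.double(durations), k)
  if (k == 0) {
    return(new_value_timeline(
      breaks = c(0, total_duration %||% 0),
      values = matrix(0, nrow = 1, ncol = max(1L, ncol(values)))
    ))
  }
  if (nrow(values) != k) {
    abort("`values` must have one row per event.")
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    abort("`values` must be finite and nonnegative.")
  }
  if (any(durations <= 0)) abort("`durations` must be positive.")
  if (any(onsets < 0)) abort("`onsets` must be nonnegative.")
  offsets <- onsets + durations
  if (k > 1 && any(onsets[-1] < offsets[-k] - 1e-9)) {
    first_bad <- which(onsets[-1] < offsets[-k] - 1e-9)[1]
    abort(sprintf(
      "Events %d and %d overlap in time.", first_bad, first_bad + 1
    ))
  }
  total_duration <- total_duration %||% offsets[k]
  if (total_duration < offsets[k] - 1e-9) {
    abort("`total_duration` must cover the last event.")
  }
  n <- ncol(values)
  # interleave off/on segments
  breaks <- c(0)
  segs <- matrix(0, nrow = 0, ncol = n)
  t_cur <- 0
  for (i in seq_len(k)) {
    if (onsets[i] > t_cur + 1e-12) {
      breaks <- c(breaks, onsets[i])
      segs <- rbind(segs, rep(0, n))
    }
    breaks <- c(breaks, offsets[i])
    segs <- rbind(segs, values[i, ])
    t_cur <- offsets[i]
  }
  if (total_duration > t_cur + 1e-12) {
    breaks <- c(breaks, total_duration)
    segs <- rbind(segs, rep(0, n))
  }
  new_value_timeline(breaks = breaks, values = segs)
}

new_value_timeline <- function(breaks, values) {
  stopifnot(length(breaks) == nrow(values) + 1, !is.unsorted(breaks))
  structure(
    list(
      breaks = as.double(breaks),
      values = values,
      n_options = ncol(values),
      duration = breaks[length(breaks)] - breaks[1]
    ),
    class = "value_timeline"
  )
}

#' Evaluate a value timeline
#'
#' Returns the value-input vector `V(t)` at one or more times. Intervals
#' are half-open `[t_k, t_{k+1})`; `t = duration` evaluates to the final
#' segment.
#'
#' @param timeline A [value_timeline].
#' @param t Times in ms, each within `[0, duration]`.
#' @return A matrix with `length(t)` rows and one column per option.
#' @export
timeline_value <- function(timeline, t) {
  stopifnot(inherits(timeline, "value_timeline"))
  br <- timeline$breaks
  if (any(t < br[1] - 1e-9 | t > br[length(br)] + 1e-9)) {
    abort("`t` outside the timeline domain.")
  }
  idx <- findInterval(t, br, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), nrow(timeline$values))
  timeline$values[idx, , drop = FALSE]
}

#' @export
print.value_timeline <- function(x, ...) {
  cat(sprintf(
    "<value_timeline> %d options, duration %g ms, %d segments (%d active)\n",
    x$n_options, x$duration, nrow(x$values),
    sum(rowSums(x$values) > 0)
  ))
  invisible(x)
}

#' @export
as_tibble.value_timeline <- function(x, ...) {
  vals <- x$values
  colnames(vals) <- paste0("v_", seq_len(ncol(vals)))
  tibble::as_tibble(vals) |>
    dplyr::mutate(
      t_start = head(x$breaks, -1), t_end = tail(x$breaks, -1),
      .before = 1
    )
}

#' Compile a behavioral session into a value-input timeline
#'
#' Maps each trial's option magnitudes through `value_map` and gates the
#' resulting two-component value vector on during the trial's display
#' period `[display_on, display_on + display_duration)`; value input is
#' zero between trials. Aborted trials still drive the timeline during
#' their display (the options were shown), while their time-outs extend
#' the zero-input gap that follows. The timeline runs from 0 to the end
#' of the last trial's inter-trial interval.
#'
#' @param session A session tibble (see [generate_session()],
#'   [read_session()]).
#' @param value_map Increasing positive function from reward magnitude to
#'   model value input; the default is the identity, so magnitudes are
#'   used directly as arbitrary value units.
#' @return A [value_timeline] with `N = 2` (option a, option b).
#' @examples
#' s <- generate_session(generator_config(trials_per_block = 10, seed = 1))
#' compile_value_timeline(s)
#' @export
compile_value_timeline <- function(session, value_map = identity) {
  session <- validate_session(session)
  if (nrow(session) == 0) {
    return(new_value_timeline(breaks = c(0, 0),
                              values = matrix(0, nrow = 1, ncol = 2)))
  }
  va <- value_map(session$mag_a)
  vb <- value_map(session$mag_b)
  if (any(!is.finite(c(va, vb))) || any(c(va, vb) < 0)) {
    abort("`value_map` must produce finite nonnegative values.")
  }
  n_tr <- nrow(session)
  total <- session$display_on[n_tr] + session$display_duration[n_tr] +
    session$iti_after[n_tr]
  value_timeline(
    onsets = session$display_on,
    durations = session$display_duration,
    values = cbind(va, vb),
    total_duration = total
  )
}
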