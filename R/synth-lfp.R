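#' Configuration for a synthetic LFP recording
#'
#' Describes a single-channel local field potential trace made of Gaussian
#' noise with injected half-sine transients of known width and amplitude.
#' Amplitudes are expressed in multiples of the noise standard deviation so
#' the detection threshold (in baseline s.d. units) applies directly. When
#' `noise_sd = 0` the unit amplitude reference is 1 uV.
#'
#' @param duration_s Recording length in seconds.
#' @param fs_hz Sampling rate, samples per second.
#' @param noise_sd Gaussian noise s.d. in uV.
#' @param events `data.frame` with columns `onset_s`, `amplitude_sd`,
#'   `width_ms` and `polarity` (`"+"` or `"-"`); may be empty.
#' @param activity_mask `data.frame` with columns `start_s`, `end_s`
#'   delimiting periods of animal activity, or `NULL` for always-active.
#' @param region Anatomical label attached to the channel.
#' @param seed Integer seed; see [derive_seed()].
#' @return An object of class `lfp_sim_config`.
#' @export
lfp_sim_config <- function(duration_s, fs_hz, noise_sd = 10,
                           events = empty_lfp_events(),
                           activity_mask = NULL, region = "CA3", seed = 1L) {
  assert_number(duration_s, "duration_s", positive = TRUE)
  assert_number(fs_hz, "fs_hz", positive = TRUE)
  assert_number(noise_sd, "noise_sd", nonneg = TRUE)
  events <- as.data.frame(events)
  req <- c("onset_s", "amplitude_sd", "width_ms", "polarity")
  if (!all(req %in% names(events)))
    stop("`events` needs columns: ", paste(req, collapse = ", "))
  if (nrow(events)) {
    if (any(events$width_ms <= 0)) stop("event widths must be > 0")
    if (any(events$onset_s < 0 |
            events$onset_s + events$width_ms / 1000 > duration_s))
      stop("all events must lie within [0, duration_s]")
    if (!all(events$polarity %in% c("+", "-")))
      stop("event polarity must be '+' or '-'")
    o <- order(events$onset_s)
    ev <- events[o, ]
    ends <- ev$onset_s + ev$width_ms / 1000
    clash <- which(ev$onset_s[-1] < ends[-nrow(ev)])
    if (length(clash))
      stop("overlapping events at onsets: ",
           paste(sprintf("%.4g/%.4g s", ev$onset_s[clash], ev$onset_s[clash + 1]),
                 collapse = ", "))
  }
  structure(list(duration_s = duration_s, fs_hz = fs_hz, noise_sd = noise_sd,
                 events = events, activity_mask = activity_mask,
                 region = region, seed = seed),
            class = "lfp_sim_config")
}

#' @rdname lfp_sim_config
#' @export
empty_lfp_events <- function() {
  data.frame(onset_s = numeric(0), amplitude_sd = numeric(0),
             width_ms = numeric(0), polarity = character(0))
}

#' Simulate an LFP recording with injected transients
#'
#' Generates Gaussian noise and adds half-sine deflections at the configured
#' onsets. The ground-truth event table is carried in `$truth` so detector
#' recall and precision can be measured exactly.
#'
#' @param config An [lfp_sim_config()].
#' @return An `lfp_recording`: list with `samples` (uV matrix, one column per
#'   channel), `fs_hz`, `channel_meta`, logical `activity_mask` and `truth`.
#' @export
simulate_lfp <- function(config) {
  stopifnot(inherits(config, "lfp_sim_config"))
  n <- round(config$duration_s * config$fs_hz)
  x <- with_seed(config$seed, rnorm(n, sd = config$noise_sd))
  unit <- if (config$noise_sd > 0) config$noise_sd else 1
  ev <- config$events
  if (nrow(ev)) {
    for (i in seq_len(nrow(ev))) {
      i0 <- floor(ev$onset_s[i] * config$fs_hz) + 1L
      w <- max(2L, round(ev$width_ms[i] / 1000 * config$fs_hz))
      idx <- i0:min(n, i0 + w - 1L)
      shape <- sin(pi * (seq_along(idx) - 0.5) / w)
      sgn <- if (ev$polarity[i] == "-") -1 else 1
      x[idx] <- x[idx] + sgn * ev$amplitude_sd[i] * unit * shape
    }
  }
  mask <- rep(TRUE, n)
  if (!is.null(config$activity_mask)) {
    mask <- rep(FALSE, n)
    for (i in seq_len(nrow(config$activity_mask))) {
      a <- max(1L, floor(config$activity_mask$start_s[i] * config$fs_hz) + 1L)
      b <- min(n, ceiling(config$activity_mask$end_s[i] * config$fs_hz))
      if (b >= a) mask[a:b] <- TRUE
    }
  }
  lfp_recording(matrix(x, ncol = 1), config$fs_hz,
                channel_meta = data.frame(channel = 1L, region = config$region,
                                          layer = "cell", stringsAsFactors = FALSE),
                activity_mask = mask, truth = ev)
}

#' Construct an LFP recording container
#'
#' @param samples Numeric matrix, samples x channels, in uV.
#' @param fs_hz Sampling rate.
#' @param channel_meta `data.frame` with one row per channel (columns
#'   `channel`, `region`, `layer`).
#' @param activity_mask Logical vector per sample, or `NULL`.
#' @param truth Optional ground-truth event table (synthetic data only).
#' @export
lfp_recording <- function(samples, fs_hz, channel_meta = NULL,
                          activity_mask = NULL, truth = NULL) {
  samples <- as.matrix(samples)
  assert_number(fs_hz, "fs_hz", positive = TRUE)
  if (is.null(channel_meta))
    channel_meta <- data.frame(channel = seq_len(ncol(samples)),
                               region = "CA3", layer = "cell",
                               stringsAsFactors = FALSE)
  if (nrow(channel_meta) != ncol(samples))
    stop("channel_meta must have one row per channel")
  if (!is.null(activity_mask) && length(activity_mask) != nrow(samples))
    stop("activity_mask length must equal the number of samples")
  structure(list(samples = samples, fs_hz = fs_hz, channel_meta = channel_meta,
                 activity_mask = activity_mask, truth = truth),
            class = "lfp_recording")
}

#' @exportS3Method base::print
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> %d channel(s), %.1f s at %g Hz\n",
              ncol(x$samples), nrow(x$samples) / x$fs_hz, x$fs_hz))
  invisible(x)
}
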