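## Single-molecule trace classification and motility statistics.
##
## A trace is the position of one fluorescent particle along a microtubule,
## sampled every frame_interval seconds. Events are classified with the
## 600-nm excursion taxonomy: diffusive traces make excursions larger than
## 0.6 um in both directions, processive traces move net-unidirectionally
## with no opposing excursion above 0.6 um, and traces displacing less than
## 0.6 um in total are static (nonmotile).

#' Segmentation and classification parameters
#'
#' Bundles the tunable constants of event classification. The 0.6 um
#' directional-change threshold is the defining length scale of the
#' taxonomy and is reused as the static-displacement floor. Pause and
#' change-point settings govern how processive events are split into
#' constant-velocity segments.
#'
#' @param reversalThreshold um; an excursion strictly greater than this
#'   counts as a directional change (default 0.6).
#' @param staticThreshold um; events with total displacement below this are
#'   static (default equals \code{reversalThreshold}).
#' @param velMergeThreshold um/s; adjacent segments whose mean velocities
#'   differ by less than this are merged (default 0.2).
#' @param minSegmentFrames minimum frame intervals per segment (default 3).
#' @param pauseMinFrames minimum frame intervals for a pause (default 3).
#' @param pauseDisplacement um; a segment at least \code{pauseMinFrames}
#'   long is a pause when its median per-frame step stays below this
#'   (default 0.1, a few times the localization error and well below a
#'   moving particle's per-frame advance) and its overall speed stays
#'   below \code{pauseMaxVelocity}.
#' @param pauseMaxVelocity um/s; a segment advancing faster than this
#'   overall is never a pause, whatever its step profile (default 0.15,
#'   well below typical motor velocities).
#' @param smoothWindow odd integer; running-mean window applied to
#'   positions before classification. 1 (default) means raw positions.
#' @return a named list of class \code{motilityParams}.
#' @export
motilityParams <- function(reversalThreshold = 0.6,
                           staticThreshold = reversalThreshold,
                           velMergeThreshold = 0.2,
                           minSegmentFrames = 3,
                           pauseMinFrames = 3,
                           pauseDisplacement = 0.1,
                           pauseMaxVelocity = 0.15,
                           smoothWindow = 1) {
  stopifnot(reversalThreshold > 0, staticThreshold > 0,
            velMergeThreshold >= 0, minSegmentFrames >= 1,
            pauseMinFrames >= 1, pauseDisplacement >= 0,
            pauseMaxVelocity >= 0,
            smoothWindow >= 1, smoothWindow %% 2 == 1)
  structure(list(reversalThreshold = reversalThreshold,
                 staticThreshold = staticThreshold,
                 velMergeThreshold = velMergeThreshold,
                 minSegmentFrames = minSegmentFrames,
                 pauseMinFrames = pauseMinFrames,
                 pauseDisplacement = pauseDisplacement,
                 pauseMaxVelocity = pauseMaxVelocity,
                 smoothWindow = smoothWindow),
            class = "motilityParams")
}

# largest rise above the running minimum / drop below the running maximum
.excursions <- function(pos) {
  cmin <- cummin(pos)
  cmax <- cummax(pos)
  c(forward = max(pos - cmin), backward = max(cmax - pos))
}

.classify_positions <- function(pos, params) {
  exc <- .excursions(pos)
  if (exc["forward"] > params$reversalThreshold &&
      exc["backward"] > params$reversalThreshold) return("diffusive")
  if (abs(pos[length(pos)] - pos[1]) >= params$staticThreshold)
    return("processive")
  "static"
}

# Bottom-up change-point segmentation of a processive trace: start from
# per-frame displacements, repeatedly merge the adjacent pair of segments
# with the smallest mean-velocity difference while that difference is below
# velMergeThreshold, then absorb segments shorter than minSegmentFrames
# into the neighbor with the closer velocity.
.segment_velocities <- function(pos, dt, params) {
  n <- length(pos) - 1L            # frame intervals
  start <- seq_len(n)              # first interval of each segment
  len <- rep(1L, n)
  disp <- diff(pos)                # displacement per segment
  # alternate threshold merging and short-segment absorption until stable:
  # absorbing a boundary blip can make two halves of one pause adjacent
  # again, so the merge phase must get another look at them
  repeat {
    changed <- FALSE
    repeat {
      if (length(start) < 2) break
      v <- disp / (len * dt)
      d <- abs(diff(v))
      j <- which.min(d)
      if (d[j] >= params$velMergeThreshold) break
      disp[j] <- disp[j] + disp[j + 1]
      len[j] <- len[j] + len[j + 1]
      disp <- disp[-(j + 1)]; len <- len[-(j + 1)]; start <- start[-(j + 1)]
      changed <- TRUE
    }
    short <- which(len < params$minSegmentFrames)
    if (length(short) > 0 && length(start) >= 2) {
      j <- short[1]
      v <- disp / (len * dt)
      nb <- if (j == 1) 2L
            else if (j == length(start)) j - 1L
            else if (abs(v[j - 1] - v[j]) <= abs(v[j + 1] - v[j])) j - 1L
            else j + 1L
      lo <- min(j, nb); hi <- max(j, nb)
      disp[lo] <- disp[lo] + disp[hi]
      len[lo] <- len[lo] + len[hi]
      disp <- disp[-hi]; len <- len[-hi]; start <- start[-hi]
      changed <- TRUE
    }
    if (!changed) break
  }
  # velocity from a boundary-trimmed slope for longer segments: the frame
  # interval straddling a change point mixes two velocities, and dropping
  # one interval per side keeps it out of the estimate
  vel <- disp / (len * dt)
  trim <- len >= 5
  if (any(trim)) {
    s0 <- start[trim]; l0 <- len[trim]
    vel[trim] <- (pos[s0 + l0 - 1] - pos[s0 + 1]) / ((l0 - 2) * dt)
  }
  data.frame(start_frame = start - 1L,           # 0-based, half-open spans
             end_frame = start - 1L + len,
             n_frames = len,
             displacement = disp,
             velocity = vel)
}

.running_mean <- function(x, w) {
  if (w <= 1) return(x)
  k <- (w - 1) %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i)
    mean(x[max(1, i - k):min(n, i + k)]), numeric(1))
}

#' Classify one trace and segment it into constant-velocity runs
#'
#' Applies the 600-nm excursion taxonomy to a single trace: diffusive if
#' the positions rise more than the reversal threshold above their running
#' minimum AND drop more than it below their running maximum (an excursion
#' in each direction); otherwise processive if the total displacement
#' reaches the static threshold; otherwise static. Processive events are
#' split into constant-velocity segments by deterministic bottom-up
#' change-point merging, and segments of at least \code{pauseMinFrames}
#' intervals with net displacement below \code{pauseDisplacement} are
#' flagged as pauses (detected on the median per-interval step so that
#' moving boundary frames folded into a pause segment do not mask it).
#' Run length is the summed magnitude of segment displacements.
#'
#' @param trace data.frame with columns \code{frame} (strictly increasing
#'   integers), \code{position_um}, optionally \code{time_s} and
#'   \code{channel2_present} (logical).
#' @param frameInterval s between frames.
#' @param nFrames total frames in the movie (frames are 0-based; frame 0 is
#'   the first, \code{nFrames - 1} the last).
#' @param params a [motilityParams()] list.
#' @return list with elements \code{event_class}, \code{segments}
#'   (data.frame of half-open frame spans with velocities and
#'   \code{is_pause}; empty for non-processive events), \code{run_length},
#'   \code{n_frames}, \code{starts_after_first_frame},
#'   \code{ends_before_last_frame}, \code{colocalized}.
#' @export
classifyEvent <- function(trace, frameInterval, nFrames,
                          params = motilityParams()) {
  if (nrow(trace) < 2) stop("a trace needs at least 2 samples")
  if (any(diff(trace$frame) <= 0)) stop("frames must be strictly increasing")
  pos <- .running_mean(trace$position_um, params$smoothWindow)
  cls <- .classify_positions(pos, params)
  segs <- data.frame(start_frame = integer(0), end_frame = integer(0),
                     n_frames = integer(0), displacement = numeric(0),
                     velocity = numeric(0), is_pause = logical(0))
  run_length <- 0
  if (cls == "processive") {
    segs <- .segment_velocities(pos, frameInterval, params)
    # pause flag: the typical (median) per-interval step inside the
    # segment is at the localization-noise scale rather than the moving
    # scale; the median is robust to moving boundary frames that the
    # change-point merge folds into a pause segment
    step <- abs(diff(pos))
    med_step <- vapply(seq_len(nrow(segs)), function(j)
      stats::median(step[(segs$start_frame[j] + 1):segs$end_frame[j]]),
      numeric(1))
    # ... and the segment as a whole advances below the pause velocity
    # ceiling, so steady slow movement is not mistaken for a pause
    segs$is_pause <- segs$n_frames >= params$pauseMinFrames &
      med_step < params$pauseDisplacement &
      abs(segs$velocity) < params$pauseMaxVelocity
    segs$start_frame <- segs$start_frame + trace$frame[1]
    segs$end_frame <- segs$end_frame + trace$frame[1]
    run_length <- sum(abs(segs$displacement))
  }
  coloc <- if (!is.null(trace$channel2_present))
    any(as.logical(trace$channel2_present)) else FALSE
  list(event_class = cls,
       segments = segs,
       run_length = run_length,
       n_frames = nrow(trace),
       starts_after_first_frame = trace$frame[1] > 0,
       ends_before_last_frame = trace$frame[nrow(trace)] < nFrames - 1,
       colocalized = coloc)
}

#' Classify every event in a trace table
#'
#' @param traces data.frame with columns \code{event_id}, \code{frame},
#'   \code{position_um}, optionally \code{channel2_present}.
#' @param frameInterval s between frames.
#' @param nFrames frames per movie.
#' @param params a [motilityParams()] list.
#' @return list of per-event classification results (see [classifyEvent()]),
#'   named by event id, with the event id stored in each element.
#' @export
classifyEvents <- function(traces, frameInterval, nFrames,
                           params = motilityParams()) {
  split_tr <- split(traces, traces$event_id)
  out <- lapply(split_tr, function(tr) {
    ev <- classifyEvent(tr[order(tr$frame), ], frameInterval, nFrames, params)
    ev$event_id <- as.character(tr$event_id[1])
    ev
  })
  out[order(names(out))]
}

#' Per-segment velocities of qualifying processive events
#'
#' Reports the absolute velocity of every non-pause segment of processive
#' events spanning more than \code{minFrames} frames. Each segment of a
#' multivelocity event contributes its own entry and is held to the same
#' more-than-\code{minFrames} span requirement as a whole event, since a
#' velocity read off one or two frame intervals is dominated by
#' localization error. Diffusive and static events contribute nothing.
#'
#' @param events list of classified events from [classifyEvents()].
#' @param minFrames events and segments must span strictly more than this
#'   many frames (default 5).
#' @return numeric vector of velocities (um/s).
#' @export
eventVelocities <- function(events, minFrames = 5) {
  v <- lapply(events, function(ev) {
    if (ev$event_class != "processive" || ev$n_frames <= minFrames)
      return(numeric(0))
    keep <- !ev$segments$is_pause & ev$segments$n_frames > minFrames
    abs(ev$segments$velocity[keep])
  })
  unlist(v, use.names = FALSE)
}

#' Run lengths of processive events
#'
#' @param events list of classified events.
#' @return numeric vector, one total run length (um) per processive event.
#' @export
runLengths <- function(events) {
  rl <- vapply(events, function(ev)
    if (ev$event_class == "processive") ev$run_length else NA_real_,
    numeric(1))
  unname(rl[!is.na(rl)])
}

#' Landing rate of processive events
#'
#' Counts processive events that start after the first frame and end
#' before the last frame of the movie (so that a complete landing and
#' release was observed) and normalizes by microtubule length and total
#' movie time. Events touching either movie boundary do not contribute.
#'
#' @param events list of classified events.
#' @param mtLength um of microtubule imaged.
#' @param movieDuration s of recording.
#' @return events per um per s.
#' @export
landingRate <- function(events, mtLength, movieDuration) {
  if (mtLength <= 0 || movieDuration <= 0)
    stop("mtLength and movieDuration must be positive")
  n <- sum(vapply(events, function(ev)
    ev$event_class == "processive" &&
      ev$starts_after_first_frame && ev$ends_before_last_frame,
    logical(1)))
  n / (mtLength * movieDuration)
}

#' Pausing frequency of processive events
#'
#' Total number of pause segments across multivelocity processive events
#' divided by the total run length of all processive events.
#'
#' @param events list of classified events.
#' @return pauses per um; errors when total run length is zero.
#' @export
pausingFrequency <- function(events) {
  proc <- Filter(function(ev) ev$event_class == "processive", events)
  total_run <- sum(vapply(proc, `[[`, numeric(1), "run_length"))
  if (total_run <= 0)
    stop("pausing frequency undefined: total run length is zero")
  pauses <- sum(vapply(proc, function(ev) sum(ev$segments$is_pause),
                       numeric(1)))
  pauses / total_run
}

#' Fraction of processive events colocalized with the second channel
#'
#' An event counts as colocalized when the second channel is present on at
#' least one of its samples (partial colocalization suffices).
#'
#' @param events list of classified events.
#' @return fraction in [0, 1]; errors when there are no processive events.
#' @export
colocalizedFraction <- function(events) {
  proc <- Filter(function(ev) ev$event_class == "processive", events)
  if (length(proc) == 0)
    stop("colocalized fraction undefined: no processive events")
  mean(vapply(proc, `[[`, logical(1), "colocalized"))
}

#' Summary statistics for one motility condition
#'
#' @param events list of classified events from [classifyEvents()].
#' @param mtLength um; total microtubule length imaged.
#' @param movieDuration s; total movie time.
#' @param minFrames velocity qualification span (see [eventVelocities()]).
#' @return list with \code{velocities}, \code{run_lengths},
#'   \code{landing_rate}, \code{pausing_frequency},
#'   \code{colocalized_fraction} (NA when no processive events),
#'   \code{n_processive}, \code{n_diffusive}, \code{n_static}.
#' @export
motilitySummary <- function(events, mtLength, movieDuration, minFrames = 5) {
  cls <- vapply(events, `[[`, character(1), "event_class")
  n_proc <- sum(cls == "processive")
  list(velocities = eventVelocities(events, minFrames),
       run_lengths = runLengths(events),
       landing_rate = landingRate(events, mtLength, movieDuration),
       pausing_frequency = if (n_proc > 0 &&
                               sum(runLengths(events)) > 0)
         pausingFrequency(events) else NA_real_,
       colocalized_fraction = if (n_proc > 0)
         colocalizedFraction(events) else NA_real_,
       n_processive = n_proc,
       n_diffusive = sum(cls == "diffusive"),
       n_static = sum(cls == "static"))
}

#' Two-group comparison with the field's standard tests
#'
#' Two-sided comparison of two samples of motility statistics, either by
#' Welch's unequal-variance t-test or by the Mann-Whitney (Wilcoxon
#' rank-sum) test with normal approximation and continuity correction.
#'
#' @param a,b numeric vectors.
#' @param test \code{"welch_t"} or \code{"mann_whitney"}.
#' @return list with \code{statistic} (t, or the Mann-Whitney U of the
#'   first sample) and \code{p_value}.
#' @export
compareGroups <- function(a, b, test = c("welch_t", "mann_whitney")) {
  test <- match.arg(test)
  if (test == "welch_t") {
    if (length(a) < 2 || length(b) < 2)
      stop("welch_t needs at least 2 values per group")
    ht <- stats::t.test(a, b, var.equal = FALSE)
    list(statistic = unname(ht$statistic), p_value = ht$p.value)
  } else {
    if (length(a) < 1 || length(b) < 1)
      stop("mann_whitney needs at least 1 value per group")
    ht <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))
    list(statistic = unname(ht$statistic), p_value = ht$p.value)
  }
}
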