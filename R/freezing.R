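#' Per-frame pixel-change trace
#'
#' Container for the number of changed pixels per video frame, the substrate
#' of freezing classification. By convention the first frame (which has no
#' predecessor) carries the value 0.
#'
#' @param values non-negative changed-pixel counts, one per frame.
#' @param fps frame rate, frames per s.
#' @param frame_pixels total pixels per frame; the default 196608 (512 x 384)
#'   matches the geometry under which the canonical global threshold of 983
#'   pixels equals 0.5 percent of the frame.
#' @param roi_mode "global" (whole frame) or "roi" (counts restricted to a
#'   region around the animal, used to discard patch-cord motion).
#' @param smoothed logical; has Gaussian temporal smoothing been applied.
#' @return a `pixel_change_trace` object.
#' @export
pixel_trace <- function(values, fps = 25, frame_pixels = 196608L,
                        roi_mode = c("global", "roi"), smoothed = FALSE) {
  roi_mode <- match.arg(roi_mode)
  stop_if_not(length(values) >= 2, "trace needs at least 2 frames")
  stop_if_not(all(values >= 0), "changed-pixel counts must be >= 0")
  stop_if_not(fps > 0, "fps must be positive")
  structure(list(values = as.numeric(values), fps = fps,
                 frame_pixels = frame_pixels, roi_mode = roi_mode,
                 smoothed = smoothed),
            class = "pixel_change_trace")
}

#' @export
print.pixel_change_trace <- function(x, ...) {
  cat(sprintf("pixel-change trace: %d frames @ %g fps (%s mode%s)\n",
              length(x$values), x$fps, x$roi_mode,
              if (x$smoothed) ", smoothed" else ""))
  invisible(x)
}

## bounding box of a changed blob, dilated; tracks the animal across frames:
## prefer the largest blob overlapping the previous ROI, so a patch cord
## moving elsewhere does not capture the ROI while the animal is still
largest_blob_roi <- function(mask, dilate_px, prev = NULL) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  labs <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nlab <- max(labs)
  if (nlab == 0L) return(prev)
  sizes <- tabulate(labs[labs > 0L], nbins = nlab)
  box <- function(id) {
    idx <- which(labs == id, arr.ind = TRUE)
    list(rows = max(1, min(idx[, 1]) - dilate_px):
           min(nrow(mask), max(idx[, 1]) + dilate_px),
         cols = max(1, min(idx[, 2]) - dilate_px):
           min(ncol(mask), max(idx[, 2]) + dilate_px))
  }
  if (!is.null(prev)) {
    overlapping <- which(vapply(seq_len(nlab), function(id) {
      idx <- which(labs == id, arr.ind = TRUE)
      any(idx[, 1] %in% prev$rows & idx[, 2] %in% prev$cols)
    }, logical(1)))
    if (length(overlapping) == 0L) return(prev)  # animal still; keep ROI
    return(box(overlapping[which.max(sizes[overlapping])]))
  }
  box(which.max(sizes))
}

#' Changed-pixel counts from a grayscale frame stack
#'
#' Frame-differences a stack of 8-bit grayscale frames: a pixel counts as
#' changed when its absolute intensity difference from the previous frame
#' exceeds `delta`. In "roi" mode only changed pixels inside a dilated
#' bounding region around the largest moving blob (the animal) are counted,
#' which discards patch-cord motion elsewhere in the frame; when no moving
#' blob is found in a frame the ROI falls back to the whole frame.
#'
#' @param frames array (height x width x n_frames) of intensities in 0..255.
#' @param mode "global" or "roi".
#' @param delta per-pixel change criterion on the 0..255 scale (default 10).
#' @param roi_dilate_px dilation margin of the ROI bounding box.
#' @param roi optional initial region list(rows, cols) seeding the tracker
#'   (e.g. the known animal position in the first frame); without it the ROI
#'   is established from the first moving blob.
#' @param fps frame rate recorded on the resulting trace.
#' @return a [pixel_trace()] (`values[1] = 0`).
#' @export
pixel_change <- function(frames, mode = c("global", "roi"), delta = 10,
                         roi_dilate_px = 8, roi = NULL, fps = 25) {
  mode <- match.arg(mode)
  d <- dim(frames)
  stop_if_not(length(d) == 3 && d[3] >= 2,
              "frames must be a height x width x (>= 2) array")
  n <- d[3]
  vals <- numeric(n)
  for (f in 2:n) {
    changed <- abs(frames[, , f] - frames[, , f - 1]) > delta
    if (mode == "global") {
      vals[f] <- sum(changed)
    } else {
      roi <- largest_blob_roi(changed, roi_dilate_px, prev = roi)
      if (is.null(roi)) {
        vals[f] <- sum(changed)   # no ROI established yet: global count
        if (any(changed)) warning("empty ROI; used global count")
      } else {
        vals[f] <- sum(changed[roi$rows, roi$cols])
      }
    }
  }
  pixel_trace(vals, fps = fps, frame_pixels = d[1] * d[2], roi_mode = mode)
}

#' Gaussian temporal smoothing of a pixel-change trace
#'
#' Discrete Gaussian convolution with the kernel truncated at +/- 4 sigma and
#' renormalized to sum 1; boundaries are handled by edge replication, so
#' constant traces are preserved exactly.
#'
#' @param trace a [pixel_trace()].
#' @param sigma_frames Gaussian SD in frames (default 3).
#' @return the smoothed trace (`smoothed = TRUE`).
#' @export
smooth_trace <- function(trace, sigma_frames = 3) {
  stopifnot(inherits(trace, "pixel_change_trace"))
  stop_if_not(sigma_frames > 0, "sigma_frames must be positive")
  x <- trace$values
  half <- ceiling(4 * sigma_frames)
  kern <- dnorm(-half:half, sd = sigma_frames)
  kern <- kern / sum(kern)
  if (length(x) < length(kern))
    warning("trace shorter than the smoothing kernel; edges dominate")
  padded <- c(rep(x[1], half), x, rep(x[length(x)], half))
  sm <- vapply(seq_along(x),
               function(i) sum(padded[i:(i + 2 * half)] * kern), numeric(1))
  out <- trace
  out$values <- sm
  out$smoothed <- TRUE
  out
}

#' Consecutive-frame count for a freezing duration criterion
#'
#' Number of consecutive sub-threshold frames required to call freezing:
#' `ceiling(duration_s * fps)`. The canonical criterion of 1.5 s at 25 fps
#' gives 38 frames.
#'
#' @param duration_s minimum immobile duration, s.
#' @param fps frame rate.
#' @return integer frame count.
#' @export
min_run_from_duration <- function(duration_s = 1.5, fps = 25) {
  stop_if_not(duration_s > 0 && fps > 0, "duration and fps must be positive")
  as.integer(ceiling(duration_s * fps))
}

#' Detect freezing bouts by run-length thresholding
#'
#' A frame is labeled freezing exactly when it belongs to a maximal run of at
#' least `min_run_frames` consecutive frames with a (smoothed) changed-pixel
#' value strictly below `threshold_px`. Ties at the threshold count as motion.
#' Default thresholds: 983 pixels in global mode (0.5 percent of the default
#' 512 x 384 frame) and 100 pixels in ROI mode. A warning is issued when a
#' global-mode threshold deviates from 0.5 percent of `frame_pixels` by more
#' than 10 percent.
#'
#' @param trace a (preferably smoothed) [pixel_trace()].
#' @param threshold_px motion threshold in changed pixels; `NULL` picks the
#'   mode-specific default.
#' @param min_run_frames minimum run length in frames (default 38 = 1.5 s at
#'   25 fps).
#' @return a `freezing_result`: list with `bouts` (matrix of 0-based
#'   half-open `[start, end)` frame intervals), `frame_labels` (logical per
#'   frame), `fps`, `n_frames`.
#' @export
detect_freezing <- function(trace, threshold_px = NULL, min_run_frames = 38L) {
  stopifnot(inherits(trace, "pixel_change_trace"))
  stop_if_not(min_run_frames >= 1, "min_run_frames must be >= 1")
  if (is.null(threshold_px)) {
    threshold_px <- if (trace$roi_mode == "global") 983 else 100
  }
  if (trace$roi_mode == "global") {
    nominal <- 0.005 * trace$frame_pixels
    if (abs(threshold_px - nominal) / nominal > 0.10) {
      warning(sprintf(paste0("global threshold %g deviates from 0.5%% of the ",
                             "frame (%g px) by more than 10%%"),
                      threshold_px, nominal))
    }
  }
  sub <- trace$values < threshold_px
  r <- rle(sub)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run_frames
  labels <- rep(FALSE, length(sub))
  bouts <- matrix(integer(), 0, 2, dimnames = list(NULL, c("start", "end")))
  if (any(keep)) {
    bouts <- cbind(start = starts[keep] - 1L, end = ends[keep])  # 0-based, half-open
    for (i in which(keep)) labels[starts[i]:ends[i]] <- TRUE
  }
  structure(list(bouts = bouts, frame_labels = labels,
                 fps = trace$fps, n_frames = length(sub),
                 threshold_px = threshold_px,
                 min_run_frames = as.integer(min_run_frames)),
            class = "freezing_result")
}

#' @export
print.freezing_result <- function(x, ...) {
  cat(sprintf("freezing: %d bouts, %.1f%% of %d frames\n",
              nrow(x$bouts), 100 * mean(x$frame_labels), x$n_frames))
  invisible(x)
}

#' Session protocol of conditioned-stimulus windows
#'
#' Describes the CS presentation schedule of a conditioning / extinction
#' session: each CS window plus the 30 s pre-CS baseline window preceding it,
#' and the early/late phase split (first versus last `phase_n` CS).
#'
#' @param cs_starts_s CS onset times, s.
#' @param cs_duration_s CS duration (default 30 s tones).
#' @param pre_window_s length of the pre-CS window (default 30 s).
#' @param phase_n number of CS per phase (default 10: early = first 10, late
#'   = last 10).
#' @return a `session_protocol` object.
#' @export
session_protocol <- function(cs_starts_s, cs_duration_s = 30,
                             pre_window_s = 30, phase_n = 10L) {
  stop_if_not(length(cs_starts_s) >= 1, "need at least one CS window")
  stop_if_not(cs_duration_s > 0 && pre_window_s > 0, "durations must be positive")
  stop_if_not(all(cs_starts_s >= pre_window_s),
              "each CS needs a full pre-CS window before it")
  structure(list(cs_starts_s = sort(cs_starts_s),
                 cs_duration_s = cs_duration_s,
                 pre_window_s = pre_window_s, phase_n = as.integer(phase_n)),
            class = "session_protocol")
}

#' Percent freezing per CS and pre-CS window
#'
#' For every CS window and its preceding pre-CS window, the percentage of
#' frames labeled freezing: 100 * (freezing frames) / (frames in window).
#' Early/late phase means (first and last `phase_n` CS) are attached as the
#' `"phases"` attribute.
#'
#' @param result a [detect_freezing()] result.
#' @param protocol a [session_protocol()].
#' @return data.frame (window, index, start_s, duration_s, percent).
#' @export
percent_freezing <- function(result, protocol) {
  stopifnot(inherits(result, "freezing_result"),
            inherits(protocol, "session_protocol"))
  fps <- result$fps
  pct_window <- function(start_s, dur_s) {
    a <- round(start_s * fps)             # 0-based frame index
    b <- round((start_s + dur_s) * fps)
    if (a < 0 || b > result$n_frames)
      stop("analysis window outside the trace", call. = FALSE)
    100 * mean(result$frame_labels[(a + 1):b])
  }
  cs <- vapply(protocol$cs_starts_s,
               pct_window, numeric(1), dur_s = protocol$cs_duration_s)
  pre <- vapply(protocol$cs_starts_s - protocol$pre_window_s,
                pct_window, numeric(1), dur_s = protocol$pre_window_s)
  k <- length(cs)
  out <- data.frame(
    window = rep(c("cs", "pre_cs"), each = k),
    index = rep(seq_len(k), 2),
    start_s = c(protocol$cs_starts_s,
                protocol$cs_starts_s - protocol$pre_window_s),
    duration_s = rep(c(protocol$cs_duration_s, protocol$pre_window_s), each = k),
    percent = c(cs, pre))
  pn <- min(protocol$phase_n, k)
  attr(out, "phases") <- data.frame(
    window = rep(c("cs", "pre_cs"), each = 2),
    phase = rep(c("early", "late"), 2),
    percent = c(mean(cs[seq_len(pn)]), mean(cs[(k - pn + 1):k]),
                mean(pre[seq_len(pn)]), mean(pre[(k - pn + 1):k])))
  out
}
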