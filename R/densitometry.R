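#' Construct a lane profile
#'
#' @param signal numeric intensity trace, top of gel first.
#' @param laneId lane identifier.
#' @param backgroundSubtracted whether a baseline has already been
#'   removed.
#' @param noiseSd optional robust per-sample noise estimate (set by
#'   [subtractBackground()]).
#' @return a [GelLane-class].
#' @export
gelLane <- function(signal, laneId = "lane1",
                    backgroundSubtracted = FALSE, noiseSd = NA_real_) {
    new("GelLane", signal = as.numeric(signal),
        laneId = as.character(laneId),
        backgroundSubtracted = backgroundSubtracted,
        noiseSd = as.numeric(noiseSd))
}

#' @describeIn gelLane signal accessor
#' @param lane a [GelLane-class].
#' @export
laneSignal <- function(lane) lane@signal

#' @describeIn gelLane lane identifier accessor
#' @export
laneId <- function(lane) lane@laneId

setMethod("show", "GelLane", function(object) {
    cat("GelLane '", object@laneId, "': ", length(object@signal),
        " samples, signal range [",
        signif(min(object@signal), 4), ", ",
        signif(max(object@signal), 4), "]",
        if (object@backgroundSubtracted) ", background-subtracted", "\n",
        sep = "")
})

#' Remove the smooth background from a lane profile
#'
#' Estimates the baseline by morphological opening (rolling minimum
#' followed by rolling maximum) of a lightly smoothed copy of the profile
#' -- smoothing first keeps the opening from tracking the minima of the
#' noise -- and subtracts it, clipping the residual at zero. The window
#' must be wider than the widest band, or bands are eaten into the
#' baseline.
#'
#' @param lane a [GelLane-class].
#' @param window opening window, samples (>= 3); should exceed several
#'   band widths.
#' @param bandWidth expected Gaussian band standard deviation, samples;
#'   a window below ~6 band sd triggers a warning.
#' @param smoothSd standard deviation of the light pre-smoothing applied
#'   only to the baseline estimate.
#' @return a background-subtracted [GelLane-class] (signal clipped at 0).
#' @examples
#' lane <- gelLane(rep(5, 64))
#' max(laneSignal(subtractBackground(lane, window = 21)))
#' @export
subtractBackground <- function(lane, window = 51L, bandWidth = 3,
                               smoothSd = 2) {
    stopifnot(is(lane, "GelLane"))
    window <- as.integer(window)
    if (window < 3L) stop("window must be >= 3 samples")
    if (window < 6 * bandWidth)
        warning("background window (", window,
                ") is not much wider than the band width (sd ", bandWidth,
                "); bands may be absorbed into the baseline")
    y <- lane@signal
    base <- .rollMax(.rollMin(.gaussSmooth(y, smoothSd), window), window)
    resid <- y - base
    gelLane(pmax(resid, 0), laneId = lane@laneId,
            backgroundSubtracted = TRUE,
            noiseSd = stats::mad(diff(resid)) / sqrt(2))
}

## Baseline residual without clipping; used internally so that the noise
## estimate is not halved by the zero clip.
.backgroundResidual <- function(signal, window = 51L, smoothSd = 2) {
    base <- .rollMax(.rollMin(.gaussSmooth(signal, smoothSd), window),
                     window)
    signal - base
}

## Classic peak prominence on a trace: height above the higher of the two
## saddle minima separating the peak from the nearest higher points (or
## the trace ends).
.prominence <- function(y, peaks) {
    n <- length(y)
    vapply(peaks, function(i) {
        lmin <- y[i]
        j <- i
        while (j > 1L && y[j - 1L] <= y[i]) {
            j <- j - 1L
            if (y[j] < lmin) lmin <- y[j]
        }
        if (j == 1L && y[1L] < lmin) lmin <- y[1L]
        rmin <- y[i]
        j <- i
        while (j < n && y[j + 1L] <= y[i]) {
            j <- j + 1L
            if (y[j] < rmin) rmin <- y[j]
        }
        if (j == n && y[n] < rmin) rmin <- y[n]
        y[i] - max(lmin, rmin)
    }, numeric(1))
}

## Sub-sample peak refinement by a parabola through (i-1, i, i+1).
.parabolicCenter <- function(y, i) {
    if (i <= 1L || i >= length(y)) return(as.numeric(i))
    d1 <- y[i - 1L]; d2 <- y[i]; d3 <- y[i + 1L]
    den <- d1 - 2 * d2 + d3
    if (den >= 0) return(as.numeric(i))
    i + 0.5 * (d1 - d3) / den
}

#' Detect protein bands in a background-subtracted lane profile
#'
#' Matched-filter band calling: the profile is smoothed with a Gaussian
#' kernel of the expected band width, local maxima are measured against a
#' wide running-median floor, and a band is kept when its amplitude
#' exceeds `minSnr` times the robust per-sample noise (MAD of the
#' first-differenced, unclipped baseline residual) and its prominence on
#' the smoothed trace exceeds `minProminence`. Overlapping bands are
#' split at the local minimum between their maxima. Each band is reported
#' with its sub-sample centre, relative mobility Rf (centre over the dye
#' front, taken as the profile end), amplitude, prominence,
#' signal-to-noise ratio, and integrated signal (trapezoidal area of the
#' background-subtracted profile between the flanking minima).
#'
#' @param lane a background-subtracted [GelLane-class] (profiles that are
#'   not flagged as subtracted are subtracted first with the default
#'   window).
#' @param minSnr minimum amplitude / noise ratio (the conventional
#'   detection-limit criterion of 3 by default).
#' @param minProminence minimum prominence on the smoothed trace, signal
#'   units.
#' @param bandWidth expected band standard deviation, samples (sets the
#'   matched filter).
#' @param floorWindow window of the running-median amplitude floor,
#'   samples.
#' @return data.frame with one row per band, sorted by centre: `lane_id`,
#'   `center`, `rf`, `amplitude`, `prominence`, `snr`, `left`, `right`
#'   (integration bounds, samples), `integrated_signal`. Zero rows when
#'   nothing is detected.
#' @examples
#' sim <- simulateLane(laneComposition("Albumin", 100), gelModel(), seed = 1)
#' detectBands(subtractBackground(sim$lane))
#' @export
detectBands <- function(lane, minSnr = 3, minProminence = 0.5,
                        bandWidth = 3, floorWindow = 81L) {
    stopifnot(is(lane, "GelLane"))
    if (!lane@backgroundSubtracted) {
        resid <- .backgroundResidual(lane@signal)
        y <- pmax(resid, 0)
        noise <- stats::mad(diff(resid)) / sqrt(2)
    } else {
        y <- lane@signal
        noise <- if (!is.na(lane@noiseSd)) lane@noiseSd else
            stats::mad(diff(y)) / sqrt(2)
    }
    n <- length(y)
    empty <- data.frame(lane_id = character(), center = numeric(),
                        rf = numeric(), amplitude = numeric(),
                        prominence = numeric(), snr = numeric(),
                        left = integer(), right = integer(),
                        integrated_signal = numeric())
    if (n < 5L || all(y == 0)) return(empty)
    noise <- max(noise, 1e-9)
    sm <- .gaussSmooth(y, bandWidth)
    floor_ <- stats::runmed(sm, .oddWindow(floorWindow, n))
    ## strict-left / non-strict-right local maxima (plateau-tolerant)
    isMax <- c(FALSE, sm[2:(n - 1)] > sm[1:(n - 2)] &
                       sm[2:(n - 1)] >= sm[3:n], FALSE)
    peaks <- which(isMax)
    if (!length(peaks)) return(empty)
    amp <- sm[peaks] - floor_[peaks]
    prom <- .prominence(sm, peaks)
    snr <- amp / noise
    keep <- snr >= minSnr & prom >= minProminence & amp > 0
    peaks <- peaks[keep]
    if (!length(peaks)) return(empty)
    amp <- amp[keep]; prom <- prom[keep]; snr <- snr[keep]
    ## integration bounds: the minimum of the smoothed trace between
    ## adjacent kept peaks, never further than 6 band widths from the
    ## peak (integrating clipped noise far from an isolated band would
    ## otherwise bias its area upward)
    k <- length(peaks)
    reach <- max(3L, as.integer(ceiling(6 * bandWidth)))
    left <- integer(k); right <- integer(k)
    for (i in seq_len(k)) {
        lo <- if (i == 1L) 1L else
            peaks[i - 1L] + which.min(sm[peaks[i - 1L]:peaks[i]]) - 1L
        hi <- if (i == k) n else
            peaks[i] + which.min(sm[peaks[i]:peaks[i + 1L]]) - 1L
        left[i] <- max(lo, peaks[i] - reach)
        right[i] <- min(hi, peaks[i] + reach)
    }
    center <- vapply(peaks, function(i) .parabolicCenter(sm, i),
                     numeric(1))
    area <- vapply(seq_len(k), function(i)
        .trapz(y, left[i], right[i]), numeric(1))
    out <- data.frame(lane_id = lane@laneId, center = center,
                      rf = (center - 1) / (n - 1), amplitude = amp,
                      prominence = prom, snr = snr, left = left,
                      right = right, integrated_signal = area)
    out[order(out$center), , drop = FALSE]
}

#' Integrate a band on a lane profile
#'
#' Trapezoidal area of the (background-subtracted) profile between two
#' sample positions. Additive over disjoint spans and linear in the
#' signal.
#'
#' @param lane a [GelLane-class].
#' @param left,right integration bounds in samples, inside the profile.
#' @return non-negative area in signal-position units.
#' @export
integrateBand <- function(lane, left, right) {
    stopifnot(is(lane, "GelLane"))
    n <- length(lane@signal)
    left <- as.integer(left); right <- as.integer(right)
    if (left < 1L || right > n || left > right)
        stop("band span [", left, ", ", right,
             "] outside the profile (length ", n, ")")
    .trapz(pmax(lane@signal, 0), left, right)
}

#' Plot a lane profile with detected bands
#'
#' @param lane a [GelLane-class].
#' @param bands optional band table from [detectBands()].
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `NULL`.
#' @export
plotLane <- function(lane, bands = NULL, ...) {
    y <- laneSignal(lane)
    graphics::plot(seq_along(y), y, type = "l", xlab = "migration (samples)",
                   ylab = "signal", main = laneId(lane), ...)
    if (!is.null(bands) && nrow(bands)) {
        graphics::abline(v = bands$center, col = "red3", lty = 3)
        graphics::points(bands$center, bands$amplitude, col = "red3",
                         pch = 16, cex = 0.7)
    }
    invisible(NULL)
}
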