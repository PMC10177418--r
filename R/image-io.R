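#' Construct a gel image from lane profiles or a pixel matrix
#'
#' Assembles a signal-oriented image (larger value = more protein) from a
#' set of lane profiles laid out left to right with blank gutters, or
#' wraps an existing pixel matrix.
#'
#' @param lanes list of [GelLane-class] objects (equal length), or a
#'   numeric matrix of signal-oriented pixels.
#' @param laneWidth lane width in pixels.
#' @param gap gutter width between lanes (and at the margins), pixels.
#' @return a [GelImage-class] with lane boundaries recorded.
#' @examples
#' sim <- simulateLane(laneComposition("Albumin", 100), seed = 1)
#' img <- gelImage(list(sim$lane))
#' dim(img@pixels)
#' @export
gelImage <- function(lanes, laneWidth = 20L, gap = 8L) {
    if (is.matrix(lanes))
        return(new("GelImage", pixels = lanes, laneBoundaries = list(),
                   source = ""))
    stopifnot(length(lanes) >= 1L,
              all(vapply(lanes, is, logical(1), "GelLane")))
    L <- unique(vapply(lanes, function(l) length(l@signal), integer(1)))
    if (length(L) != 1L) stop("all lanes must have the same length")
    nl <- length(lanes)
    width <- nl * laneWidth + (nl + 1L) * gap
    px <- matrix(0, nrow = L, ncol = width)
    bounds <- vector("list", nl)
    for (i in seq_len(nl)) {
        c0 <- gap * i + laneWidth * (i - 1L) + 1L
        c1 <- c0 + laneWidth - 1L
        px[, c0:c1] <- lanes[[i]]@signal
        bounds[[i]] <- c(c0, c1)
    }
    new("GelImage", pixels = px, laneBoundaries = bounds, source = "")
}

#' Write a gel image to a 16-bit grayscale TIFF or PNG
#'
#' Scans of Coomassie gels are dark-bands-on-light-background; the
#' signal-oriented pixels are therefore inverted on write (pixel =
#' 1 - signal/white) and re-inverted on read. The scale and any lane
#' boundaries travel in a JSON sidecar (`<path>.json`) so that a
#' write/read round trip restores the signal units.
#'
#' @param image a [GelImage-class].
#' @param path output file; extension selects the format (.tif/.tiff or
#'   .png).
#' @param white signal value mapped to pure white; defaults to 1.05 times
#'   the pixel maximum.
#' @return invisibly, `path`.
#' @export
writeGelImage <- function(image, path, white = NULL) {
    stopifnot(is(image, "GelImage"))
    if (is.null(white)) white <- max(image@pixels) * 1.05
    if (white <= 0) white <- 1
    img01 <- pmin(pmax(1 - image@pixels / white, 0), 1)
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("tif", "tiff")) {
        tiff::writeTIFF(img01, path, bits.per.sample = 16L)
    } else if (ext == "png") {
        png::writePNG(img01, path)
    } else stop("unsupported image format: .", ext)
    sidecar <- list(schema = "urinePAGE-gel-image/1", white = white,
                    lane_boundaries = image@laneBoundaries)
    jsonlite::write_json(sidecar, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Read a gel scan into signal orientation
#'
#' Reads a grayscale TIFF or PNG, inverts it (dark = more protein), and
#' restores the signal scale and lane boundaries from the JSON sidecar
#' when present.
#'
#' @param path image file.
#' @return a [GelImage-class].
#' @export
readGelImage <- function(path) {
    if (!file.exists(path)) stop("image file not found: ", path)
    ext <- tolower(tools::file_ext(path))
    px <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
          else if (ext == "png") png::readPNG(path)
          else stop("unsupported image format: .", ext)
    if (length(dim(px)) == 3L) px <- px[, , 1L]  # grayscale channel
    white <- 1
    bounds <- list()
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar)) {
        sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
        if (!is.null(sc$white)) white <- sc$white
        if (length(sc$lane_boundaries))
            bounds <- lapply(seq_len(nrow(sc$lane_boundaries)),
                             function(i) as.integer(sc$lane_boundaries[i, ]))
    }
    new("GelImage", pixels = (1 - px) * white, laneBoundaries = bounds,
        source = path)
}

#' Extract per-lane profiles from a gel image
#'
#' Uses the recorded lane boundaries when available; otherwise detects
#' lanes by 2-means clustering of the column means (lanes carry the
#' background signal, gutters are blank) and takes runs of lane-like
#' columns. Each profile is the row-wise mean across the lane's columns,
#' ordered left to right.
#'
#' @param image a [GelImage-class].
#' @param nLanes expected number of lanes, or `"auto"`; a mismatch with
#'   the detected structure is an error reporting the detected count.
#' @return list of [GelLane-class] profiles.
#' @export
extractLaneProfiles <- function(image, nLanes = "auto") {
    stopifnot(is(image, "GelImage"))
    px <- image@pixels
    bounds <- image@laneBoundaries
    if (!length(bounds)) {
        cm <- colMeans(px)
        if (diff(range(cm)) < 1e-8) {
            bounds <- list(c(1L, ncol(px)))  # featureless: one lane
        } else {
            km <- stats::kmeans(cm, centers = range(cm))
            laneCluster <- which.max(km$centers)
            r <- rle(km$cluster == laneCluster)
            ends <- cumsum(r$lengths)
            starts <- ends - r$lengths + 1L
            keep <- r$values & r$lengths >= 3L
            bounds <- Map(c, starts[keep], ends[keep])
        }
    }
    if (!identical(nLanes, "auto") && length(bounds) != nLanes)
        stop("requested ", nLanes, " lanes but the image contains ",
             length(bounds), " detectable lane(s)")
    lapply(seq_along(bounds), function(i) {
        b <- bounds[[i]]
        gelLane(rowMeans(px[, b[1]:b[2], drop = FALSE]),
                laneId = sprintf("lane%02d", i))
    })
}

#' Write or read a lane profile as CSV
#'
#' Two-column CSV (`position`, `signal`), UTF-8, '.' decimal.
#'
#' @param lane a [GelLane-class].
#' @param path CSV file path.
#' @return `writeProfileCsv`: invisibly, `path`; `readProfileCsv`: a
#'   [GelLane-class].
#' @export
writeProfileCsv <- function(lane, path) {
    stopifnot(is(lane, "GelLane"))
    utils::write.csv(data.frame(position = seq_along(lane@signal),
                                signal = lane@signal),
                     path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeProfileCsv
#' @param laneId lane identifier for the profile read.
#' @export
readProfileCsv <- function(path, laneId = NULL) {
    if (!file.exists(path)) stop("profile file not found: ", path)
    d <- utils::read.csv(path)
    stopifnot(all(c("position", "signal") %in% names(d)))
    gelLane(d$signal[order(d$position)],
            laneId = laneId %||% tools::file_path_sans_ext(basename(path)))
}
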