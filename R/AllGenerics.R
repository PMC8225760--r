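#' Number of frames
#' @param x a [Trajectory-class] (or list of frames).
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Number of atoms
#' @param x a [Frame-class] or [Trajectory-class].
#' @return integer atom count.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Frame times
#' @param x a [Trajectory-class].
#' @param unit "ps" or "ns".
#' @return numeric vector of frame times.
#' @export
setGeneric("frameTimes", function(x, unit = c("ps", "ns"))
    standardGeneric("frameTimes"))

#' Extract one frame
#' @param x a [Trajectory-class].
#' @param i frame index.
#' @return a [Frame-class].
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))

#' Atom template table
#' @param x a [Frame-class] or [Trajectory-class].
#' @return data.frame of atom metadata.
#' @export
setGeneric("atomData", function(x) standardGeneric("atomData"))

#' Coordinate access
#' @param x a [Frame-class] or [Trajectory-class].
#' @param ... unused.
#' @return for a Frame an `n x 3` matrix; for a Trajectory the
#'   `n x 3 x n_frames` array.
#' @export
setGeneric("coords", function(x, ...) standardGeneric("coords"))

#' @describeIn nFrames frame count of a Trajectory.
#' @export
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[3])

#' @describeIn nAtoms atom count of a Frame.
#' @export
setMethod("nAtoms", "Frame", function(x) nrow(x@atoms))

#' @describeIn nAtoms atom count of a Trajectory.
#' @export
setMethod("nAtoms", "Trajectory", function(x) nrow(x@atoms))

#' @describeIn frameTimes times of a Trajectory.
#' @export
setMethod("frameTimes", "Trajectory", function(x, unit = c("ps", "ns")) {
    unit <- match.arg(unit)
    if (unit == "ns") x@times_ps / 1000 else x@times_ps
})

#' @describeIn getFrame extract frame `i` as a Frame object.
#' @export
setMethod("getFrame", "Trajectory", function(x, i) {
    i <- as.integer(i)
    stopifnot(i >= 1L, i <= nFrames(x))
    at <- x@atoms
    at$x <- x@coords[, 1L, i]
    at$y <- x@coords[, 2L, i]
    at$z <- x@coords[, 3L, i]
    new("Frame", atoms = at, time_ps = x@times_ps[i])
})

#' @describeIn atomData atom metadata of a Frame.
#' @export
setMethod("atomData", "Frame", function(x)
    x@atoms[, c("name", "resid", "resname", "chain")])

#' @describeIn atomData atom metadata of a Trajectory.
#' @export
setMethod("atomData", "Trajectory", function(x) x@atoms)

#' @describeIn coords coordinates of a Frame as an `n x 3` matrix.
#' @export
setMethod("coords", "Frame", function(x, ...)
    unname(as.matrix(x@atoms[, c("x", "y", "z")])))

#' @describeIn coords coordinate array of a Trajectory.
#' @export
setMethod("coords", "Trajectory", function(x, ...) x@coords)
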