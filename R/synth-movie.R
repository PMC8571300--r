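#' Specification for a synthetic dual-channel TIRF movie
#'
#' @slot dim frame size c(height, width) in pixels.
#' @slot psfSigma Gaussian point-spread s.d. in pixels (> 0).
#' @slot spots n x 2 matrix of donor-channel spot centres (x, y), 0-based
#'   pixel coordinates, all inside the frame.
#' @slot amplitude peak amplitude per spot (recycled).
#' @slot transform named numeric c(dx, dy, rotation): the donor-to-acceptor
#'   channel mapping (rotation about the frame centre, radians).
#' @slot background uniform background level.
#' @slot nFrames number of frames.
#' @slot poissonNoise apply Poisson noise to each pixel.
#' @export
setClass("MovieSpec",
         representation(dim = "integer", psfSigma = "numeric",
                        spots = "matrix", amplitude = "numeric",
                        transform = "numeric", background = "numeric",
                        nFrames = "integer", poissonNoise = "logical"))

setValidity("MovieSpec", function(object) {
  if (object@psfSigma <= 0) return("psfSigma must be > 0")
  if (nrow(object@spots) > 0) {
    if (any(object@spots[, 1] < 0 | object@spots[, 1] > object@dim[2] - 1) ||
        any(object@spots[, 2] < 0 | object@spots[, 2] > object@dim[1] - 1))
      return("spot positions must lie inside the frame")
  }
  TRUE
})

#' @rdname MovieSpec-class
#' @param dim,psfSigma,spots,amplitude,transform,background,nFrames,poissonNoise
#'   see the class slots.
#' @export
movieSpec <- function(dim = c(64L, 64L), psfSigma = 1.2,
                      spots = matrix(numeric(0), 0, 2), amplitude = 500,
                      transform = c(dx = 0, dy = 0, rotation = 0),
                      background = 10, nFrames = 1L, poissonNoise = TRUE) {
  new("MovieSpec", dim = as.integer(dim), psfSigma = psfSigma,
      spots = spots, amplitude = amplitude, transform = transform,
      background = background, nFrames = as.integer(nFrames),
      poissonNoise = poissonNoise)
}

#' Map donor-channel coordinates into the acceptor channel
#'
#' @param spots n x 2 matrix (x, y), 0-based pixels.
#' @param transform named numeric c(dx, dy, rotation); rotation is about
#'   the frame centre.
#' @param dim frame size c(height, width), needed when rotation != 0.
#' @return transformed n x 2 matrix.
#' @export
applyChannelTransform <- function(spots, transform, dim = NULL) {
  rot <- if ("rotation" %in% names(transform)) transform[["rotation"]] else 0
  xy <- spots
  if (rot != 0) {
    if (is.null(dim)) stop("dim is required when rotation != 0")
    cx <- (dim[2] - 1) / 2; cy <- (dim[1] - 1) / 2
    x <- spots[, 1] - cx; y <- spots[, 2] - cy
    xy <- cbind(cx + cos(rot) * x - sin(rot) * y,
                cy + sin(rot) * x + cos(rot) * y)
  }
  cbind(xy[, 1] + transform[["dx"]], xy[, 2] + transform[["dy"]])
}

#' Simulate a dual-channel TIRF image stack
#'
#' Each spot is rendered as a symmetric 2D Gaussian (pixel sum about
#' 2 pi sigma^2 A) on a uniform background, with optional Poisson noise.
#' Acceptor-channel spot positions are the donor positions mapped through
#' the stored channel transform; the ground truth is returned alongside.
#'
#' @param spec a \linkS4class{MovieSpec}.
#' @param seed optional integer seed.
#' @return list with \code{donor} and \code{acceptor} arrays
#'   (height x width x nFrames), \code{spec}, and \code{truth} (donor and
#'   acceptor spot positions).
#' @export
simulateMovie <- function(spec, seed = NULL) {
  validObject(spec)
  if (!is.null(seed)) set.seed(seed)
  h <- spec@dim[1]; w <- spec@dim[2]
  accSpots <- if (nrow(spec@spots))
    applyChannelTransform(spec@spots, spec@transform, spec@dim)
  else spec@spots
  amp <- rep_len(spec@amplitude, max(1L, nrow(spec@spots)))

  renderFrame <- function(spots) {
    img <- matrix(spec@background, h, w)
    if (nrow(spots)) {
      xg <- matrix(0:(w - 1), h, w, byrow = TRUE)
      yg <- matrix(0:(h - 1), h, w)
      for (i in seq_len(nrow(spots))) {
        img <- img + amp[i] *
          exp(-((xg - spots[i, 1])^2 + (yg - spots[i, 2])^2) /
                (2 * spec@psfSigma^2))
      }
    }
    img
  }
  donorClean <- renderFrame(spec@spots)
  accClean <- renderFrame(accSpots)

  donor <- array(0, c(h, w, spec@nFrames))
  acceptor <- array(0, c(h, w, spec@nFrames))
  for (f in seq_len(spec@nFrames)) {
    donor[, , f] <- if (spec@poissonNoise)
      matrix(stats::rpois(h * w, pmax(donorClean, 0)), h, w) else donorClean
    acceptor[, , f] <- if (spec@poissonNoise)
      matrix(stats::rpois(h * w, pmax(accClean, 0)), h, w) else accClean
  }
  list(donor = donor, acceptor = acceptor, spec = spec,
       truth = list(donorSpots = spec@spots, acceptorSpots = accSpots))
}
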