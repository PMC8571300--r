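## Image-stack front end: spot detection by local maxima + 2D Gaussian
## refinement in a 9x9 window, dual-channel registration by translation
## voting, fixed-position trace extraction and anticorrelation-based trace
## selection.

## Least-squares symmetric 2D Gaussian fit over a square window.
## x0/y0 are 0-based pixel coordinates in the full frame.
fitGaussianWindow <- function(img, cx, cy, halfWidth = 4L,
                              fixPosition = FALSE, sigma0 = 1.5,
                              fixSigma = NA_real_) {
  cx <- unname(cx); cy <- unname(cy)
  h <- nrow(img); w <- ncol(img)
  rows <- (cy + 1L) + (-halfWidth:halfWidth)   # 1-based rows = y + 1
  cols <- (cx + 1L) + (-halfWidth:halfWidth)
  if (min(rows) < 1L || max(rows) > h || min(cols) < 1L || max(cols) > w)
    return(NULL)                               # window clipped by the edge
  z <- img[rows, cols]
  xg <- matrix(cols - 1L, length(rows), length(cols), byrow = TRUE)
  yg <- matrix(rows - 1L, length(rows), length(cols))
  bg0 <- stats::median(c(z[1, ], z[nrow(z), ], z[, 1], z[, ncol(z)]))
  a0 <- max(z) - bg0
  if (a0 <= 0) return(NULL)

  if (fixPosition) {
    par0 <- if (is.na(fixSigma)) c(A = a0, sigma = sigma0, b = bg0)
            else c(A = a0, b = bg0)
    resid <- function(p) {
      s <- if (is.na(fixSigma)) p[["sigma"]] else fixSigma
      as.vector(p[["A"]] * exp(-((xg - cx)^2 + (yg - cy)^2) / (2 * s^2)) +
                  p[["b"]] - z)
    }
  } else {
    par0 <- c(x0 = cx, y0 = cy, A = a0, sigma = sigma0, b = bg0)
    resid <- function(p) {
      as.vector(p[["A"]] *
                  exp(-((xg - p[["x0"]])^2 + (yg - p[["y0"]])^2) /
                        (2 * p[["sigma"]]^2)) + p[["b"]] - z)
    }
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par0, fn = resid,
                       control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit) || fit$info == 0) return(NULL)
  p <- fit$par
  s <- if (fixPosition && !is.na(fixSigma)) fixSigma
       else abs(p[["sigma"]])
  list(x = if (fixPosition) cx else p[["x0"]],
       y = if (fixPosition) cy else p[["y0"]],
       amplitude = p[["A"]], sigma = s, background = p[["b"]],
       residual = sqrt(mean(resid(p)^2)))
}

#' Detect fluorescence spots by 2D Gaussian fitting
#'
#' Local maxima above \code{background + threshold} are refined by a
#' least-squares symmetric 2D Gaussian fit within a 9x9 pixel window
#' centred on the maximum. Fits that fail to converge, drift out of the
#' window, or return a PSF width outside \code{sigmaBounds} are dropped;
#' maxima whose window is clipped by the frame edge are skipped.
#'
#' @param image 2D numeric matrix (one frame).
#' @param threshold intensity above the image median required for a local
#'   maximum to be considered.
#' @param sigmaBounds admissible fitted sigma range in pixels.
#' @param minSeparation minimum distance between accepted maxima (pixels).
#' @return data.frame with columns x, y (0-based sub-pixel positions),
#'   amplitude, sigma, background, residual.
#' @export
detectSpots <- function(image, threshold, sigmaBounds = c(0.5, 4),
                        minSeparation = 4) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  h <- nrow(image); w <- ncol(image)
  med <- stats::median(image)
  empty <- data.frame(x = numeric(0), y = numeric(0), amplitude = numeric(0),
                      sigma = numeric(0), background = numeric(0),
                      residual = numeric(0))
  if (h < 9L || w < 9L) return(empty)

  ## 8-neighbourhood local maxima on the interior
  cand <- which(image > med + threshold, arr.ind = TRUE)
  cand <- cand[cand[, 1] > 1 & cand[, 1] < h & cand[, 2] > 1 & cand[, 2] < w,
               , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  isMax <- apply(cand, 1, function(rc) {
    nb <- image[(rc[1] - 1):(rc[1] + 1), (rc[2] - 1):(rc[2] + 1)]
    image[rc[1], rc[2]] >= max(nb)
  })
  cand <- cand[isMax, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)

  ## suppress secondary maxima closer than minSeparation, keep the brighter
  ord <- order(image[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) {
      j <- (i + 1):nrow(cand)
      d2 <- (cand[j, 1] - cand[i, 1])^2 + (cand[j, 2] - cand[i, 2])^2
      keep[j[d2 < minSeparation^2]] <- FALSE
    }
  }
  cand <- cand[keep, , drop = FALSE]

  out <- lapply(seq_len(nrow(cand)), function(i) {
    cy <- cand[i, 1] - 1L; cx <- cand[i, 2] - 1L
    f <- fitGaussianWindow(image, cx, cy)
    if (is.null(f)) return(NULL)
    if (f$sigma < sigmaBounds[1] || f$sigma > sigmaBounds[2]) return(NULL)
    if (abs(f$x - cx) > 4 || abs(f$y - cy) > 4) return(NULL)
    as.data.frame(f[c("x", "y", "amplitude", "sigma", "background",
                      "residual")])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else out
}

#' Register donor and acceptor channels by translation voting
#'
#' Every donor-acceptor spot pair implies a candidate translation; votes
#' are accumulated on a 2D grid (bin width \code{binWidth}), the modal bin
#' taken, and the translation refined by least squares over the inlier
#' pairs. Each spot enters at most one matched pair.
#'
#' @param donorSpots,acceptorSpots data.frames with x, y columns (as from
#'   \code{\link{detectSpots}}).
#' @param maxOffset largest translation magnitude considered (pixels).
#' @param binWidth vote-accumulator bin width (pixels).
#' @param minVotes minimum votes in the modal bin; below this registration
#'   fails.
#' @param tol inlier radius around the refined translation (pixels).
#' @return a \linkS4class{ChannelTransform}.
#' @export
registerChannels <- function(donorSpots, acceptorSpots, maxOffset = 10,
                             binWidth = 0.5, minVotes = 3L, tol = 1) {
  nd <- nrow(donorSpots); na <- nrow(acceptorSpots)
  if (nd == 0L || na == 0L) stop("registration failed: empty spot list")
  dx <- outer(acceptorSpots$x, donorSpots$x, "-")
  dy <- outer(acceptorSpots$y, donorSpots$y, "-")
  ok <- abs(dx) <= maxOffset & abs(dy) <= maxOffset
  if (!any(ok)) stop("registration failed: no candidate translation")
  bx <- floor(dx[ok] / binWidth); by <- floor(dy[ok] / binWidth)
  key <- paste(bx, by)
  tab <- table(key)
  if (max(tab) < minVotes)
    stop("registration failed: no translation bin reaches ", minVotes,
         " votes")
  mode <- names(tab)[which.max(tab)]
  mb <- as.numeric(strsplit(mode, " ")[[1]])
  cx <- (mb[1] + 0.5) * binWidth; cy <- (mb[2] + 0.5) * binWidth

  ## inliers around the modal translation, refined by least squares (the
  ## LS solution for a pure translation is the mean inlier offset)
  for (iter in 1:3) {
    inl <- which(sqrt((dx - cx)^2 + (dy - cy)^2) <= max(tol, binWidth),
                 arr.ind = TRUE)
    if (nrow(inl) == 0L) break
    cx <- mean(dx[inl]); cy <- mean(dy[inl])
  }
  inl <- which(sqrt((dx - cx)^2 + (dy - cy)^2) <= tol, arr.ind = TRUE)
  if (nrow(inl) == 0L) stop("registration failed: no inlier pairs")

  ## greedy one-to-one matching by residual
  res <- sqrt((dx[inl] - cx)^2 + (dy[inl] - cy)^2)
  ord <- order(res)
  usedA <- logical(na); usedD <- logical(nd)
  pairs <- matrix(0L, 0L, 2L, dimnames = list(NULL, c("donor", "acceptor")))
  for (i in ord) {
    ai <- inl[i, 1]; di <- inl[i, 2]
    if (usedA[ai] || usedD[di]) next
    usedA[ai] <- TRUE; usedD[di] <- TRUE
    pairs <- rbind(pairs, c(di, ai))
  }
  new("ChannelTransform", dx = cx, dy = cy, rotation = 0,
      pairs = pairs, score = max(tab) / sum(ok))
}

#' Extract a fluorescence trace at a fixed spot position
#'
#' Refits a 2D Gaussian at the (fixed) spot position on every frame; the
#' background-subtracted volume of the fitted peak,
#' 2 pi * amplitude * sigma^2, is the raw intensity. Frames where the fit
#' diverges fall back to the background-subtracted windowed sum (flagged).
#'
#' @param stack height x width x nFrames array (one channel).
#' @param x,y 0-based spot position (rounded to the nearest pixel for the
#'   window centre; sub-pixel structure is absorbed by the fit).
#' @param refitShape refit sigma per frame (default); if FALSE, sigma is
#'   frozen at \code{sigma0}.
#' @param sigma0 initial (or frozen) PSF sigma in pixels.
#' @return list with \code{intensity} (per-frame), \code{fallback}
#'   (logical per frame: TRUE where the windowed-sum fallback was used).
#' @export
extractTrace <- function(stack, x, y, refitShape = TRUE, sigma0 = 1.5) {
  stopifnot(length(dim(stack)) == 3L)
  nF <- dim(stack)[3]
  cx <- as.integer(round(x)); cy <- as.integer(round(y))
  intensity <- numeric(nF); fallback <- logical(nF)
  for (f in seq_len(nF)) {
    img <- stack[, , f]
    fit <- fitGaussianWindow(img, cx, cy, fixPosition = TRUE,
                             sigma0 = sigma0,
                             fixSigma = if (refitShape) NA_real_ else sigma0)
    if (!is.null(fit) && fit$amplitude > 0) {
      intensity[f] <- 2 * pi * fit$amplitude * fit$sigma^2
    } else {
      rows <- (cy + 1L) + (-4:4); cols <- (cx + 1L) + (-4:4)
      rows <- rows[rows >= 1 & rows <= nrow(img)]
      cols <- cols[cols >= 1 & cols <= ncol(img)]
      z <- img[rows, cols]
      bg <- stats::median(c(z[1, ], z[nrow(z), ], z[, 1], z[, ncol(z)]))
      intensity[f] <- sum(z - bg)
      fallback[f] <- TRUE
    }
  }
  list(intensity = intensity, fallback = fallback)
}

#' Extract a donor/acceptor trace pair from a registered movie
#'
#' @param movie list with \code{donor} and \code{acceptor} stacks (as from
#'   \code{\link{simulateMovie}} or \code{\link{readMovieTiff}}).
#' @param donorXY donor-channel position c(x, y), 0-based.
#' @param transform a \linkS4class{ChannelTransform} mapping donor to
#'   acceptor coordinates.
#' @param frameInterval seconds per frame (default 0.025).
#' @param id trace identifier.
#' @inheritParams extractTrace
#' @return a \linkS4class{FretTrace}.
#' @export
extractTracePair <- function(movie, donorXY, transform,
                             frameInterval = 0.025, refitShape = TRUE,
                             sigma0 = 1.5, id = "trace") {
  d <- extractTrace(movie$donor, donorXY[1], donorXY[2],
                    refitShape = refitShape, sigma0 = sigma0)
  a <- extractTrace(movie$acceptor, donorXY[1] + transform@dx,
                    donorXY[2] + transform@dy,
                    refitShape = refitShape, sigma0 = sigma0)
  n <- length(d$intensity)
  new("FretTrace", time = (seq_len(n) - 0.5) * frameInterval,
      donor = d$intensity, acceptor = a$intensity,
      frameInterval = frameInterval, truthState = integer(0),
      truthBleach = c(donor = Inf, acceptor = Inf), id = id)
}

#' Select analyzable FRET traces
#'
#' Accepts traces that (a) carry signal in both channels, (b) show
#' donor-acceptor anticorrelation over the pre-bleach segment (Pearson r at
#' or below \code{anticorrThreshold}), and (c) at most a single bleach
#' step. Selection is deterministic given the criteria.
#'
#' @param traces list of \linkS4class{FretTrace}.
#' @param minSignal minimum mean pre-bleach intensity per channel, as a
#'   fraction of the brighter channel's mean (absolute floor of 10 counts).
#' @param anticorrThreshold Pearson correlation threshold (default -0.3).
#' @return list with \code{accepted} (traces) and \code{rejected}
#'   (data.frame id, reason).
#' @export
selectTraces <- function(traces, minSignal = 0.1, anticorrThreshold = -0.3) {
  stopifnot(length(traces) > 0L)
  accepted <- list()
  rejected <- data.frame(id = character(0), reason = character(0))
  for (tr in traces) {
    nb <- detectBleach(tr)
    end <- if (is.na(nb)) length(tr@time) else nb - 1L
    reason <- NULL
    if (end < 10L) {
      reason <- "too short before bleach"
    } else {
      d <- tr@donor[seq_len(end)]; a <- tr@acceptor[seq_len(end)]
      floorSig <- max(10, minSignal * max(mean(d), mean(a)))
      if (mean(a) < floorSig) reason <- "no acceptor"
      else if (mean(d) < floorSig) reason <- "no donor"
      else if (stats::sd(d) == 0 || stats::sd(a) == 0 ||
               stats::cor(d, a) > anticorrThreshold)
        reason <- "no anticorrelation"
    }
    if (is.null(reason)) accepted <- c(accepted, tr)
    else rejected <- rbind(rejected,
                           data.frame(id = tr@id, reason = reason))
  }
  list(accepted = accepted, rejected = rejected)
}

setMethod("show", "ChannelTransform", function(object) {
  cat(sprintf(
    "ChannelTransform: dx = %.3f px, dy = %.3f px, %d matched pairs (score %.2f)\n",
    object@dx, object@dy, nrow(object@pairs), object@score))
})
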