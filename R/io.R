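## Plain-text interchange: trace TSV (frame, time_s, I_donor, I_acceptor,
## truth_state), 3-column whitespace .dat scattering curves, multi-page
## TIFF movies, and JSON sidecars recording generator parameters and seed.

#' Write a FRET trace to TSV
#'
#' Columns: frame, time_s, I_donor, I_acceptor and (when ground truth is
#' available) truth_state. A JSON sidecar (same path + ".json") records
#' the frame interval and any extra metadata such as generator parameters
#' and seed.
#'
#' @param trace a \linkS4class{FretTrace}.
#' @param path output TSV path.
#' @param meta named list merged into the sidecar.
#' @return \code{path}, invisibly.
#' @export
writeTraceTsv <- function(trace, path, meta = list()) {
  df <- data.frame(frame = seq_along(trace@time), time_s = trace@time,
                   I_donor = trace@donor, I_acceptor = trace@acceptor)
  if (length(trace@truthState)) df$truth_state <- STATE_LABELS[trace@truthState]
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  sidecar <- c(list(id = trace@id, frame_interval_s = trace@frameInterval),
               meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a FRET trace from TSV
#'
#' @param path TSV written by \code{\link{writeTraceTsv}}, or any table
#'   with time_s, I_donor, I_acceptor columns.
#' @param frameInterval frame interval; if NULL, taken from the sidecar or
#'   inferred from the time column.
#' @return a \linkS4class{FretTrace}.
#' @export
readTraceTsv <- function(path, frameInterval = NULL) {
  df <- utils::read.delim(path)
  stopifnot(all(c("time_s", "I_donor", "I_acceptor") %in% names(df)))
  id <- basename(path)
  if (is.null(frameInterval)) {
    sc <- paste0(path, ".json")
    if (file.exists(sc)) {
      meta <- jsonlite::read_json(sc)
      frameInterval <- meta$frame_interval_s
      if (!is.null(meta$id)) id <- meta$id
    } else {
      frameInterval <- stats::median(diff(df$time_s))
    }
  }
  truth <- if ("truth_state" %in% names(df))
    match(df$truth_state, STATE_LABELS) else integer(0)
  new("FretTrace", time = df$time_s, donor = df$I_donor,
      acceptor = df$I_acceptor, frameInterval = frameInterval,
      truthState = as.integer(truth),
      truthBleach = c(donor = Inf, acceptor = Inf), id = id)
}

#' Write / read a scattering curve as 3-column whitespace .dat
#'
#' @param curve a \linkS4class{ScatteringCurve}.
#' @param path .dat path (columns q, I, sigma).
#' @return the path (write) or a \linkS4class{ScatteringCurve} (read).
#' @export
writeScatteringDat <- function(curve, path) {
  sig <- if (length(curve@sigma)) curve@sigma else rep(0, length(curve@q))
  utils::write.table(data.frame(curve@q, curve@I, sig), path,
                     sep = " ", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeScatteringDat
#' @export
readScatteringDat <- function(path) {
  df <- utils::read.table(path, col.names = c("q", "I", "sigma"))
  scatteringCurve(df$q, df$I, df$sigma)
}

#' Write / read a dual-channel movie as multi-page TIFF
#'
#' Pages alternate donor, acceptor per frame. Requires the tiff package.
#'
#' @param movie list with donor and acceptor stacks.
#' @param path TIFF path.
#' @param scale intensities are divided by this before writing (TIFF
#'   stores [0, 1]).
#' @return the path (write) or a movie list (read).
#' @export
writeMovieTiff <- function(movie, path, scale = 65535) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the tiff package is required to write TIFF movies")
  nF <- dim(movie$donor)[3]
  pages <- vector("list", 2L * nF)
  for (f in seq_len(nF)) {
    pages[[2L * f - 1L]] <- movie$donor[, , f] / scale
    pages[[2L * f]] <- movie$acceptor[, , f] / scale
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname writeMovieTiff
#' @export
readMovieTiff <- function(path, scale = 65535) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the tiff package is required to read TIFF movies")
  pages <- tiff::readTIFF(path, all = TRUE)
  nF <- length(pages) %/% 2L
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  donor <- array(0, c(h, w, nF)); acceptor <- array(0, c(h, w, nF))
  for (f in seq_len(nF)) {
    donor[, , f] <- pages[[2L * f - 1L]] * scale
    acceptor[, , f] <- pages[[2L * f]] * scale
  }
  list(donor = donor, acceptor = acceptor)
}

#' C1'-C1' distance between two residues of an RNA structure
#'
#' Distance between the C1' atoms of two residues in a PDB file, e.g. the
#' L3 labeling-site residue and the 3'-terminal residue of an xrRNA
#' crystal structure. Requires the bio3d package.
#'
#' @param pdbFile path to a PDB file.
#' @param resno1,resno2 residue numbers.
#' @param chain optional chain identifier applied to both residues.
#' @return distance in Angstrom.
#' @export
labelSiteDistance <- function(pdbFile, resno1, resno2, chain = NULL) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("the bio3d package is required to read PDB files")
  pdb <- bio3d::read.pdb(pdbFile)
  pick <- function(resno) {
    sel <- bio3d::atom.select(pdb, resno = resno, elety = "C1'",
                              chain = chain, verbose = FALSE)
    if (length(sel$xyz) != 3L)
      stop("residue ", resno, " does not yield a unique C1' atom")
    pdb$xyz[sel$xyz]
  }
  sqrt(sum((pick(resno1) - pick(resno2))^2))
}
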