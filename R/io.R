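## Plain-text file formats: whitespace-delimited columns with '#' header
## lines. Field axes are stored in mT offsets from the sweep centre.

.writeHeader <- function(con, fields) {
  for (nm in names(fields))
    writeLines(sprintf("# %s %s", nm,
                       paste(format(fields[[nm]], digits = 17),
                             collapse = " ")), con)
}

.readHeader <- function(path) {
  lines <- readLines(path, n = 64)
  hdr <- grep("^#", lines, value = TRUE)
  out <- list()
  for (h in hdr) {
    toks <- strsplit(sub("^#\\s*", "", h), "\\s+")[[1]]
    if (length(toks) >= 2)
      out[[toks[1]]] <- toks[-1]
  }
  out
}

#' Read and write orientational trajectories
#'
#' Columnar text with header records (`delta_ps`, `n_frames`, optional
#' `seed`) and columns `time_ps qw qx qy qz`. The round trip is lossless to
#' the stored precision.
#'
#' @param traj An [OrientationTrajectory-class].
#' @param path File path.
#' @param seed Optional integer recorded in the header for provenance.
#' @return `readTrajectory` returns an [OrientationTrajectory-class];
#'   `writeTrajectory` returns `path` invisibly.
#' @export
writeTrajectory <- function(traj, path, seed = NULL) {
  stopifnot(is(traj, "OrientationTrajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- list(format = "spinESR-trajectory-1",
              delta_ps = trajectoryDelta(traj),
              n_frames = nFrames(traj))
  if (!is.null(seed)) hdr$seed <- as.integer(seed)
  .writeHeader(con, hdr)
  writeLines("# time_ps qw qx qy qz", con)
  q <- trajectoryQuaternions(traj)
  t <- (seq_len(nrow(q)) - 1) * trajectoryDelta(traj)
  utils::write.table(data.frame(t, q), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTrajectory
#' @export
readTrajectory <- function(path) {
  hdr <- .readHeader(path)
  if (is.null(hdr$delta_ps)) stop("missing 'delta_ps' header in ", path)
  dat <- utils::read.table(path, comment.char = "#")
  if (ncol(dat) != 5) stop("trajectory file must have 5 columns, found ",
                           ncol(dat), " in ", path)
  orientationTrajectory(as.matrix(dat[, 2:5]),
                        deltaPs = as.numeric(hdr$delta_ps[1]),
                        normalize = TRUE)
}

#' Read and write spectra
#'
#' Two-column text (`field_mT intensity`) with a header carrying the mode
#' and acquisition metadata.
#'
#' @param spectrum An [EsrSpectrum-class].
#' @param path File path.
#' @return `readSpectrum` returns an [EsrSpectrum-class].
#' @export
writeSpectrum <- function(spectrum, path) {
  stopifnot(is(spectrum, "EsrSpectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(list(format = "spinESR-spectrum-1", mode = spectrum@mode),
           spectrum@meta[vapply(spectrum@meta, is.numeric, logical(1))])
  .writeHeader(con, hdr)
  writeLines("# field_mT intensity", con)
  utils::write.table(data.frame(spectrum@fieldMt, spectrum@intensity), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSpectrum
#' @export
readSpectrum <- function(path) {
  hdr <- .readHeader(path)
  dat <- utils::read.table(path, comment.char = "#")
  if (ncol(dat) != 2) stop("spectrum file must have 2 columns in ", path)
  mode <- if (!is.null(hdr$mode)) hdr$mode[1] else "first_derivative"
  meta <- hdr[setdiff(names(hdr), c("format", "mode"))]
  meta <- lapply(meta, function(v) suppressWarnings(as.numeric(v)))
  esrSpectrum(dat[, 1], dat[, 2], mode = mode, meta = meta)
}

#' Read and write FIDs
#'
#' Three-column text: `time_ps re im`.
#'
#' @param fid A [Fid-class].
#' @param path File path.
#' @return `readFid` returns a [Fid-class].
#' @export
writeFid <- function(fid, path) {
  stopifnot(is(fid, "Fid"))
  con <- file(path, "w")
  on.exit(close(con))
  .writeHeader(con, list(format = "spinESR-fid-1", carrier = fid@carrier))
  writeLines("# time_ps re im", con)
  utils::write.table(data.frame(fid@timesPs, Re(fid@values),
                                Im(fid@values)), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFid
#' @export
readFid <- function(path) {
  hdr <- .readHeader(path)
  dat <- utils::read.table(path, comment.char = "#")
  new("Fid", timesPs = dat[, 1],
      values = complex(real = dat[, 2], imaginary = dat[, 3]),
      carrier = if (!is.null(hdr$carrier))
        paste(hdr$carrier, collapse = " ") else "rotating frame")
}

#' Read a spin-system configuration file
#'
#' Key-value text format, e.g.
#' \preformatted{
#' nuclear_spin 1
#' g_principal 2.0083 2.0061 2.0022
#' a_principal 17.4 17.4 98.0
#' a_unit MHz
#' mw_frequency_ghz 9.45
#' }
#'
#' @param path File path.
#' @return List with elements `spec` ([SpinSystem-class]) and `field`
#'   ([FieldConfig-class]).
#' @export
readSpinConfig <- function(path) {
  lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
  kv <- list()
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(toks) < 2)
      stop("malformed line ", i, " in ", path, ": '", lines[i], "'")
    kv[[toks[1]]] <- toks[-1]
  }
  need <- c("nuclear_spin", "g_principal", "a_principal")
  miss <- setdiff(need, names(kv))
  if (length(miss))
    stop("spin config ", path, " is missing field(s): ",
         paste(miss, collapse = ", "))
  spec <- spinSystem(
    nuclearSpin = as.numeric(kv$nuclear_spin[1]),
    gPrincipal = as.numeric(kv$g_principal),
    aPrincipal = as.numeric(kv$a_principal),
    aUnit = if (!is.null(kv$a_unit)) kv$a_unit[1] else "MHz")
  field <- if (!is.null(kv$field_t))
    fieldConfig(B0 = as.numeric(kv$field_t[1]),
                mwFrequency = if (!is.null(kv$mw_frequency_ghz))
                  as.numeric(kv$mw_frequency_ghz[1]) else 9.45,
                gIso = gIso(spec))
  else
    fieldConfig(mwFrequency = if (!is.null(kv$mw_frequency_ghz))
      as.numeric(kv$mw_frequency_ghz[1]) else 9.45, gIso = gIso(spec))
  list(spec = spec, field = field)
}

#' Read a multi-frame XYZ coordinate file
#'
#' @param path File path of a concatenated-frames XYZ file.
#' @return List with `elements` (character vector) and `coords`
#'   (`nFrames x nAtoms x 3` array, Angstrom).
#' @export
readXyzFrames <- function(path) {
  lines <- readLines(path)
  nAtoms <- as.integer(lines[1])
  per <- nAtoms + 2L
  nFramesF <- length(lines) %/% per
  if (nFramesF < 1) stop("no complete frames in ", path)
  coords <- array(NA_real_, c(nFramesF, nAtoms, 3))
  elements <- character(nAtoms)
  for (f in seq_len(nFramesF)) {
    block <- lines[((f - 1) * per + 3):((f - 1) * per + 2 + nAtoms)]
    toks <- strsplit(trimws(block), "\\s+")
    for (a in seq_len(nAtoms)) {
      if (f == 1) elements[a] <- toks[[a]][1]
      coords[f, a, ] <- as.numeric(toks[[a]][2:4])
    }
  }
  list(elements = elements, coords = coords)
}

#' Read a multi-model PDB into a coordinate array
#'
#' Uses `bio3d` for parsing; atoms are selected by name in the order given.
#'
#' @param path PDB file with MODEL records.
#' @param atomNames Character vector of atom names to extract, in order.
#' @return `nFrames x length(atomNames) x 3` array.
#' @export
readPdbFrames <- function(path, atomNames) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("reading PDB files requires the 'bio3d' package")
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  xyz <- pdb$xyz
  sel <- match(atomNames, pdb$atom$elety)
  if (anyNA(sel))
    stop("atom(s) not found in ", path, ": ",
         paste(atomNames[is.na(sel)], collapse = ", "))
  nf <- nrow(xyz)
  out <- array(NA_real_, c(nf, length(sel), 3))
  for (k in seq_along(sel)) {
    idx <- (sel[k] - 1) * 3 + 1:3
    out[, k, ] <- xyz[, idx, drop = FALSE]
  }
  out
}
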