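## ASCII OFF and PLY mesh file support. One mesh per structure per subject;
## file indices are 0-based (both formats' native convention), in-memory
## indices are 1-based.

.stripComments <- function(lines) {
  sub("\\s*#.*$", "", lines)
}

.parseNumbers <- function(line, lineNo, path, n = NULL) {
  toks <- strsplit(trimws(line), "\\s+")[[1]]
  vals <- suppressWarnings(as.numeric(toks))
  if (length(vals) == 0 || any(is.na(vals)))
    stop(sprintf("parse error in '%s' at line %d: expected numbers, got '%s'",
                 path, lineNo, line), call. = FALSE)
  if (!is.null(n) && length(vals) < n)
    stop(sprintf("parse error in '%s' at line %d: expected %d values",
                 path, lineNo, n), call. = FALSE)
  vals
}

.readOff <- function(path, structureTag) {
  raw <- readLines(path, warn = FALSE)
  lines <- .stripComments(raw)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) < 2L)
    stop(sprintf("parse error in '%s' at line 1: empty OFF file", path),
         call. = FALSE)
  hdr <- trimws(lines[keep[1L]])
  cursor <- 2L
  if (toupper(hdr) == "OFF") {
    counts <- .parseNumbers(lines[keep[2L]], keep[2L], path, 3)
    cursor <- 3L
  } else if (toupper(substr(hdr, 1, 3)) == "OFF") {
    # counts on the header line
    counts <- .parseNumbers(substr(hdr, 4, nchar(hdr)), keep[1L], path, 3)
  } else {
    stop(sprintf("parse error in '%s' at line %d: missing OFF header",
                 path, keep[1L]), call. = FALSE)
  }
  nV <- as.integer(counts[1]); nF <- as.integer(counts[2])
  need <- nV + nF
  body <- keep[seq(cursor, length.out = need)]
  if (length(keep) < cursor - 1L + need || anyNA(body))
    stop(sprintf("parse error in '%s': header promises %d vertices + %d faces but file ends early",
                 path, nV, nF), call. = FALSE)
  V <- matrix(0, nV, 3)
  for (i in seq_len(nV))
    V[i, ] <- .parseNumbers(lines[body[i]], body[i], path, 3)[1:3]
  Tm <- matrix(0L, nF, 3)
  for (i in seq_len(nF)) {
    ln <- body[nV + i]
    f <- .parseNumbers(lines[ln], ln, path, 4)
    if (f[1] != 3)
      stop(sprintf("parse error in '%s' at line %d: only triangular faces supported",
                   path, ln), call. = FALSE)
    Tm[i, ] <- as.integer(f[2:4]) + 1L
  }
  list(V = V, T = Tm)
}

.readPly <- function(path, structureTag) {
  raw <- readLines(path, warn = FALSE)
  if (length(raw) < 3L || trimws(raw[1]) != "ply")
    stop(sprintf("parse error in '%s' at line 1: missing 'ply' magic", path),
         call. = FALSE)
  endHdr <- which(trimws(raw) == "end_header")[1]
  if (is.na(endHdr))
    stop(sprintf("parse error in '%s': no end_header", path), call. = FALSE)
  hdr <- trimws(raw[2:(endHdr - 1L)])
  fmt <- grep("^format", hdr, value = TRUE)
  if (!length(fmt) || !grepl("ascii", fmt[1]))
    stop(sprintf("parse error in '%s' at line %d: only ascii PLY is supported",
                 path, 1L + grep("^format", hdr)[1]), call. = FALSE)
  nV <- nF <- NA_integer_
  vertProps <- character(0)
  current <- ""
  for (h in hdr) {
    toks <- strsplit(h, "\\s+")[[1]]
    if (toks[1] == "element") {
      current <- toks[2]
      if (current == "vertex") nV <- as.integer(toks[3])
      if (current == "face") nF <- as.integer(toks[3])
    } else if (toks[1] == "property" && current == "vertex" &&
               toks[2] != "list") {
      vertProps <- c(vertProps, toks[3])
    }
  }
  if (is.na(nV) || is.na(nF))
    stop(sprintf("parse error in '%s': vertex/face element counts missing", path),
         call. = FALSE)
  xyz <- match(c("x", "y", "z"), vertProps)
  if (anyNA(xyz))
    stop(sprintf("parse error in '%s': vertex element lacks x/y/z properties", path),
         call. = FALSE)
  body <- raw[(endHdr + 1L):length(raw)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < nV + nF)
    stop(sprintf("parse error in '%s': body shorter than promised %d + %d lines",
                 path, nV, nF), call. = FALSE)
  V <- matrix(0, nV, 3)
  for (i in seq_len(nV)) {
    vals <- .parseNumbers(body[i], endHdr + i, path, length(vertProps))
    V[i, ] <- vals[xyz]
  }
  Tm <- matrix(0L, nF, 3)
  for (i in seq_len(nF)) {
    ln <- endHdr + nV + i
    f <- .parseNumbers(body[nV + i], ln, path, 4)
    if (f[1] != 3)
      stop(sprintf("parse error in '%s' at line %d: only triangular faces supported",
                   path, ln), call. = FALSE)
    Tm[i, ] <- as.integer(f[2:4]) + 1L
  }
  list(V = V, T = Tm)
}

.guessFormat <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("off", "ply")) ext else
    stop("cannot guess mesh format from extension '", ext,
         "'; pass format = \"off\" or \"ply\"", call. = FALSE)
}

#' Read a triangulated surface mesh from an OFF or ASCII PLY file
#'
#' The parsed mesh is validated as a closed, consistently oriented
#' triangulated 2-manifold; malformed files raise a parse error naming the
#' offending line, non-manifold connectivity a validation error.
#'
#' @param path file to read.
#' @param format "off", "ply" or "auto" (by extension).
#' @param structureTag tag to attach to the mesh (default "synthetic").
#' @return A \linkS4class{SurfaceMesh}.
#' @seealso \code{\link{writeMesh}}
#' @export
readMesh <- function(path, format = c("auto", "off", "ply"),
                     structureTag = "synthetic") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") format <- .guessFormat(path)
  parsed <- switch(format,
                   off = .readOff(path, structureTag),
                   ply = .readPly(path, structureTag))
  surfaceMesh(parsed$V, parsed$T, structureTag = structureTag)
}

#' Write a surface mesh to an OFF or ASCII PLY file
#'
#' Coordinates are serialized with 10 significant digits so that a
#' read/write round trip preserves vertex order bit-identically at that
#' precision. The OFF edge-count header field is written as 0 (the common
#' dialect); vertex indices are emitted 0-based as both formats expect.
#'
#' @param mesh A \linkS4class{SurfaceMesh}.
#' @param path output file.
#' @param format "off", "ply" or "auto" (by extension).
#' @return Invisibly, the path.
#' @export
writeMesh <- function(mesh, path, format = c("auto", "off", "ply")) {
  stopifnot(is(mesh, "SurfaceMesh"))
  if (nrow(mesh@vertices) == 0 || nrow(mesh@triangles) == 0)
    stop("refusing to write an empty mesh", call. = FALSE)
  format <- match.arg(format)
  if (format == "auto") format <- .guessFormat(path)
  V <- mesh@vertices
  Tm <- mesh@triangles - 1L
  vlines <- sprintf("%.10g %.10g %.10g", V[, 1], V[, 2], V[, 3])
  flines <- sprintf("3 %d %d %d", Tm[, 1], Tm[, 2], Tm[, 3])
  txt <- if (format == "off") {
    c("OFF", sprintf("%d %d 0", nrow(V), nrow(Tm)), vlines, flines)
  } else {
    c("ply", "format ascii 1.0",
      sprintf("comment structure %s", mesh@structureTag),
      sprintf("element vertex %d", nrow(V)),
      "property float x", "property float y", "property float z",
      sprintf("element face %d", nrow(Tm)),
      "property list uchar int vertex_indices",
      "end_header", vlines, flines)
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(txt, con)
  invisible(path)
}

#' Write a pairwise distance matrix as CSV
#'
#' Header row and first column carry the subject ids, so the file
#' round-trips through \code{\link{readDistanceMatrix}}.
#'
#' @param D A \linkS4class{ShapeDistanceMatrix}.
#' @param path output CSV file.
#' @return Invisibly, the path.
#' @export
writeDistanceMatrix <- function(D, path) {
  stopifnot(is(D, "ShapeDistanceMatrix"))
  df <- data.frame(subject_id = D@subjectIds, D@values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a pairwise distance matrix written by \code{writeDistanceMatrix}
#'
#' @param path CSV file.
#' @return A \linkS4class{ShapeDistanceMatrix}.
#' @export
readDistanceMatrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  ids <- as.character(df[[1]])
  v <- as.matrix(df[, -1, drop = FALSE])
  # serialization truncates; re-impose exact symmetry and zero diagonal
  v <- (v + t(v)) / 2
  diag(v) <- 0
  shapeDistanceMatrix(v, ids)
}
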