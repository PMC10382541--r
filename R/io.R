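#' Read a triangulated surface mesh (ASCII OFF or PLY)
#'
#' Minimal readers for the two common ASCII mesh formats. Faces with more
#' than three vertices are fan-triangulated.
#'
#' @param path path to a `.off` or `.ply` file (format sniffed from the
#'   first line, not the extension).
#' @return list with `vertices` (v x 3 numeric matrix) and `faces`
#'   (f x 3 integer matrix, 1-based).
#' @export
readMesh <- function(path) {
  if (!file.exists(path)) stop("mesh file not found: ", path)
  first <- readLines(path, n = 1L)
  if (grepl("^OFF", first)) .readOFF(path)
  else if (grepl("^ply", first)) .readPLY(path)
  else stop("unrecognised mesh format (expected ASCII OFF or PLY)")
}

.meshFromFaces <- function(verts, faceList) {
  tri <- list()
  for (f in faceList) {
    k <- length(f)
    if (k < 3) next
    for (t in seq_len(k - 2)) tri[[length(tri) + 1L]] <- f[c(1, t + 1, t + 2)]
  }
  if (!length(tri)) stop("mesh contains no triangle")
  list(vertices = verts, faces = do.call(rbind, tri))
}

.readOFF <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (toks[1] != "OFF") stop("not an OFF file")
  nv <- as.integer(toks[2]); nf <- as.integer(toks[3])
  pos <- 5L
  verts <- matrix(as.numeric(toks[pos:(pos + 3 * nv - 1)]), nv, 3, byrow = TRUE)
  pos <- pos + 3L * nv
  faces <- vector("list", nf)
  for (i in seq_len(nf)) {
    k <- as.integer(toks[pos]); pos <- pos + 1L
    faces[[i]] <- as.integer(toks[pos:(pos + k - 1)]) + 1L
    pos <- pos + k
  }
  .meshFromFaces(verts, faces)
}

.readPLY <- function(path) {
  lines <- readLines(path)
  endHdr <- which(lines == "end_header")[1]
  if (is.na(endHdr)) stop("malformed PLY header")
  hdr <- lines[seq_len(endHdr)]
  if (!any(grepl("format ascii", hdr))) stop("only ASCII PLY is supported")
  el <- grep("^element ", hdr, value = TRUE)
  counts <- as.integer(sub("^element \\S+ ", "", el))
  names(counts) <- sub("^element (\\S+).*", "\\1", el)
  nv <- counts[["vertex"]]; nf <- counts[["face"]]
  body <- lines[(endHdr + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  vpart <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  verts <- t(vapply(vpart, function(x) as.numeric(x[1:3]), numeric(3)))
  fpart <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  faces <- lapply(fpart, function(x) {
    k <- as.integer(x[1])
    as.integer(x[2:(1 + k)]) + 1L
  })
  .meshFromFaces(verts, faces)
}

#' Read a scalar signal from single-column text or a PCM WAV file
#'
#' WAV input is parsed directly (RIFF container, 8/16/24/32-bit integer or
#' 32-bit float PCM); multi-channel recordings are averaged to one channel
#' and samples are scaled to \[-1, 1\].
#'
#' @param path path to the signal file; WAV detected from the RIFF magic.
#' @return numeric vector of samples.
#' @export
readSignal <- function(path) {
  if (!file.exists(path)) stop("signal file not found: ", path)
  magic <- readBin(path, "raw", n = 4L)
  if (identical(rawToChar(magic), "RIFF")) return(.readWavPCM(path))
  x <- scan(path, what = numeric(), quiet = TRUE, comment.char = "#")
  if (!all(is.finite(x))) stop("signal contains non-finite values")
  x
}

.readWavPCM <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readChar(con, 4)                      # "RIFF"
  readBin(con, "integer", size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file")
  fmt <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || !nzchar(id)) break
    sz <- readBin(con, "integer", size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        audioFormat  = readBin(con, "integer", size = 2, endian = "little", signed = FALSE),
        channels     = readBin(con, "integer", size = 2, endian = "little", signed = FALSE),
        sampleRate   = readBin(con, "integer", size = 4, endian = "little"),
        byteRate     = readBin(con, "integer", size = 4, endian = "little"),
        blockAlign   = readBin(con, "integer", size = 2, endian = "little", signed = FALSE),
        bitsPerSample = readBin(con, "integer", size = 2, endian = "little", signed = FALSE))
      if (sz > 16) readBin(con, "raw", n = sz - 16)
    } else if (id == "data") {
      data <- readBin(con, "raw", n = sz)
      break
    } else {
      readBin(con, "raw", n = sz)
    }
  }
  if (is.null(fmt) || is.null(data)) stop("malformed WAV: missing fmt or data chunk")
  bits <- fmt$bitsPerSample
  x <- if (fmt$audioFormat == 3 && bits == 32) {
    readBin(data, "numeric", size = 4, n = length(data) %/% 4, endian = "little")
  } else if (bits == 8) {
    (as.numeric(readBin(data, "integer", size = 1, n = length(data),
                        signed = FALSE)) - 128) / 128
  } else if (bits == 16) {
    readBin(data, "integer", size = 2, n = length(data) %/% 2,
            endian = "little") / 32768
  } else if (bits == 24) {
    raw3 <- matrix(as.integer(data), nrow = 3)
    v <- raw3[1, ] + 256 * raw3[2, ] + 65536 * raw3[3, ]
    v[v >= 2^23] <- v[v >= 2^23] - 2^24
    v / 2^23
  } else if (bits == 32) {
    readBin(data, "integer", size = 4, n = length(data) %/% 4,
            endian = "little") / 2^31
  } else stop("unsupported WAV bit depth: ", bits)
  if (fmt$channels > 1) {
    x <- colMeans(matrix(x, nrow = fmt$channels))
  }
  x
}

#' Write / read a point cloud as headerless CSV
#'
#' One point per row, comma-delimited, full double precision; an optional
#' JSON sidecar (`<path>.json`) records model, parameters and seed.
#'
#' @param pc a [PointCloud-class].
#' @param path destination path.
#' @param sidecar write the JSON provenance sidecar (default TRUE).
#' @return `writePointCloud`: `path`, invisibly. `readPointCloud`: a
#'   [PointCloud-class] (provenance restored from the sidecar when present).
#' @export
writePointCloud <- function(pc, path, sidecar = TRUE) {
  stopifnot(is(pc, "PointCloud"))
  write.table(format(coords(pc), digits = 17, trim = TRUE, scientific = FALSE),
              path, sep = ",", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  if (sidecar) {
    jsonlite::write_json(
      list(model = modelName(pc), params = modelParams(pc), seed = pc@seed),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname writePointCloud
#' @export
readPointCloud <- function(path) {
  if (!file.exists(path)) stop("point-cloud file not found: ", path)
  m <- as.matrix(read.table(path, sep = ",", header = FALSE))
  dimnames(m) <- NULL
  meta <- list(model = "external", params = list(), seed = NA_integer_)
  sc <- paste0(path, ".json")
  if (file.exists(sc)) {
    j <- jsonlite::read_json(sc, simplifyVector = TRUE)
    meta$model <- j$model %||% "external"
    meta$params <- as.list(j$params)
    meta$seed <- if (is.null(j$seed) || is.na(j$seed)) NA_integer_ else as.integer(j$seed)
  }
  new("PointCloud", points = m, model = meta$model, params = meta$params,
      seed = meta$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a persistence diagram as CSV
#'
#' The on-disk format has a `degree,birth,death` header, one feature per
#' row, full double precision and the token `inf` for infinite deaths.
#' Malformed rows (negative birth, death before birth) are rejected with
#' their row number.
#'
#' @param dgm a [PersistenceDiagram-class].
#' @param path file path.
#' @param filtration,threshold,nPoints metadata for `readDiagram` when no
#'   sidecar is present.
#' @return `readDiagram`: a [PersistenceDiagram-class].
#' @export
writeDiagram <- function(dgm, path) {
  stopifnot(is(dgm, "PersistenceDiagram"))
  f <- features(dgm)
  dd <- ifelse(is.finite(f$death), format(f$death, digits = 17, trim = TRUE), "inf")
  lines <- c("degree,birth,death",
             sprintf("%d,%s,%s", as.integer(f$degree),
                     format(f$birth, digits = 17, trim = TRUE), dd))
  writeLines(lines, path)
  jsonlite::write_json(
    list(filtration = filtrationType(dgm), scale = "radius",
         threshold = if (is.finite(dgm@threshold)) dgm@threshold else "inf",
         n_points = dgm@nPoints),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeDiagram
#' @export
readDiagram <- function(path, filtration = "rips", threshold = Inf,
                        nPoints = NA_integer_) {
  lines <- readLines(path)
  if (!length(lines) || tolower(gsub("\\s", "", lines[1])) != "degree,birth,death")
    stop("diagram file must start with a 'degree,birth,death' header")
  sc <- paste0(path, ".json")
  if (file.exists(sc)) {
    j <- jsonlite::read_json(sc, simplifyVector = TRUE)
    filtration <- j$filtration %||% filtration
    threshold <- if (identical(j$threshold, "inf")) Inf else j$threshold %||% threshold
    nPoints <- if (is.null(j$n_points) || is.na(j$n_points)) nPoints else as.integer(j$n_points)
  }
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) {
    feats <- data.frame(degree = integer(), birth = numeric(), death = numeric())
  } else {
    parts <- strsplit(body, ",")
    bad <- which(lengths(parts) != 3)
    if (length(bad)) stop("malformed diagram row ", bad[1] + 1L)
    parseDeath <- function(x) {
      x <- trimws(tolower(x))
      ifelse(x %in% c("inf", "infinity"), Inf, suppressWarnings(as.numeric(x)))
    }
    feats <- data.frame(
      degree = as.integer(vapply(parts, `[`, "", 1)),
      birth  = as.numeric(vapply(parts, `[`, "", 2)),
      death  = parseDeath(vapply(parts, `[`, "", 3)))
    probs <- which(is.na(feats$degree) | is.na(feats$birth) | is.na(feats$death))
    if (length(probs)) stop("unparseable diagram row ", probs[1] + 1L)
    neg <- which(feats$birth < 0)
    if (length(neg)) stop("negative birth in diagram row ", neg[1] + 1L)
    rev <- which(feats$death < feats$birth)
    if (length(rev)) stop("death before birth in diagram row ", rev[1] + 1L)
  }
  new("PersistenceDiagram", features = feats, filtration = filtration,
      scale = "radius", threshold = threshold, nPoints = nPoints)
}
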