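# shared fixtures and comparison helpers

unitSquare <- function() {
  matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE)
}

# multiset equality of two feature tables to a tolerance
expect_same_diagram <- function(a, b, tol = 1e-9) {
  fa <- if (is(a, "PersistenceDiagram")) features(a) else a
  fb <- if (is(b, "PersistenceDiagram")) features(b) else b
  fa <- fa[order(fa$degree, fa$birth, fa$death), , drop = FALSE]
  fb <- fb[order(fb$degree, fb$birth, fb$death), , drop = FALSE]
  expect_equal(nrow(fa), nrow(fb))
  expect_equal(fa$degree, fb$degree)
  expect_equal(fa$birth, fb$birth, tolerance = tol)
  finA <- is.finite(fa$death); finB <- is.finite(fb$death)
  expect_equal(finA, finB)
  expect_equal(fa$death[finA], fb$death[finB], tolerance = tol)
  invisible(TRUE)
}

# drop zero-persistence pairs (used when comparing complexes whose raw
# diagrams differ only in diagonal pairs, e.g. alpha vs full Cech)
positivePart <- function(dgm, tol = 1e-12) {
  f <- features(dgm)
  f[!is.finite(f$death) | f$death > f$birth + tol, , drop = FALSE]
}

# write a small PCM WAV file (for the signal reader round trip)
writeTestWav <- function(path, samples, rate = 8000L) {
  ints <- as.integer(round(pmin(pmax(samples, -1), 1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  dataSize <- 2L * length(ints)
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + dataSize, con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(rate, con, size = 4, endian = "little")
  writeBin(rate * 2L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(dataSize, con, size = 4, endian = "little")
  writeBin(ints, con, size = 2, endian = "little")
  invisible(path)
}

offUnitTriangle <- function(path) {
  writeLines(c("OFF", "3 1 0", "0 0 0", "1 0 0", "0 1 0", "3 0 1 2"), path)
  path
}

# ASCII OFF for the surface of the unit cube (12 triangles)
offUnitCube <- function(path) {
  v <- rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0),
             c(0,0,1), c(1,0,1), c(1,1,1), c(0,1,1))
  f <- rbind(c(0,2,1), c(0,3,2),   # bottom
             c(4,5,6), c(4,6,7),   # top
             c(0,1,5), c(0,5,4),   # front
             c(1,2,6), c(1,6,5),   # right
             c(2,3,7), c(2,7,6),   # back
             c(3,0,4), c(3,4,7))   # left
  writeLines(c("OFF", paste(nrow(v), nrow(f), 0),
               apply(v, 1, paste, collapse = " "),
               apply(cbind(3, f), 1, paste, collapse = " ")), path)
  path
}
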