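## Internal helpers: seeded RNG substreams and a small string fingerprint.

## Evaluate expr with a private RNG stream, restoring the caller's state.
withSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Deterministic per-subject / per-trial substream seed. Arithmetic seed
## progressions leave detectable correlation between Mersenne-Twister
## streams, so the (seed, index) pair is scrambled through splitmix32-style
## avalanche rounds first; the result stays inside the 32-bit range
## set.seed accepts.
.mix32 <- function(x) {
  mul32 <- function(a, b) {
    lo <- a %% 65536
    hi <- (a - lo) / 65536
    (lo * b + (hi * b %% 65536) * 65536) %% 4294967296
  }
  x <- x %% 4294967296
  x <- bitwXor(as.integer(x %% 2147483648), as.integer((x %/% 65536) %% 32768))
  x <- mul32(as.double(x), 2246822519)
  x <- bitwXor(as.integer(x %% 2147483648), as.integer((x %/% 8192) %% 262144))
  x <- mul32(as.double(x), 3266489917)
  x %% 2147483648
}

.subjectSeed <- function(seed, i) {
  h <- .mix32(as.double(seed) * 2654435761 + as.double(i) * 40503 + 977)
  h <- .mix32(h + as.double(i))
  as.integer(h %% 2147483647) + 1L
}

## djb2-style 31-bit fingerprint of a string; used to stamp report artifacts
## with the configuration they came from.
.hashString <- function(s) {
  b <- utf8ToInt(s)
  h <- 5381
  for (x in b) h <- (h * 33 + x) %% 2147483647
  sprintf("%08x", h)
}

.upperTriangle <- function(m) m[upper.tri(m)]
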