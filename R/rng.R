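# Counter-based random substreams.
#
# Every stochastic cell of the synthetic cohort is a pure function of
# (master seed, participant id, purpose code, draw index): a splitmix-style
# 32-bit hash maps the tuple to a uniform, and all draws are inverse-CDF
# transforms of that uniform. Consequences: appending participants or
# permuting rows never changes the values of existing rows, and no global
# RNG state is read or written.
#
# Arithmetic is done on doubles holding exact 32-bit values; products are
# split into 16-bit halves so nothing exceeds 2^53.

.M32 <- 4294967296  # 2^32

.mul32 <- function(a, b) {
  hi <- floor(a / 65536)
  lo <- a - hi * 65536
  (((hi * b) %% 65536) * 65536 + lo * b) %% .M32
}

.xor32 <- function(a, b) {
  ah <- as.integer(a %/% 65536); al <- as.integer(a %% 65536)
  bh <- as.integer(b %/% 65536); bl <- as.integer(b %% 65536)
  as.numeric(bitwXor(ah, bh)) * 65536 + as.numeric(bitwXor(al, bl))
}

.mix32 <- function(z) {
  z <- z %% .M32
  z <- .xor32(z, floor(z / 65536))
  z <- .mul32(z, 569420461)      # 0x21f0aaad
  z <- .xor32(z, floor(z / 32768))
  z <- .mul32(z, 1935289751)     # 0x735a2d97
  z <- .xor32(z, floor(z / 32768))
  z
}

#' Deterministic substream uniform
#'
#' Hashes `(seed, id, purpose, draw)` to a uniform in (0, 1). Vectorized
#' over `id` and `draw`. This is the sole randomness primitive of the
#' synthetic-cohort generator: values are independent of row order and of
#' the global R RNG.
#'
#' @param seed Master seed (integer, any 32-bit value).
#' @param id Participant id(s), non-negative integers.
#' @param purpose Integer code naming the variable being drawn.
#' @param draw Draw index within the (id, purpose) cell.
#' @return Numeric vector of uniforms strictly inside (0, 1).
#' @export
substream_uniform <- function(seed, id, purpose = 0, draw = 0) {
  h <- .mix32((as.numeric(seed) %% .M32) + 2654435769)   # golden-ratio offset
  h <- .mix32(.xor32(h, as.numeric(id) %% .M32))
  h <- .mix32(.xor32(h, (as.numeric(purpose) * 2246822519) %% .M32))
  h <- .mix32(.xor32(h, (as.numeric(draw) * 3266489917) %% .M32))
  (h + 0.5) / .M32
}

# Purpose codes (stable; appending new purposes must not renumber old ones).
.purpose <- c(
  age = 1, sex = 2, ethnicity = 3, education = 4, income = 5, bmi = 6,
  hypertension = 7, diabetes = 8, hyperlipidemia = 9, smoking = 10,
  gds15 = 11, iadl = 12, memory_complaint = 13, dementia = 14,
  intake_base = 20,       # + component index
  outcome = 50,
  neuro_base = 60,        # + test index
  missing_base = 80       # + variable index
)
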