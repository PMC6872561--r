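#' Per-stage reproducible random streams
#'
#' A single global seed lives in the pipeline configuration; every
#' stochastic stage derives its own seed from `(seed, stage name)` by
#' hashing the stage name (FNV-1a) into the 32-bit integer range. Running
#' a stage in isolation with the same global seed therefore reproduces its
#' stream bit for bit, independent of what ran before it.
#'
#' @param seed integer global seed.
#' @param stage character stage name, e.g. `"scene"`, `"noise"`.
#' @return An integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  h <- fnv1a(stage)
  as.integer((as.numeric(seed) + h) %% 2147483646) + 1L
}

# FNV-1a 32-bit hash of a character scalar, done in doubles to avoid
# integer overflow (all intermediates stay below 2^53; the XOR with a
# byte only touches the low 8 bits, so it is done on h mod 256).
fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- (h - h %% 256) + bitwXor(as.integer(h %% 256), as.integer(b))
    # exact (h * 16777619) mod 2^32 via 16-bit limbs
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 2^32
  }
  h
}

#' Evaluate code under a temporary seed, restoring RNG state afterwards
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Short content hash for provenance reports
#'
#' FNV-1a over the JSON serialization, reported as hex. Not cryptographic;
#' used only to tag reports with the configuration that produced them.
#'
#' @param x any jsonlite-serializable object.
#' @return character hex string.
#' @export
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  h <- fnv1a(as.character(s))
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
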