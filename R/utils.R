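# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state, so that
#' seeded internals never perturb the global random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Deterministic per-purpose seed substream derived from one global seed.
# Keeps every derived seed inside the 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 7919) %% 2147483562L) + 1L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stopf("'%s' must be a probability in [0, 1]", name)
  }
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stopf("'%s' must be an integer >= %d", name, min)
  }
}

assert_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stopf("'%s' must be a positive number", name)
  }
}

# md5 of a file (used in stage manifests)
file_md5 <- function(path) unname(tools::md5sum(path))

# md5 of an R object via canonical JSON serialization
object_md5 <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA, null = "null")
  file_md5(tf)
}
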