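#' @keywords internal
"_PACKAGE"

# Deterministic sub-stream seed for a named pipeline stage. Keeps every
# derived seed strictly below 2^31 so set.seed() always accepts it.
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 48271 + h * 100003) %% 2147483629 + 1)
}

# Quantile with the interpolation rule fixed (type 7, the linear
# interpolation between order statistics used throughout the package).
pctl <- function(x, probs) {
  unname(stats::quantile(x, probs = probs, type = 7, names = FALSE, na.rm = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(msg) {
  stop(structure(class = c("noisequity_config_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == round(x)

is_prob <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x <= 1

# md5 of a canonical JSON serialization, via base R (tools::md5sum).
hash_object <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f), add = TRUE)
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}
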