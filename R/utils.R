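# internal helpers shared across modules

#' Derive a deterministic sub-seed
#'
#' Maps a base seed plus any number of integer indices (node, repeat,
#' wavelength, ...) to a new seed, so that every Monte Carlo stream in a
#' pipeline is a pure function of one user-facing seed while staying inside
#' the 32-bit integer range.
#'
#' @param base Integer base seed.
#' @param ... Integer indices identifying the stream.
#' @return A single integer seed.
#' @export
derive_seed <- function(base, ...) {
  idx <- c(...)
  s <- as.double(base) %% 2147483647
  for (k in idx) {
    s <- (s * 48271 + as.double(k) * 7919 + 1) %% 2147483647
  }
  as.integer(s)
}

# md5 of an arbitrary R object via its canonical JSON serialization
object_md5 <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  unname(tools::md5sum(tmp))
}

file_md5 <- function(path) unname(tools::md5sum(path))

stop_bad_arg <- function(msg) abort(msg, class = "mldos_invalid_argument")

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
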