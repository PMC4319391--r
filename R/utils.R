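# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @keywords internal
#' @noRd
assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop(..., call. = FALSE)
  invisible(TRUE)
}

#' Derive a reproducible sub-seed for a named random stream
#'
#' A single global seed drives independent, named streams (expression matrix,
#' each drug, ...) so that adding one simulation stage never perturbs the
#' draws of another. The stream seed is a deterministic 31-bit hash of the
#' stream name folded into the global seed.
#'
#' @param seed integer global seed.
#' @param name character stream name.
#' @return an integer seed in [1, 2^31 - 2].
#' @export
stream_seed <- function(seed, name) {
  assert_that(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
              "'seed' must be a single finite number")
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483629
  as.integer((abs(seed) + h) %% 2147483629 + 1)
}

# Evaluate expr under a named stream without disturbing the caller's RNG state.
with_stream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed(seed, name))
  expr
}

# 32-bit FNV-1a hash of a string, as 8 hex characters. Used to stamp output
# files with a stable fingerprint of the run configuration.
fnv1a_hash <- function(x) {
  # xor on 16-bit halves keeps operands inside R's 31-bit integer range
  xor32 <- function(a, b) {
    bitwXor(a %% 65536, b %% 65536) +
      bitwXor(a %/% 65536, b %/% 65536) * 65536
  }
  h <- 2166136261
  for (b in utf8ToInt(x)) {
    h <- xor32(h, b)
    # 32-bit multiply by the FNV prime 16777619, done in two 16-bit halves
    # to stay within double precision.
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- ((lo * 16777619) + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

# Write a data.frame as TSV with a comment header carrying provenance.
write_tsv_stamped <- function(df, path, comment = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv_plain <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    quote = "", ...)
}
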