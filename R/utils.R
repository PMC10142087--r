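#' Evaluate code under a local random seed
#'
#' Runs `code` with the RNG seeded to `seed`, then restores the caller's
#' random state, so generators are reproducible without touching global
#' state. Every synthetic-data generator routes its randomness through
#' this helper.
#'
#' @param seed Single integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# scalar validators used across the generators
check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x != floor(x))
    stop("`", name, "` must be a single non-negative integer", call. = FALSE)
  as.integer(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop("`", name, "` must be a single number in [0, 1]", call. = FALSE)
  as.numeric(x)
}

#' Write a data frame as tab-separated values
#' @param x A data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @keywords internal
write_tsv_file <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
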