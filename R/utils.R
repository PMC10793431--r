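#' @keywords internal
`%||%` <- function(x, y) if (is.null(x)) y else x

# HP identifier shape: "HP:" + exactly 7 digits.
HP_ID_REGEX <- "^HP:[0-9]{7}$"

is_hp_id <- function(x) {
  is.character(x) & !is.na(x) & grepl(HP_ID_REGEX, x)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random-number state set from `seed`, then
#' restores the previous state, so seeded operations do not disturb the
#' caller's RNG stream. With `seed = NULL` the code runs on the ambient RNG.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
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

# sample() misbehaves for length-1 x; always sample indices.
sample_values <- function(x, k) {
  x[sample.int(length(x), k)]
}

# Round-half-up (round() in R is banker's rounding).
round_half_up <- function(x) floor(x + 0.5)

capitalize <- function(x) {
  substr(x, 1L, 1L) <- toupper(substr(x, 1L, 1L))
  x
}
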