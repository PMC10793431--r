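#' QWERTY keyboard adjacency table
#'
#' Physical neighbors of each lowercase letter on a staggered QWERTY layout,
#' including diagonal neighbors across rows (so `i` neighbors `u`, `o`, `j`,
#' `k`, and `m` neighbors `n`, `j`, `k`). The table is symmetric and every
#' letter has at least one neighbor; non-letter characters have no entry.
#'
#' @return Named list mapping each of `a`–`z` to a character vector of
#'   neighboring letters.
#' @export
#' @examples
#' qwerty_layout()[["i"]]  # u, o, j, k
qwerty_layout <- function() {
  rows <- c("qwertyuiop", "asdfghjkl", "zxcvbnm")
  # Horizontal stagger of each row on a physical keyboard, in key widths.
  offsets <- c(0, 0.25, 0.75)
  keys <- character()
  xs <- numeric()
  ys <- integer()
  for (r in seq_along(rows)) {
    ch <- strsplit(rows[r], "")[[1]]
    keys <- c(keys, ch)
    xs <- c(xs, seq_along(ch) + offsets[r])
    ys <- c(ys, rep.int(r, length(ch)))
  }
  adj <- stats::setNames(vector("list", length(keys)), keys)
  for (i in seq_along(keys)) {
    same_row <- ys == ys[i] & abs(xs - xs[i]) == 1
    adj_row <- abs(ys - ys[i]) == 1 & abs(xs - xs[i]) < 1
    adj[[i]] <- keys[same_row | adj_row]
  }
  adj
}

letter_positions <- function(term) {
  which(grepl("[A-Za-z]", strsplit(term, "")[[1]]))
}

replace_with_neighbor <- function(chars, pos, layout) {
  orig <- chars[pos]
  lower <- tolower(orig)
  nbrs <- layout[[lower]]
  if (is.null(nbrs) || length(nbrs) == 0L) {
    stop("no keyboard neighbors for character: ", orig)
  }
  repl <- sample_values(nbrs, 1L)
  if (orig != lower) repl <- toupper(repl)
  chars[pos] <- repl
  chars
}

#' Introduce a single keyboard-proximity typo
#'
#' Alters exactly one letter of `term`, replacing it with a uniformly drawn
#' physical neighbor on the QWERTY keyboard (case preserved). Non-letter
#' characters (spaces, digits, punctuation) are never altered, and the output
#' always has Hamming distance exactly 1 from the input.
#'
#' @param term Term containing at least one letter.
#' @param layout Adjacency table, by default [qwerty_layout()].
#' @param seed Integer seed for a deterministic draw, or `NULL` to use the
#'   ambient RNG stream.
#' @return The perturbed term.
#' @export
#' @examples
#' simple_typo("Vascular dilatation", seed = 1)
simple_typo <- function(term, layout = qwerty_layout(), seed = NULL) {
  stopifnot(is_string(term))
  pos <- letter_positions(term)
  if (length(pos) == 0L) stop("term contains no letters: ", deparse(term))
  with_seed(seed, {
    chars <- strsplit(term, "")[[1]]
    p <- sample_values(pos, 1L)
    paste(replace_with_neighbor(chars, p, layout), collapse = "")
  })
}

#' Introduce a complex multi-character typo
#'
#' Alters `k = min(3, max(1, round(0.2 * L)))` distinct letter positions,
#' where `L` is the number of letters in `term` and rounding is half-up; each
#' altered letter is replaced by a QWERTY neighbor. The output has the same
#' length as the input and Hamming distance exactly `k`; at most three
#' characters are ever altered.
#'
#' @inheritParams simple_typo
#' @return The perturbed term.
#' @export
complex_typo <- function(term, layout = qwerty_layout(), seed = NULL) {
  stopifnot(is_string(term))
  pos <- letter_positions(term)
  if (length(pos) == 0L) stop("term contains no letters: ", deparse(term))
  k <- min(3L, max(1L, round_half_up(0.2 * length(pos))))
  k <- min(k, length(pos))
  with_seed(seed, {
    chars <- strsplit(term, "")[[1]]
    picked <- sample_values(pos, k)
    for (p in picked) chars <- replace_with_neighbor(chars, p, layout)
    paste(chars, collapse = "")
  })
}

#' Normalize hyphens to spaces
#'
#' Replaces each `-` with a space, collapses whitespace runs, and trims.
#' Idempotent; useful because hyphenated cross-vocabulary surfaces such as
#' `"Kidney - Abnormal"` are poorly handled by models trained on
#' hyphen-free names.
#'
#' @param term A character vector of terms.
#' @return Terms with hyphens replaced by single spaces.
#' @export
#' @examples
#' strip_hyphens("Kidney - Abnormal")  # "Kidney Abnormal"
strip_hyphens <- function(term) {
  out <- gsub("-", " ", term, fixed = TRUE)
  out <- gsub("[[:space:]]+", " ", out)
  trimws(out)
}
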