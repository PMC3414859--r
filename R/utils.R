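# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero, the
#' convention used for all reported percentages (base `round()` rounds
#' ties to even).
#'
#' @param x numeric vector.
#' @param digits integer, decimal places (default 1).
#' @return numeric vector rounded to `digits` places.
#' @examples
#' round_half_up(9.75)   # 9.8, not 9.8/9.7 banker's ambiguity
#' round_half_up(0.5, 0) # 1
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Collapse runs of whitespace and trim; used on search terms and ids.
squish <- function(x) {
  gsub("[[:space:]]+", " ", trimws(x))
}

# stop() with a classed condition so callers can test error types.
abort <- function(message, class) {
  stop(structure(
    class = c(class, "searcheval_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

# Evaluate `code` with a temporary RNG state seeded at `seed`; the caller's
# RNG stream is untouched.  Keeps simulation streams independent of any
# randomness in the surrounding session.
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Balanced-parentheses check used by query invariant validation.
parens_balanced <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (ch in chars) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (depth < 0L) return(FALSE)
  }
  depth == 0L
}
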