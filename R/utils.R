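#' Derive a reproducible child seed from a master seed
#'
#' Stage- and participant-level random draws are controlled by child seeds
#' derived deterministically from one master seed, so any subset of the
#' pipeline can be rerun consistently. The derivation hashes the string
#' representation of the tags into a 31-bit integer (a polynomial rolling
#' hash), which keeps every derived seed valid for [set.seed()].
#'
#' @param master Integer master seed.
#' @param ... Tags (strings or numbers) identifying the stage, participant,
#'   condition, fold, etc.
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "simulate", "P01", "ambiguity")
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master))
  mod <- 2147483647
  h <- as.numeric(master) %% mod
  tags <- vapply(list(...), function(x) paste(as.character(x), collapse = ","),
                 character(1))
  for (tag in tags) {
    for (code in utf8ToInt(paste0(tag, "|"))) {
      h <- (h * 31 + code) %% mod
    }
  }
  as.integer(h)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so seeded internals do not disturb the
#' caller's RNG stream.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG untouched.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
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
  set.seed(seed)
  expr
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a probability in [0, 1], got %s",
                 name, paste(format(x), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

assert_pos <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) {
    stop(sprintf("`%s` must be a %s number", name,
                 if (strict) "positive" else "non-negative"), call. = FALSE)
  }
  invisible(x)
}

# milliseconds -> 0-based sample offset at sampling rate fs (Hz)
ms_to_samples <- function(ms, fs) as.integer(round(ms * fs / 1000))

`%||%` <- function(a, b) if (is.null(a)) b else a
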