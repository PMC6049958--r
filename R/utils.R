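
# shared input checks -------------------------------------------------------

abort_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)

check_prob <- function(x, name = deparse(substitute(x))) {
  abort_if(!is.numeric(x) || any(is.na(x)) || any(x < 0 | x > 1),
           sprintf("`%s` must be numeric in [0, 1]", name))
  invisible(x)
}

check_count <- function(x, name = deparse(substitute(x)), min = 1L) {
  abort_if(!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
             x != round(x),
           sprintf("`%s` must be a single integer >= %d", name, min))
  invisible(as.integer(x))
}

# Format a numeric for deterministic table output: fixed 6 significant digits.
format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else format(signif(v, 6), scientific = FALSE)
  }, character(1))
  out
}

#' Derive a child RNG seed from a master seed
#'
#' Deterministic integer stream derivation (kept below 2^31) so that
#' multi-stage simulations can be driven from one seed.
#'
#' @param seed Master integer seed.
#' @param offset Integer stream index.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1000003L * as.integer(offset)) %% 2147483647L
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
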