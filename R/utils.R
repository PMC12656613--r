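#' @keywords internal
"_PACKAGE"

# Canonical grade levels, ascending quality. Kept in one place because the
# robustness module relies on integer coding in this order.
PLUM_GRADES <- c("processing", "standard", "premium")

# Maturity classes, descending ripeness as the SSC mean defaults are listed.
PLUM_MATURITY <- c("ripe", "semi_ripe", "unripe")

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores the global `.Random.seed`, so seeded helpers do not
#' perturb the caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-item seed derived from a base seed; stays below 2^31.
derive_seed <- function(seed, offset, i = 0L) {
  as.integer((as.numeric(seed) * 48271 + offset * 7919 + i * 104729) %% 2147483647)
}

stop_plum <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "plum_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

as_grade <- function(x) factor(as.character(x), levels = PLUM_GRADES)
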