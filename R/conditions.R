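#' @keywords internal
#' Condition helpers
#'
#' All user-input problems raise conditions inheriting from
#' "opitaper_validation_error" so the command-line front end can map them to
#' exit status 2, distinct from internal errors (status 1). Lookup failures
#' (unknown drug) carry the subclass "opitaper_lookup_error".
#' @name opitaper-conditions
NULL

stop_validation <- function(msg, class = character()) {
  stop(structure(
    class = c(class, "opitaper_validation_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_lookup <- function(msg) {
  stop_validation(msg, class = "opitaper_lookup_error")
}

check_number <- function(x, name, min = -Inf, max = Inf,
                         strict_min = FALSE, strict_max = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_validation(sprintf("'%s' must be a single finite number", name))
  }
  lo_ok <- if (strict_min) x > min else x >= min
  hi_ok <- if (strict_max) x < max else x <= max
  if (!lo_ok || !hi_ok) {
    stop_validation(sprintf(
      "'%s' = %g is outside the allowed range %s%g, %g%s", name, x,
      if (strict_min) "(" else "[", min, max, if (strict_max) ")" else "]"
    ))
  }
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x)) {
    stop_validation(sprintf("'%s' must be a single integer", name))
  }
  if (x < min) {
    stop_validation(sprintf("'%s' = %d must be >= %d", name, as.integer(x), min))
  }
  invisible(as.integer(x))
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_validation(sprintf("'%s' must be TRUE or FALSE", name))
  }
  invisible(x)
}

check_choice <- function(x, name, choices) {
  if (!is.character(x) || length(x) != 1L || !(x %in% choices)) {
    stop_validation(sprintf(
      "'%s' must be one of: %s", name, paste(choices, collapse = ", ")
    ))
  }
  invisible(x)
}

#' Run an expression with a locally seeded RNG
#'
#' Saves and restores `.Random.seed` so seeded fixture generators never leak
#' state into the caller's random stream.
#' @keywords internal
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
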