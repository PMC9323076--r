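# Internal helpers shared across modules.

vib_abort <- function(msg, class = "vib_error", call. = FALSE) {
  stop(structure(
    class = c(class, "vib_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is_number(x)) {
    vib_abort(sprintf("`%s` must be a single finite number", name),
              "vib_invalid_parameter")
  }
  bad <- if (strict_lower) x <= lower else x < lower
  bad <- bad || if (strict_upper) x >= upper else x > upper
  if (bad) {
    vib_abort(sprintf("`%s` = %g is out of range", name, x),
              "vib_invalid_parameter")
  }
  invisible(x)
}

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global random-number generator seeded at `seed`, then
#' restores the previous RNG state so callers are not disturbed.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- parameter-tree helpers -------------------------------------------------
# Model parameters are nested lists whose leaves are numeric vectors/matrices.

tree_map <- function(f, x) {
  if (is.list(x)) lapply(x, function(e) tree_map(f, e)) else f(x)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else {
    f(a, b)
  }
}

tree_zeros_like <- function(x) tree_map(function(p) p * 0, x)

tree_n_leaves <- function(x) {
  if (is.list(x)) sum(vapply(x, tree_n_leaves, numeric(1))) else length(x)
}

tree_max_abs <- function(x) {
  if (is.list(x)) {
    if (length(x) == 0L) return(0)
    max(vapply(x, tree_max_abs, numeric(1)))
  } else if (length(x) == 0L) 0 else max(abs(x))
}

# Flatten a parameter tree to a single numeric vector and back (used by the
# finite-difference gradient checks in the test suite).
tree_flatten <- function(x) {
  if (is.list(x)) {
    unlist(lapply(x, tree_flatten), use.names = FALSE)
  } else {
    as.numeric(x)
  }
}

tree_unflatten <- function(template, values) {
  idx <- 0L
  rebuild <- function(x) {
    if (is.list(x)) {
      lapply(x, rebuild)
    } else {
      n <- length(x)
      out <- x
      out[] <- values[(idx + 1L):(idx + n)]
      idx <<- idx + n
      out
    }
  }
  rebuild(template)
}
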