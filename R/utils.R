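`%||%` <- function(x, y) if (is.null(x)) y else x

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Check a scalar probability
#' @noRd
check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stopf("`%s` must be a single probability in [0, 1], got %s",
          name, deparse(substitute(x)))
  invisible(x)
}

#' @noRd
check_pos <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) stopf("`%s` must be a single %s number", name,
                 if (strict) "positive" else "non-negative")
  invisible(x)
}

#' Cell-class vocabulary used throughout the package
#' @noRd
CELL_CLASSES <- c("sensory", "interneuron", "motoneuron",
                  "muscle_effector", "ciliated_effector", "glia", "fragment")

#' Effector classes (targets of the motoneuron layer)
#' @noRd
EFFECTOR_CLASSES <- c("muscle_effector", "ciliated_effector")

#' Segment vocabulary
#' @noRd
SEGMENTS <- c("head", "sg0", "sg1", "sg2", "sg3", "pygidium", "unknown")
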