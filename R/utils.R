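# Physical constants
.kB <- 1.380649e-23       # Boltzmann constant, J/K (CODATA)
.MBAR_TO_PA <- 100        # exact

#' @noRd
abort_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("freqchase_invalid", "error")))
}

#' @noRd
check_number <- function(x, name, positive = TRUE, allow_zero = FALSE,
                         scalar = TRUE) {
  if (scalar && length(x) != 1L)
    abort_invalid(name, " must be a single number")
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    abort_invalid(name, " must be finite numeric")
  if (positive) {
    ok <- if (allow_zero) all(x >= 0) else all(x > 0)
    if (!ok)
      abort_invalid(name, if (allow_zero) " must be non-negative"
                    else " must be strictly positive")
  }
  invisible(x)
}

#' @noRd
check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    abort_invalid(name, " must be TRUE or FALSE")
  invisible(x)
}
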