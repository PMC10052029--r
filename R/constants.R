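#' Physical constants used throughout the package
#'
#' Units are kcal/mol, Angstrom, Kelvin and picoseconds everywhere.
#'
#' @format `kB` is the Boltzmann constant in kcal/(mol K); `coulomb_k` is
#'   the electrostatic conversion factor in kcal A / (mol e^2).
#' @name constants
NULL

#' @rdname constants
#' @export
kB <- 0.0019872041

#' @rdname constants
#' @export
coulomb_k <- 332.0636

# internal: formatted stop/warning
stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
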