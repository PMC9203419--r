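#' Galaxy velocity data (Richardson-Green version)
#'
#' The 82 galaxy velocities from the Corona Borealis survey in the form
#' customarily used as a mixture-modelling benchmark: the version of
#' \code{MASS::galaxies} with the documented transcription error in
#' observation 78 corrected (26690 -> 26960) and velocities scaled to
#' units of 1000 km/s. Requires the \pkg{MASS} package.
#'
#' @return numeric vector of length 82 (roughly between 9.2 and 34.3).
#' @examples
#' if (requireNamespace("MASS", quietly = TRUE)) {
#'   y <- galaxy_data()
#'   c(n = length(y), midpoint = mean(range(y)), R2 = diff(range(y))^2)
#' }
#' @export
galaxy_data <- function() {
  if (!requireNamespace("MASS", quietly = TRUE)) {
    stop("galaxy_data() needs the MASS package", call. = FALSE)
  }
  g <- MASS::galaxies
  g[78] <- 26960
  g / 1000
}
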