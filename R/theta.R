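#' Uncertain-parameter bounds
#'
#' The eight uncertain inputs and their uniform prior bounds: proximal
#' arterial, structured-tree and proximal venous wall stiffnesses `K_A`,
#' `K_ST`, `K_V` (g/cm/s^2); the major/minor daughter radius scaling factors
#' `alpha`, `beta`; the arterial and venous length-to-radius ratios `lrrA`,
#' `lrrV`; and the minimum structured-tree radius `rmin` (cm).
#'
#' @return A tibble with columns `parameter`, `lower`, `upper`.
#' @export
#' @examples
#' theta_bounds()
theta_bounds <- function() {
  tibble(
    parameter = c("K_A", "K_ST", "K_V", "alpha", "beta", "lrrA", "lrrV", "rmin"),
    lower = c(5.60e5, 1.75e5, 5.95e5, 0.80, 0.60, 10, 10, 1e-3),
    upper = c(1.04e6, 3.25e5, 1.11e6, 0.92, 0.70, 50, 50, 1e-2)
  )
}

#' Default parameter vector (prior midpoints)
#'
#' @return Named numeric vector of the eight parameters at the midpoints of
#'   their prior bounds.
#' @export
#' @examples
#' default_theta()
default_theta <- function() {
  b <- theta_bounds()
  setNames((b$lower + b$upper) / 2, b$parameter)
}

## internal: validate a named theta vector against the prior bounds
validate_theta <- function(theta) {
  b <- theta_bounds()
  theta <- unlist(theta)
  missing <- setdiff(b$parameter, names(theta))
  if (length(missing) > 0) {
    abort(paste0("theta is missing: ", paste(missing, collapse = ", ")))
  }
  theta <- theta[b$parameter]
  bad <- theta < b$lower - 1e-12 | theta > b$upper + 1e-12
  if (any(bad)) {
    abort(paste0("theta outside prior bounds: ",
                 paste(b$parameter[bad], collapse = ", ")))
  }
  if (theta[["beta"]] >= theta[["alpha"]]) {
    abort("need beta < alpha")
  }
  theta
}
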