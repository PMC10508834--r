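#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col facet_wrap labs
#'   position_dodge theme_bw geom_point scale_y_log10
NULL

#' @export
ggplot2::autoplot

#' Plot midvessel pressure and flow traces of a simulation
#'
#' @param object A `proximal_solution`.
#' @param vessels Vessel names (default: root artery and vein roots).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.proximal_solution <- function(object, vessels = NULL, ...) {
  if (is.null(vessels)) {
    vessels <- c(object$network$root_artery, object$network$vein_roots)
  }
  df <- purrr::map_dfr(vessels, function(nm) {
    dplyr::mutate(vessel_trace(object, nm), vessel = nm)
  })
  long <- tidyr::pivot_longer(df[, c("t", "vessel", "p_mmHg", "q")],
                              c("p_mmHg", "q"),
                              names_to = "field", values_to = "value")
  ggplot(long, aes(.data$t, .data$value, colour = .data$vessel)) +
    geom_line() +
    facet_wrap(~field, scales = "free_y",
               labeller = ggplot2::as_labeller(
                 c(p_mmHg = "pressure (mmHg)", q = "flow (cm^3/s)"))) +
    labs(x = "time (s)", y = NULL) +
    theme_bw()
}

#' Bar chart of Sobol' indices
#'
#' @param object A `sobol_indices` (scalar output) or `generalized_sobol`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sobol_indices <- function(object, ...) {
  df <- tidy(object)
  if ("coordinate" %in% names(df)) df <- df[df$coordinate == 1, ]
  long <- tidyr::pivot_longer(df, c("S", "ST"),
                              names_to = "order", values_to = "index")
  ggplot(long, aes(.data$parameter, .data$index, fill = .data$order)) +
    geom_col(position = position_dodge()) +
    labs(x = NULL, y = "Sobol' index") +
    theme_bw()
}

#' @rdname autoplot.sobol_indices
#' @export
autoplot.generalized_sobol <- function(object, ...) {
  long <- tidyr::pivot_longer(tidy(object), c("GS", "GST"),
                              names_to = "order", values_to = "index")
  ggplot(long, aes(.data$parameter, .data$index, fill = .data$order)) +
    geom_col(position = position_dodge()) +
    labs(x = NULL, y = "generalized Sobol' index (t = T)") +
    theme_bw()
}

#' Plot a distal pathway profile
#'
#' Mean pressure, flow, wall shear stress and cyclic stretch against signed
#' distance from the distal end of the structured tree (arterial side
#' positive, venous side negative).
#'
#' @param object A `pathway_profile` (or row-bound profiles from
#'   [distal_qoi()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pathway_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object[, c("distance_cm", "side", "segment", "mean_p_mmHg", "mean_q",
               "wss", "cs")],
    c("mean_p_mmHg", "mean_q", "wss", "cs"),
    names_to = "field", values_to = "value")
  ggplot(long, aes(.data$distance_cm, .data$value,
                   colour = .data$side, shape = .data$segment)) +
    geom_point() + geom_line() +
    facet_wrap(~field, scales = "free_y") +
    labs(x = "distance from tree end (cm)", y = NULL) +
    theme_bw()
}

#' Plot wave intensity components over one cycle
#'
#' @param object A `wia_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wia_result <- function(object, ...) {
  df <- tidy(object)
  long <- tidyr::pivot_longer(df, c("FCW", "FDW", "BCW", "BDW"),
                              names_to = "type", values_to = "intensity")
  ggplot(long, aes(.data$t, .data$intensity, colour = .data$type)) +
    geom_line() +
    labs(x = "time (s)", y = "wave intensity") +
    theme_bw()
}
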