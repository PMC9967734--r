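#' Min-max (polar difference) normalisation
#'
#' (x - min) / (max - min), mapping the pooled values onto [0, 1]. The
#' inverse orientation (max - x) / (max - min) is available for variables
#' where high raw values mean low benefit; it is off by default.
#'
#' @param x numeric vector with at least two distinct values.
#' @param inverse flip the orientation.
#' @export
minmax_normalize <- function(x, inverse = FALSE) {
  rng <- range(x, finite = TRUE)
  if (diff(rng) == 0) stop("cannot normalise a constant vector")
  out <- (x - rng[1]) / diff(rng)
  if (inverse) out <- 1 - out
  out
}

#' Coupling degree between two normalised subsystems
#'
#' C = 2 * sqrt(W * S / (W + S)^2), in [0, 1], equal to 1 exactly when
#' W = S. Returns 0 with a warning when both inputs are 0 (undefined).
#'
#' @param W,S normalised subsystem values in [0, 1] (vectorised).
#' @export
coupling_degree <- function(W, S) {
  out <- ifelse(W + S > 0, 2 * sqrt(pmax(W * S, 0) / (W + S)^2), 0)
  if (any(W + S == 0)) warning("W = S = 0: coupling undefined, returning 0")
  out
}

#' Development index T = alpha W + beta S
#'
#' @param W,S normalised subsystem values.
#' @param alpha,beta non-negative weights summing to 1 (default 0.5 each,
#'   treating the two subsystems as equally important).
#' @export
development_index <- function(W, S, alpha = 0.5, beta = 0.5) {
  if (alpha < 0 || beta < 0 || abs(alpha + beta - 1) > 1e-9)
    stop("alpha and beta must be non-negative and sum to 1")
  alpha * W + beta * S
}

#' Coupling coordination degree D = sqrt(C * T)
#'
#' @param C coupling degree.
#' @param T development index.
#' @export
coordination_degree <- function(C, T) sqrt(pmax(C * T, 0))

#' Coupling-coordination scores for a set of units
#'
#' Computes (W, S, C, T, D) per analysis unit. Raw values are normalised
#' across the pooled set supplied here, so D values are comparable only
#' within that pool; pass pre-normalised values with `normalize = FALSE`
#' (e.g. printed W/S pairs).
#'
#' @param carbon raw (or normalised) carbon values per unit.
#' @param risk raw (or normalised) risk values per unit.
#' @param unit_id optional identifiers.
#' @param alpha,beta development-index weights.
#' @param normalize min-max normalise the inputs over the pool.
#' @param inverse_risk use inverse orientation for the risk subsystem.
#' @return data.frame unit_id, W_raw, S_raw, W, S, C, T, D.
#' @export
coupling_scores <- function(carbon, risk, unit_id = seq_along(carbon),
                            alpha = 0.5, beta = 0.5,
                            normalize = TRUE, inverse_risk = FALSE) {
  stopifnot(length(carbon) == length(risk))
  W <- if (normalize) minmax_normalize(carbon) else carbon
  S <- if (normalize) minmax_normalize(risk, inverse = inverse_risk) else risk
  C <- coupling_degree(W, S)
  T <- development_index(W, S, alpha, beta)
  D <- coordination_degree(C, T)
  data.frame(unit_id = unit_id, W_raw = carbon, S_raw = risk,
             W = W, S = S, C = C, T = T, D = D)
}

#' Round half away from zero (reporting convention)
#'
#' Unlike base [round()] (banker's rounding), 0.0005 rounds up to 0.001.
#' Used to report scores at 3 decimals.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
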