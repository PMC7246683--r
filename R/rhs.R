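#' Right-hand side of the single-channel SIS model
#'
#' Evaluates the derivative of the classical SIS system
#' \deqn{dS/dt = -\beta S I + \gamma I, \quad dI/dt = \beta S I - \gamma I,}
#' where S is the pool of potential customers and I the purchasers.
#' The two components sum to zero identically, so S + I is conserved.
#'
#' @param state numeric `c(S, I)`, both non-negative.
#' @param params a [single_channel_params()] object.
#' @return Named numeric `c(dS, dI)`.
#' @examples
#' p <- single_channel_params(beta = 0.5, gamma = 0.1, N = 6)
#' sis_rhs_single(c(S = 4, I = 2), p)  # c(-3.8, 3.8)
#' @export
sis_rhs_single <- function(state, params) {
  if (!inherits(params, "sis_single_params")) {
    params <- do.call(single_channel_params, as.list(params))
  }
  S <- state[[1]]; I <- state[[2]]
  if (S < 0 || I < 0) stop("state components must be non-negative", call. = FALSE)
  flow <- params$beta * S * I - params$gamma * I
  c(dS = -flow, dI = flow)
}

# per-capita demand growth of each channel; both vanish at the interior
# demand equilibrium M, which is why the thresholds A and B collapse to the
# recovery rates there
growth_terms <- function(N1, N2, p) {
  c(g1 = p$r1 * (1 - N1 / p$K1) + p$m * N2 / p$K2,
    g2 = p$r2 * (1 - N2 / p$K2) + p$n * N1 / p$K1)
}

#' Right-hand side of the two-dimensional demand system
#'
#' The customer-base (demand) dynamics of the two channels decouple from the
#' purchase counts and form a Lotka-Volterra-type competition system:
#' \deqn{dN_1/dt = r_1 N_1 (1 - N_1/K_1) + m N_1 N_2 / K_2,}
#' \deqn{dN_2/dt = r_2 N_2 (1 - N_2/K_2) + n N_1 N_2 / K_1.}
#'
#' @param state numeric `c(N1, N2)` in the admissible box G (see
#'   [in_region()]).
#' @param params an [model_params()] object.
#' @return Named numeric `c(dN1, dN2)`.
#' @export
rhs_2d <- function(state, params) {
  p <- validate_params(params)
  N1 <- state[[1]]; N2 <- state[[2]]
  g <- growth_terms(N1, N2, p)
  c(dN1 = N1 * g[["g1"]], dN2 = N2 * g[["g2"]])
}

#' Right-hand side of the four-dimensional demand-and-purchase system
#'
#' Couples the demand dynamics of [rhs_2d()] with SIS purchase transmission.
#' Writing \eqn{g_i} for the per-capita demand growth of channel i
#' (\eqn{g_1 = r_1(1 - N_1/K_1) + m N_2/K_2} and symmetrically for
#' \eqn{g_2}), the purchase equations use mass-action incidence
#' \deqn{dI_i/dt = (\beta_{ii} I_i + \beta_{ij} I_j)(N_i - I_i)
#'   - \gamma_i I_i + g_i I_i,}
#' where the final demographic term (purchasers carried along with the
#' growing or shrinking customer base) is controlled by the
#' `demographic_coupling` switch of [model_params()]. With the term on,
#' `I_i <= N_i` is forward-invariant: at `I_i = N_i` one has
#' `dI_i/dt - dN_i/dt = -gamma_i N_i <= 0`. Either way the equation reduces
#' to \eqn{\beta_{11} I_1 (K_1 - I_1) - \gamma_1 I_1} on the boundary face
#' `N1 = K1, N2 = I2 = 0`, since `g1` vanishes there.
#'
#' @param state numeric `c(N1, I1, N2, I2)` in the admissible region G'
#'   (see [in_region()]).
#' @param params an [model_params()] object.
#' @return Named numeric `c(dN1, dI1, dN2, dI2)`.
#' @export
rhs_4d <- function(state, params) {
  p <- validate_params(params)
  N1 <- state[[1]]; I1 <- state[[2]]; N2 <- state[[3]]; I2 <- state[[4]]
  g <- growth_terms(N1, N2, p)
  cpl <- if (p$demographic_coupling) 1 else 0
  dI1 <- (p$beta11 * I1 + p$beta12 * I2) * (N1 - I1) - p$gamma1 * I1 +
    cpl * g[["g1"]] * I1
  dI2 <- (p$beta21 * I1 + p$beta22 * I2) * (N2 - I2) - p$gamma2 * I2 +
    cpl * g[["g2"]] * I2
  c(dN1 = N1 * g[["g1"]], dI1 = dI1, dN2 = N2 * g[["g2"]], dI2 = dI2)
}

#' Admissible-region membership
#'
#' Tests whether a state lies in the admissible box of the model:
#' region G = \{0 <= Ni <= Ki\} for a 2-component state `c(N1, N2)`, or
#' region G' = \{0 <= Ii <= Ni <= Ki\} for a 4-component state
#' `c(N1, I1, N2, I2)`. All inequalities are checked with an absolute
#' tolerance scaled by the carrying capacities.
#'
#' @param state numeric of length 2 or 4.
#' @param params an [model_params()] object.
#' @param tol non-negative relative tolerance (scaled by `max(K1, K2)`).
#' @return `TRUE` or `FALSE`.
#' @export
in_region <- function(state, params, tol = 1e-9) {
  p <- validate_params(params)
  if (tol < 0) stop("'tol' must be non-negative", call. = FALSE)
  eps <- tol * max(p$K1, p$K2, 1)
  if (length(state) == 2L) {
    N1 <- state[[1]]; N2 <- state[[2]]
    return(N1 >= -eps && N1 <= p$K1 + eps && N2 >= -eps && N2 <= p$K2 + eps)
  }
  if (length(state) == 4L) {
    N1 <- state[[1]]; I1 <- state[[2]]; N2 <- state[[3]]; I2 <- state[[4]]
    return(I1 >= -eps && I1 <= N1 + eps && N1 <= p$K1 + eps &&
           I2 >= -eps && I2 <= N2 + eps && N2 <= p$K2 + eps)
  }
  stop("'state' must have length 2 (G) or 4 (G')", call. = FALSE)
}
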