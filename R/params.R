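#' Parameters of the single-channel SIS model
#'
#' The classical susceptible-infected-susceptible model of one sales channel:
#' a closed population of `N` consumers in which purchasers ("infected")
#' convert potential customers ("susceptible") at per-contact rate `beta` and
#' stop purchasing ("recover") at rate `gamma`, returning to the potential
#' pool.
#'
#' @param beta transmission influence rate per contact per unit time
#'   (non-negative).
#' @param gamma purchase-termination (recovery) rate per unit time
#'   (non-negative).
#' @param N total population size (constant, persons; positive).
#' @return An object of class `sis_single_params`.
#' @examples
#' single_channel_params(beta = 0.5, gamma = 0.1, N = 6)
#' @export
single_channel_params <- function(beta, gamma, N) {
  stop_unless_number(beta, "beta")
  stop_unless_number(gamma, "gamma")
  stop_unless_number(N, "N")
  if (beta < 0) stop("'beta' must be non-negative", call. = FALSE)
  if (gamma < 0) stop("'gamma' must be non-negative", call. = FALSE)
  if (N <= 0) stop("'N' must be positive", call. = FALSE)
  structure(list(beta = beta, gamma = gamma, N = N),
            class = "sis_single_params")
}

#' Parameters of the dual-channel SIS model
#'
#' Constructs and validates the twelve rate/capacity constants of the
#' two-channel system. Channel 1 is conventionally the offline channel and
#' channel 2 the online channel. Demand in each channel grows logistically at
#' intrinsic rate `ri` towards carrying capacity `Ki`, modified by a signed
#' cross-influence of the other channel's customer base (`m`: effect of
#' channel 2 on channel 1, `n`: effect of channel 1 on channel 2; both
#' negative means the channels compete). Purchase spreads by mass-action
#' contact with within-channel rates `beta11`, `beta22` and cross-channel
#' rates `beta12` (purchasers of channel 2 converting potential customers of
#' channel 1) and `beta21`; purchasers stop buying at rates `gamma1`,
#' `gamma2`.
#'
#' @param r1,r2 intrinsic demand growth rates per unit time (positive).
#' @param K1,K2 channel carrying capacities (persons; positive).
#' @param m,n signed cross-influence rates; unrestricted in sign
#'   (competition corresponds to `m < 0` and `n < 0`).
#' @param beta11,beta12,beta21,beta22 transmission influence rates
#'   (non-negative).
#' @param gamma1,gamma2 recovery rates (positive).
#' @param demographic_coupling logical; if `TRUE` (default) the purchase
#'   equations carry the per-capita demand growth term so that purchasers are
#'   created and removed in proportion as the channel's customer base grows
#'   or shrinks. Both readings agree at every studied equilibrium.
#' @return A validated object of class `sis_params`. Degeneracies that
#'   downstream code must know about are recorded in `attr(, "flags")`:
#'   `"interior equilibrium undefined"` when `r1*r2 - m*n == 0`.
#' @seealso [validate_params()], [read_model_config()]
#' @examples
#' model_params(r1 = 1, r2 = 1, K1 = 1000, K2 = 1000, m = -1.2, n = -1.5,
#'              beta11 = 5e-06, beta12 = 0.05, beta21 = 0.05, beta22 = 0.05,
#'              gamma1 = 0.01, gamma2 = 0.01)
#' @export
model_params <- function(r1, r2, K1, K2, m, n,
                         beta11, beta12, beta21, beta22,
                         gamma1, gamma2,
                         demographic_coupling = TRUE) {
  p <- list(r1 = r1, r2 = r2, K1 = K1, K2 = K2, m = m, n = n,
            beta11 = beta11, beta12 = beta12,
            beta21 = beta21, beta22 = beta22,
            gamma1 = gamma1, gamma2 = gamma2,
            demographic_coupling = isTRUE(demographic_coupling))
  validate_params(p)
}

#' Validate a dual-channel parameter set
#'
#' Checks every parameter invariant and attaches degeneracy flags. Invalid
#' values are rejected with a message naming the offending field.
#'
#' @param params a list or `sis_params` object carrying the fields of
#'   [model_params()].
#' @return The validated `sis_params` object (flags in `attr(, "flags")`).
#' @export
validate_params <- function(params) {
  p <- unclass(params)
  need <- c("r1", "r2", "K1", "K2", "m", "n",
            "beta11", "beta12", "beta21", "beta22", "gamma1", "gamma2")
  miss <- setdiff(need, names(p))
  if (length(miss)) {
    stop("missing parameter field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (f in need) stop_unless_number(p[[f]], f)
  bad <- character(0)
  for (f in c("K1", "K2", "gamma1", "gamma2")) {
    if (p[[f]] <= 0) bad <- c(bad, sprintf("%s must be positive", f))
  }
  for (f in c("r1", "r2")) {
    if (p[[f]] <= 0) bad <- c(bad, sprintf("%s must be positive", f))
  }
  for (f in c("beta11", "beta12", "beta21", "beta22")) {
    if (p[[f]] < 0) bad <- c(bad, sprintf("%s must be non-negative", f))
  }
  if (length(bad)) stop(paste(bad, collapse = "; "), call. = FALSE)
  if (is.null(p$demographic_coupling)) p$demographic_coupling <- TRUE
  flags <- character(0)
  if (p$r1 * p$r2 - p$m * p$n == 0) {
    flags <- c(flags, "interior equilibrium undefined")
  }
  structure(p[c(need, "demographic_coupling")],
            flags = flags, class = "sis_params")
}

#' @export
print.sis_params <- function(x, ...) {
  cat("Dual-channel SIS model parameters\n")
  cat(sprintf("  demand:       r1=%g r2=%g K1=%g K2=%g m=%g n=%g\n",
              x$r1, x$r2, x$K1, x$K2, x$m, x$n))
  cat(sprintf("  transmission: beta11=%g beta12=%g beta21=%g beta22=%g\n",
              x$beta11, x$beta12, x$beta21, x$beta22))
  cat(sprintf("  recovery:     gamma1=%g gamma2=%g\n", x$gamma1, x$gamma2))
  cat(sprintf("  demographic coupling in purchase equations: %s\n",
              if (x$demographic_coupling) "on" else "off"))
  fl <- attr(x, "flags")
  if (length(fl)) cat("  flags:", paste(fl, collapse = "; "), "\n")
  invisible(x)
}

#' Read model parameters and run settings from a config file
#'
#' Reads a flat key-value config in YAML or JSON. Recognised keys are the
#' twelve parameter names of [model_params()] (transliterated:
#' `r1, r2, K1, K2, m, n, beta11, beta12, beta21, beta22, gamma1, gamma2`),
#' the optional initial state `N1_0, I1_0, N2_0, I2_0`, the horizon `t_end`
#' and `demographic_coupling`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file; the dialect is
#'   inferred from the extension (anything else is tried as YAML, which is a
#'   superset of JSON for flat maps).
#' @return A list with elements `params` (an `sis_params`), `state0` (named
#'   numeric `c(N1, I1, N2, I2)` or `NULL`) and `t_end` (or `NULL`).
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  # YAML 1.1 reads a bare key `n` as the boolean FALSE (and `y` as TRUE);
  # map it back to the cross-influence parameter
  names(raw)[names(raw) %in% c("FALSE", "no")] <- "n"
  pn <- c("r1", "r2", "K1", "K2", "m", "n",
          "beta11", "beta12", "beta21", "beta22", "gamma1", "gamma2")
  p <- raw[intersect(pn, names(raw))]
  if (!is.null(raw$demographic_coupling)) {
    p$demographic_coupling <- as.logical(raw$demographic_coupling)
  }
  params <- validate_params(p)
  state0 <- NULL
  sn <- c("N1_0", "I1_0", "N2_0", "I2_0")
  if (all(sn %in% names(raw))) {
    state0 <- c(N1 = as.numeric(raw$N1_0), I1 = as.numeric(raw$I1_0),
                N2 = as.numeric(raw$N2_0), I2 = as.numeric(raw$I2_0))
  }
  t_end <- if (!is.null(raw$t_end)) as.numeric(raw$t_end) else NULL
  list(params = params, state0 = state0, t_end = t_end)
}

#' Swap the channel labels of a parameter set
#'
#' Relabels channel 1 as channel 2 and vice versa: exchanges `r1/r2`,
#' `K1/K2`, `m/n`, `beta11/beta22`, `beta12/beta21` and `gamma1/gamma2`.
#' The model is equivariant under this relabelling, which makes it a useful
#' consistency check: simulating swapped parameters from a swapped initial
#' state reproduces the original trajectory with the channels exchanged.
#'
#' @param params an [model_params()] object.
#' @return The relabelled `sis_params`.
#' @export
swap_channels <- function(params) {
  p <- validate_params(params)
  model_params(r1 = p$r2, r2 = p$r1, K1 = p$K2, K2 = p$K1,
               m = p$n, n = p$m,
               beta11 = p$beta22, beta12 = p$beta21,
               beta21 = p$beta12, beta22 = p$beta11,
               gamma1 = p$gamma2, gamma2 = p$gamma1,
               demographic_coupling = p$demographic_coupling)
}

stop_unless_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  invisible(TRUE)
}
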