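#' Circuit parameter sets for the Notch signaling models
#'
#' Constructs a validated parameter set for the dimensionless Notch-Delta
#' circuit models. Three model forms are supported:
#' \describe{
#'   \item{MODEL1}{the dimensional five-species system, represented only as a
#'     rescaling of MODEL2 via [scaling_constants()]; it is never integrated
#'     directly.}
#'   \item{MODEL2}{five species per cell (Notch mRNA, NOTCH receptor, Dll
#'     mRNA, DLL ligand, NICD) with explicit transcription and translation.}
#'   \item{MODEL3}{the quasi-steady-state protein reduction with three
#'     species per cell (NOTCH, DLL, NICD); see [qssa_reduce()].}
#' }
#'
#' Regulatory strengths \code{S_PF} (positive feedback: NICD-activated Notch
#' transcription) and \code{S_LI} (lateral inhibition: signaling-repressed
#' Dll transcription) are fractions in \[0, 1\] of the maximum transcription
#' rates \code{beta_nm = beta_n0 + beta_n} and \code{beta_dm = beta_d0 +
#' beta_d}. Setting \code{S_PF = 0} gives the pure lateral-inhibition (LI)
#' circuit; \code{S_PF > 0} gives PFLI.
#'
#' @param beta_N,beta_D synthesis rates: translation rates in MODEL2,
#'   effective maximum production rates in MODEL3 (dimensionless).
#' @param alpha_N,alpha_D,alpha_R protein degradation rates. In MODEL3 the
#'   NOTCH decay rate is stored in both \code{alpha_n} and \code{alpha_N}
#'   (the reduction collapses the mRNA and protein stages).
#' @param alpha_n,alpha_d mRNA degradation rates (MODEL2 only).
#' @param beta_n0,beta_n,beta_d0,beta_d basal and regulated transcription
#'   rates (MODEL2); their sums are the maximum rates \code{beta_nm},
#'   \code{beta_dm}.
#' @param beta_nm,beta_dm maximum transcription rates; supply either these
#'   together with \code{S_PF}/\code{S_LI}, or the four split rates.
#' @param k_p,k_d saturation coefficients of the activating and repressing
#'   Hill functions (inputs are the trans-activation flux \code{N * <D>}).
#' @param p,h Hill coefficients of PF activation and LI repression.
#' @param S_PF,S_LI regulatory-strength fractions in \[0, 1\].
#' @param model_form one of \code{"MODEL1"}, \code{"MODEL2"}, \code{"MODEL3"}.
#'
#' @return An object of class \code{circuit_params} (a named list).
#' @export
circuit_params <- function(beta_N, beta_D,
                           alpha_N, alpha_D, alpha_R,
                           S_PF, S_LI, k_p, k_d, p = 2, h = 2,
                           model_form = c("MODEL3", "MODEL2", "MODEL1"),
                           beta_nm = NULL, beta_dm = NULL,
                           beta_n0 = NULL, beta_n = NULL,
                           beta_d0 = NULL, beta_d = NULL,
                           alpha_n = NULL, alpha_d = NULL) {
  model_form <- match.arg(model_form)
  if (model_form == "MODEL3") {
    alpha_n <- alpha_N
    alpha_d <- alpha_D
    beta_nm <- beta_nm %||% NA_real_
    beta_dm <- beta_dm %||% NA_real_
  } else {
    if (is.null(alpha_n) || is.null(alpha_d))
      stop("MODEL1/MODEL2 require mRNA degradation rates alpha_n, alpha_d")
    if (is.null(beta_nm)) {
      if (is.null(beta_n0) || is.null(beta_n))
        stop("supply beta_nm or both beta_n0 and beta_n")
      beta_nm <- beta_n0 + beta_n
    }
    if (is.null(beta_dm)) {
      if (is.null(beta_d0) || is.null(beta_d))
        stop("supply beta_dm or both beta_d0 and beta_d")
      beta_dm <- beta_d0 + beta_d
    }
  }
  # derive the split rates from (max rate, strength) when absent
  if (is.null(beta_n0) && !is.na(beta_nm)) {
    beta_n <- S_PF * beta_nm
    beta_n0 <- beta_nm - beta_n
  }
  if (is.null(beta_d0) && !is.na(beta_dm)) {
    beta_d <- S_LI * beta_dm
    beta_d0 <- beta_dm - beta_d
  }
  p <- as.numeric(p); h <- as.numeric(h)
  obj <- structure(list(
    beta_N = beta_N, beta_D = beta_D,
    alpha_n = alpha_n, alpha_N = alpha_N,
    alpha_d = alpha_d, alpha_D = alpha_D, alpha_R = alpha_R,
    k_p = k_p, k_d = k_d, p = p, h = h,
    S_PF = S_PF, S_LI = S_LI,
    beta_nm = beta_nm, beta_dm = beta_dm,
    beta_n0 = beta_n0 %||% NA_real_, beta_n = beta_n %||% NA_real_,
    beta_d0 = beta_d0 %||% NA_real_, beta_d = beta_d %||% NA_real_,
    model_form = model_form
  ), class = "circuit_params")
  validate_params(obj)
  obj
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a circuit parameter set
#'
#' Checks positivity of rates, the \[0, 1\] bounds on the regulatory
#' strengths, the Hill-coefficient lower bounds, and the consistency of the
#' split and maximum transcription rates.
#'
#' @param params a \code{circuit_params} object.
#' @return \code{params}, invisibly, if valid; otherwise an error.
#' @export
validate_params <- function(params) {
  stopifnot(inherits(params, "circuit_params"))
  pos <- c("beta_N", "beta_D", "alpha_N", "alpha_D", "alpha_R", "k_p", "k_d")
  if (params$model_form != "MODEL3")
    pos <- c(pos, "alpha_n", "alpha_d", "beta_nm", "beta_dm")
  for (f in pos) {
    v <- params[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop(sprintf("parameter '%s' must be a positive scalar", f))
  }
  if (params$S_PF < 0 || params$S_PF > 1)
    stop("S_PF must lie in [0, 1]")
  if (params$S_LI < 0 || params$S_LI > 1)
    stop("S_LI must lie in [0, 1]")
  if (params$p < 1) stop("Hill coefficient p must be >= 1")
  if (params$h < 1) stop("Hill coefficient h must be >= 1")
  if (!is.na(params$beta_nm) && !is.na(params$beta_n0) && !is.na(params$beta_n)) {
    if (abs(params$beta_nm - (params$beta_n0 + params$beta_n)) > 1e-9 * params$beta_nm)
      stop("beta_nm must equal beta_n0 + beta_n")
  }
  if (!is.na(params$beta_dm) && !is.na(params$beta_d0) && !is.na(params$beta_d)) {
    if (abs(params$beta_dm - (params$beta_d0 + params$beta_d)) > 1e-9 * params$beta_dm)
      stop("beta_dm must equal beta_d0 + beta_d")
  }
  if (params$model_form == "MODEL3" && !isTRUE(all.equal(params$alpha_n, params$alpha_N)))
    stop("MODEL3 carries a single NOTCH decay rate: alpha_n must equal alpha_N")
  invisible(params)
}

#' @export
print.circuit_params <- function(x, ...) {
  cat(sprintf("<circuit_params> %s  (S_PF = %g, S_LI = %g, p = %g, h = %g)\n",
              x$model_form, x$S_PF, x$S_LI, x$p, x$h))
  num <- vapply(x[setdiff(names(x), "model_form")], as.numeric, numeric(1))
  print(round(num, 4))
  invisible(x)
}

#' Scaling constants linking the dimensional and dimensionless models
#'
#' The dimensional five-species model (MODEL1) is mapped onto the
#' dimensionless MODEL2 by measuring time in units of \code{t0} and
#' concentrations in units of the reference levels, with the protein
#' references tied to the trans-activation rate: \code{N0 = D0 = R0 = t0 *
#' k_t}. Transcription and degradation rates rescale as \code{beta/(t0 *
#' ref)} and \code{alpha/t0}; the saturation coefficients rescale by
#' \code{k_t * N0 * D0}.
#'
#' @param t0 reference timescale (time units).
#' @param k_t dimensional trans-activation rate constant.
#' @param Nm0,Dm0 reference mRNA concentrations.
#' @return An object of class \code{scaling_constants}.
#' @export
scaling_constants <- function(t0, k_t, Nm0 = 1, Dm0 = 1) {
  stopifnot(t0 > 0, k_t > 0, Nm0 > 0, Dm0 > 0)
  ref <- t0 * k_t
  structure(list(t0 = t0, k_t = k_t, N0 = ref, D0 = ref, R0 = ref,
                 Nm0 = Nm0, Dm0 = Dm0),
            class = "scaling_constants")
}

#' Nondimensionalize a dimensional parameter set
#'
#' Applies the reference scales of [scaling_constants()] to a list of
#' dimensional rates, producing a dimensionless MODEL2 parameter set.
#'
#' @param dimensional named list with dimensional \code{beta_n0, beta_n,
#'   beta_N, beta_d0, beta_d, beta_D, alpha_n, alpha_N, alpha_d, alpha_D,
#'   alpha_R, k_p, k_d} plus \code{S_PF}, \code{S_LI} implied by the split
#'   transcription rates, and Hill coefficients \code{p}, \code{h}.
#' @param sc a \code{scaling_constants} object.
#' @return a \code{circuit_params} object with \code{model_form = "MODEL2"}.
#' @export
nondimensionalize <- function(dimensional, sc) {
  stopifnot(inherits(sc, "scaling_constants"))
  d <- dimensional
  beta_n0 <- d$beta_n0 / (sc$t0^-1 * sc$Nm0) # beta_n0 / (Nm0 / t0)
  beta_n  <- d$beta_n  / (sc$t0^-1 * sc$Nm0)
  beta_d0 <- d$beta_d0 / (sc$t0^-1 * sc$Dm0)
  beta_d  <- d$beta_d  / (sc$t0^-1 * sc$Dm0)
  beta_nm <- beta_n0 + beta_n
  beta_dm <- beta_d0 + beta_d
  circuit_params(
    beta_N = d$beta_N * sc$Nm0 / (sc$N0 / sc$t0),
    beta_D = d$beta_D * sc$Dm0 / (sc$D0 / sc$t0),
    alpha_N = d$alpha_N * sc$t0, alpha_D = d$alpha_D * sc$t0,
    alpha_R = d$alpha_R * sc$t0,
    alpha_n = d$alpha_n * sc$t0, alpha_d = d$alpha_d * sc$t0,
    k_p = d$k_p / (sc$k_t * sc$N0 * sc$D0),
    k_d = d$k_d / (sc$k_t * sc$N0 * sc$D0),
    S_PF = beta_n / beta_nm, S_LI = beta_d / beta_dm,
    p = d$p, h = d$h,
    beta_n0 = beta_n0, beta_n = beta_n,
    beta_d0 = beta_d0, beta_d = beta_d,
    model_form = "MODEL2")
}

#' Quasi-steady-state reduction of the five-species model
#'
#' Eliminates the two mRNA species of MODEL2 by setting their time
#' derivatives to zero (mRNA turnover assumed fast relative to proteins) and
#' substituting the resulting quasi-steady-state mRNA levels into the
#' protein equations. The effective MODEL3 production rates are
#' \code{beta_N' = beta_N * beta_nm / alpha_n} and \code{beta_D' = beta_D *
#' beta_dm / alpha_d}; all regulatory parameters carry over unchanged. The
#' reduced NOTCH species decays at the receptor degradation rate
#' \code{alpha_N}.
#'
#' @param params a MODEL2 \code{circuit_params} object.
#' @return the reduced MODEL3 \code{circuit_params} object.
#' @export
qssa_reduce <- function(params) {
  validate_params(params)
  if (params$model_form != "MODEL2")
    stop("qssa_reduce expects MODEL2 parameters")
  if (params$alpha_n <= 0 || params$alpha_d <= 0)
    stop("mRNA degradation rates must be positive for the reduction")
  circuit_params(
    beta_N = params$beta_N * params$beta_nm / params$alpha_n,
    beta_D = params$beta_D * params$beta_dm / params$alpha_d,
    alpha_N = params$alpha_N, alpha_D = params$alpha_D,
    alpha_R = params$alpha_R,
    k_p = params$k_p, k_d = params$k_d,
    p = params$p, h = params$h,
    S_PF = params$S_PF, S_LI = params$S_LI,
    model_form = "MODEL3")
}
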