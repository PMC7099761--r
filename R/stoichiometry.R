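#' Create a stoichiometry policy
#'
#' @param mode `"redfield"` for the fixed 1:16 P:N uptake ratio, `"lof"` for
#'   the phosphate-dependent line-of-frugality ratio.
#' @param lofSlope,lofIntercept,nToC constants of the variable formulation:
#'   P:C of organic matter is `lofSlope * PO4 + lofIntercept` (permil) and is
#'   divided by a constant N:C of `nToC` (permil). Defaults 6.9, 6 and 144
#'   give `iRfr = (6.9 * PO4 + 6) / 144`, i.e. N:P of organic matter falling
#'   from 24 at zero phosphate and crossing Redfield (16) at
#'   PO4 = 3/6.9 mmol m^-3.
#'
#' @return A [StoichiometryPolicy-class] object.
#' @examples
#' npOM(stoichiometryPolicy("lof"), 0)        # 24, the zero-phosphate maximum
#' npOM(stoichiometryPolicy("redfield"), 0.3) # always 16
#' @export
stoichiometryPolicy <- function(mode = c("lof", "redfield"), lofSlope = 6.9,
                                lofIntercept = 6, nToC = 144) {
  mode <- match.arg(mode)
  new("StoichiometryPolicy", mode = mode, pToN = 1 / 16, lofSlope = lofSlope,
      lofIntercept = lofIntercept, nToC = nToC)
}

#' @describeIn stoichiometryPolicy the policy mode string.
#' @param object,policy a [StoichiometryPolicy-class].
#' @export
policyMode <- function(policy) {
  stopifnot(is(policy, "StoichiometryPolicy"))
  policy@mode
}

setMethod("show", "StoichiometryPolicy", function(object) {
  if (object@mode == "redfield") {
    cat("StoichiometryPolicy: redfield (P:N fixed at 1/16)\n")
  } else {
    cat(sprintf(
      "StoichiometryPolicy: lof (P:N = (%g*PO4 + %g)/%g; N:P_OM %g..%g)\n",
      object@lofSlope, object@lofIntercept, object@nToC,
      object@nToC / object@lofIntercept,
      round(object@nToC / (object@lofSlope * 2 + object@lofIntercept), 2)))
  }
})

.checkPo4 <- function(po4) {
  if (any(!is.finite(po4)))
    stop("`po4` must be finite", call. = FALSE)
  if (any(po4 < 0))
    stop("`po4` must be non-negative (got ", min(po4), ")", call. = FALSE)
  invisible(po4)
}

.checkAlpha <- function(alpha) {
  if (any(!is.finite(alpha)) || any(alpha <= 0))
    stop("half-saturation `alpha` must be a finite positive number",
         call. = FALSE)
  invisible(alpha)
}

#' Internal P:N uptake ratio
#'
#' The molar P:N ratio at which newly produced organic matter draws phosphate
#' per unit nitrogen. Constant 1/16 under the redfield policy; under the
#' line-of-frugality policy it increases linearly with ambient phosphate,
#' `(6.9 * po4 + 6) / 144`, so phytoplankton are "frugal" with phosphorus
#' where it is scarce.
#'
#' @param policy a [StoichiometryPolicy-class].
#' @param po4 ambient phosphate (mmol P m^-3), vectorized, must be >= 0.
#' @return Dimensionless P:N molar ratio(s), strictly positive.
#' @examples
#' iRfr(stoichiometryPolicy("lof"), 0)       # 6/144 = 1/24
#' iRfr(stoichiometryPolicy("lof"), 3 / 6.9) # 1/16, the Redfield crossing
#' @export
iRfr <- function(policy, po4) {
  stopifnot(is(policy, "StoichiometryPolicy"))
  .checkPo4(po4)
  if (policy@mode == "redfield")
    rep_len(policy@pToN, length(po4))
  else
    (policy@lofSlope * po4 + policy@lofIntercept) / policy@nToC
}

#' N:P molar ratio of newly produced organic matter
#'
#' The reciprocal of [iRfr()]. Under the line-of-frugality policy it decreases
#' strictly with phosphate from a supremum of `nToC / lofIntercept` (24 with
#' the default constants) at zero phosphate.
#'
#' @inheritParams iRfr
#' @return Dimensionless N:P molar ratio(s).
#' @export
npOM <- function(policy, po4) {
  stopifnot(is(policy, "StoichiometryPolicy"))
  .checkPo4(po4)
  if (policy@mode == "redfield")
    rep_len(1 / policy@pToN, length(po4))
  else
    policy@nToC / (policy@lofSlope * po4 + policy@lofIntercept)
}

#' Nitrogen limitation factor
#'
#' Squared Michaelis-Menten form on dissolved inorganic nitrogen
#' `D = nh4 + no3`: `D^2 / (alpha^2 + D^2)`. Equals 0.5 exactly when
#' `D == alpha` and lies in `[0, 1)`.
#'
#' @param no3,nh4 nitrate and ammonium concentrations (mmol N m^-3),
#'   vectorized, must be >= 0.
#' @param alpha nutrient half-saturation constant (mmol N m^-3), > 0.
#' @return Dimensionless limitation factor(s) in `[0, 1)`.
#' @export
nLim <- function(no3, nh4, alpha) {
  .checkAlpha(alpha)
  if (any(no3 < 0) || any(nh4 < 0))
    stop("nutrient concentrations must be >= 0", call. = FALSE)
  d <- no3 + nh4
  d^2 / (alpha^2 + d^2)
}

#' Phosphorus limitation factor
#'
#' Squared Michaelis-Menten form mirroring [nLim()], with the half-saturation
#' rescaled from nitrogen to phosphorus units by the P:N ratio:
#' `po4^2 / ((pToN * alpha)^2 + po4^2)`. Under a line-of-frugality policy
#' `pToN` itself depends on `po4`, which moves the limitation threshold with
#' the ambient phosphate.
#'
#' @param po4 phosphate concentration (mmol P m^-3), >= 0.
#' @param alpha nutrient half-saturation constant in nitrogen units
#'   (mmol N m^-3), > 0.
#' @param pToN P:N molar ratio used to rescale `alpha` (from [iRfr()]).
#' @return Dimensionless limitation factor(s) in `[0, 1)`.
#' @export
pLim <- function(po4, alpha, pToN) {
  .checkAlpha(alpha)
  .checkPo4(po4)
  if (any(pToN <= 0)) stop("`pToN` must be > 0", call. = FALSE)
  h <- pToN * alpha
  po4^2 / (h^2 + po4^2)
}

#' Liebig-minimum nutrient limitation
#'
#' Evaluates both limitation factors at the ambient nutrient concentrations
#' (with the P:N ratio taken from the policy at the same phosphate) and
#' selects the smaller as the limiting factor. Under the line-of-frugality
#' policy the nitrogen/phosphorus decision boundary therefore shifts with
#' phosphate.
#'
#' @inheritParams nLim
#' @param po4 phosphate (mmol P m^-3), >= 0.
#' @param policy a [StoichiometryPolicy-class].
#' @return A `data.frame` with columns `nlim`, `plim`, `limiting`
#'   (`"nitrogen"`, `"phosphorus"` or `"tie"`) and `factor = pmin(nlim, plim)`.
#' @export
limitation <- function(no3, nh4, po4, alpha, policy) {
  nl <- nLim(no3, nh4, alpha)
  pl <- pLim(po4, alpha, iRfr(policy, po4))
  data.frame(
    nlim = nl, plim = pl,
    limiting = ifelse(nl < pl, "nitrogen",
                      ifelse(pl < nl, "phosphorus", "tie")),
    factor = pmin(nl, pl))
}

#' Inorganic N:P ratio of seawater
#'
#' Nitrate-to-phosphate molar ratio, `no3 / po4` (nitrate only; ammonium is
#' not part of this diagnostic). Where `po4 == 0` the ratio is undefined and
#' the sentinel `NA_real_` is returned rather than infinity, so gridded
#' diagnostics never abort.
#'
#' @param no3,po4 concentrations (mmol m^-3), vectorized.
#' @return Numeric vector; `NA_real_` where phosphate is zero.
#' @export
npWater <- function(no3, po4) {
  ifelse(po4 > 0, no3 / po4, NA_real_)
}
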