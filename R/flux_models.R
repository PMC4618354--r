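# Intercellular / inter-compartment flux laws.
#
# Sign convention (used everywhere in the package): a positive flux moves
# auxin from the first-named compartment to the second-named one, i.e.
# basipetally for axial faces and outward for lateral faces. Fluxes are per
# unit membrane area, in concentration * cm/s; concentrations are in
# arbitrary "model units" (only ratios to Km matter under saturation).

check_nonneg_conc <- function(...) {
  vals <- c(...)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("concentrations must be finite and nonnegative", call. = FALSE)
}

#' Linear polar + diffusion-like flux parameters
#'
#' Parameters of the basic intercellular flux rule
#' \eqn{\phi = p a_{up} + q (a_{up} - a_{down})}: a polar (directional)
#' permeability `p` and a symmetric, diffusion-like permeability `q`,
#' both in cm/s.
#'
#' @param p polar permeability (cm/s), `>= 0`.
#' @param q diffusion-like permeability (cm/s), `>= 0`.
#' @return an object of class `"linear_flux_params"`.
#' @seealso [linear_flux()], [derive_pq()]
#' @export
linear_flux_params <- function(p, q) {
  stopifnot(is.numeric(p), is.numeric(q), length(p) == 1, length(q) == 1)
  if (!is.finite(p) || !is.finite(q) || p < 0 || q < 0)
    stop("p and q must be finite and >= 0", call. = FALSE)
  structure(list(p = p, q = q), class = "linear_flux_params")
}

#' Carrier-based transporter parameters for one cell-cell interface
#'
#' Describes the exporter/importer arrangement across one apoplastic gap:
#' total exporter permeability `alpha1` on the basal face of the upper cell,
#' `alpha2` on the apical face of the lower cell, a combined importer +
#' passive permeability `beta` (assumed equal on both faces), and the
#' apoplast width `L0` and diffusion constant `D0` that set the
#' dimensionless resistance `r = beta * L0 / D0`.
#'
#' @param alpha1,alpha2 exporter permeabilities (cm/s), `>= 0`.
#' @param beta importer + passive permeability (cm/s), `>= 0`.
#' @param L0 apoplast width (cm), `>= 0`.
#' @param D0 apoplast diffusion constant (cm^2/s), `> 0`.
#' @return an object of class `"transporter_params"` with derived field `r`.
#' @export
transporter_params <- function(alpha1, alpha2, beta, L0, D0) {
  vals <- c(alpha1 = alpha1, alpha2 = alpha2, beta = beta, L0 = L0, D0 = D0)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all transporter parameters must be finite and >= 0", call. = FALSE)
  if (D0 <= 0)
    stop("apoplast diffusion constant D0 must be > 0", call. = FALSE)
  structure(list(alpha1 = alpha1, alpha2 = alpha2, beta = beta,
                 L0 = L0, D0 = D0, r = beta * L0 / D0),
            class = "transporter_params")
}

#' Michaelis-Menten saturating flux parameters
#'
#' Directional saturating flux across a face,
#' \eqn{\phi = \kappa_1 a_1/(K_m + a_1) - \kappa_2 a_2/(K_m + a_2)}.
#' The maximal fluxes can be given directly as `kappa1`/`kappa2`
#' (concentration * cm/s) or, for a coupling that is linear with
#' permeability `s` at low concentration, via `s` so that
#' `kappa1 = kappa2 = Km * s`.
#'
#' @param kappa1,kappa2 maximal directional fluxes; omit when `s` is given.
#' @param Km half-saturation concentration, `> 0`.
#' @param s optional low-concentration permeability (cm/s); sets
#'   `kappa1 = kappa2 = Km * s`.
#' @return an object of class `"saturating_flux_params"`.
#' @export
saturating_flux_params <- function(kappa1 = NULL, kappa2 = NULL, Km, s = NULL) {
  if (!is.numeric(Km) || length(Km) != 1 || !is.finite(Km) || Km <= 0)
    stop("Km must be a finite value > 0", call. = FALSE)
  if (!is.null(s)) {
    if (!is.null(kappa1) || !is.null(kappa2))
      stop("give either s or (kappa1, kappa2), not both", call. = FALSE)
    if (!is.finite(s) || s < 0) stop("s must be finite and >= 0", call. = FALSE)
    kappa1 <- kappa2 <- Km * s
  }
  if (is.null(kappa1) || is.null(kappa2))
    stop("kappa1 and kappa2 (or s) are required", call. = FALSE)
  if (any(!is.finite(c(kappa1, kappa2))) || kappa1 < 0 || kappa2 < 0)
    stop("kappa1 and kappa2 must be finite and >= 0", call. = FALSE)
  structure(list(kappa1 = kappa1, kappa2 = kappa2, Km = Km),
            class = "saturating_flux_params")
}

#' Asymmetric lateral flux parameters
#'
#' Lateral coupling with different permeabilities in the two directions,
#' \eqn{\phi = s_{fwd} a_1 - s_{rev} a_2}. With `s_fwd == s_rev == s` this
#' reduces to the symmetric lateral coupling \eqn{\phi = s (a_1 - a_2)}.
#' Used e.g. for the tonoplast, where the cytosol-to-vacuole and
#' vacuole-to-cytosol permeabilities differ because of the pH difference.
#'
#' @param s_fwd permeability from compartment 1 to compartment 2 (cm/s).
#' @param s_rev permeability from compartment 2 to compartment 1 (cm/s).
#' @return an object of class `"asymmetric_lateral_params"`.
#' @export
asymmetric_lateral_params <- function(s_fwd, s_rev) {
  if (any(!is.finite(c(s_fwd, s_rev))) || s_fwd < 0 || s_rev < 0)
    stop("s_fwd and s_rev must be finite and >= 0", call. = FALSE)
  structure(list(s_fwd = s_fwd, s_rev = s_rev),
            class = "asymmetric_lateral_params")
}

#' Chemiosmotic context for passive weak-acid permeation
#'
#' Auxin (IAA) is a weak acid (carboxyl pK 4.7); only the protonated form
#' crosses membranes passively. The effective passive permeability of a
#' compartment boundary therefore depends on the compartment pH and on the
#' membrane permeability to the protonated form, `P_IAAH`.
#'
#' @param pH compartment pH.
#' @param pK auxin carboxyl pK (default 4.7).
#' @param P_IAAH membrane permeability to protonated auxin (cm/s), `> 0`.
#' @return an object of class `"chemiosmotic_context"`.
#' @export
chemiosmotic_context <- function(pH, pK = 4.7, P_IAAH) {
  if (!is.finite(P_IAAH) || P_IAAH <= 0)
    stop("P_IAAH must be finite and > 0", call. = FALSE)
  structure(list(pH = pH, pK = pK, P_IAAH = P_IAAH),
            class = "chemiosmotic_context")
}

#' Linear polar + diffusion-like intercellular flux
#'
#' \eqn{\phi = p a_{up} + q (a_{up} - a_{down})}. Positive flux is
#' basipetal (from `a_up` towards `a_down`).
#'
#' @param params a [linear_flux_params()] object.
#' @param a_up,a_down nonnegative concentrations in the upstream and
#'   downstream compartments.
#' @return flux per unit area (concentration * cm/s); vectorized over
#'   concentrations.
#' @export
linear_flux <- function(params, a_up, a_down) {
  stopifnot(inherits(params, "linear_flux_params"))
  check_nonneg_conc(a_up, a_down)
  params$p * a_up + params$q * (a_up - a_down)
}

#' Flux across a cell-cell interface from transporter permeabilities
#'
#' Eliminating the apoplastic concentrations from the exporter/importer
#' balance gives \eqn{\phi = (\alpha_1 a_1 - \alpha_2 a_2)/(2 + r)} with
#' \eqn{r = \beta L_0 / D_0}. Algebraically identical to [linear_flux()]
#' with the permeabilities returned by [derive_pq()].
#'
#' @param params a [transporter_params()] object.
#' @param a1,a2 nonnegative cytoplasmic concentrations at the basal end of
#'   the upper cell and the apical end of the lower cell.
#' @return flux per unit area; vectorized over concentrations.
#' @export
transporter_flux <- function(params, a1, a2) {
  stopifnot(inherits(params, "transporter_params"))
  check_nonneg_conc(a1, a2)
  (params$alpha1 * a1 - params$alpha2 * a2) / (2 + params$r)
}

#' Reduce transporter permeabilities to (p, q) and the ratio q/p
#'
#' The carrier-based interface law maps onto the linear law with
#' \eqn{p = (\alpha_1 - \alpha_2)/(2 + r)}, \eqn{q = \alpha_2/(2 + r)},
#' so the diffusion-to-polar ratio is
#' \eqn{q/p = \alpha_2/(\alpha_1 - \alpha_2)} independently of `r`.
#' When `alpha1 == alpha2` the interface is apolar: `p = 0` and the ratio
#' is infinite (flagged with a warning).
#'
#' @param params a [transporter_params()] object with `alpha1 >= alpha2`.
#' @return a [linear_flux_params()] object with an extra field `qp_ratio`.
#' @export
derive_pq <- function(params) {
  stopifnot(inherits(params, "transporter_params"))
  if (params$alpha1 < params$alpha2)
    stop("alpha1 must be >= alpha2 for a nonnegative polar permeability",
         call. = FALSE)
  denom <- 2 + params$r
  p <- (params$alpha1 - params$alpha2) / denom
  q <- params$alpha2 / denom
  out <- linear_flux_params(p, q)
  if (params$alpha1 == params$alpha2) {
    if (params$alpha2 > 0)
      warning("alpha1 == alpha2: apolar exporters, p = 0 and q/p is infinite",
              call. = FALSE)
    out$qp_ratio <- if (params$alpha2 > 0) Inf else NaN
  } else {
    out$qp_ratio <- params$alpha2 / (params$alpha1 - params$alpha2)
  }
  out
}

#' Michaelis-Menten saturating flux
#'
#' \eqn{\phi = \kappa_1 a_1/(K_m + a_1) - \kappa_2 a_2/(K_m + a_2)}.
#' For `a << Km` this is linear with permeability `kappa/Km`; for
#' `a >> Km` the directional flux saturates at `kappa`.
#'
#' @param params a [saturating_flux_params()] object.
#' @param a1,a2 nonnegative concentrations.
#' @return flux per unit area; vectorized over concentrations.
#' @export
saturating_flux <- function(params, a1, a2) {
  stopifnot(inherits(params, "saturating_flux_params"))
  check_nonneg_conc(a1, a2)
  params$kappa1 * a1 / (params$Km + a1) - params$kappa2 * a2 / (params$Km + a2)
}

#' Asymmetric lateral flux
#'
#' \eqn{\phi = s_{fwd} a_1 - s_{rev} a_2}; at zero net flux the
#' equilibrium concentration ratio is \eqn{a_2/a_1 = s_{fwd}/s_{rev}}.
#'
#' @param params an [asymmetric_lateral_params()] object.
#' @param a1,a2 nonnegative concentrations.
#' @return flux per unit area; vectorized over concentrations.
#' @export
asymmetric_lateral_flux <- function(params, a1, a2) {
  stopifnot(inherits(params, "asymmetric_lateral_params"))
  check_nonneg_conc(a1, a2)
  params$s_fwd * a1 - params$s_rev * a2
}

#' Protonated fraction of a weak acid (Henderson-Hasselbalch)
#'
#' \eqn{f = 1/(1 + 10^{pH - pK})}. At apoplastic pH near the pK about half
#' of the auxin is protonated; at cytoplasmic pH 7.2 about 99.7% is in the
#' charged (membrane-impermeant) anion form.
#'
#' @param pH compartment pH (vectorized).
#' @param pK acid dissociation constant (default 4.7 for the auxin
#'   carboxyl group).
#' @return fraction in `[0, 1]`.
#' @export
protonated_fraction <- function(pH, pK = 4.7) {
  1 / (1 + 10^(pH - pK))
}

#' Effective passive permeability of a compartment boundary
#'
#' Total-auxin permeability out of a compartment at a given pH:
#' `P_IAAH * protonated_fraction(pH, pK)`. Only the protonated fraction
#' can cross the membrane passively, so the higher the pH the smaller the
#' effective permeability (ion trapping).
#'
#' @param ctx a [chemiosmotic_context()] object.
#' @return permeability in cm/s.
#' @examples
#' # cytosol (pH 7.2) and vacuole (pH 5.5) with P_IAAH = 4e-5 cm/s
#' passive_permeability(chemiosmotic_context(7.2, P_IAAH = 4e-5))
#' passive_permeability(chemiosmotic_context(5.5, P_IAAH = 4e-5))
#' @export
passive_permeability <- function(ctx) {
  stopifnot(inherits(ctx, "chemiosmotic_context"))
  ctx$P_IAAH * protonated_fraction(ctx$pH, ctx$pK)
}
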