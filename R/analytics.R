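# Closed-form pulse kinetics and derived quantities.
#
# The measurable summary of a travelling auxin pulse is its velocity v
# (mm/hr) and spreading rate rho = d(variance)/dt (mm^2/hr). For a single
# file of well-mixed cells of length L with flux phi = p a + q (a_up -
# a_down), v = p and rho = L (p + 2 q); with finite intracellular diffusion
# D these become 1/v = 1/p + (L/2D)(1 + 2 q/p) and rho <= L v (1 + 2 q/p).
# The functions here evaluate these relations, invert them to infer q/p
# from measurements, and compute the effective lateral diffusion constant
# of coupled channels.

#' Pulse kinetics of the well-mixed single-channel model
#'
#' For a row of well-mixed cells of length `L` with linear flux
#' (permeabilities `p`, `q`), the pulse velocity is `v = p` and the
#' spreading rate is `rho = L * (p + 2 q)`. The relation is
#' unit-agnostic: pass `p`, `q` in mm/hr and `L` in mm to get `v` in
#' mm/hr and `rho` in mm^2/hr (or use CGS throughout).
#'
#' @param p polar permeability, `> 0`.
#' @param q diffusion-like permeability, `>= 0`.
#' @param L cell (or computational-unit) length.
#' @return a list of class `"kinetics_pair"` with fields `v` and `rho` in
#'   the units implied by the inputs.
#' @examples
#' simple_kinetics(p = 9, q = 0, L = 2)  # 2 mm segments: rho = 18 mm^2/hr
#' @export
simple_kinetics <- function(p, q, L) {
  stopifnot(p > 0, q >= 0, L > 0)
  structure(list(v = p, rho = L * (p + 2 * q)), class = "kinetics_pair")
}

#' Pulse velocity with finite intracellular diffusion
#'
#' Solves `1/v = 1/p + (L / 2 D) * (1 + 2 q / p)` for `v`. Use consistent
#' CGS units (cm/s, cm, cm^2/s). As `D -> Inf` this recovers `v = p`;
#' for `q = 0` and `p -> Inf` the velocity approaches the
#' diffusion-limited bound `2 D / L`.
#'
#' @param p polar permeability (cm/s), `> 0`.
#' @param q diffusion-like permeability (cm/s), `>= 0`.
#' @param L cell length (cm).
#' @param D intracellular diffusion constant (cm^2/s), `> 0`.
#' @return velocity in cm/s.
#' @export
velocity_with_diffusion <- function(p, q, L, D) {
  stopifnot(p > 0, q >= 0, L > 0, D > 0)
  1 / (1 / p + (L / (2 * D)) * (1 + 2 * q / p))
}

#' Upper bound on the spreading rate of a single channel
#'
#' `rho <= L * v * (1 + 2 * q/p)`, approached as the intracellular
#' diffusion constant becomes large. Unit-agnostic (e.g. `v` mm/hr and
#' `L` mm give mm^2/hr).
#'
#' @param v pulse velocity, `> 0`.
#' @param L cell length, `> 0`.
#' @param qp_ratio ratio q/p, `>= 0`.
#' @return maximal spreading rate.
#' @export
spreading_bound <- function(v, L, qp_ratio) {
  stopifnot(v > 0, L > 0, qp_ratio >= 0)
  L * v * (1 + 2 * qp_ratio)
}

#' Infer the diffusion-to-polar permeability ratio from pulse kinetics
#'
#' Inverts `rho = L * v * (1 + 2 q/p)` to give
#' `q/p = (rho / (L v) - 1) / 2`. With measured `v` (mm/hr), `rho`
#' (mm^2/hr) and a cell length `L` (mm) this is the per-cell ratio of
#' diffusion-like to polar permeability needed to explain the observed
#' spreading. A measured `rho < L v` is inconsistent with the model; the
#' (negative) value is returned with a warning rather than an error,
#' because measured spreading rates carry error bars.
#'
#' @param v pulse velocity, `> 0`.
#' @param rho spreading rate, `>= 0` (same length/time units as `v`).
#' @param L cell length (same length unit).
#' @return the dimensionless ratio q/p.
#' @examples
#' infer_qp(v = 10.7, rho = 26.0, L = 0.1)  # ~11.7
#' @export
infer_qp <- function(v, rho, L) {
  stopifnot(v > 0, rho >= 0, L > 0)
  qp <- (rho / (L * v) - 1) / 2
  if (qp < 0)
    warning("rho < L*v: inferred q/p is negative (model inconsistency)",
            call. = FALSE)
  qp
}

#' Minimum intracellular diffusion constant consistent with a spreading rate
#'
#' In the limit of a very fast polar pump (`p -> Inf`) with the spreading
#' bound at equality, the velocity relation reduces to `rho = 2 D`, so the
#' smallest diffusion constant able to produce a given spreading rate is
#' `D_min = rho / 2`. The result is converted from mm^2/hr to cm^2/s.
#'
#' Derivation: at equality rho = L v (1 + 2 q/p) and
#' 1/v = 1/p + (L/2D)(1 + 2 q/p); substituting the first into the second
#' gives 1/v = 1/p + rho/(2 D v), i.e. D = (rho/2) / (1 - v/p), minimized
#' over p at p -> Inf, where D = rho/2.
#'
#' @param v pulse velocity (mm/hr), `> 0` (enters only through the
#'   consistency requirement; `D_min` depends on `rho` alone).
#' @param rho spreading rate (mm^2/hr), `> 0`.
#' @return minimal diffusion constant in cm^2/s.
#' @examples
#' min_diffusion(v = 9, rho = 10)  # ~1.4e-5 cm^2/s
#' @export
min_diffusion <- function(v, rho) {
  stopifnot(v > 0, rho > 0)
  mm2hr_to_cm2s(rho / 2)
}

#' Effective lateral diffusion constant of coupled channels
#'
#' Lateral movement through a tissue combines diffusion within cells
#' (constant `D`) in series with membrane crossing (permeability `s` over
#' cell width `w`): `1/D_eff = 1/D + 1/(w s)`. With `s = 0` there is no
#' lateral movement and `D_eff = 0`.
#'
#' @param D intracellular diffusion constant (cm^2/s), `> 0`.
#' @param w cell width (cm), `> 0`.
#' @param s lateral membrane permeability (cm/s), `>= 0`.
#' @return effective diffusion constant in cm^2/s.
#' @examples
#' effective_diffusion(5e-6, 2e-3, 7.1e-6)  # ~1.4e-8 cm^2/s
#' @export
effective_diffusion <- function(D, w, s) {
  stopifnot(D > 0, w > 0, s >= 0)
  if (s == 0) return(0)
  1 / (1 / D + 1 / (w * s))
}

#' Lateral permeability matching membrane crossing to cytoplasmic diffusion
#'
#' The "engineering" matching condition `w * s = D`: beyond this point
#' increasing the membrane permeability `s` gives rapidly diminishing
#' gains in the effective lateral diffusion constant. Returns `s = D / w`.
#'
#' @param D intracellular diffusion constant (cm^2/s), `> 0`.
#' @param w cell width (cm), `> 0`.
#' @return matched permeability in cm/s.
#' @examples
#' matched_permeability(5e-6, 2e-3)  # 2.5e-3 cm/s
#' @export
matched_permeability <- function(D, w) {
  stopifnot(D > 0, w > 0)
  D / w
}

#' Characteristic lateral diffusion time over a distance
#'
#' `t = L^2 / D_eff`, reported in hours, for a distance given in mm and an
#' effective diffusion constant in cm^2/s.
#'
#' @param L_dist distance (mm), `> 0`.
#' @param D_eff effective diffusion constant (cm^2/s), `> 0`.
#' @return time in hours.
#' @examples
#' diffusion_time(1, 2.5e-6)  # ~1.1 hr over 1 mm
#' @export
diffusion_time <- function(L_dist, D_eff) {
  stopifnot(L_dist > 0, D_eff > 0)
  mm_to_cm(L_dist)^2 / D_eff / 3600
}

#' Quadratic scaling prediction for the effective diffusion constant
#'
#' If pulse broadening is controlled by the time to diffuse laterally
#' across the whole group of `n` channels, models of different width give
#' similar pulses when `D_eff` scales with the square of the number of
#' channels: `D_eff(n) = D_eff(n_ref) * (n / n_ref)^2`.
#'
#' @param D_eff_ref reference effective diffusion constant (cm^2/s).
#' @param n_ref reference channel count.
#' @param n channel count to predict for (vectorized).
#' @return predicted effective diffusion constant(s) in cm^2/s.
#' @export
quadratic_scaling_prediction <- function(D_eff_ref, n_ref, n) {
  stopifnot(D_eff_ref > 0, n_ref > 0, all(n > 0))
  D_eff_ref * (n / n_ref)^2
}

#' Rescale a lateral permeability for a channel of different width
#'
#' Sub-cellular compartments (cytoplasmic sheet, half-vacuole) are
#' narrower than the 20-micron reference cell file; reproducing the
#' dynamics of the best-fitting reference model requires scaling the
#' lateral permeability in proportion to the compartment width:
#' `s = s_ref * (d / w_ref)`.
#'
#' @param s_ref reference permeability (cm/s).
#' @param d compartment width (micron, or any unit shared with `w_ref`).
#' @param w_ref reference width (default 20 micron).
#' @return rescaled permeability in the units of `s_ref`.
#' @examples
#' rescale_width_permeability(7.1e-6, 1)  # cytoplasmic sheet, ~3.6e-7 cm/s
#' rescale_width_permeability(7.1e-6, 9)  # half-vacuole, ~3.2e-6 cm/s
#' @export
rescale_width_permeability <- function(s_ref, d, w_ref = 20) {
  stopifnot(s_ref > 0, d > 0, w_ref > 0)
  s_ref * (d / w_ref)
}

#' Vacuole-to-cytoplasm volume ratio of the brick-shaped model cell
#'
#' The model cell is a brick `cell_w` x `cell_w` x `cell_L` with the
#' cytoplasm forming a layer of depth `cytoplasm_depth` just inside the
#' boundary and the vacuole filling the rest:
#' vacuole volume `(w - 2d)^2 (L - 2d)` against the remaining cytoplasmic
#' volume. Defaults (100 x 20 x 20 micron cell, 1 micron layer) give about
#' 4:1.
#'
#' @param cell_L cell length (micron, default 100).
#' @param cell_w cell width (micron, default 20).
#' @param cytoplasm_depth cytoplasmic layer depth (micron, default 1);
#'   must be `<= cell_w / 2` (at the limit there is no vacuole and the
#'   ratio is 0).
#' @return the vacuole:cytoplasm volume ratio (dimensionless).
#' @export
vacuole_geometry <- function(cell_L = 100, cell_w = 20, cytoplasm_depth = 1) {
  stopifnot(cell_L > 0, cell_w > 0, cytoplasm_depth >= 0,
            cytoplasm_depth <= cell_w / 2)
  vac <- max(0, cell_w - 2 * cytoplasm_depth)^2 *
    max(0, cell_L - 2 * cytoplasm_depth)
  cell <- cell_w^2 * cell_L
  cyt <- cell - vac
  if (cyt <= 0) return(Inf)
  vac / cyt
}

#' @export
print.kinetics_pair <- function(x, ...) {
  cat(sprintf("pulse kinetics: v = %g, rho = %g (units as supplied)\n",
              x$v, x$rho))
  invisible(x)
}
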