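.as_geometry <- function(geometry) {
  if (inherits(geometry, "fibril_geometry")) return(geometry)
  if (is.numeric(geometry) && length(geometry) == 1)
    return(fibril_geometry(geometry))
  stop("`geometry` must be a fibril_geometry object or a diameter in nm",
       call. = FALSE)
}

.default_barrier_uf <- function(params)
  barrier_to_pullout(published_barriers()[["uncrosslinked"]], params)

.default_barrier_cf <- function(params)
  barrier_to_pullout(published_barriers()[["crosslinked"]], params)

# stage endpoints shared by the fibril laws, all in (strain, Pa)
.fibril_stages <- function(geometry, params, barrier_uf, barrier_cf) {
  u <- unfolding_endpoint(params)
  A <- molecule_area(params)
  k <- bond_law_constants(params)
  cp <- geometry$c_pack
  cs <- geometry$c_surf

  eps2_uf <- params$n_beads * (params$r0 + barrier_uf$delta_r) / params$L0 - 1
  sigma2_uf <- u$sigma1_Pa + cp * cs * barrier_uf$F_pull_N / A
  E2_uf <- (sigma2_uf - u$sigma1_Pa) / (eps2_uf - u$eps1)

  eps2_cf <- params$n_beads * params$r1 / params$L0 - 1
  F2 <- force_kcalmolA_to_N(params$KT0 * (params$r1 - params$r0))
  sigma2_cf <- u$sigma1_Pa + cp * F2 / A          # no Csurf: all molecules held
  E2_cf <- (sigma2_cf - u$sigma1_Pa) / (eps2_cf - u$eps1)

  eps3_cf <- params$n_beads * barrier_cf$r_sliding / params$L0 - 1
  sigma3_cf <- u$sigma1_Pa + cp * barrier_cf$F_pull_N / A
  E3_cf <- (sigma3_cf - sigma2_cf) / (eps3_cf - eps2_cf)

  list(u = u, eps2_uf = eps2_uf, sigma2_uf = sigma2_uf, E2_uf = E2_uf,
       eps2_cf = eps2_cf, sigma2_cf = sigma2_cf, E2_cf = E2_cf,
       eps3_cf = eps3_cf, sigma3_cf = sigma3_cf, E3_cf = E3_cf)
}

#' Stress-strain law of an uncrosslinked collagen fibril
#'
#' Three regimes: uncoiling (identical to the single molecule),
#' backbone stretching until the bond force reaches the sliding
#' pull-out force, then a perfectly plastic plateau — once sliding
#' starts the bond forces stay constant.  The plateau stress is the
#' pull-out force per molecular cross-section, weighted by the
#' hexagonal packing fraction and by the bulk-molecule fraction
#' `Csurf(phi)` (surface molecules are not radially confined and carry
#' no sliding resistance): `sigma2 = sigma1 + Cpack Csurf F / A_mol`.
#'
#' @param geometry A [fibril_geometry()] or a fibril diameter in nm.
#' @param params A [molecule_params()] object.
#' @param barrier_uf A [barrier_to_pullout()] result in the harmonic
#'   regime; defaults to the published relaxed barrier (11.36
#'   kcal/mol).
#' @return A [stress_strain_curve()] with segments unfold / stretch /
#'   plateau.
#' @examples
#' fibril_summary(uncrosslinked_curve(25))$UTS_Pa / 1e6   # ~445 MPa
#' @export
uncrosslinked_curve <- function(geometry, params = molecule_params(),
                                barrier_uf = NULL) {
  geometry <- .as_geometry(geometry)
  stopifnot(inherits(params, "molecule_params"))
  if (is.null(barrier_uf)) barrier_uf <- .default_barrier_uf(params)
  stopifnot(inherits(barrier_uf, "barrier_result"))
  if (barrier_uf$regime != "harmonic")
    stop("uncrosslinked sliding requires a harmonic-regime barrier ",
         "(bond stays below r1)", call. = FALSE)
  st <- .fibril_stages(geometry, params, barrier_uf,
                       .default_barrier_cf(params))
  seg <- data.frame(
    label = c("unfold", "stretch_pre_hyper", "plateau"),
    eps_start = c(0, st$u$eps1, st$eps2_uf),
    eps_end = c(st$u$eps1, st$eps2_uf, Inf),
    sigma_start = c(0, st$u$sigma1_Pa, st$sigma2_uf),
    modulus = c(st$u$E1_Pa, st$E2_uf, 0),
    stringsAsFactors = FALSE
  )
  stress_strain_curve(seg, metadata = list(model = "fibril_uncrosslinked",
                                           phi = geometry$phi, beta = 0))
}

#' Stress-strain law of a fully crosslinked collagen fibril
#'
#' With every molecule terminal crosslinked, all molecules (surface
#' included) are anchored, so `Csurf` drops out and the stretching
#' stage runs through both bond branches: soft stretching to the
#' hyperelastic onset `eps2 = n r1 / L0 - 1`, stiff stretching to the
#' sliding strain `eps3 = n r_sliding / L0 - 1` set by the crosslinked
#' barrier.  There the crosslinks break simultaneously and the stress
#' drops instantaneously to the uncrosslinked plateau of the same
#' diameter.
#'
#' @inheritParams uncrosslinked_curve
#' @param barrier_cf A [barrier_to_pullout()] result that resolves to
#'   the hyperelastic regime; defaults to the published crosslinked
#'   barrier (187 kcal/mol).
#' @param barrier_uf Barrier for the post-drop plateau (defaults to the
#'   published 11.36 kcal/mol).
#' @return A [stress_strain_curve()] with a terminal stress drop.
#' @export
crosslinked_curve <- function(geometry, params = molecule_params(),
                              barrier_cf = NULL, barrier_uf = NULL) {
  geometry <- .as_geometry(geometry)
  stopifnot(inherits(params, "molecule_params"))
  if (is.null(barrier_cf)) barrier_cf <- .default_barrier_cf(params)
  if (is.null(barrier_uf)) barrier_uf <- .default_barrier_uf(params)
  stopifnot(inherits(barrier_cf, "barrier_result"),
            inherits(barrier_uf, "barrier_result"))
  if (barrier_cf$regime != "hyperelastic")
    stop("crosslinked sliding must resolve to the hyperelastic regime ",
         "(r0 + delta_r > r1)", call. = FALSE)
  if (barrier_cf$delta_E <= barrier_uf$delta_E)
    stop("crosslinked barrier must exceed the uncrosslinked barrier",
         call. = FALSE)
  st <- .fibril_stages(geometry, params, barrier_uf, barrier_cf)
  seg <- data.frame(
    label = c("unfold", "stretch_pre_hyper", "stretch_post_hyper", "plateau"),
    eps_start = c(0, st$u$eps1, st$eps2_cf, st$eps3_cf),
    eps_end = c(st$u$eps1, st$eps2_cf, st$eps3_cf, Inf),
    sigma_start = c(0, st$u$sigma1_Pa, st$sigma2_cf, st$sigma2_uf),
    modulus = c(st$u$E1_Pa, st$E2_cf, st$E3_cf, 0),
    stringsAsFactors = FALSE
  )
  stress_strain_curve(seg, metadata = list(model = "fibril_crosslinked",
                                           phi = geometry$phi, beta = 1))
}

#' Stress-strain law of a partially crosslinked fibril
#'
#' A molecule resists sliding like a crosslinked one only if both of
#' its terminals are crosslinked; with terminal occupancy `beta` that
#' happens with probability `alpha = beta^2` (two independent "coin
#' flips").  The fibril stress is the pointwise mixture
#' `sigma = beta^2 sigma_CF + (1 - beta^2) sigma_UF`, assembled here in
#' its explicit five-branch piecewise-linear form.  At `beta = 0` and
#' `beta = 1` the pure laws are returned.
#'
#' @inheritParams crosslinked_curve
#' @param beta Crosslink density: fraction of molecule terminals
#'   occupied by a crosslink, in \[0, 1\].
#' @return A [stress_strain_curve()].
#' @export
partial_curve <- function(geometry, beta, params = molecule_params(),
                          barrier_uf = NULL, barrier_cf = NULL) {
  stopifnot(is.numeric(beta), length(beta) == 1)
  if (beta < 0 || beta > 1)
    stop("`beta` must lie in [0, 1]", call. = FALSE)
  geometry <- .as_geometry(geometry)
  if (is.null(barrier_uf)) barrier_uf <- .default_barrier_uf(params)
  if (is.null(barrier_cf)) barrier_cf <- .default_barrier_cf(params)
  if (beta == 0)
    return(uncrosslinked_curve(geometry, params, barrier_uf))
  if (beta == 1)
    return(crosslinked_curve(geometry, params, barrier_cf, barrier_uf))
  if (barrier_cf$delta_E <= barrier_uf$delta_E)
    stop("crosslinked barrier must exceed the uncrosslinked barrier",
         call. = FALSE)
  if (barrier_uf$regime != "harmonic")
    stop("uncrosslinked sliding requires a harmonic-regime barrier ",
         "(bond stays below r1)", call. = FALSE)
  if (barrier_cf$regime != "hyperelastic")
    stop("crosslinked sliding must resolve to the hyperelastic regime ",
         "(r0 + delta_r > r1)", call. = FALSE)

  st <- .fibril_stages(geometry, params, barrier_uf, barrier_cf)
  a <- beta^2
  u <- st$u
  # branch starts follow from the mixture evaluated at each breakpoint
  s3 <- (1 - a) * st$sigma2_uf +
    a * (u$sigma1_Pa + st$E2_cf * (st$eps2_uf - u$eps1))
  s4 <- (1 - a) * st$sigma2_uf + a * st$sigma2_cf
  seg <- data.frame(
    label = c("unfold", "stretch_pre_hyper", "stretch_pre_hyper",
              "stretch_post_hyper", "plateau"),
    eps_start = c(0, u$eps1, st$eps2_uf, st$eps2_cf, st$eps3_cf),
    eps_end = c(u$eps1, st$eps2_uf, st$eps2_cf, st$eps3_cf, Inf),
    sigma_start = c(0, u$sigma1_Pa, s3, s4, st$sigma2_uf),
    modulus = c(u$E1_Pa,
                a * st$E2_cf + (1 - a) * st$E2_uf,
                a * st$E2_cf,
                a * st$E3_cf,
                0),
    stringsAsFactors = FALSE
  )
  stress_strain_curve(seg, metadata = list(model = "fibril_partial",
                                           phi = geometry$phi, beta = beta))
}

#' Summary statistics of a fibril (or molecule) stress-strain curve
#'
#' Extracts the ultimate tensile strength (maximum stress), the strain
#' at which it is first attained, and the stage moduli (segment
#' slopes).
#'
#' @param curve A [stress_strain_curve()].
#' @return A one-row data.frame: `phi` (nm, NA for a molecule), `beta`,
#'   `UTS_Pa`, `yield_strain`, `E1_Pa`, `E2_Pa`, `E3_Pa` (NA where the
#'   curve has no post-hyperelastic stage).
#' @export
fibril_summary <- function(curve) {
  stopifnot(inherits(curve, "stress_strain_curve"))
  seg <- curve$segments
  fin <- is.finite(seg$eps_end)
  end_stress <- seg$sigma_start +
    seg$modulus * ifelse(fin, seg$eps_end - seg$eps_start, 0)
  cand_eps <- c(seg$eps_start, seg$eps_end[fin])
  cand_sig <- c(seg$sigma_start, end_stress[fin])
  uts <- max(cand_sig)
  yield <- min(cand_eps[cand_sig >= uts - 1e-9 * max(1, uts)])
  slope_of <- function(lbl) {
    i <- which(seg$label == lbl)
    if (length(i)) seg$modulus[i[1]] else NA_real_
  }
  md <- curve$metadata
  data.frame(
    phi = md$phi %||% NA_real_,
    beta = md$beta %||% NA_real_,
    UTS_Pa = uts,
    yield_strain = yield,
    E1_Pa = slope_of("unfold"),
    E2_Pa = slope_of("stretch_pre_hyper"),
    E3_Pa = slope_of("stretch_post_hyper")
  )
}

#' Parameter sweeps over fibril diameter and crosslink density
#'
#' Convenience wrappers building one [partial_curve()] per parameter
#' value and stacking the [fibril_summary()] rows into a tidy table.
#'
#' @param phi Fibril diameter(s), nm.
#' @param beta Crosslink density value(s) in \[0, 1\].
#' @param params A [molecule_params()] object.
#' @param barrier_uf,barrier_cf Barrier results (defaults: published
#'   values).
#' @return A data.frame with one row per parameter value.
#' @examples
#' sweep_beta(c(0, 0.5, 1), phi = 25)$UTS_Pa / 1e6
#' @export
sweep_diameter <- function(phi, beta = 0, params = molecule_params(),
                           barrier_uf = NULL, barrier_cf = NULL) {
  stopifnot(is.numeric(phi), length(phi) >= 1)
  do.call(rbind, lapply(phi, function(p)
    fibril_summary(partial_curve(p, beta, params, barrier_uf, barrier_cf))))
}

#' @rdname sweep_diameter
#' @export
sweep_beta <- function(beta, phi = 100, params = molecule_params(),
                       barrier_uf = NULL, barrier_cf = NULL) {
  stopifnot(is.numeric(beta), length(beta) >= 1)
  do.call(rbind, lapply(beta, function(b)
    fibril_summary(partial_curve(phi, b, params, barrier_uf, barrier_cf))))
}
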