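# Physical constants used at the unit-conversion boundary.
# Internal computation stays in (kcal/mol, Angstrom); SI only for reporting.
.KCAL_J <- 4184            # 1 kcal in J (thermochemical calorie, exact)
.N_AVOGADRO <- 6.02214076e23

#' Unit conversion factors
#'
#' Fixed conversion table between the internal working units
#' (kcal/mol for energies, Angstrom for lengths, degrees for tabulated
#' angles) and SI.  Round-tripping a value through a factor and its
#' inverse is the identity to better than 1e-12 relative.
#'
#' @return A named list of multiplicative conversion factors:
#'   `kcalmolA_to_N` (kcal mol^-1 A^-1 to newton), `kcalmol_to_J`
#'   (kcal/mol to joule per molecule), `deg_to_rad`, `angstrom_to_m`.
#' @examples
#' us <- unit_system()
#' 1 * us$kcalmolA_to_N   # ~6.9477e-11 N
#' @export
unit_system <- function() {
  list(
    kcalmolA_to_N = (.KCAL_J / .N_AVOGADRO) / 1e-10,
    kcalmol_to_J  = .KCAL_J / .N_AVOGADRO,
    deg_to_rad    = pi / 180,
    angstrom_to_m = 1e-10
  )
}

#' Convert a force from kcal mol^-1 A^-1 to newton
#'
#' The coarse-grained force field works in kcal mol^-1 A^-1; published
#' forces are printed in newton.  1 kcal mol^-1 A^-1 is approximately
#' 6.9477e-11 N.
#'
#' @param f Force in kcal mol^-1 A^-1 (vectorised).
#' @return Force in newton.
#' @export
force_kcalmolA_to_N <- function(f) {
  stopifnot(is.numeric(f), all(is.finite(f)))
  f * (.KCAL_J / .N_AVOGADRO) / 1e-10
}

#' Convert an energy from kcal/mol to joule (per molecule)
#'
#' @param e Energy in kcal/mol (vectorised).
#' @return Energy in joule per molecule.
#' @export
energy_kcalmol_to_J <- function(e) {
  stopifnot(is.numeric(e), all(is.finite(e)))
  e * .KCAL_J / .N_AVOGADRO
}

.deg2rad <- function(x) x * pi / 180

.check_field <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

#' Coarse-grained tropocollagen molecule parameters
#'
#' A tropocollagen molecule (the ~300 nm collagen triple helix) is
#' represented as a chain of `n_beads` beads connected by hyperelastic
#' two-stiffness bonds and harmonic bending angles.  Defaults are the
#' standard mesoscale parameterisation for type I collagen.
#'
#' @param n_beads Number of beads per molecule.
#' @param L0 Molecule length along its principal axis (Angstrom).
#' @param r0 Bond equilibrium distance (Angstrom).
#' @param r1 Critical distance triggering the hyperelastic (stiff)
#'   bond branch (Angstrom).
#' @param rb Bond-breaking distance (Angstrom).
#' @param KT0,KT1 Bond stretching stiffnesses below/above `r1`
#'   (kcal mol^-1 A^-2); `KT1 > KT0`.
#' @param Ktheta Bending stiffness (kcal mol^-1 rad^-2).
#' @param theta0_min,theta0_max Range of equilibrium bending angles
#'   along the molecule (degrees); 180 is a straight chain segment.
#' @param D_mol Effective molecule diameter used for the cross-sectional
#'   area (Angstrom).
#' @param mass_total Molecule mass (g/mol).
#' @param n_amino_acids Number of amino acids in the molecule.
#' @return An object of class `molecule_params`.
#' @examples
#' p <- molecule_params()
#' p$KT1   # 97.66
#' @export
molecule_params <- function(n_beads = 218, L0 = 3011,
                            r0 = 14.00, r1 = 18.20, rb = 21.00,
                            KT0 = 17.13, KT1 = 97.66,
                            Ktheta = 14.98,
                            theta0_min = 164, theta0_max = 180,
                            D_mol = 16.52,
                            mass_total = 287000, n_amino_acids = 3134) {
  p <- list(n_beads = n_beads, L0 = L0, r0 = r0, r1 = r1, rb = rb,
            KT0 = KT0, KT1 = KT1, Ktheta = Ktheta,
            theta0_min = theta0_min, theta0_max = theta0_max,
            D_mol = D_mol, mass_total = mass_total,
            n_amino_acids = n_amino_acids)
  validate_molecule_params(p)
}

validate_molecule_params <- function(p) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  .check_field(all(num),
               paste0("non-numeric molecule parameter(s): ",
                      paste(names(p)[!num], collapse = ", ")))
  .check_field(p$r0 > 0, "`r0` must be positive")
  .check_field(p$r1 > p$r0, "`r1` must exceed `r0`")
  .check_field(p$rb > p$r1, "`rb` must exceed `r1`")
  .check_field(p$KT0 > 0, "`KT0` must be positive")
  .check_field(p$KT1 > p$KT0, "`KT1` must exceed `KT0`")
  .check_field(p$Ktheta > 0, "`Ktheta` must be positive")
  .check_field(p$theta0_min > 0 && p$theta0_min <= p$theta0_max &&
                 p$theta0_max <= 180,
               "`theta0_min`/`theta0_max` must satisfy 0 < min <= max <= 180")
  .check_field(p$n_beads >= 2, "`n_beads` must be at least 2")
  .check_field(p$L0 > 0, "`L0` must be positive")
  .check_field(p$D_mol > 0, "`D_mol` must be positive")
  structure(p, class = "molecule_params")
}

#' Cross-sectional area of a molecule
#'
#' Circular cross-section of diameter `D_mol`, in m^2.  All stresses in
#' the model are forces per this area (with packing/surface corrections
#' at the fibril scale).
#'
#' @param params A [molecule_params()] object.
#' @return Area in m^2.
#' @export
molecule_area <- function(params) {
  stopifnot(inherits(params, "molecule_params"))
  d <- params$D_mol * 1e-10
  pi * d^2 / 4
}

#' Lennard-Jones parameters for intermolecular bead interactions
#'
#' @param epsilon Well depth (kcal/mol).
#' @param sigma Zero-crossing distance (Angstrom); the minimum sits at
#'   `2^(1/6) * sigma`.
#' @return An object of class `lj_params`.
#' @export
lj_params <- function(epsilon = 6.87, sigma = 14.72) {
  .check_field(is.numeric(epsilon) && length(epsilon) == 1 && epsilon > 0,
               "`epsilon` must be a positive number")
  .check_field(is.numeric(sigma) && length(sigma) == 1 && sigma > 0,
               "`sigma` must be a positive number")
  structure(list(epsilon = epsilon, sigma = sigma), class = "lj_params")
}

#' Enzymatic crosslink bond parameters
#'
#' Divalent (immature) crosslinks join a molecule terminal to one
#' neighbouring molecule; trivalent (mature) crosslinks join it to two.
#' Both are modelled with the same hyperelastic two-stiffness bond law
#' as the backbone, with their own constants.
#'
#' @param valency `"divalent"` or `"trivalent"`.
#' @param r0,r1,rb,KT0,KT1 Bond-law constants; defaults are the standard
#'   values for the chosen valency (lengths in Angstrom, stiffnesses in
#'   kcal mol^-1 A^-2).
#' @return An object of class `crosslink_params` (also
#'   `molecule_params`-like for the shared bond fields).
#' @export
crosslink_params <- function(valency = c("divalent", "trivalent"),
                             r0 = NULL, r1 = NULL, rb = NULL,
                             KT0 = NULL, KT1 = NULL) {
  valency <- match.arg(valency)
  def <- switch(valency,
    divalent  = list(r0 = 10.00, r1 = 12.00, rb = 14.68,
                     KT0 = 0.20, KT1 = 41.84),
    trivalent = list(r0 = 8.60, r1 = 12.20, rb = 14.89,
                     KT0 = 0.20, KT1 = 54.60))
  p <- list(r0 = r0 %||% def$r0, r1 = r1 %||% def$r1, rb = rb %||% def$rb,
            KT0 = KT0 %||% def$KT0, KT1 = KT1 %||% def$KT1,
            valency = valency)
  .check_field(p$r0 > 0, "`r0` must be positive")
  .check_field(p$r1 > p$r0, "`r1` must exceed `r0`")
  .check_field(p$rb > p$r1, "`rb` must exceed `r1`")
  .check_field(p$KT0 > 0, "`KT0` must be positive")
  .check_field(p$KT1 > p$KT0, "`KT1` must exceed `KT0`")
  structure(p, class = "crosslink_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load model parameters, optionally overridden from a config file
#'
#' Reads a YAML or JSON configuration with sections `molecule`,
#' `lennard_jones`, `crosslink.divalent` and `crosslink.trivalent`,
#' whose keys are the parameter names of [molecule_params()],
#' [lj_params()] and [crosslink_params()].  Missing sections or keys
#' fall back to the defaults; everything is invariant-checked.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file, or `NULL` for the
#'   defaults.
#' @return A list with elements `molecule`, `lj`, `crosslink_divalent`,
#'   `crosslink_trivalent`.
#' @examples
#' ps <- load_params()
#' ps$crosslink_divalent$rb   # 14.68
#' @export
load_params <- function(path = NULL) {
  cfg <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    ext <- tolower(tools::file_ext(path))
    cfg <- if (ext %in% c("yaml", "yml")) {
      yaml::read_yaml(path)
    } else if (ext == "json") {
      jsonlite::fromJSON(path, simplifyVector = TRUE)
    } else {
      stop("unsupported config format: .", ext, " (use YAML or JSON)",
           call. = FALSE)
    }
  }
  mol_over <- cfg$molecule %||% list()
  lj_over  <- cfg$lennard_jones %||% list()
  cl       <- cfg$crosslink %||% list()

  mol <- do.call(molecule_params, mol_over)
  lj  <- do.call(lj_params, lj_over)
  di  <- do.call(crosslink_params,
                 c(list(valency = "divalent"), cl$divalent %||% list()))
  tri <- do.call(crosslink_params,
                 c(list(valency = "trivalent"), cl$trivalent %||% list()))
  list(molecule = mol, lj = lj,
       crosslink_divalent = di, crosslink_trivalent = tri)
}

#' @export
print.molecule_params <- function(x, ...) {
  cat("Tropocollagen molecule parameters\n")
  cat(sprintf("  %d beads, L0 = %.0f A, bond r0/r1/rb = %.2f/%.2f/%.2f A\n",
              x$n_beads, x$L0, x$r0, x$r1, x$rb))
  cat(sprintf("  KT0 = %.2f, KT1 = %.2f kcal/mol/A^2; Ktheta = %.2f kcal/mol/rad^2\n",
              x$KT0, x$KT1, x$Ktheta))
  cat(sprintf("  theta0 in [%g, %g] deg; D_mol = %.2f A\n",
              x$theta0_min, x$theta0_max, x$D_mol))
  invisible(x)
}

#' @export
print.crosslink_params <- function(x, ...) {
  cat(sprintf("%s enzymatic crosslink: r0/r1/rb = %.2f/%.2f/%.2f A, KT0 = %.2f, KT1 = %.2f kcal/mol/A^2\n",
              x$valency, x$r0, x$r1, x$rb, x$KT0, x$KT1))
  invisible(x)
}

#' @export
print.lj_params <- function(x, ...) {
  cat(sprintf("Lennard-Jones: epsilon = %.2f kcal/mol, sigma = %.2f A (minimum at %.2f A)\n",
              x$epsilon, x$sigma, 2^(1 / 6) * x$sigma))
  invisible(x)
}
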