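#' Published sliding energy barriers
#'
#' Named reference values of the intermolecular energy barrier a bead
#' must cross to slide one lattice site (kcal/mol): the frozen-lattice
#' estimate (`fixed_lattice`), the relaxed estimate for an
#' uncrosslinked environment (`uncrosslinked`), and the relaxed
#' estimate with a divalent crosslink attached (`crosslinked`).  These
#' are the defaults that feed the fibril-scale laws; the estimators in
#' this package are opt-in replacements.
#'
#' @return A named numeric vector (kcal/mol).
#' @export
published_barriers <- function() {
  c(fixed_lattice = 6.29, uncrosslinked = 11.36, crosslinked = 187)
}

# LJ energy of the sliding bead at axial position z against all beads
# of other chains within cutoff.
.sliding_bead_energy <- function(lattice, lj, cutoff, z) {
  xyz <- lattice$xyz
  s <- lattice$sliding
  other <- lattice$chain != lattice$chain[s]
  dx <- xyz[other, 1] - xyz[s, 1]
  dy <- xyz[other, 2] - xyz[s, 2]
  dz <- xyz[other, 3] - z
  d <- sqrt(dx^2 + dy^2 + dz^2)
  d <- d[d <= cutoff]
  sum(lj_energy(d, lj))
}

#' Frozen-lattice sliding energy barrier
#'
#' Energy barrier for one bead to slide one site along the fibril
#' axis, with every other bead frozen at its ideal lattice position:
#' the difference between the Lennard-Jones lattice sum with the bead
#' coplanar with a hexagonal layer (saddle) and with the bead midway
#' between layers (rest).  Pairs within the bead's own chain are
#' excluded — those are governed by the bond/angle terms.
#'
#' @param lattice A [build_hex_lattice()] result (or [bead_lattice()]).
#' @param lj An [lj_params()] object.
#' @param cutoff Pair cutoff (Angstrom); must be at least twice the
#'   in-plane spacing so the first coordination shell is included.
#'   The default (6 sigma) is converged to well under 0.5%.
#' @return Barrier height in kcal/mol.
#' @examples
#' fixed_lattice_barrier(build_hex_lattice())   # ~6.2 kcal/mol
#' @export
fixed_lattice_barrier <- function(lattice, lj = lj_params(),
                                  cutoff = 6 * lj$sigma) {
  stopifnot(inherits(lattice, "bead_lattice"), inherits(lj, "lj_params"))
  if (cutoff < 2 * lattice$spacing)
    stop("`cutoff` too small to include the first coordination shell ",
         "(need >= 2 x lattice spacing)", call. = FALSE)
  .sliding_bead_energy(lattice, lj, cutoff, lattice$z_high) -
    .sliding_bead_energy(lattice, lj, cutoff, lattice$z_low)
}

#' Frozen-lattice energy profile along the sliding path
#'
#' @inheritParams fixed_lattice_barrier
#' @param n Number of sampled positions over one axial period starting
#'   at the rest position.
#' @return A data.frame with columns `position_A` and
#'   `energy_kcal_mol` (energy relative to the rest position).
#' @export
barrier_profile <- function(lattice, lj = lj_params(),
                            cutoff = 6 * lj$sigma, n = 41) {
  stopifnot(inherits(lattice, "bead_lattice"), n >= 2)
  if (cutoff < 2 * lattice$spacing)
    stop("`cutoff` too small to include the first coordination shell ",
         "(need >= 2 x lattice spacing)", call. = FALSE)
  z <- seq(lattice$z_low, lattice$z_low + lattice$axial_spacing,
           length.out = n)
  e <- vapply(z, function(zi) .sliding_bead_energy(lattice, lj, cutoff, zi),
              numeric(1))
  data.frame(position_A = z, energy_kcal_mol = e - e[1])
}

# ---- relaxed barrier: constrained minimisation machinery ----------------

# scatter-add pair contributions (npair x 3) into an N x 3 gradient
.rowsum_into <- function(contrib, idx, n) {
  out <- matrix(0, n, 3)
  s <- rowsum(contrib, group = idx)
  out[as.integer(rownames(s)), ] <- s
  out
}

# index arrays for the energy terms of a lattice, built once per call
.lattice_terms <- function(lattice, cutoff) {
  xyz <- lattice$xyz
  n <- nrow(xyz)
  ch <- lattice$chain
  # inter-chain LJ pairs within cutoff (+ margin for relaxation motion)
  pr <- which(outer(ch, ch, "!="), arr.ind = TRUE)
  pr <- pr[pr[, 1] < pr[, 2], , drop = FALSE]
  d0 <- sqrt(rowSums((xyz[pr[, 1], , drop = FALSE] -
                      xyz[pr[, 2], , drop = FALSE])^2))
  pr <- pr[d0 <= cutoff + 4, , drop = FALSE]  # margin for relaxation motion
  # bonds and angles: consecutive beads within each chain, by z order
  bi <- integer(0); bj <- integer(0)
  ai <- integer(0); aj <- integer(0); ak <- integer(0)
  for (c_id in unique(ch)) {
    idx <- which(ch == c_id)
    if (length(idx) < 2) next
    idx <- idx[order(xyz[idx, 3])]
    bi <- c(bi, idx[-length(idx)]); bj <- c(bj, idx[-1])
    if (length(idx) >= 3) {
      ai <- c(ai, idx[seq_len(length(idx) - 2)])
      aj <- c(aj, idx[seq_len(length(idx) - 2) + 1])
      ak <- c(ak, idx[seq_len(length(idx) - 2) + 2])
    }
  }
  list(lj_i = pr[, 1], lj_j = pr[, 2], bond_i = bi, bond_j = bj,
       ang_i = ai, ang_j = aj, ang_k = ak, n = n, cutoff = cutoff)
}

.cluster_energy <- function(X, terms, lj, bp, cl = NULL) {
  e <- 0
  if (length(terms$lj_i)) {
    d <- sqrt(rowSums((X[terms$lj_i, , drop = FALSE] -
                       X[terms$lj_j, , drop = FALSE])^2))
    d <- d[d <= terms$cutoff]   # truncation applied at evaluation time
    e <- e + sum(lj_energy(d, lj))
  }
  if (length(terms$bond_i)) {
    db <- sqrt(rowSums((X[terms$bond_i, , drop = FALSE] -
                        X[terms$bond_j, , drop = FALSE])^2))
    e <- e + sum(bond_energy(db, bp))
  }
  if (length(terms$ang_i)) {
    u <- X[terms$ang_i, , drop = FALSE] - X[terms$ang_j, , drop = FALSE]
    v <- X[terms$ang_k, , drop = FALSE] - X[terms$ang_j, , drop = FALSE]
    cth <- rowSums(u * v) / (sqrt(rowSums(u^2)) * sqrt(rowSums(v^2)))
    th <- acos(pmin(1, pmax(-1, cth)))
    e <- e + sum(bp$Ktheta * (th - pi)^2)
  }
  if (!is.null(cl)) {
    d <- sqrt(sum((X[cl$i, ] - X[cl$j, ])^2))
    e <- e + bond_energy(max(cl$params$r0 + (d - cl$d_init), 1e-6), cl$params)
  }
  e
}

.cluster_gradient <- function(X, terms, lj, bp, cl = NULL) {
  G <- matrix(0, terms$n, 3)
  if (length(terms$lj_i)) {
    dd <- X[terms$lj_i, , drop = FALSE] - X[terms$lj_j, , drop = FALSE]
    d <- sqrt(rowSums(dd^2))
    f <- ifelse(d <= terms$cutoff, lj_force(d, lj) / d, 0)  # (dE/dr)/r
    G <- G + .rowsum_into(dd * f, terms$lj_i, terms$n) -
             .rowsum_into(dd * f, terms$lj_j, terms$n)
  }
  if (length(terms$bond_i)) {
    dd <- X[terms$bond_i, , drop = FALSE] - X[terms$bond_j, , drop = FALSE]
    d <- sqrt(rowSums(dd^2))
    f <- bond_force(d, bp) / d
    G <- G + .rowsum_into(dd * f, terms$bond_i, terms$n) -
             .rowsum_into(dd * f, terms$bond_j, terms$n)
  }
  if (length(terms$ang_i)) {
    u <- X[terms$ang_i, , drop = FALSE] - X[terms$ang_j, , drop = FALSE]
    v <- X[terms$ang_k, , drop = FALSE] - X[terms$ang_j, , drop = FALSE]
    nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
    uh <- u / nu; vh <- v / nv
    cth <- pmin(1, pmax(-1, rowSums(uh * vh)))
    th <- acos(cth)
    sth <- pmax(sqrt(pmax(0, 1 - cth^2)), 1e-12)
    q <- 2 * bp$Ktheta * (th - pi) / sth   # finite limit ~ -2*Ktheta at th=pi
    gi <- q * (cth * uh - vh) / nu
    gk <- q * (cth * vh - uh) / nv
    G <- G + .rowsum_into(gi, terms$ang_i, terms$n) +
             .rowsum_into(gk, terms$ang_k, terms$n) -
             .rowsum_into(gi + gk, terms$ang_j, terms$n)
  }
  if (!is.null(cl)) {
    dd <- X[cl$i, ] - X[cl$j, ]
    d <- sqrt(sum(dd^2))
    f <- bond_force(max(cl$params$r0 + (d - cl$d_init), 1e-6), cl$params) / d
    G[cl$i, ] <- G[cl$i, ] + f * dd
    G[cl$j, ] <- G[cl$j, ] - f * dd
  }
  G
}

# damped gradient descent with Armijo backtracking on the movable beads
.relax_cluster <- function(X, movable, terms, lj, bp, cl, tol, max_iter) {
  e <- .cluster_energy(X, terms, lj, bp, cl)
  if (max_iter == 0) return(list(X = X, energy = e, grad_norm = NA_real_))
  step <- 0.05
  gnorm <- Inf
  for (it in seq_len(max_iter)) {
    G <- .cluster_gradient(X, terms, lj, bp, cl)
    Gm <- G[movable, , drop = FALSE]
    gnorm <- sqrt(sum(Gm^2))
    if (gnorm < tol)
      return(list(X = X, energy = e, grad_norm = gnorm))
    repeat {
      Xn <- X
      Xn[movable, ] <- X[movable, , drop = FALSE] - step * Gm
      en <- .cluster_energy(Xn, terms, lj, bp, cl)
      if (en <= e - 1e-4 * step * gnorm^2) break
      step <- step / 2
      if (step < 1e-12) return(list(X = X, energy = e, grad_norm = gnorm,
                                    stalled = TRUE))
    }
    X <- Xn; e <- en
    step <- min(step * 1.5, 0.5)
  }
  stop(sprintf(paste0("relaxation did not converge within %d iterations ",
                      "(last gradient norm %.3g kcal/mol/A)"),
               max_iter, gnorm), call. = FALSE)
}

#' Relaxed sliding energy barrier
#'
#' Moves the sliding bead stepwise from its rest position (midway
#' between axial layers) to the coplanar saddle and, at each step,
#' relaxes all interior beads by damped gradient descent on the full
#' cluster energy (inter-chain Lennard-Jones + backbone bonds + bending
#' angles, plus an optional crosslink bond attached to the sliding
#' bead).  Outermost-ring chains are held fixed as boundary conditions;
#' initialisation is the ideal lattice, so the procedure is
#' deterministic.  The barrier is the max-minus-min of the relaxed
#' energy profile.
#'
#' This estimator is reported alongside — not substituted for — the
#' [published_barriers()], which remain the defaults downstream.
#'
#' @param lattice A [build_hex_lattice()] result.
#' @param lj An [lj_params()] object.
#' @param bond_params Backbone bond/angle parameters
#'   ([molecule_params()]).
#' @param crosslink Optional [crosslink_params()]; if given, a
#'   crosslink bond is attached between the sliding bead and its
#'   nearest neighbour-chain bead, at equilibrium in the rest geometry
#'   (elongation measured from the formation distance).
#' @param n_path Number of sliding-bead positions along the half-period
#'   path (including both endpoints).
#' @param cutoff LJ pair cutoff (Angstrom).
#' @param tol Convergence threshold on the gradient norm over movable
#'   beads (kcal mol^-1 A^-1).
#' @param max_iter Iteration budget per path step; `0` skips relaxation
#'   entirely (frozen-lattice reduction).
#' @return A list of class `relaxed_barrier` with `delta_E` (kcal/mol),
#'   `profile` (data.frame: `position_A`, `E_frozen`, `E_relaxed`,
#'   absolute cluster energies in kcal/mol) and `crosslinked` flag.
#' @export
relaxed_barrier <- function(lattice, lj = lj_params(),
                            bond_params = molecule_params(),
                            crosslink = NULL,
                            n_path = 8, cutoff = 3 * lj$sigma,
                            tol = 0.5, max_iter = 2000) {
  stopifnot(inherits(lattice, "bead_lattice"), n_path >= 2, tol > 0)
  X0 <- lattice$xyz
  s <- lattice$sliding
  terms <- .lattice_terms(lattice, cutoff)

  # movable: interior beads; boundary ring chains and the sliding bead fixed
  d_pl <- sqrt((X0[, 1] - X0[s, 1])^2 + (X0[, 2] - X0[s, 2])^2)
  r_max <- max(d_pl)
  movable <- which(d_pl < r_max - 0.5 * lattice$spacing &
                   seq_len(nrow(X0)) != s)
  if (!length(movable))
    stop("lattice too small: no interior beads to relax (need n_rings >= 2)",
         call. = FALSE)

  cl <- NULL
  if (!is.null(crosslink)) {
    stopifnot(inherits(crosslink, "crosslink_params"))
    nb <- which(lattice$chain != lattice$chain[s])
    d_all <- sqrt(rowSums((X0[nb, , drop = FALSE] -
                           matrix(X0[s, ], length(nb), 3, byrow = TRUE))^2))
    j <- nb[which.min(d_all)]
    cl <- list(i = s, j = j, d_init = min(d_all), params = crosslink)
  }

  zs <- seq(lattice$z_low, lattice$z_high, length.out = n_path)
  e_frozen <- numeric(n_path)
  e_relaxed <- numeric(n_path)
  for (k in seq_len(n_path)) {
    X <- X0
    X[s, 3] <- zs[k]
    e_frozen[k] <- .cluster_energy(X, terms, lj, bond_params, cl)
    res <- .relax_cluster(X, movable, terms, lj, bond_params, cl,
                          tol = tol, max_iter = max_iter)
    e_relaxed[k] <- res$energy
  }
  structure(list(
    delta_E = max(e_relaxed) - min(e_relaxed),
    profile = data.frame(position_A = zs, E_frozen = e_frozen,
                         E_relaxed = e_relaxed),
    crosslinked = !is.null(crosslink)
  ), class = "relaxed_barrier")
}

#' @export
print.relaxed_barrier <- function(x, ...) {
  cat(sprintf("Relaxed sliding barrier: %.3f kcal/mol (%s, %d path steps)\n",
              x$delta_E, if (x$crosslinked) "with crosslink" else "no crosslink",
              nrow(x$profile)))
  invisible(x)
}

#' Convert a sliding energy barrier into bond elongation and pull-out force
#'
#' The intermolecular barrier is compensated by the backbone bond
#' pulling the bead: the critical elongation satisfies
#' `E_bond(r0 + delta_r) = delta_E`.  On the soft (harmonic) branch
#' this gives `delta_r = sqrt(2 delta_E / KT0)` and
#' `F = KT0 delta_r`; if the required elongation carries the bond past
#' `r1`, the stiff branch applies:
#' `delta_r = (r1_bar - r0) + sqrt(2 (delta_E - C1) / KT1)` with
#' `F = KT1 (r0 + delta_r - r1_bar)`.  The two formulas agree exactly
#' at the switch point.
#'
#' @param delta_E Energy barrier (kcal/mol), positive.
#' @param params Bond-law parameters ([molecule_params()]).
#' @param regime `"auto"` picks the branch from `delta_E`;
#'   `"harmonic"`/`"hyperelastic"` force one.
#' @param method Provenance tag stored in the result:
#'   `"published"`, `"fixed_lattice"` or `"relaxed"`.
#' @return An object of class `barrier_result`: `delta_E` (kcal/mol),
#'   `delta_r` (Angstrom), `F_pull_N` (N), `r_sliding = r0 + delta_r`
#'   (Angstrom), `regime`, `method`.
#' @examples
#' barrier_to_pullout(11.36)$delta_r     # ~1.15 A
#' barrier_to_pullout(187)$r_sliding     # ~18.59 A (> r1 = 18.2)
#' @export
barrier_to_pullout <- function(delta_E, params = molecule_params(),
                               regime = c("auto", "harmonic", "hyperelastic"),
                               method = c("published", "fixed_lattice",
                                          "relaxed")) {
  regime <- match.arg(regime)
  method <- match.arg(method)
  stopifnot(is.numeric(delta_E), length(delta_E) == 1, delta_E > 0)
  k <- bond_law_constants(params)
  e_switch <- params$KT0 / 2 * (params$r1 - params$r0)^2  # elongation hits r1
  if (regime == "auto")
    regime <- if (delta_E <= e_switch) "harmonic" else "hyperelastic"
  if (regime == "harmonic") {
    delta_r <- sqrt(2 * delta_E / params$KT0)
    f <- params$KT0 * delta_r
  } else {
    if (delta_E < k$C1)
      stop("`delta_E` below C1: barrier too small for the hyperelastic branch",
           call. = FALSE)
    delta_r <- (k$r1_bar - params$r0) + sqrt(2 * (delta_E - k$C1) / params$KT1)
    f <- params$KT1 * (params$r0 + delta_r - k$r1_bar)
  }
  r_sliding <- params$r0 + delta_r
  # construction cross-check: the bond energy at the critical
  # elongation must return the barrier
  e_back <- bond_energy(r_sliding, params)
  if (abs(e_back - delta_E) > 1e-9 * max(1, delta_E) && r_sliding <= params$rb)
    stop("internal inconsistency: bond energy at r0 + delta_r does not ",
         "reproduce delta_E", call. = FALSE)
  structure(list(delta_E = delta_E, delta_r = delta_r,
                 F_pull_N = force_kcalmolA_to_N(f),
                 r_sliding = r_sliding, regime = regime, method = method),
            class = "barrier_result")
}

#' @export
print.barrier_result <- function(x, ...) {
  cat(sprintf("Sliding barrier %.3f kcal/mol (%s, %s regime):\n",
              x$delta_E, x$method, x$regime))
  cat(sprintf("  bond elongation %.3f A (r_sliding = %.3f A), pull-out force %.3g N\n",
              x$delta_r, x$r_sliding, x$F_pull_N))
  invisible(x)
}
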