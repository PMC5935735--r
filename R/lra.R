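# Linear-response protonation free energies and pKa shifts. The free energy
# of switching a titratable group's charges is estimated as
#   dG = sum_i dq_i (<V_i>_A + <V_i>_B) / 2
# where <V_i> is the electrostatic potential on site atom i averaged over
# snapshot ensembles of the two endpoint states (A protonated, B
# deprotonated). Under linear response (equal-variance Gaussian potential
# fluctuations) this two-ensemble average is exact.

#' Ensemble-averaged potentials on a titratable site
#'
#' For each snapshot of each endpoint ensemble, rebuilds the solute at the
#' frame coordinates with the matching protonation state (state A frames are
#' solved with the protonated charges, state B with the deprotonated ones),
#' solves the linearized Poisson-Boltzmann equation, and interpolates the
#' potential at the site atoms. Returns per-atom means over each ensemble.
#'
#' @param template a [structure_set()] supplying charges/radii (taken as
#'   deprotonated for this site unless previously assigned).
#' @param frames_A,frames_B [frame_set()] ensembles for the protonated (A)
#'   and deprotonated (B) states.
#' @param site a [titratable_site()].
#' @param pb_config named list of [build_maps()] / solver options:
#'   `spacing`, `probe_radius`, `eps_in`, `eps_out`, `ionic_strength`,
#'   `ion_exclusion`, `temperature`, `tol`, `padding`.
#' @return object of class `ensemble_potentials`: `site_label`, `mean_V_A`,
#'   `mean_V_B` (kcal/(mol e), site-atom order), `n_A`, `n_B`.
#' @export
ensemble_mean_potentials <- function(template, frames_A, frames_B, site,
                                     pb_config = list()) {
  stopifnot(inherits(template, "structure_set"), inherits(site, "titratable_site"))
  for (fs in list(frames_A, frames_B)) {
    if (!inherits(fs, "frame_set")) stop("frames must be frame_set objects")
    if (fs$n_atoms != n_atoms(template)) {
      stop("frame atom count (", fs$n_atoms, ") does not match template (",
           n_atoms(template), ")")
    }
    if (n_frames(fs) < 1L) stop("empty frame set")
  }
  cfg <- modifyList(list(spacing = 0.4, probe_radius = 1.4, eps_in = 2,
                         eps_out = 80, ionic_strength = 0.15,
                         ion_exclusion = 2.0, temperature = 300,
                         tol = 1e-6, padding = NULL), pb_config)
  site_pot <- function(frames, state) {
    base <- apply_charge_state(template, site, state)
    acc <- matrix(0, n_frames(frames), length(site$atom_indices))
    for (f in seq_len(n_frames(frames))) {
      s <- set_coords(base, frames$frames[[f]])
      grid <- auto_grid(s, spacing = cfg$spacing, padding = cfg$padding)
      maps <- build_maps(s, grid, probe_radius = cfg$probe_radius,
                         eps_in = cfg$eps_in, eps_out = cfg$eps_out,
                         ionic_strength = cfg$ionic_strength,
                         ion_exclusion = cfg$ion_exclusion,
                         temperature = cfg$temperature)
      field <- solve_lpb(maps$diel, maps$kappa, s, tol = cfg$tol)
      acc[f, ] <- potential_at_atoms(field, s)[site$atom_indices + 1L]
    }
    acc
  }
  VA <- site_pot(frames_A, "protonated")
  VB <- site_pot(frames_B, "deprotonated")
  structure(list(site_label = site$label,
                 mean_V_A = colMeans(VA), mean_V_B = colMeans(VB),
                 n_A = n_frames(frames_A), n_B = n_frames(frames_B),
                 samples_A = VA, samples_B = VB),
            class = "ensemble_potentials")
}

#' Construct ensemble potentials from precomputed means
#'
#' For workflows where the per-state mean potentials are already available
#' (e.g. from a synthetic generator or an external electrostatics run).
#'
#' @param site_label site name.
#' @param mean_V_A,mean_V_B per-site-atom mean potentials, kcal/(mol e).
#' @param n_A,n_B snapshot counts behind each mean.
#' @return an `ensemble_potentials` object.
#' @export
ensemble_potentials <- function(site_label, mean_V_A, mean_V_B, n_A = 1L, n_B = 1L) {
  mean_V_A <- as.numeric(mean_V_A); mean_V_B <- as.numeric(mean_V_B)
  if (length(mean_V_A) != length(mean_V_B)) {
    stop("mean potential vectors must have equal length (same site-atom order)")
  }
  if (n_A < 1L || n_B < 1L) stop("snapshot counts must be >= 1")
  structure(list(site_label = site_label, mean_V_A = mean_V_A,
                 mean_V_B = mean_V_B, n_A = as.integer(n_A), n_B = as.integer(n_B)),
            class = "ensemble_potentials")
}

#' Linear-response free energy of a protonation-state change
#'
#' `dG = sum_i dq_i (<V_i>_A + <V_i>_B) / 2` over the site atoms. With
#' `delta_q` defined as protonated-minus-deprotonated charges, the returned
#' value is the free energy of the charging step A -> B read in the
#' direction the caller's convention implies; for a deprotonation free
#' energy, negate `delta_q` or the result (the expression is symmetric in
#' the two ensembles, so only the sign convention matters).
#'
#' @param site a [titratable_site()].
#' @param pots an `ensemble_potentials` for the same site-atom ordering.
#' @return object of class `lra_result`: `delta_g` (kcal/mol),
#'   `per_atom_terms` (summing to `delta_g`), `site_label`.
#' @examples
#' site <- titratable_site("s", 0, 1, model_pka = 4.4)
#' pots <- ensemble_potentials("s", 2.0, 4.0)
#' lra_free_energy(site, pots)$delta_g # 3.0
#' @export
lra_free_energy <- function(site, pots) {
  stopifnot(inherits(site, "titratable_site"), inherits(pots, "ensemble_potentials"))
  if (length(site$delta_q) != length(pots$mean_V_A)) {
    stop("delta_q length (", length(site$delta_q),
         ") does not match potential vectors (", length(pots$mean_V_A), ")")
  }
  terms <- site$delta_q * (pots$mean_V_A + pots$mean_V_B) / 2
  # Uncertainty by 5-block averaging over snapshots where per-frame site
  # potentials are available; the two ensembles contribute independently.
  se <- NA_real_
  if (!is.null(pots$samples_A) && !is.null(pots$samples_B)) {
    gA <- as.numeric(pots$samples_A %*% site$delta_q) / 2
    gB <- as.numeric(pots$samples_B %*% site$delta_q) / 2
    seA <- block_std_error(gA); seB <- block_std_error(gB)
    if (!is.na(seA) && !is.na(seB)) se <- sqrt(seA^2 + seB^2)
  }
  structure(list(delta_g = sum(terms), per_atom_terms = terms,
                 std_error = se, site_label = site$label),
            class = "lra_result")
}

#' pKa of a group in the protein from free-energy shifts
#'
#' `pKa_prot = pKa_solv + (dG_prot - dG_solv) / (2.303 R T)`: the pKa shift
#' relative to the model compound in solvent is the difference between the
#' protonation free-energy change computed in the protein and in solvent,
#' in pKa units.
#'
#' @param dG_prot,dG_solv free-energy changes in protein and solvent, kcal/mol.
#' @param pka_solv model-compound pKa in solvent.
#' @param thermo a [thermo_config()] (default 300 K).
#' @return object of class `pka_result` with `pka_prot`, `pka_solv`,
#'   `dG_prot`, `dG_solv`, `shift`, `T`.
#' @examples
#' # glutamate buried in a hydrophobic pocket: deprotonation costs
#' # 8.9 kcal/mol more than in solvent, so its pKa rises from 4.4 to ~10.8
#' pka_in_protein(8.9, 0, pka_solv = 4.4)$pka_prot
#' @export
pka_in_protein <- function(dG_prot, dG_solv, pka_solv, thermo = thermo_config()) {
  stopifnot(inherits(thermo, "thermo_config"))
  shift <- (dG_prot - dG_solv) / (2.303 * thermo$R * thermo$T)
  structure(list(pka_prot = pka_solv + shift, pka_solv = pka_solv,
                 dG_prot = dG_prot, dG_solv = dG_solv, shift = shift,
                 T = thermo$T),
            class = "pka_result")
}

#' @export
print.pka_result <- function(x, ...) {
  cat(sprintf("pKa(protein) = %.2f  [pKa(solvent) %.2f %+.2f units; ddG = %.3g kcal/mol at %g K]\n",
              x$pka_prot, x$pka_solv, x$shift, x$dG_prot - x$dG_solv, x$T))
  invisible(x)
}

#' Rank protonation states by relative free energy
#'
#' Re-references the supplied states to the most stable one (set to 0),
#' sorts ascending, and breaks exact ties lexicographically by label.
#'
#' @param states data.frame with columns `label`, `delta_g`, and optionally
#'   `uncertainty`; or a named numeric vector of free energies (kcal/mol).
#' @return data.frame of class `state_ranking`, sorted, with `delta_g`
#'   relative to the minimum.
#' @examples
#' rank_protonation_states(c("OH/NH2" = 0, "O-/NH3+" = 2.7,
#'                           "OH/NH3+" = 0.8, "O-/NH2" = 7.7))
#' @export
rank_protonation_states <- function(states) {
  if (is.numeric(states)) {
    states <- data.frame(label = names(states), delta_g = as.numeric(states),
                         stringsAsFactors = FALSE)
  }
  if (!nrow(states)) stop("need at least one state")
  if (!all(c("label", "delta_g") %in% names(states))) {
    stop("states needs 'label' and 'delta_g' columns")
  }
  if (!"uncertainty" %in% names(states)) states$uncertainty <- NA_real_
  states$delta_g <- states$delta_g - min(states$delta_g)
  ord <- order(states$delta_g, states$label)
  out <- states[ord, c("label", "delta_g", "uncertainty")]
  rownames(out) <- NULL
  class(out) <- c("state_ranking", "data.frame")
  out
}

#' Absolute protonation free energy at a reference pH
#'
#' Convention used by this package to combine a relative in-protein
#' free-energy change with a model-compound pKa:
#' `dG_abs = ddG + 2.303 R T (pKa_model - pH)`, i.e. the protein shift on
#' top of the solution cost of (de)protonating the model compound at the
#' given pH.
#'
#' @param ddG relative free-energy change in the protein, kcal/mol.
#' @param pka_model model-compound pKa.
#' @param thermo a [thermo_config()] carrying T and the reference pH.
#' @return scalar free energy, kcal/mol.
#' @export
absolute_protonation_dg <- function(ddG, pka_model, thermo = thermo_config()) {
  ddG + 2.303 * thermo$R * thermo$T * (pka_model - thermo$pH)
}

# Standard error by block averaging: split the series into `blocks`
# contiguous blocks, take the block means, and return sd/sqrt(nblocks).
block_std_error <- function(x, blocks = 5L) {
  n <- length(x)
  if (n < blocks) blocks <- max(1L, n)
  if (blocks < 2L) return(NA_real_)
  idx <- cut(seq_len(n), blocks, labels = FALSE)
  bm <- tapply(x, idx, mean)
  sd(bm) / sqrt(length(bm))
}
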