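# Compound-quality and screening metrics: LE, LLE, hit rate, Kp,uu.

#' Ligand efficiency
#'
#' `LE = c * pIC50 / heavy_atoms` with `c = 2.303 * R * T` at 298.15 K
#' (1.364 kcal/mol), i.e. the potency-derived binding free energy per heavy
#' atom. The constant is exposed because some groups use 1.37; both
#' reproduce typical 2-decimal values.
#'
#' @param pic50 numeric, -log10 IC50 (molar)
#' @param heavy_atoms integer heavy-atom count, >= 1
#' @param constant kcal/mol conversion constant (default 1.364)
#' @param digits decimals for half-up rounding (default 2); `NA` = unrounded
#' @return LE in kcal/mol per heavy atom
#' @examples
#' ligand_efficiency(6.70, 20)   # 0.46
#' @export
ligand_efficiency <- function(pic50, heavy_atoms, constant = 1.364,
                              digits = 2) {
  if (any(heavy_atoms < 1)) stop("heavy_atoms must be >= 1")
  stopifnot(all(is.finite(pic50)))
  le <- constant * pic50 / heavy_atoms
  if (is.na(digits)) le else round_half_up(le, digits)
}

#' Lipophilic ligand efficiency
#'
#' `LLE = pIC50 - logP`; potency not bought with lipophilicity.
#'
#' @param pic50 numeric, -log10 IC50 (molar)
#' @param logp numeric logP (or logD) estimate
#' @param digits decimals for half-up rounding (default 1); `NA` = unrounded
#' @return LLE (unitless)
#' @examples
#' lipophilic_ligand_efficiency(6.70, 2.80)   # 3.9
#' @export
lipophilic_ligand_efficiency <- function(pic50, logp, digits = 1) {
  stopifnot(all(is.finite(pic50)), all(is.finite(logp)))
  lle <- pic50 - logp
  if (is.na(digits)) lle else round_half_up(lle, digits)
}

#' Screening hit rate as a percentage
#'
#' @param n_hits number of actives, 0 <= n_hits <= n_screened
#' @param n_screened number screened, >= 1
#' @param digits decimals for half-up rounding (default 1); `NA` = unrounded
#' @return percentage
#' @examples
#' hit_rate(5, 960)   # 0.5
#' @export
hit_rate <- function(n_hits, n_screened, digits = 1) {
  if (any(n_screened < 1)) stop("n_screened must be >= 1")
  if (any(n_hits < 0) || any(n_hits > n_screened))
    stop("n_hits must lie in [0, n_screened]")
  hr <- 100 * n_hits / n_screened
  if (is.na(digits)) hr else round_half_up(hr, digits)
}

#' Unbound brain-to-plasma partition coefficient (Kp,uu)
#'
#' Ratio of free (unbound) brain to free plasma concentration:
#' `(total_brain * fu_brain) / (total_plasma * fu_plasma)`. Unit-free as
#' long as both totals share units; a value near 1 indicates free-drug
#' equilibration across the blood-brain barrier.
#'
#' @param total_brain,total_plasma total concentrations (same units)
#' @param fu_brain,fu_plasma unbound fractions in (0, 1]
#' @param digits decimals for half-up rounding (default 2); `NA` = unrounded
#' @return Kp,uu (unitless)
#' @examples
#' kpuu(100, 0.1, 50, 0.2)   # 1.00
#' @export
kpuu <- function(total_brain, fu_brain, total_plasma, fu_plasma, digits = 2) {
  if (any(c(total_brain, fu_brain, total_plasma, fu_plasma) <= 0))
    stop("all Kp,uu inputs must be positive")
  if (any(fu_brain > 1) || any(fu_plasma > 1))
    stop("unbound fractions must lie in (0, 1]")
  k <- (total_brain * fu_brain) / (total_plasma * fu_plasma)
  if (is.na(digits)) k else round_half_up(k, digits)
}

#' SAR-style efficiency table for a set of compounds
#'
#' Joins activities with heavy-atom counts (computed from structures when a
#' deck is given) and reports LE and LLE per compound.
#'
#' @param activities data.frame with columns `id`, `pic50`, `logp`
#' @param deck optional `compound_deck` supplying heavy-atom counts
#' @param heavy_atoms optional named (by id) or parallel integer vector,
#'   used when no deck is given
#' @param constant LE constant (see [ligand_efficiency()])
#' @return data.frame `id`, `pic50`, `logp`, `heavy_atoms`, `le`, `lle`
#' @export
efficiency_table <- function(activities, deck = NULL, heavy_atoms = NULL,
                             constant = 1.364) {
  stopifnot(all(c("id", "pic50", "logp") %in% names(activities)))
  if (!is.null(deck)) {
    desc <- compute_descriptors(deck_subset(deck, activities$id))
    heavy_atoms <- desc$heavy_atoms[match(activities$id, desc$id)]
  } else if (!is.null(names(heavy_atoms))) {
    heavy_atoms <- heavy_atoms[activities$id]
  }
  if (is.null(heavy_atoms))
    stop("supply either a deck or heavy_atoms")
  data.frame(
    id = activities$id,
    pic50 = activities$pic50,
    logp = activities$logp,
    heavy_atoms = as.integer(heavy_atoms),
    le = ligand_efficiency(activities$pic50, heavy_atoms,
                           constant = constant),
    lle = lipophilic_ligand_efficiency(activities$pic50, activities$logp))
}
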