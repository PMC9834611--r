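# ODE right-hand side of the PBPK model: flow-limited tissues with
# saturable tubulin binding, ABCB1 efflux, permeability-limited brain,
# and metabolic / biliary / renal elimination.

#' Free (venous) tissue concentration under saturable tubulin binding
#'
#' The total tissue concentration `CT` is partitioned between a linearly
#' partitioned pool and a saturable tubulin-bound pool, so the free
#' concentration `Cv` leaving the tissue in venous blood satisfies the
#' implicit relation `CT = Cv * (PC + BC / (KD + Cv))`. This is a quadratic
#' in `Cv`,
#' `PC*Cv^2 + (PC*KD + BC - CT)*Cv - CT*KD = 0`,
#' whose unique non-negative root is returned. `Cv <= CT/PC` always, with
#' equality when `BC = 0`, and `Cv` is strictly increasing in `CT`.
#'
#' @param CT Total tissue concentration in nM (vectorized, >= 0).
#' @param PC Tissue-to-plasma partition coefficient (> 0).
#' @param BC Tubulin binding capacity in nmol/kg; with density 1 kg/L this
#'   is used directly as nM.
#' @param KD Drug-tubulin dissociation constant in nM (> 0).
#' @return Free concentration in nM, same length as `CT`.
#' @export
tissue_free_concentration <- function(CT, PC, BC, KD) {
  if (any(CT < 0)) stop("CT must be non-negative", call. = FALSE)
  if (any(PC <= 0) || any(KD <= 0) || any(BC < 0))
    stop("require PC > 0, KD > 0, BC >= 0", call. = FALSE)
  free_conc_fast(CT, PC, BC, KD)
}

# unchecked, fully vectorized core; stable against cancellation for CT >> BC
free_conc_fast <- function(CT, PC, BC, KD) {
  b <- PC * KD + BC - CT
  disc <- sqrt(b * b + 4 * PC * KD * CT)
  cv <- ifelse(b <= 0, (disc - b) / (2 * PC), 2 * KD * CT / (disc + b))
  pmax(cv, 0)
}

# Internal: assemble everything the RHS needs into flat vectors.
# Peripheral tissues (generic flow-limited mass balance) exclude brain,
# which has its own two-compartment barrier sub-model, and blood/lung which
# form the central path.
build_pbpk <- function(phys, drug, include_lung = TRUE) {
  stopifnot(inherits(phys, "species_physiology"),
            inherits(drug, "drug_parameters"))
  comp <- resolve_physiology(phys, include_lung = include_lung)
  peripheral <- c("bone_marrow", "kidney", "liver", "gut",
                  "slowly_perfused", "rapidly_perfused")
  sf <- function(tis) if (tis %in% names(drug$SF_ABCB1)) drug$SF_ABCB1[[tis]] else 0

  sf_per <- vapply(peripheral, sf, numeric(1))
  # liver ABCB1 efflux *is* the biliary route (handled by the biliary term);
  # only gut and kidney keep a peripheral efflux term here
  sf_per[!(peripheral %in% c("gut", "kidney"))] <- 0

  p <- list(
    include_lung = include_lung,
    cardiac_output = attr(comp, "cardiac_output"),
    v_blood = comp["blood", "volume_L"],
    v_bb = comp["brain_blood", "volume_L"],
    v_cns = comp["brain_tissue", "volume_L"],
    q_brain = comp["brain_blood", "flow_Lh"],
    v_lung = if (include_lung) comp["lung", "volume_L"] else NA_real_,
    peripheral = peripheral,
    v_per = stats::setNames(comp[peripheral, "volume_L"], peripheral),
    q_per = stats::setNames(comp[peripheral, "flow_Lh"], peripheral),
    pc_per = drug$PC[peripheral],
    bc_per = drug$BC[peripheral],
    sf_per = sf_per,
    pc_blood = drug$PC[["blood"]], bc_blood = drug$BC[["blood"]],
    pc_lung = drug$PC[["lung"]], bc_lung = drug$BC[["lung"]],
    pc_brain = drug$PC[["brain"]], bc_brain = drug$BC[["brain"]],
    sf_brain = sf("brain"),
    drug = drug
  )
  p$state_names <- c("blood", if (include_lung) "lung", peripheral,
                     "brain_tissue", "brain_blood",
                     "cl_metabolism", "cl_feces", "cl_urine")
  p
}

# Internal: derivative of the amount state vector (nmol), time in h.
# Layout of y follows p$state_names.
pbpk_rhs <- function(t, y, p) {
  drug <- p$drug
  KD <- drug$KD_tubulin
  fu <- drug$fu

  c_blood <- max(y[["blood"]], 0) / p$v_blood
  ca <- free_conc_fast(c_blood, p$pc_blood, p$bc_blood, KD)

  per <- p$peripheral
  c_per <- pmax(y[per], 0) / p$v_per
  cv_per <- free_conc_fast(c_per, p$pc_per, p$bc_per, KD)

  # saturable ABCB1 efflux from gut and kidney (nmol/h)
  efflux <- p$sf_per * p$v_per * drug$Vmax_ABCB1 * cv_per /
    (drug$Km_ABCB1 + cv_per)

  # hepatic elimination, driven by the liver free concentration
  cv_liv <- cv_per[["liver"]]
  v_liv <- p$v_per[["liver"]]
  rate_met <- v_liv * drug$Vmax_met * fu * cv_liv / (drug$Km_met + fu * cv_liv)
  rate_bil <- drug$sf_bil * v_liv * drug$Vmax_bil * cv_liv /
    (drug$Km_bil + cv_liv)

  # glomerular filtration from the blood pool
  rate_filt <- drug$GFR_fraction * p$q_per[["kidney"]] * fu * ca

  d_per <- p$q_per * (ca - cv_per) - efflux
  d_per[["liver"]] <- d_per[["liver"]] - rate_met - rate_bil

  # permeability-limited brain: vascular space exchanges with tissue across
  # the barrier; efflux pumps free tissue drug back into the vascular space
  c_bb <- max(y[["brain_blood"]], 0) / p$v_bb
  c_cns <- max(y[["brain_tissue"]], 0) / p$v_cns
  cv_cns <- free_conc_fast(c_cns, p$pc_brain, p$bc_brain, KD)
  psa_flux <- drug$PSA * fu * (c_bb - cv_cns)
  efflux_brain <- p$sf_brain * p$v_cns * drug$Vmax_ABCB1 * cv_cns /
    (drug$Km_ABCB1 + cv_cns)
  d_cns <- psa_flux - efflux_brain
  d_bb <- p$q_brain * (ca - c_bb) - psa_flux + efflux_brain

  venous_return <- sum(p$q_per * cv_per) + p$q_brain * c_bb
  q_tot <- sum(p$q_per) + p$q_brain

  if (p$include_lung) {
    c_lung <- max(y[["lung"]], 0) / p$v_lung
    cv_lung <- free_conc_fast(c_lung, p$pc_lung, p$bc_lung, KD)
    d_lung <- venous_return - q_tot * cv_lung
    d_blood <- q_tot * cv_lung - q_tot * ca - rate_filt
  } else {
    d_blood <- venous_return - q_tot * ca - rate_filt
  }

  dy <- c(d_blood,
          if (p$include_lung) d_lung,
          d_per,
          d_cns, d_bb,
          rate_met,
          rate_bil + efflux[["gut"]],
          rate_filt + efflux[["kidney"]])
  names(dy) <- p$state_names
  list(dy)
}
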