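# Vinblastine-specific parameters: tubulin binding, partitioning, ABCB1
# efflux, metabolism, biliary and renal elimination.

# tissues that carry a tubulin binding capacity / partition coefficient
binding_tissues <- c("brain", "lung", "bone_marrow", "kidney", "liver", "gut",
                     "slowly_perfused", "rapidly_perfused", "blood")

#' Construct a drug parameter set
#'
#' Holds all drug-specific parameters of the model in a single internal unit
#' system: concentrations in nmol/L (nM), volumes in L, times in h, amounts
#' in nmol. Tubulin binding capacities are given per kg tissue; with tissue
#' density fixed at 1 kg/L they are used directly as nmol/L.
#'
#' @param molecular_weight Molecular weight in g/mol (vinblastine free base
#'   811.0, matching the parent ion).
#' @param KD_tubulin Drug-tubulin dissociation constant in nM.
#' @param BC Named vector of tissue tubulin binding capacities in nmol/kg.
#'   Must cover brain, lung, bone_marrow, kidney, liver, gut,
#'   slowly_perfused, rapidly_perfused and blood (blood conventionally 0).
#' @param PC Named vector of tissue-to-plasma partition coefficients
#'   (dimensionless), same tissue set; `brain` refers to the CNS tissue
#'   sub-compartment.
#' @param SF_ABCB1 Named vector of relative ABCB1 expression scaling factors
#'   for brain, gut, liver and kidney.
#' @param Vmax_ABCB1,Km_ABCB1 Michaelis-Menten constants of ABCB1 efflux,
#'   nmol/L/h and nM.
#' @param Vmax_met,Km_met Hepatic metabolism constants, nmol/L/h and nM
#'   (liver-volume referenced).
#' @param Vmax_bil,Km_bil Biliary excretion constants, nmol/L/h and nM.
#' @param sf_bil Expression scaling factor applied to the biliary term. In
#'   wild-type animals biliary excretion is ABCB1-driven and scaled by the
#'   liver ABCB1 expression factor; in the knockout it is a separate
#'   (Mrp2-attributed) route with no ABCB1 scaling.
#' @param PSA Permeability-surface-area product of the blood-brain barrier
#'   in L/h (0.379 ml/h = 3.79e-4 L/h by default).
#' @param GFR_fraction Fraction of renal blood flow cleared by glomerular
#'   filtration (dimensionless).
#' @param fu Optional unbound-fraction multiplier applied to the driving
#'   concentrations of the metabolic, filtration and barrier-permeation
#'   terms. Default 1 (no plasma-protein-binding correction), matching the
#'   base model equations.
#' @param fraction_bound_plasma Plasma protein binding stored as metadata
#'   (not used in any flux term).
#' @return An object of class `drug_parameters`.
#' @seealso [default_drug_parameters()], [apply_scenario()]
#' @export
drug_parameters <- function(molecular_weight = 811.0,
                            KD_tubulin = 196.08,
                            BC,
                            PC,
                            SF_ABCB1,
                            Vmax_ABCB1, Km_ABCB1,
                            Vmax_met, Km_met,
                            Vmax_bil, Km_bil, sf_bil = 1,
                            PSA = 0.379e-3,
                            GFR_fraction = 0.11,
                            fu = 1,
                            fraction_bound_plasma = 0.75) {
  if (molecular_weight <= 0) stop("molecular_weight must be positive", call. = FALSE)
  if (KD_tubulin <= 0) stop("KD_tubulin must be positive", call. = FALSE)
  missing_bc <- setdiff(binding_tissues, names(BC))
  if (length(missing_bc))
    stop("BC missing tissue(s): ", paste(missing_bc, collapse = ", "),
         call. = FALSE)
  missing_pc <- setdiff(binding_tissues, names(PC))
  if (length(missing_pc))
    stop("PC missing tissue(s): ", paste(missing_pc, collapse = ", "),
         call. = FALSE)
  extra_sf <- setdiff(names(SF_ABCB1), c("brain", "gut", "liver", "kidney"))
  if (length(extra_sf))
    stop("SF_ABCB1 only applies to brain, gut, liver, kidney; got: ",
         paste(extra_sf, collapse = ", "), call. = FALSE)
  kin <- c(Vmax_ABCB1 = Vmax_ABCB1, Km_ABCB1 = Km_ABCB1, Vmax_met = Vmax_met,
           Km_met = Km_met, Vmax_bil = Vmax_bil, Km_bil = Km_bil,
           PSA = PSA, GFR_fraction = GFR_fraction)
  if (any(kin < 0))
    stop("kinetic constants must be non-negative: ",
         paste(names(kin)[kin < 0], collapse = ", "), call. = FALSE)
  if (any(BC < 0) || any(PC <= 0))
    stop("BC must be non-negative and PC positive for every tissue", call. = FALSE)
  if (fu <= 0 || fu > 1) stop("fu must lie in (0, 1]", call. = FALSE)

  structure(list(
    molecular_weight = molecular_weight,
    KD_tubulin = KD_tubulin,
    BC = BC[binding_tissues],
    PC = PC[binding_tissues],
    SF_ABCB1 = SF_ABCB1,
    Vmax_ABCB1 = Vmax_ABCB1, Km_ABCB1 = Km_ABCB1,
    Vmax_met = Vmax_met, Km_met = Km_met,
    Vmax_bil = Vmax_bil, Km_bil = Km_bil, sf_bil = sf_bil,
    PSA = PSA, GFR_fraction = GFR_fraction,
    fu = fu,
    fraction_bound_plasma = fraction_bound_plasma
  ), class = "drug_parameters")
}

#' Shipped vinblastine parameter sets
#'
#' Species defaults for vinblastine. Tubulin binding capacities (nmol/kg):
#' brain 10710, lung 2580, kidney 1470, liver 3510, gut 1080, slowly
#' perfused 900, rapidly perfused 3420, bone marrow 371.25; KD 196.08 nM.
#' Partition coefficients: gut 1.08, kidney 3.73, liver 2.26, bone marrow
#' 1.0, CNS 1.21, blood 1.0; tissues without an optimized value (lung,
#' slowly/rapidly perfused) default to 1.0. ABCB1 expression scaling
#' factors: brain 1.0, gut 0.14, liver 0.28, kidney 0.78. Clearance
#' kinetics: mouse metabolism Vmax 1794.9 umol/L/h, Km 11.6 umol/L; dog and
#' human metabolism Vmax 189.6 umol/L/h, Km 9.53 umol/L; mouse ABCB1 Vmax
#' 928.8 nmol/L/h, Km 6.41 nM; dog/human ABCB1 Vmax 64.54 nmol/L/h with Km
#' 5760 nM (5.76 uM ATPase-derived). Wild-type biliary excretion reuses the
#' ABCB1 kinetics scaled by the liver expression factor 0.28. PSA 0.379
#' ml/h; GFR fraction 0.11.
#'
#' @param species One of `"mouse"`, `"dog"`, `"human"`.
#' @param ... Overrides passed to [drug_parameters()].
#' @return A `drug_parameters` object (wild-type configuration; use
#'   [apply_scenario()] for knockout or induction variants).
#' @export
default_drug_parameters <- function(species = c("mouse", "dog", "human"), ...) {
  species <- match.arg(species)
  BC <- c(brain = 10710, lung = 2580, bone_marrow = 371.25, kidney = 1470,
          liver = 3510, gut = 1080, slowly_perfused = 900,
          rapidly_perfused = 3420, blood = 0)
  PC <- c(brain = 1.21, lung = 1.0, bone_marrow = 1.0, kidney = 3.73,
          liver = 2.26, gut = 1.08, slowly_perfused = 1.0,
          rapidly_perfused = 1.0, blood = 1.0)
  SF <- c(brain = 1.0, gut = 0.14, liver = 0.28, kidney = 0.78)
  if (species == "mouse") {
    kin <- list(Vmax_ABCB1 = 928.8, Km_ABCB1 = 6.41,
                Vmax_met = 1794.9 * 1e3, Km_met = 11.6 * 1e3,
                Vmax_bil = 928.8, Km_bil = 6.41, sf_bil = SF[["liver"]])
  } else {
    kin <- list(Vmax_ABCB1 = 64.54, Km_ABCB1 = 5760,
                Vmax_met = 189.6 * 1e3, Km_met = 9.53 * 1e3,
                Vmax_bil = 64.54, Km_bil = 5760, sf_bil = SF[["liver"]])
  }
  defaults <- c(list(BC = BC, PC = PC, SF_ABCB1 = SF), kin)
  args <- utils::modifyList(defaults, list(...))
  do.call(drug_parameters, args)
}

#' Apply a simulation scenario to a drug parameter set
#'
#' Scenarios are the model's switchable biological configurations:
#' \describe{
#'   \item{`wild_type`}{identity, parameters returned unchanged.}
#'   \item{`mdr1a1b_knockout`}{ABCB1 efflux disabled (`Vmax_ABCB1 = 0`) and
#'     biliary excretion swapped to the knockout kinetics
#'     (Vmax 23.35 nmol/L/h, Km 0.0152 pmol/L = 1.52e-5 nM, no ABCB1
#'     expression scaling) — the residual Mrp2-attributed route observed in
#'     knockout fecal data.}
#'   \item{`cyp3a_induction_2x`}{metabolic Vmax doubled, emulating the
#'     reported twofold CYP3A induction by omeprazole.}
#' }
#'
#' @param drug A `drug_parameters` object; never modified in place.
#' @param scenario Scenario label (see above), or `"custom"` together with
#'   `multipliers`.
#' @param multipliers Named list of multiplicative perturbations applied to
#'   scalar parameters for `scenario = "custom"`, e.g.
#'   `list(Vmax_met = 2, PSA = 0.5)`.
#' @return A new `drug_parameters` object.
#' @export
apply_scenario <- function(drug,
                           scenario = c("wild_type", "mdr1a1b_knockout",
                                        "cyp3a_induction_2x", "custom"),
                           multipliers = NULL) {
  stopifnot(inherits(drug, "drug_parameters"))
  scenario <- match.arg(scenario)
  out <- drug
  if (scenario == "wild_type") {
    # identity
  } else if (scenario == "mdr1a1b_knockout") {
    out$Vmax_ABCB1 <- 0
    out$Vmax_bil <- 23.35
    out$Km_bil <- 0.0152e-3 # 0.0152 pmol/L as printed, in nM
    out$sf_bil <- 1
  } else if (scenario == "cyp3a_induction_2x") {
    out$Vmax_met <- 2 * out$Vmax_met
  } else {
    if (is.null(multipliers) || is.null(names(multipliers)))
      stop("custom scenario requires a named 'multipliers' list", call. = FALSE)
    for (nm in names(multipliers)) {
      if (is.null(out[[nm]]) || !is.numeric(out[[nm]]))
        stop("unknown or non-numeric parameter in multipliers: ", nm,
             call. = FALSE)
      out[[nm]] <- out[[nm]] * multipliers[[nm]]
    }
  }
  attr(out, "scenario") <- scenario
  out
}

#' Convert a dose in mg to nmol
#'
#' @param dose_mg Dose in mg.
#' @param molecular_weight Molecular weight in g/mol.
#' @return Dose in nmol.
#' @export
dose_mg_to_nmol <- function(dose_mg, molecular_weight = 811.0) {
  dose_mg * 1e6 / molecular_weight
}

#' Canine body-surface area
#'
#' BSA-weight relation used to convert per-square-metre dosing to absolute
#' dose: `BSA (m^2) = k * BW^(2/3)` with `k = 0.101` for dogs.
#'
#' @param body_weight Body weight in kg.
#' @param k BSA coefficient (m^2/kg^(2/3)).
#' @return Body surface area in m^2.
#' @export
bsa_dog <- function(body_weight, k = 0.101) {
  if (any(body_weight <= 0)) stop("body_weight must be positive", call. = FALSE)
  k * body_weight^(2 / 3)
}

#' IV bolus dose event
#'
#' A single intravenous bolus at t = 0, specified as mg/kg, absolute mg, or
#' mg/m^2 (converted through [bsa_dog()]). Exactly one of the three must be
#' given.
#'
#' @param mg_per_kg Dose in mg per kg body weight.
#' @param mg Absolute dose in mg.
#' @param mg_per_m2 Dose in mg per m^2 body surface area.
#' @param bsa_k BSA coefficient used with `mg_per_m2`.
#' @return An object of class `dose_event`.
#' @export
dose_event <- function(mg_per_kg = NULL, mg = NULL, mg_per_m2 = NULL,
                       bsa_k = 0.101) {
  given <- !vapply(list(mg_per_kg, mg, mg_per_m2), is.null, logical(1))
  if (sum(given) != 1L)
    stop("specify exactly one of mg_per_kg, mg, mg_per_m2", call. = FALSE)
  amt <- c(mg_per_kg, mg, mg_per_m2)
  if (amt < 0) stop("dose must be non-negative", call. = FALSE)
  structure(list(mg_per_kg = mg_per_kg, mg = mg, mg_per_m2 = mg_per_m2,
                 bsa_k = bsa_k, route = "iv_bolus", time = 0),
            class = "dose_event")
}

# absolute dose in nmol for a given physiology
dose_nmol <- function(dose, phys, drug) {
  stopifnot(inherits(dose, "dose_event"))
  mg <- if (!is.null(dose$mg)) {
    dose$mg
  } else if (!is.null(dose$mg_per_kg)) {
    dose$mg_per_kg * phys$body_weight
  } else {
    dose$mg_per_m2 * bsa_dog(phys$body_weight, dose$bsa_k)
  }
  dose_mg_to_nmol(mg, drug$molecular_weight)
}

#' Get or set a parameter by dotted path
#'
#' Parameters of a model configuration (a list with elements `phys` and
#' `drug`) are addressed by dotted paths such as `"drug.PSA"`,
#' `"drug.PC.kidney"` or `"phys.body_weight"`. Used by the calibration and
#' virtual-population machinery.
#'
#' @param config A list with elements `phys` (`species_physiology`) and
#'   `drug` (`drug_parameters`).
#' @param path Dotted parameter path.
#' @param value Replacement value for `param_set()`.
#' @return `param_get()` the numeric value; `param_set()` the modified
#'   config.
#' @export
param_get <- function(config, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  x <- config
  for (k in keys) {
    if (is.null(x[[k]]) && !(is.atomic(x) && k %in% names(x)))
      stop("unknown parameter path: ", path, call. = FALSE)
    x <- x[[k]]
  }
  x
}

#' @rdname param_get
#' @export
param_set <- function(config, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  set_rec <- function(x, keys, value) {
    k <- keys[[1]]
    if (!(k %in% names(x)))
      stop("unknown parameter path: ", path, call. = FALSE)
    if (length(keys) == 1L) {
      x[[k]] <- value
    } else {
      x[[k]] <- set_rec(x[[k]], keys[-1], value)
    }
    x
  }
  cls <- class(config)
  out <- set_rec(config, keys, value)
  class(out) <- cls
  out
}

#' @export
print.drug_parameters <- function(x, ...) {
  cat(sprintf(paste0(
    "<drug_parameters> MW %.1f g/mol, KD(tubulin) %.4g nM\n",
    "  ABCB1: Vmax %.4g nmol/L/h, Km %.4g nM\n",
    "  metabolism: Vmax %.4g nmol/L/h, Km %.4g nM\n",
    "  biliary: Vmax %.4g nmol/L/h, Km %.4g nM (sf %.2f)\n",
    "  PSA %.4g L/h, GFR fraction %.2f\n"),
    x$molecular_weight, x$KD_tubulin, x$Vmax_ABCB1, x$Km_ABCB1,
    x$Vmax_met, x$Km_met, x$Vmax_bil, x$Km_bil, x$sf_bil,
    x$PSA, x$GFR_fraction))
  invisible(x)
}

#' Read / write drug parameter configuration files
#'
#' Drug parameters are stored as YAML in the units of the reference tables
#' (metabolism in umol/L/h and umol/L, transporter kinetics in nmol/L/h
#' and nmol/L, PSA in ml/h, binding capacities in nmol/kg); the biliary Km
#' carries an explicit unit field (`nmol/L` or `pmol/L`). The loader
#' converts everything to the internal nmol/L/h system.
#'
#' @param drug A `drug_parameters`.
#' @param path File path.
#' @return `read_drug_parameters()` returns a `drug_parameters`;
#'   `write_drug_parameters()` returns `path` invisibly.
#' @export
write_drug_parameters <- function(drug, path) {
  stopifnot(inherits(drug, "drug_parameters"))
  x <- list(
    molecular_weight_g_mol = drug$molecular_weight,
    KD_tubulin_nM = drug$KD_tubulin,
    BC_nmol_kg = as.list(drug$BC),
    PC = as.list(drug$PC),
    SF_ABCB1 = as.list(drug$SF_ABCB1),
    Vmax_ABCB1_nmol_L_h = drug$Vmax_ABCB1,
    Km_ABCB1_nmol_L = drug$Km_ABCB1,
    Vmax_met_umol_L_h = drug$Vmax_met / 1e3,
    Km_met_umol_L = drug$Km_met / 1e3,
    Vmax_bil_nmol_L_h = drug$Vmax_bil,
    Km_bil = list(value = drug$Km_bil, unit = "nmol/L"),
    sf_bil = drug$sf_bil,
    PSA_ml_h = drug$PSA * 1e3,
    GFR_fraction = drug$GFR_fraction,
    fu = drug$fu,
    fraction_bound_plasma = drug$fraction_bound_plasma
  )
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_drug_parameters
#' @export
read_drug_parameters <- function(path) {
  x <- yaml::read_yaml(path)
  km_bil <- x$Km_bil
  if (is.list(km_bil)) {
    km_bil_nM <- switch(km_bil$unit %||% "nmol/L",
      "nmol/L" = km_bil$value,
      "pmol/L" = km_bil$value * 1e-3,
      "umol/L" = km_bil$value * 1e3,
      stop("unknown Km_bil unit: ", km_bil$unit, call. = FALSE))
  } else km_bil_nM <- km_bil
  drug_parameters(
    molecular_weight = x$molecular_weight_g_mol,
    KD_tubulin = x$KD_tubulin_nM,
    BC = unlist(x$BC_nmol_kg),
    PC = unlist(x$PC),
    SF_ABCB1 = unlist(x$SF_ABCB1),
    Vmax_ABCB1 = x$Vmax_ABCB1_nmol_L_h,
    Km_ABCB1 = x$Km_ABCB1_nmol_L,
    Vmax_met = x$Vmax_met_umol_L_h * 1e3,
    Km_met = x$Km_met_umol_L * 1e3,
    Vmax_bil = x$Vmax_bil_nmol_L_h,
    Km_bil = km_bil_nM,
    sf_bil = x$sf_bil,
    PSA = x$PSA_ml_h / 1e3,
    GFR_fraction = x$GFR_fraction,
    fu = x$fu %||% 1,
    fraction_bound_plasma = x$fraction_bound_plasma %||% 0.75
  )
}
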