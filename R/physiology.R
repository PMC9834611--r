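# Species physiology: tissue volumes and blood flows for the PBPK model.

#' Tissues of the vinblastine PBPK model
#'
#' The model partitions the body into a fixed set of compartments: brain
#' (split into a vascular and a tissue sub-compartment at the blood-brain
#' barrier), bone marrow, kidney, liver, gut, slowly perfused tissue
#' (muscle, skin, fat), rapidly perfused tissue (remaining viscera), and the
#' central blood pool. The lung sits in the central blood path and is
#' handled separately (see [resolve_physiology()]).
#'
#' @format Character vector of tissue labels.
#' @export
pbpk_tissues <- c("brain", "bone_marrow", "kidney", "liver", "gut",
                  "slowly_perfused", "rapidly_perfused", "blood")

# tissues perfused by a fractional share of cardiac output
perfused_tissues <- setdiff(pbpk_tissues, "blood")

#' Construct a species physiology
#'
#' Bundles the species-level physiological parameters of the model: body
#' weight, cardiac output (measured or allometric), hematocrit, and the
#' fractional tissue weights and blood flows that [resolve_physiology()]
#' turns into absolute volumes (L) and flows (L/h).
#'
#' @param species_name Label, e.g. `"mouse"`.
#' @param body_weight Body weight in kg; must be positive.
#' @param hematocrit Hematocrit as a fraction in (0, 1). Stored as metadata;
#'   the model treats the blood-pool concentration as the serum/plasma
#'   concentration without a hematocrit correction.
#' @param cardiac_output Cardiac output in L/h, or `NULL` to derive it from
#'   the allometric relationship `co_coefficient * body_weight^co_exponent`.
#' @param tissue_weight_fraction Named numeric vector, percent of body weight
#'   per tissue; must cover all of [pbpk_tissues].
#' @param tissue_flow_fraction Named numeric vector, percent of cardiac
#'   output per perfused tissue (all tissues except `blood`).
#' @param co_coefficient,co_exponent Allometric cardiac-output coefficients
#'   (L/h/kg^exponent and dimensionless). Defaults 16.5 and 0.75, the
#'   conventional mammalian power law, give ~1.0 L/h for a 25 g mouse and
#'   ~400 L/h for a 70 kg human.
#' @param brain_tissue_fraction,brain_blood_fraction Split of total brain
#'   volume into tissue and vascular sub-compartments; must sum to 1.
#'   Defaults 0.97 / 0.03.
#' @param lung_weight_fraction Percent of body weight assigned to the lung
#'   compartment in the central blood path. The lung share is carved out of
#'   the rapidly perfused pool so total tissue volume is unchanged.
#' @return An object of class `species_physiology`.
#' @seealso [default_physiology()] for shipped mouse/dog/human parameter
#'   sets, [resolve_physiology()] for absolute volumes and flows.
#' @export
species_physiology <- function(species_name,
                               body_weight,
                               hematocrit,
                               tissue_weight_fraction,
                               tissue_flow_fraction,
                               cardiac_output = NULL,
                               co_coefficient = 16.5,
                               co_exponent = 0.75,
                               brain_tissue_fraction = 0.97,
                               brain_blood_fraction = 0.03,
                               lung_weight_fraction = 0.75) {
  if (!is.numeric(body_weight) || length(body_weight) != 1L || body_weight <= 0)
    stop("body_weight must be a single positive number (kg)", call. = FALSE)
  if (hematocrit <= 0 || hematocrit >= 1)
    stop("hematocrit must lie in (0, 1)", call. = FALSE)
  if (abs(brain_tissue_fraction + brain_blood_fraction - 1) > 1e-12)
    stop("brain_tissue_fraction + brain_blood_fraction must equal 1", call. = FALSE)

  missing_w <- setdiff(pbpk_tissues, names(tissue_weight_fraction))
  if (length(missing_w))
    stop("tissue_weight_fraction missing tissue(s): ",
         paste(missing_w, collapse = ", "), call. = FALSE)
  missing_f <- setdiff(perfused_tissues, names(tissue_flow_fraction))
  if (length(missing_f))
    stop("tissue_flow_fraction missing tissue(s): ",
         paste(missing_f, collapse = ", "), call. = FALSE)
  if (any(tissue_weight_fraction[pbpk_tissues] <= 0))
    stop("all tissue weight fractions must be positive", call. = FALSE)
  if (any(tissue_flow_fraction[perfused_tissues] <= 0))
    stop("all tissue flow fractions must be positive", call. = FALSE)
  if (sum(tissue_weight_fraction[pbpk_tissues]) > 100 + 1e-9)
    stop("tissue weight fractions sum to more than 100% of body weight",
         call. = FALSE)
  if (sum(tissue_flow_fraction[perfused_tissues]) > 100 + 1e-9)
    stop("tissue flow fractions sum to more than 100% of cardiac output",
         call. = FALSE)
  if (!is.null(cardiac_output) && cardiac_output <= 0)
    stop("cardiac_output must be positive (L/h)", call. = FALSE)
  if (lung_weight_fraction < 0 ||
      lung_weight_fraction >= tissue_weight_fraction[["rapidly_perfused"]])
    stop("lung_weight_fraction must be non-negative and smaller than the ",
         "rapidly perfused weight fraction it is carved from", call. = FALSE)

  structure(list(
    species_name = species_name,
    body_weight = body_weight,
    hematocrit = hematocrit,
    cardiac_output = cardiac_output,
    co_coefficient = co_coefficient,
    co_exponent = co_exponent,
    tissue_weight_fraction = tissue_weight_fraction[pbpk_tissues],
    tissue_flow_fraction = tissue_flow_fraction[perfused_tissues],
    brain_tissue_fraction = brain_tissue_fraction,
    brain_blood_fraction = brain_blood_fraction,
    lung_weight_fraction = lung_weight_fraction
  ), class = "species_physiology")
}

#' Allometric cardiac output
#'
#' Power-law scaling of cardiac output with body weight,
#' `CO = coefficient * BW^exponent`.
#'
#' @param body_weight Body weight in kg, positive.
#' @param coefficient Scaling coefficient in L/h/kg^exponent.
#' @param exponent Allometric exponent (dimensionless), conventionally 0.75.
#' @return Cardiac output in L/h.
#' @export
allometric_cardiac_output <- function(body_weight, coefficient = 16.5,
                                      exponent = 0.75) {
  if (any(body_weight <= 0) || coefficient <= 0)
    stop("body_weight and coefficient must be positive", call. = FALSE)
  coefficient * body_weight^exponent
}

#' Shipped species physiologies
#'
#' Reference physiologies for the three species of the model. Tissue weight
#' and flow fractions are the standard laboratory-animal/human values; the
#' mouse body weight defaults to 0.025 kg (adult female FVB), the dog to
#' 25 kg and the human to 70 kg unless overridden.
#'
#' @param species One of `"mouse"`, `"dog"`, `"human"`.
#' @param body_weight Optional body-weight override in kg.
#' @param ... Further arguments passed to [species_physiology()].
#' @return A `species_physiology` object.
#' @export
default_physiology <- function(species = c("mouse", "dog", "human"),
                               body_weight = NULL, ...) {
  species <- match.arg(species)
  tab <- species_reference_table()[[species]]
  bw <- if (is.null(body_weight)) tab$body_weight else body_weight
  species_physiology(
    species_name = species,
    body_weight = bw,
    hematocrit = tab$hematocrit,
    tissue_weight_fraction = tab$weight_fraction,
    tissue_flow_fraction = tab$flow_fraction,
    ...
  )
}

# Percent body weight and percent cardiac output per species.
species_reference_table <- function() {
  w <- function(...) {
    x <- c(...)
    names(x) <- pbpk_tissues
    x
  }
  f <- function(...) {
    x <- c(...)
    names(x) <- perfused_tissues
    x
  }
  list(
    mouse = list(
      body_weight = 0.025, hematocrit = 0.45,
      weight_fraction = w(1.65, 3.1, 1.67, 5.49, 4.22, 70.5, 8.43, 4.9),
      flow_fraction = f(3.3, 1, 9.1, 2, 13, 35, 36.6)
    ),
    dog = list(
      body_weight = 25, hematocrit = 0.45,
      weight_fraction = w(0.78, 1.2, 0.5, 3.3, 3.68, 75.8, 6.53, 8.2),
      flow_fraction = f(2, 3, 17.3, 4.6, 25.1, 38, 10)
    ),
    human = list(
      body_weight = 70, hematocrit = 0.45,
      weight_fraction = w(2, 1.1, 0.44, 2.57, 2.83, 77.3, 5.86, 7.9),
      flow_fraction = f(11.4, 3, 17.5, 4.6, 18.1, 34.3, 11.1)
    )
  )
}

#' Resolve a physiology to absolute compartment volumes and flows
#'
#' Converts fractional parameters into the absolute quantities used by the
#' ODE right-hand side: `volume = body_weight * weight_fraction/100 / density`
#' with density fixed at 1 kg/L, and `flow = cardiac_output * flow_fraction/100`.
#' The brain is split into a tissue sub-compartment (97% of brain volume by
#' default) and a vascular sub-compartment (3%); the brain blood flow
#' perfuses the vascular side. When the lung is included it receives total
#' cardiac output in series between the venous return and the blood pool,
#' and its volume is carved out of the rapidly perfused pool.
#'
#' @param phys A `species_physiology`.
#' @param include_lung Keep the lung compartment in the central blood path
#'   (default `TRUE`). `FALSE` drops it for sensitivity testing; venous
#'   returns then mix directly into the blood pool.
#' @return A data.frame with columns `compartment`, `volume_L`, `flow_Lh`
#'   and attribute `cardiac_output` (L/h). Tissue density is 1 kg/L
#'   throughout.
#' @export
resolve_physiology <- function(phys, include_lung = TRUE) {
  stopifnot(inherits(phys, "species_physiology"))
  density <- 1.0 # kg/L
  bw <- phys$body_weight
  co <- phys$cardiac_output
  if (is.null(co))
    co <- allometric_cardiac_output(bw, phys$co_coefficient, phys$co_exponent)

  wf <- phys$tissue_weight_fraction
  ff <- phys$tissue_flow_fraction
  vol <- bw * wf / 100 / density
  flow <- co * ff / 100

  v_brain <- vol[["brain"]]
  rows <- list(
    data.frame(compartment = "blood", volume_L = vol[["blood"]],
               flow_Lh = co),
    data.frame(compartment = "brain_blood",
               volume_L = phys$brain_blood_fraction * v_brain,
               flow_Lh = flow[["brain"]]),
    data.frame(compartment = "brain_tissue",
               volume_L = phys$brain_tissue_fraction * v_brain,
               flow_Lh = 0)
  )
  if (include_lung) {
    v_lung <- bw * phys$lung_weight_fraction / 100 / density
    rows <- c(rows, list(
      data.frame(compartment = "lung", volume_L = v_lung, flow_Lh = co)))
  }
  for (tis in setdiff(perfused_tissues, "brain")) {
    v <- vol[[tis]]
    if (include_lung && tis == "rapidly_perfused")
      v <- v - bw * phys$lung_weight_fraction / 100 / density
    rows <- c(rows, list(
      data.frame(compartment = tis, volume_L = v, flow_Lh = flow[[tis]])))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- out$compartment
  if (any(out$volume_L <= 0))
    stop("resolved non-positive volume for compartment(s): ",
         paste(out$compartment[out$volume_L <= 0], collapse = ", "),
         call. = FALSE)
  attr(out, "cardiac_output") <- co
  attr(out, "body_weight") <- bw
  out
}

#' Read / write species physiology configuration files
#'
#' Physiologies are stored as YAML with keys mirroring the fields of
#' [species_physiology()]. A round trip through `write_physiology()` and
#' `read_physiology()` reproduces identical resolved compartments.
#'
#' @param phys A `species_physiology`.
#' @param path File path.
#' @return `read_physiology()` returns a `species_physiology`;
#'   `write_physiology()` returns `path` invisibly.
#' @export
write_physiology <- function(phys, path) {
  stopifnot(inherits(phys, "species_physiology"))
  x <- unclass(phys)
  x$tissue_weight_fraction <- as.list(x$tissue_weight_fraction)
  x$tissue_flow_fraction <- as.list(x$tissue_flow_fraction)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_physiology
#' @export
read_physiology <- function(path) {
  x <- yaml::read_yaml(path)
  species_physiology(
    species_name = x$species_name,
    body_weight = x$body_weight,
    hematocrit = x$hematocrit,
    tissue_weight_fraction = unlist(x$tissue_weight_fraction),
    tissue_flow_fraction = unlist(x$tissue_flow_fraction),
    cardiac_output = x$cardiac_output,
    co_coefficient = x$co_coefficient,
    co_exponent = x$co_exponent,
    brain_tissue_fraction = x$brain_tissue_fraction,
    brain_blood_fraction = x$brain_blood_fraction,
    lung_weight_fraction = x$lung_weight_fraction
  )
}

#' @export
print.species_physiology <- function(x, ...) {
  co <- x$cardiac_output
  co_lab <- if (is.null(co)) {
    sprintf("%.3g L/h (allometric %.3g * BW^%.3g)",
            allometric_cardiac_output(x$body_weight, x$co_coefficient,
                                      x$co_exponent),
            x$co_coefficient, x$co_exponent)
  } else sprintf("%.3g L/h", co)
  cat(sprintf("<species_physiology> %s: BW %.3g kg, CO %s, Hct %.2f\n",
              x$species_name, x$body_weight, co_lab, x$hematocrit))
  invisible(x)
}
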