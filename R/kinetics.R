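# Enzyme kinetics: Michaelis-Menten glycosidases, sequential-order Bi-Bi
# glycosyltransferases, and the parameter containers for the Golgi model.

.COMPARTMENTS <- c("cis", "medial", "trans", "TGN")

.ENZYME_LAW <- c(ManI = "MM", ManII = "MM",
                 GnTI = "BiBi", GnTII = "BiBi", GnTIV = "BiBi", GnTV = "BiBi",
                 b4GalT = "BiBi", a3SiaT = "BiBi", a6FucT = "BiBi",
                 a3FucT = "BiBi", iGnT = "BiBi")

.ENZYME_NSD <- c(GnTI = "UDP-GlcNAc", GnTII = "UDP-GlcNAc",
                 GnTIV = "UDP-GlcNAc", GnTV = "UDP-GlcNAc",
                 iGnT = "UDP-GlcNAc",
                 b4GalT = "UDP-Gal", a3SiaT = "CMP-Neu5Ac",
                 a6FucT = "GDP-Fuc", a3FucT = "GDP-Fuc")

# Literature-style cis/medial/trans/TGN localisation profiles; fully
# overridable through enzyme_specs().
.ENZYME_FRACTIONS <- list(
  ManI   = c(0.55, 0.35, 0.08, 0.02),
  ManII  = c(0.10, 0.60, 0.25, 0.05),
  GnTI   = c(0.10, 0.60, 0.25, 0.05),
  GnTII  = c(0.05, 0.55, 0.30, 0.10),
  GnTIV  = c(0.05, 0.45, 0.40, 0.10),
  GnTV   = c(0.05, 0.45, 0.40, 0.10),
  a6FucT = c(0.05, 0.40, 0.45, 0.10),
  a3FucT = c(0.05, 0.40, 0.45, 0.10),
  b4GalT = c(0.02, 0.18, 0.50, 0.30),
  a3SiaT = c(0.01, 0.09, 0.40, 0.50),
  iGnT   = c(0.05, 0.25, 0.50, 0.20))

#' Enzyme kinetic specifications
#'
#' Builds the per-enzyme specification used by the Golgi model: kinetic
#' law (Michaelis-Menten for the glycosidases ManI and ManII,
#' sequential-order Bi-Bi for all glycosyltransferases), the nucleotide
#' sugar donor consumed by each transferase, and the fraction of the
#' enzyme pool localised to each of the four Golgi compartments.
#'
#' @param enzymes Enzyme names (subset of [GLYCO_ENZYMES]).
#' @param fractions Optional named list overriding the compartment
#'   localisation profile of individual enzymes; each entry a length-4
#'   non-negative vector summing to 1 (cis, medial, trans, TGN).
#' @return Named list of `enzyme_spec` objects with fields `name`,
#'   `law`, `nsd`, `compartment_fractions`.
#' @export
enzyme_specs <- function(enzymes = GLYCO_ENZYMES, fractions = list()) {
  stopifnot(all(enzymes %in% GLYCO_ENZYMES))
  out <- lapply(enzymes, function(e) {
    f <- fractions[[e]] %||% .ENZYME_FRACTIONS[[e]]
    f <- stats::setNames(as.numeric(f), .COMPARTMENTS)
    if (any(f < 0) || abs(sum(f) - 1) > 1e-9)
      stop("compartment fractions of ", e, " must be non-negative and sum to 1")
    structure(list(name = e,
                   law = unname(.ENZYME_LAW[[e]]),
                   nsd = if (e %in% names(.ENZYME_NSD)) .ENZYME_NSD[[e]]
                         else NA_character_,
                   compartment_fractions = f),
              class = "enzyme_spec")
  })
  stats::setNames(out, enzymes)
}

#' Protein entity transiting the Golgi
#'
#' @param name Entity label (e.g. `"IgG"`, `"HCP"`).
#' @param molecular_weight Molecular weight in kDa; the Golgi transit
#'   velocity is inversely proportional to it, so heavier cargo resides
#'   longer in each compartment.
#' @param production_rate Molar production rate entering the cis
#'   compartment, in uM/min. The default model assumption is equal
#'   production rates for all entities.
#' @return An `protein_entity` object.
#' @export
protein_entity <- function(name, molecular_weight, production_rate = 1) {
  stopifnot(molecular_weight > 0, production_rate > 0)
  structure(list(name = name, molecular_weight = molecular_weight,
                 production_rate = production_rate),
            class = "protein_entity")
}

#' Golgi compartment configuration
#'
#' @param residence_time_ref Reference residence time (minutes) per
#'   compartment for cargo of molecular weight `mw_ref`; scaled for each
#'   entity by `MW / mw_ref` (inverse-velocity assumption).
#' @param mw_ref Reference molecular weight in kDa.
#' @return A `golgi_config` object.
#' @export
golgi_config <- function(residence_time_ref = c(cis = 5, medial = 5,
                                                trans = 5, TGN = 5),
                         mw_ref = 150) {
  residence_time_ref <- stats::setNames(as.numeric(residence_time_ref),
                                        .COMPARTMENTS)
  stopifnot(all(residence_time_ref > 0), mw_ref > 0)
  structure(list(compartments = .COMPARTMENTS,
                 residence_time_ref = residence_time_ref,
                 mw_ref = mw_ref),
            class = "golgi_config")
}

# Literature-style fixed constants (per-enzyme turnover rates in 1/min,
# compartment-constant NSD pools and NSD dissociation constants in uM);
# all user-overridable via kinetic_parameters(). Enzyme levels default
# to a partial-conversion regime that yields a core-fucosylated,
# moderately galactosylated complex-type profile for slow-transiting
# cargo.
.DEFAULT_KF <- c(ManI = 888, ManII = 1924, GnTI = 1022, GnTII = 1406,
                 GnTIV = 873, GnTV = 1022, b4GalT = 742, a3SiaT = 491,
                 a6FucT = 291, a3FucT = 291, iGnT = 1022)
.DEFAULT_ENZ <- c(ManI = 0.5, ManII = 0.4, GnTI = 0.3, GnTII = 0.4,
                  GnTIV = 0.005, GnTV = 0.005, b4GalT = 0.03,
                  a3SiaT = 0.05, a6FucT = 1.5, a3FucT = 0.01, iGnT = 0.01)
.DEFAULT_NSD <- c(`UDP-GlcNAc` = 1000, `UDP-Gal` = 500,
                  `CMP-Neu5Ac` = 150, `GDP-Fuc` = 50)
.DEFAULT_KMD <- c(`UDP-GlcNAc` = 170, `UDP-Gal` = 65,
                  `CMP-Neu5Ac` = 57, `GDP-Fuc` = 46)

#' Kinetic parameter set for the Golgi model
#'
#' Collects every tunable quantity of the kinetic model: turnover rates
#' `kf` (1/min, per enzyme), total Golgi enzyme concentrations
#' `enz_total` (uM), compartment-constant NSD concentrations `nsd_conc`
#' (uM), oligosaccharide dissociation constants `km` (uM, per enzyme and
#' entity with optional per-substrate override), NSD dissociation
#' constants `kmd` (uM, per enzyme), and the M9 mass fraction `m9_prop`
#' of the M8/M9 pool entering the cis compartment per entity.
#'
#' @param enzymes Enzyme names present in the model.
#' @param entities Character vector of entity names.
#' @param kf,enz_total Named numeric overrides per enzyme.
#' @param nsd_conc Named numeric overrides per NSD.
#' @param km Default dissociation constant, a single number, or a named
#'   list `km[[entity]][[enzyme]]`.
#' @param km_override Nested list `[[entity]][[enzyme]][[node]]` of
#'   per-substrate overrides.
#' @param kmd Named numeric overrides per enzyme.
#' @param m9_prop Named numeric in (0,1) per entity (default 0.5).
#' @return A `kinetic_parameters` object.
#' @export
kinetic_parameters <- function(enzymes = GLYCO_ENZYMES, entities = c("IgG", "HCP"),
                               kf = NULL, enz_total = NULL, nsd_conc = NULL,
                               km = 200, km_override = list(), kmd = NULL,
                               m9_prop = NULL) {
  kf_full <- .DEFAULT_KF[enzymes]
  if (!is.null(kf)) kf_full[names(kf)] <- kf
  et <- .DEFAULT_ENZ[enzymes]
  if (!is.null(enz_total)) et[names(enz_total)] <- enz_total
  nsd <- .DEFAULT_NSD
  if (!is.null(nsd_conc)) nsd[names(nsd_conc)] <- nsd_conc
  if (is.numeric(km) && length(km) == 1L)
    km <- stats::setNames(lapply(entities, function(p)
      stats::setNames(as.list(rep(km, length(enzymes))), enzymes)), entities)
  bibi <- enzymes[enzymes %in% names(.ENZYME_NSD)]
  kmd_full <- stats::setNames(.DEFAULT_KMD[.ENZYME_NSD[bibi]], bibi)
  if (!is.null(kmd)) kmd_full[names(kmd)] <- kmd
  m9 <- stats::setNames(rep(0.5, length(entities)), entities)
  if (!is.null(m9_prop)) m9[names(m9_prop)] <- m9_prop
  p <- structure(list(kf = kf_full, enz_total = et, nsd_conc = nsd,
                      km = km, km_override = km_override, kmd = kmd_full,
                      m9_prop = m9, entities = entities, enzymes = enzymes),
                 class = "kinetic_parameters")
  .validate_params(p)
  p
}

.validate_params <- function(p) {
  if (any(p$kf <= 0, na.rm = TRUE) || any(p$enz_total < 0) ||
      any(p$nsd_conc < 0) || any(unlist(p$km) <= 0) ||
      any(unlist(p$kmd) <= 0))
    stop("parameter error: kinetic constants must be positive")
  if (any(p$m9_prop <= 0 | p$m9_prop >= 1))
    stop("parameter error: m9_prop must lie strictly in (0, 1)")
  invisible(p)
}

# Dissociation constant lookup with per-substrate override.
.get_km <- function(params, node, enzyme, entity) {
  ov <- params$km_override[[entity]][[enzyme]][[node]]
  if (!is.null(ov)) return(ov)
  v <- params$km[[entity]][[enzyme]]
  if (is.null(v)) stop("parameter error: no Km for enzyme ", enzyme,
                       " and entity ", entity)
  v
}

#' Michaelis-Menten rate with competing substrates
#'
#' Rate of a glycosidase acting on one substrate while all alternative
#' substrates of the same enzyme (across protein entities) compete for
#' the active site:
#' \deqn{r = \frac{k_f [ENZ] [OS]}{K_m (1 + \sum_c [OS]_c / K_{m,c})}}
#' where the competition sum runs over every competing substrate,
#' including the one being converted.
#'
#' @param os Substrate concentration (uM).
#' @param enz Enzyme concentration in the compartment (uM).
#' @param kf Turnover rate (1/min).
#' @param km Dissociation constant of the substrate (uM).
#' @param competing_conc,competing_km Concentrations and dissociation
#'   constants of all competing substrates (defaults: just the substrate
#'   itself).
#' @return Reaction rate in uM/min.
#' @examples
#' rate_mm(100, 1, 60, 100)            # half-saturation: 30
#' @export
rate_mm <- function(os, enz, kf, km, competing_conc = os, competing_km = km) {
  if (km <= 0 || any(competing_km <= 0))
    stop("parameter error: Km must be positive")
  kf * enz * os / (km * (1 + sum(competing_conc / competing_km)))
}

#' Sequential-order Bi-Bi rate with competing substrates
#'
#' Rate of a glycosyltransferase binding its nucleotide sugar donor
#' first and the oligosaccharide second:
#' \deqn{r = \frac{k_f [ENZ] [NSD] [OS]}{K_m K_{md} \left[1 +
#'   \frac{[NSD]}{K_{md}} \left(1 + \sum_c [OS]_c / K_{m,c}\right)\right]}}
#'
#' @inheritParams rate_mm
#' @param nsd Nucleotide sugar donor concentration (uM).
#' @param kmd Dissociation constant of the enzyme-NSD complex (uM).
#' @return Reaction rate in uM/min.
#' @examples
#' rate_bibi(100, 1, 60, 100, nsd = 50, kmd = 50)   # kf*E/3 = 20
#' @export
rate_bibi <- function(os, enz, kf, km, nsd, kmd,
                      competing_conc = os, competing_km = km) {
  if (km <= 0 || any(competing_km <= 0))
    stop("parameter error: Km must be positive")
  if (kmd <= 0) stop("parameter error: Kmd must be positive")
  kf * enz * nsd * os /
    (km * kmd * (1 + (nsd / kmd) * (1 + sum(competing_conc / competing_km))))
}
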