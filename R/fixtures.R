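# Synthetic fixtures: a small biosynthetically sensible reaction network
# and model-generated glycoprofiles, so every stage of the pipeline can
# be exercised without external data.

# Hand-authored LinearCode constants (kept literal so the parser and the
# fixture can never disagree on composition).
.TOY_NODES <- data.frame(
  id = c("M9", "M8", "M6", "M5", "M6A1", "M5A1", "A1", "A2", "FA1", "FA2",
         "FA2G1a", "FA2G1b", "FA2G2", "FA2G2S1", "FA2G2S2", "FA3", "FA4"),
  linear_code = c(
    "Ma2Ma2Ma3(Ma2Ma3(Ma2Ma6)Ma6)Mb4GNb4GN",
    "Ma2Ma2Ma3(Ma2Ma3(Ma6)Ma6)Mb4GNb4GN",
    "Ma2Ma3(Ma3(Ma6)Ma6)Mb4GNb4GN",
    "Ma3(Ma3(Ma6)Ma6)Mb4GNb4GN",
    "GNb2Ma2Ma3(Ma3(Ma6)Ma6)Mb4GNb4GN",
    "GNb2Ma3(Ma3(Ma6)Ma6)Mb4GNb4GN",
    "GNb2Ma3(Ma6)Mb4GNb4GN",
    "GNb2Ma3(GNb2Ma6)Mb4GNb4GN",
    "GNb2Ma3(Ma6)Mb4GNb4(Fa6)GN",
    "GNb2Ma3(GNb2Ma6)Mb4GNb4(Fa6)GN",
    "Ab4GNb2Ma3(GNb2Ma6)Mb4GNb4(Fa6)GN",
    "GNb2Ma3(Ab4GNb2Ma6)Mb4GNb4(Fa6)GN",
    "Ab4GNb2Ma3(Ab4GNb2Ma6)Mb4GNb4(Fa6)GN",
    "NNa3Ab4GNb2Ma3(Ab4GNb2Ma6)Mb4GNb4(Fa6)GN",
    "NNa3Ab4GNb2Ma3(NNa3Ab4GNb2Ma6)Mb4GNb4(Fa6)GN",
    "GNb2(GNb4)Ma3(GNb2Ma6)Mb4GNb4(Fa6)GN",
    "GNb2(GNb4)Ma3(GNb2(GNb6)Ma6)Mb4GNb4(Fa6)GN"),
  stringsAsFactors = FALSE)

.TOY_EDGES <- data.frame(
  from = c("M9", "M8", "M6", "M6", "M5", "M6A1", "M5A1", "A1", "A1", "A2",
           "FA1", "FA2", "FA2", "FA2G1a", "FA2G1b", "FA2G2", "FA2G2S1",
           "FA2", "FA3"),
  to = c("M8", "M6", "M5", "M6A1", "M5A1", "M5A1", "A1", "A2", "FA1", "FA2",
         "FA2", "FA2G1a", "FA2G1b", "FA2G2", "FA2G2", "FA2G2S1", "FA2G2S2",
         "FA3", "FA4"),
  enzyme = c("ManI", "ManI", "ManI", "GnTI", "GnTI", "ManI", "ManII",
             "GnTII", "a6FucT", "a6FucT", "GnTII", "b4GalT", "b4GalT",
             "b4GalT", "b4GalT", "a3SiaT", "a3SiaT", "GnTIV", "GnTV"),
  stringsAsFactors = FALSE)

#' Toy glycosylation reaction network fixture
#'
#' A 17-node N-glycan maturation network rooted at M9: mannose trimming
#' (ManI) to M5, hybrid formation (GnTI) with a trimming/branching
#' diamond converging at M5A1, antenna completion and core fucosylation
#' with a second diamond converging at FA2, galactosylation on either
#' arm (two FA2G1 isomorphs) converging at FA2G2, sialylation up to the
#' disialylated FA2G2S2, and a divergent GnTIV/GnTV branch to
#' tri-/tetra-antennary structures. By construction the dual
#' betweenness/dominance-frontier criterion flags exactly the M5A1, FA2
#' and FA2G2 nodes as critical.
#'
#' @param n_isomorph_pairs 1 (default) keeps both FA2G1 arm isomorphs;
#'   0 drops the a1-6-arm isomorph (the FA2G2 convergence diamond, and
#'   with it that node's criticality, disappears).
#' @param enzymes Optional enzyme subset; edges catalysed by other
#'   enzymes are removed (an error if that disconnects a requested sink).
#' @param sinks Sink node ids (default the terminal structures
#'   `FA2G2S2` and `FA4`).
#' @return A validated `glyco_grn` with source `"M9"`.
#' @export
make_toy_grn <- function(n_isomorph_pairs = 1, enzymes = NULL,
                         sinks = c("FA2G2S2", "FA4")) {
  nodes <- .TOY_NODES
  edges <- .TOY_EDGES
  if (n_isomorph_pairs < 1) {
    nodes <- nodes[nodes$id != "FA2G1b", ]
    edges <- edges[edges$from != "FA2G1b" & edges$to != "FA2G1b", ]
  }
  if (!is.null(enzymes)) {
    edges <- edges[edges$enzyme %in% enzymes, ]
    keep <- unique(c("M9", edges$from, edges$to))
    nodes <- nodes[nodes$id %in% keep, ]
    if (!all(sinks %in% nodes$id))
      stop("fixture error: enzyme subset disconnects requested sink(s): ",
           paste(setdiff(sinks, nodes$id), collapse = ", "))
  }
  net <- tryCatch(
    reaction_network(nodes, edges, source = "M9", sinks = sinks),
    error = function(e)
      stop("fixture error: enzyme subset disconnects requested sinks (",
           conditionMessage(e), ")"))
  net
}

#' Fixture protein entities
#'
#' Two competing cargo proteins mirroring a recombinant-antibody /
#' host-cell-protein contrast: a heavy slow-transiting entity and a
#' light fast-transiting one, with equal production rates.
#'
#' @return List of two [protein_entity] objects (`IgG`, 150 kDa; `HCP`,
#'   45 kDa).
#' @export
toy_entities <- function() {
  list(protein_entity("IgG", molecular_weight = 150, production_rate = 1),
       protein_entity("HCP", molecular_weight = 45, production_rate = 1))
}

#' Fixture kinetic parameters with an IgG/HCP affinity contrast
#'
#' The default parameter set extended with the qualitative contrast of
#' the two fixture entities: enzymes bind the light entity's glycans
#' with much lower affinity (Km 3000 uM vs 200 uM), and the light
#' entity enters the Golgi with a high M9 fraction. Combined with its
#' faster transit this leaves it high-mannose dominated while the heavy
#' entity matures to a core-fucosylated complex-type profile.
#'
#' @param km_heavy,km_light Dissociation constants (uM) for the heavy
#'   and light entity (defaults 200 and 3000).
#' @return A [kinetic_parameters()] object for entities `IgG`, `HCP`.
#' @export
toy_parameters <- function(km_heavy = 200, km_light = 3000) {
  enz <- GLYCO_ENZYMES
  kinetic_parameters(
    enzymes = enz, entities = c("IgG", "HCP"),
    km = list(IgG = stats::setNames(as.list(rep(km_heavy, length(enz))), enz),
              HCP = stats::setNames(as.list(rep(km_light, length(enz))), enz)),
    m9_prop = c(IgG = 0.5, HCP = 0.8))
}

#' Synthetic observed glycoprofiles from a known parameter set
#'
#' Simulates the Golgi model at ground-truth parameters, perturbs the
#' tag percentages with truncated Gaussian noise and renormalises each
#' entity to 100 percent. The ground truth is recorded as attribute
#' `theta_star` for recovery experiments.
#'
#' @param net A `glyco_grn` (default [make_toy_grn()]).
#' @param params Ground-truth [kinetic_parameters()].
#' @param entities List of [protein_entity] objects.
#' @param noise_sd Noise standard deviation in percent units (default 1).
#' @param seed RNG seed (default 1).
#' @param theta_star Optional named vector of free-parameter values
#'   applied on top of `params` (stored as the recoverable truth).
#' @param specs,config Enzyme specifications and Golgi configuration.
#' @return Data frame `entity`, `tag`, `percent` with attribute
#'   `theta_star`.
#' @export
make_synthetic_profiles <- function(net = make_toy_grn(),
                                    params = kinetic_parameters(),
                                    entities = toy_entities(),
                                    noise_sd = 1, seed = 1,
                                    theta_star = NULL,
                                    specs = enzyme_specs(),
                                    config = golgi_config()) {
  model <- assemble_golgi_model(net, entities, specs, config, params)
  if (!is.null(theta_star)) params <- apply_free_params(params, theta_star)
  res <- simulate_golgi(model, params)
  if (!res$converged)
    stop("fixture error: model not convergent at the ground-truth parameters")
  set.seed(seed)
  out <- do.call(rbind, lapply(names(res$profiles), function(ent) {
    pct <- res$profiles[[ent]]
    if (noise_sd > 0) {
      pct <- pmax(pct + stats::rnorm(length(pct), 0, noise_sd), 0)
      pct <- 100 * pct / sum(pct)
    }
    data.frame(entity = ent, tag = names(pct), percent = as.numeric(pct),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "theta_star") <- theta_star
  out
}
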