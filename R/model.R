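# Golgi model assembly and steady-state simulation: four well-mixed
# compartments in series (vesicular transport), competing protein
# entities, Michaelis-Menten / sequential Bi-Bi kinetics.

#' Build the stoichiometric matrix of a reaction network
#'
#' One species per (node, entity) pair and one reaction column per
#' (edge, entity) pair: the substrate row carries -1, the product row
#' +1, so each column sums to zero (one glycan converted per reaction)
#' and species of different entities never mix within a column.
#' Ordering is deterministic: topological node order within
#' entity-major blocks.
#'
#' @param net A pruned `glyco_grn`.
#' @param entities List of [protein_entity] objects (or entity names).
#' @return A `stoichiometric_model`: list with `species` (data frame
#'   `node`, `entity`), `reactions` (data frame `from`, `to`, `enzyme`,
#'   `entity`) and the matrix `S`.
#' @export
build_stoichiometry <- function(net, entities) {
  stopifnot(inherits(net, "glyco_grn"))
  ent_names <- vapply(entities, function(p)
    if (inherits(p, "protein_entity")) p$name else as.character(p), "")
  g <- net$graph
  topo <- names(igraph::topo_sort(g, mode = "out"))
  ed <- network_edges(net)
  if (nrow(ed) && any(!ed$enzyme %in% GLYCO_ENZYMES))
    stop("edge with unknown enzyme: ",
         paste(unique(ed$enzyme[!ed$enzyme %in% GLYCO_ENZYMES]), collapse = ", "))
  ed <- ed[order(match(ed$from, topo), match(ed$to, topo)), , drop = FALSE]

  species <- expand.grid(node = topo, entity = ent_names,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  species <- species[order(match(species$entity, ent_names),
                           match(species$node, topo)), ]
  rownames(species) <- NULL
  reactions <- do.call(rbind, lapply(ent_names, function(p)
    cbind(ed, entity = p, stringsAsFactors = FALSE)))
  if (is.null(reactions))
    reactions <- data.frame(from = character(), to = character(),
                            enzyme = character(), entity = character())
  S <- matrix(0L, nrow(species), nrow(reactions),
              dimnames = list(paste(species$node, species$entity, sep = "."),
                              NULL))
  if (nrow(reactions)) {
    si <- match(paste(reactions$from, reactions$entity, sep = "."),
                rownames(S))
    pi <- match(paste(reactions$to, reactions$entity, sep = "."), rownames(S))
    for (j in seq_len(nrow(reactions))) {
      S[si[j], j] <- -1L
      S[pi[j], j] <- 1L
    }
  }
  structure(list(species = species, reactions = reactions, S = S),
            class = "stoichiometric_model")
}

#' Assemble the four-compartment Golgi kinetic model
#'
#' Combines the network stoichiometry, enzyme specifications, Golgi
#' configuration and protein entities into a model object whose
#' steady-state residual for species `i` of entity `p` in compartment
#' `c` is
#' \deqn{\frac{1}{\tau_{c,p}}([OS]_{i,c-1,p} - [OS]_{i,c,p}) +
#'   \sum_j S_{ij} r_j = 0,}
#' with \eqn{\tau_{c,p}} the reference residence time scaled by
#' `MW_p / mw_ref` (transit velocity inversely proportional to
#' molecular weight). The inlet to the cis compartment splits each
#' entity's inflow between the M9 node (fraction `m9_prop`) and the M8
#' node (remainder); when the network carries no M8 node the entire
#' inflow enters at M9.
#'
#' @param net A pruned `glyco_grn` whose source is the M9 node.
#' @param entities List of [protein_entity] objects.
#' @param specs Output of [enzyme_specs()] covering every edge enzyme.
#' @param config A [golgi_config()].
#' @param params A [kinetic_parameters()] set.
#' @param competition `"all_substrates"` (default): the competition sum
#'   in the rate laws runs over every alternative substrate of the
#'   enzyme across all entities; `"entities_only"`: only over entities
#'   at the same substrate.
#' @return A `golgi_model` object.
#' @export
assemble_golgi_model <- function(net, entities, specs = enzyme_specs(),
                                 config = golgi_config(),
                                 params = NULL,
                                 competition = c("all_substrates",
                                                 "entities_only")) {
  competition <- match.arg(competition)
  stopifnot(inherits(net, "glyco_grn"), inherits(config, "golgi_config"))
  if (!all(vapply(entities, inherits, TRUE, "protein_entity")))
    stop("assembly error: entities must be protein_entity objects")
  ent_names <- vapply(entities, `[[`, "", "name")
  stoich <- build_stoichiometry(net, entities)
  enz_used <- unique(stoich$reactions$enzyme)
  if (!all(enz_used %in% names(specs)))
    stop("assembly error: missing enzyme spec(s): ",
         paste(setdiff(enz_used, names(specs)), collapse = ", "))
  if (is.null(params))
    params <- kinetic_parameters(enzymes = union(enz_used, GLYCO_ENZYMES),
                                 entities = ent_names)
  tags <- stats::setNames(igraph::V(net$graph)$tag, igraph::V(net$graph)$name)
  m9_node <- names(tags)[tags == "M9"]
  m8_node <- names(tags)[tags == "M8"]
  if (length(m9_node) != 1L)
    stop("assembly error: network must carry exactly one M9 node")
  structure(list(net = net, entities = entities, specs = specs,
                 config = config, params = params, stoich = stoich,
                 competition = competition,
                 m9_node = m9_node,
                 m8_node = if (length(m8_node)) m8_node[1] else NA_character_),
            class = "golgi_model")
}

# residence time matrix: compartments x entities
.tau_matrix <- function(model) {
  mw <- vapply(model$entities, `[[`, 0, "molecular_weight")
  ent <- vapply(model$entities, `[[`, "", "name")
  outer(model$config$residence_time_ref,
        stats::setNames(mw / model$config$mw_ref, ent))
}

# inlet concentration vector (over species rows) to the cis compartment
.inlet_vector <- function(model, params) {
  sp <- model$stoich$species
  ent <- vapply(model$entities, `[[`, "", "name")
  tau_cis <- .tau_matrix(model)["cis", , drop = FALSE]
  x <- stats::setNames(numeric(nrow(sp)), rownames(model$stoich$S))
  for (k in seq_along(ent)) {
    total <- model$entities[[k]]$production_rate * tau_cis[1, ent[k]]
    m9p <- params$m9_prop[[ent[k]]]
    if (is.na(model$m8_node)) {
      x[paste(model$m9_node, ent[k], sep = ".")] <- total
    } else {
      x[paste(model$m9_node, ent[k], sep = ".")] <- m9p * total
      x[paste(model$m8_node, ent[k], sep = ".")] <- (1 - m9p) * total
    }
  }
  x
}

# Precompute index structures and rate-law coefficients for fast
# residual/Jacobian evaluation. Rates take the common form
#   r_j = a_j * x[sub_j] / D_j,  D_j = d0_j + b_j * C_{g(j)},
# with C_g = sum over the competition pool of x/Km; for MM d0 = 1 and
# b = 1, for sequential Bi-Bi b = [NSD]/Kmd and d0 = 1 + b.
.compile_model <- function(model, params) {
  sp <- model$stoich$species
  rx <- model$stoich$reactions
  n <- nrow(sp)
  key <- rownames(model$stoich$S)
  sub <- match(paste(rx$from, rx$entity, sep = "."), key)
  nr <- nrow(rx)
  if (nr == 0L)
    return(list(n = n, nr = 0L))
  km_r <- vapply(seq_len(nr), function(j)
    .get_km(params, rx$from[j], rx$enzyme[j], rx$entity[j]), numeric(1))
  law <- vapply(rx$enzyme, function(e) model$specs[[e]]$law, "")
  kf_r <- params$kf[rx$enzyme]
  nsd_r <- vapply(seq_len(nr), function(j) {
    s <- model$specs[[rx$enzyme[j]]]
    if (s$law == "BiBi") params$nsd_conc[[s$nsd]] else NA_real_
  }, numeric(1))
  kmd_r <- ifelse(law == "BiBi", params$kmd[rx$enzyme], NA_real_)
  b <- ifelse(law == "BiBi", nsd_r / kmd_r, 1)
  d0 <- ifelse(law == "BiBi", 1 + b, 1)
  # per-compartment maximal velocity coefficient a_jc
  frac <- t(vapply(rx$enzyme, function(e)
    model$specs[[e]]$compartment_fractions, numeric(4)))
  vmax <- kf_r * params$enz_total[rx$enzyme] * frac    # nr x 4
  a <- ifelse(law == "BiBi", nsd_r / (km_r * kmd_r), 1 / km_r) * vmax
  colnames(a) <- .COMPARTMENTS

  # competition pools: one group per enzyme (all_substrates) or per
  # (enzyme, substrate node) (entities_only), spanning all entities
  gkey <- if (model$competition == "all_substrates") rx$enzyme
          else paste(rx$enzyme, rx$from)
  groups <- unique(gkey)
  gid <- match(gkey, groups)
  ent <- unique(sp$entity)
  G <- matrix(0, length(groups), n)
  for (gi in seq_along(groups)) {
    jj <- which(gid == gi)
    subs <- unique(rx$from[jj])
    e <- rx$enzyme[jj[1]]
    for (nd in subs) for (p in ent) {
      idx <- match(paste(nd, p, sep = "."), key)
      G[gi, idx] <- 1 / .get_km(params, nd, e, p)
    }
  }
  list(n = n, nr = nr, sub = sub, km_r = km_r, a = a, b = b, d0 = d0,
       gid = gid, G = G, S = model$stoich$S)
}

.cm_rates <- function(cm, x, compartment, scale = 1) {
  C <- as.vector(cm$G %*% x)[cm$gid]
  D <- cm$d0 + cm$b * C
  scale * cm$a[, compartment] * x[cm$sub] / D
}

.cm_residual <- function(cm, x, prev, compartment, tau_v, scale = 1) {
  dil <- (prev - x) / tau_v
  if (cm$nr == 0L) return(dil)
  dil + as.vector(cm$S %*% .cm_rates(cm, x, compartment, scale))
}

.cm_jacobian <- function(cm, x, compartment, tau_v, scale = 1) {
  J <- diag(-1 / tau_v, cm$n)
  if (cm$nr == 0L) return(J)
  C <- as.vector(cm$G %*% x)[cm$gid]
  D <- cm$d0 + cm$b * C
  aj <- scale * cm$a[, compartment]
  Jr <- matrix(0, cm$nr, cm$n)
  Jr[cbind(seq_len(cm$nr), cm$sub)] <- aj / D
  coef <- -aj * x[cm$sub] * cm$b / D^2
  for (gi in unique(cm$gid)) {
    rows <- which(cm$gid == gi)
    Jr[rows, ] <- Jr[rows, , drop = FALSE] + outer(coef[rows], cm$G[gi, ])
  }
  J + cm$S %*% Jr
}

#' Solve the Golgi model to steady state
#'
#' Solves the compartments in series (cis to TGN; each compartment's
#' inlet is the previous compartment's steady state) with a
#' Levenberg-Marquardt root finder (analytic Jacobian) on the
#' mass-balance residuals. On poor convergence the solve is retried
#' along an enzyme-scaling continuation ladder (enzyme levels ramped
#' from a small fraction to 1, warm-starting each step).
#'
#' @param model A `golgi_model` from [assemble_golgi_model()].
#' @param params Optional [kinetic_parameters()] overriding the set
#'   stored in the model.
#' @param tol Residual norm (Euclidean) required for convergence
#'   (default `1e-9`).
#' @param ladder Enzyme scales for the continuation fallback.
#' @return A `simulation_result`: `state` (node x entity x compartment
#'   array, uM), `profiles` (per entity, named percent vector over tags
#'   at the TGN outlet), `converged`, `residual_norm`, `inlet` (inlet
#'   concentration matrix, nodes x entities).
#' @export
simulate_golgi <- function(model, params = NULL, tol = 1e-9,
                           ladder = c(0.25, 0.5, 0.75, 1)) {
  stopifnot(inherits(model, "golgi_model"))
  params <- params %||% model$params
  .validate_params(params)
  cm <- .compile_model(model, params)
  sp <- model$stoich$species
  nodes <- unique(sp$node)
  ent <- vapply(model$entities, `[[`, "", "name")
  tau <- .tau_matrix(model)
  tau_v <- stats::setNames(numeric(nrow(sp)), NULL)
  inlet <- .inlet_vector(model, params)
  state <- array(0, dim = c(length(nodes), length(ent), 4),
                 dimnames = list(nodes, ent, .COMPARTMENTS))
  sp_row <- cbind(match(sp$node, nodes), match(sp$entity, ent))
  prev <- inlet
  worst <- 0
  ok <- TRUE
  for (cmp in .COMPARTMENTS) {
    tv <- tau[cmp, sp$entity]
    sol <- .solve_compartment(cm, prev, cmp, tv, tol, ladder)
    st <- matrix(0, length(nodes), length(ent))
    st[sp_row] <- sol$x
    state[, , cmp] <- st
    worst <- max(worst, sol$norm)
    ok <- ok && sol$converged
    prev <- sol$x
  }
  profiles <- if (ok) {
    stats::setNames(lapply(ent, function(p)
      aggregate_profile(state, model$net, p)), ent)
  } else NULL
  inlet_mat <- matrix(0, length(nodes), length(ent),
                      dimnames = list(nodes, ent))
  inlet_mat[sp_row] <- inlet
  structure(list(state = state, profiles = profiles, converged = ok,
                 residual_norm = worst, inlet = inlet_mat),
            class = "simulation_result")
}

.solve_compartment <- function(cm, prev, compartment, tau_v, tol, ladder) {
  solve_at <- function(x0, scale) {
    fit <- minpack.lm::nls.lm(
      par = x0,
      fn = function(v) .cm_residual(cm, pmax(v, 0), prev, compartment,
                                    tau_v, scale),
      jac = function(v) .cm_jacobian(cm, pmax(v, 0), compartment, tau_v,
                                     scale),
      lower = rep(0, length(x0)),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                           ptol = 1e-15, gtol = 0))
    x <- pmax(fit$par, 0)
    list(x = x, norm = sqrt(sum(.cm_residual(cm, x, prev, compartment,
                                             tau_v, scale)^2)))
  }
  out <- solve_at(prev, 1)
  if (out$norm > tol) {
    x0 <- prev
    for (s in ladder) {
      step <- solve_at(x0, s)
      x0 <- step$x
      out <- step
    }
  }
  list(x = out$x, norm = out$norm, converged = out$norm <= tol)
}

#' Aggregate a steady state into a tag-level glycoprofile
#'
#' Sums the TGN-outlet concentrations of all structural isomorphs
#' sharing a compositional tag and normalises to 100 percent.
#'
#' @param state A node x entity x compartment array (from
#'   [simulate_golgi()]) or a node x entity matrix of outlet
#'   concentrations.
#' @param net The `glyco_grn` the state refers to.
#' @param entity Entity name.
#' @return Named numeric vector of percentages summing to 100.
#' @export
aggregate_profile <- function(state, net, entity) {
  outlet <- if (length(dim(state)) == 3) state[, entity, "TGN"]
            else state[, entity]
  tags <- igraph::V(net$graph)$tag[match(names(outlet),
                                         igraph::V(net$graph)$name)]
  tot <- sum(outlet)
  if (tot <= 0) stop("all-zero outlet: cannot form a relative profile")
  agg <- tapply(outlet, tags, sum)
  stats::setNames(100 * as.vector(agg) / tot, names(agg))
}

#' Molar balance of a converged simulation
#'
#' At steady state every reaction conserves glycan count, so the total
#' outlet concentration of each entity must equal its total inlet
#' concentration (equivalently, with a constant volumetric flow per
#' entity, molar outflow equals molar inflow).
#'
#' @param result A `simulation_result`.
#' @return Data frame with per-entity inlet and outlet totals (uM) and
#'   the relative conservation error.
#' @export
molar_balance <- function(result) {
  stopifnot(inherits(result, "simulation_result"))
  ent <- colnames(result$inlet)
  inlet <- colSums(result$inlet)
  outlet <- colSums(matrix(result$state[, , "TGN"],
                           ncol = length(ent), dimnames = list(NULL, ent)))
  data.frame(entity = ent, inlet = as.numeric(inlet[ent]),
             outlet = as.numeric(outlet[ent]),
             rel_error = abs(as.numeric(outlet[ent]) - as.numeric(inlet[ent])) /
               pmax(as.numeric(inlet[ent]), .Machine$double.eps),
             row.names = NULL)
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation_result> converged:", x$converged,
      " residual norm:", format(x$residual_norm, digits = 3), "\n")
  if (!is.null(x$profiles))
    for (p in names(x$profiles)) {
      pr <- sort(x$profiles[[p]], decreasing = TRUE)
      cat("  ", p, ": ",
          paste(names(pr), sprintf("%.1f", pr), sep = "=", collapse = " "),
          "\n", sep = "")
    }
  invisible(x)
}
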