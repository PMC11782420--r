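# Approximate Bayesian computation, sequential Monte Carlo flavour:
# multivariate-normal KDE proposals, weighted-median epsilon schedule,
# RMSE distance, MAP and credible-interval summaries.

#' Independent uniform prior specification
#'
#' @param lo,hi Named numeric vectors of lower and upper bounds (same
#'   names, `lo < hi` elementwise). Names identify the free parameters.
#' @return A `prior_spec` object.
#' @export
prior_spec <- function(lo, hi) {
  stopifnot(length(lo) == length(hi), !is.null(names(lo)),
            all(names(lo) == names(hi)))
  if (any(lo >= hi)) stop("prior bounds require lo < hi for every parameter")
  structure(list(lo = lo, hi = hi, names = names(lo)), class = "prior_spec")
}

#' Default uniform priors for Golgi-model free parameters
#'
#' Maps free-parameter names to the study-style uninformative uniform
#' bounds: M9 inlet fractions `m9_prop:*` ~ U(0.05, 0.95), total enzyme
#' levels `enz_total:*` ~ U(0.001, 35) uM, dissociation constants
#' `km:*` ~ U(10, 10000) uM.
#'
#' @param free_names Character vector of free-parameter names.
#' @return A [prior_spec()].
#' @export
default_priors <- function(free_names) {
  lo <- vapply(free_names, function(nm) {
    switch(strsplit(nm, ":")[[1]][1],
           m9_prop = 0.05, enz_total = 0.001, km = 10,
           stop("no default prior for parameter '", nm, "'"))
  }, numeric(1))
  hi <- vapply(free_names, function(nm) {
    switch(strsplit(nm, ":")[[1]][1],
           m9_prop = 0.95, enz_total = 35, km = 10000)
  }, numeric(1))
  prior_spec(lo, hi)
}

.prior_sample <- function(prior, n) {
  d <- length(prior$lo)
  m <- matrix(stats::runif(n * d, rep(prior$lo, each = n),
                           rep(prior$hi, each = n)), n, d)
  colnames(m) <- prior$names
  m
}

.prior_contains <- function(prior, theta) {
  all(theta >= prior$lo & theta <= prior$hi)
}

.prior_density <- function(prior, theta) {
  if (!.prior_contains(prior, theta)) return(0)
  prod(1 / (prior$hi - prior$lo))
}

#' Root-mean-square error between glycoprofiles
#'
#' Profiles are compared on the observed (entity, tag) support, with
#' predicted tags missing from a profile treated as zero; several
#' entities are concatenated into a single vector before averaging
#' (joint fitting).
#'
#' @param pred,obs Either named percent vectors (single entity) or data
#'   frames `entity`, `tag`, `percent`.
#' @return Non-negative RMSE on the percent scale.
#' @export
rmse <- function(pred, obs) {
  if (is.data.frame(obs)) {
    key <- paste(obs$entity, obs$tag)
    ov <- obs$percent
    pv <- if (is.data.frame(pred))
      pred$percent[match(key, paste(pred$entity, pred$tag))]
    else pred[key]
  } else {
    ov <- obs
    pv <- pred[names(obs)]
  }
  if (!length(ov)) stop("rmse: empty profile support")
  pv[is.na(pv)] <- 0
  sqrt(mean((as.numeric(pv) - as.numeric(ov))^2))
}

#' Weighted quantile with linear interpolation
#'
#' Reduces to the standard type-7 sample quantile under equal weights:
#' sorted values are placed at cumulative-weight positions
#' `(C_{i-1}) / (S - w_last)` and interpolated linearly.
#'
#' @param x Numeric values.
#' @param w Non-negative weights.
#' @param probs Probabilities in `[0, 1]`.
#' @return Quantile value(s).
#' @export
weighted_quantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w), all(w >= 0), sum(w) > 0)
  o <- order(x)
  x <- x[o]; w <- w[o]
  if (length(x) == 1L) return(rep(x, length(probs)))
  cw <- cumsum(w)
  p <- (cw - w) / (sum(w) - w[length(w)])
  vapply(probs, function(q) {
    if (q <= p[1]) return(x[1])
    if (q >= p[length(p)]) return(x[length(x)])
    i <- max(which(p <= q))
    if (p[i + 1] == p[i]) return(x[i])
    x[i] + (x[i + 1] - x[i]) * (q - p[i]) / (p[i + 1] - p[i])
  }, numeric(1))
}

# log-density of a multivariate normal via Cholesky factorisation
.dmvnorm_log <- function(x, mean, sigma_chol) {
  d <- length(mean)
  z <- backsolve(sigma_chol, x - mean, transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(sigma_chol))) - 0.5 * sum(z^2)
}

# kernel density of each row of `at` under the weighted mixture of
# normals centred at rows of `centres` (shared Cholesky factor)
.kde_density <- function(at, centres, weights, sigma_chol) {
  d <- ncol(centres)
  lc <- -0.5 * d * log(2 * pi) - sum(log(diag(sigma_chol)))
  vapply(seq_len(nrow(at)), function(q) {
    z <- backsolve(sigma_chol, t(centres) - at[q, ], transpose = TRUE)
    sum(weights * exp(lc - 0.5 * colSums(z^2)))
  }, numeric(1))
}

# Kernel covariance: weighted-sample covariance scaled by the
# multivariate Silverman factor (squared), jittered for rank safety.
.kernel_cov <- function(theta, w, mult = 1) {
  d <- ncol(theta)
  n_eff <- 1 / sum((w / sum(w))^2)
  h2 <- (4 / (d + 2))^(2 / (d + 4)) * n_eff^(-2 / (d + 4)) * mult^2
  cv <- stats::cov.wt(theta, wt = w / sum(w), method = "ML")$cov
  cv <- h2 * cv
  diag(cv) <- diag(cv) + 1e-12 * pmax(diag(cv), 1e-8)
  cv
}

#' ABC sequential Monte Carlo sampler
#'
#' Generation 0 draws the particle population from the prior with equal
#' weights. Each subsequent generation sets the acceptance threshold
#' epsilon to the weighted median of the previous generation's
#' distances, proposes particles by sampling from the previous
#' population (probability proportional to weight) and perturbing with
#' a multivariate-normal KDE kernel (proposals outside the prior
#' support are redrawn), accepts a proposal when the distance between
#' its simulated profile and the observation is at most epsilon, and
#' reweights by `prior(theta) / sum_q w_q K(theta | theta_q)`. The
#' sampler stops after `max_generations`, when epsilon reaches
#' `eps_min`, or when a generation stalls (attempt budget exhausted).
#'
#' @param prior A [prior_spec()].
#' @param simulator Function mapping a named parameter vector to a
#'   simulated profile (any shape accepted by `distance`); return
#'   `NULL` to flag a failed (non-convergent) simulation, which rejects
#'   the draw.
#' @param observed Observed profile (passed to `distance`).
#' @param config List: `n` population size (default 200),
#'   `max_generations` (default 25), `eps_min` (default 0), `seed`,
#'   `max_attempts` per particle (default 500),
#'   `bandwidth_mult` KDE bandwidth multiplier (default 1).
#' @param distance Distance function `d(pred, obs)`; default [rmse()].
#' @return List of `particle_population` objects (one per generation),
#'   each with `particles` (matrix), `weights`, `distances`, `epsilon`,
#'   `generation`, `attempts`.
#' @export
abc_smc <- function(prior, simulator, observed,
                    config = list(), distance = rmse) {
  cfg <- utils::modifyList(list(n = 200L, max_generations = 25L, eps_min = 0,
                                seed = NULL, max_attempts = 500L,
                                bandwidth_mult = 1), config)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n
  stopifnot(n >= 2)
  d <- length(prior$lo)

  sim_distance <- function(theta) {
    pred <- simulator(theta)
    if (is.null(pred)) return(NA_real_)
    distance(pred, observed)
  }

  # generation 0: prior draws, equal weights, epsilon = Inf
  theta <- matrix(NA_real_, n, d, dimnames = list(NULL, prior$names))
  dist0 <- numeric(n)
  attempts <- 0L
  for (q in seq_len(n)) {
    repeat {
      attempts <- attempts + 1L
      cand <- .prior_sample(prior, 1)[1, ]
      dl <- sim_distance(cand)
      if (!is.na(dl)) { theta[q, ] <- cand; dist0[q] <- dl; break }
      if (attempts > cfg$max_attempts * n)
        stop("ABC: simulator failed for every prior draw")
    }
  }
  pops <- list(structure(list(particles = theta, weights = rep(1 / n, n),
                              distances = dist0, epsilon = Inf,
                              generation = 0L, attempts = attempts),
                         class = "particle_population"))

  for (gen in seq_len(cfg$max_generations - 1L)) {
    prev <- pops[[length(pops)]]
    eps <- weighted_quantile(prev$distances, prev$weights, 0.5)
    if (eps <= cfg$eps_min) break
    kcov <- .kernel_cov(prev$particles, prev$weights, cfg$bandwidth_mult)
    kchol <- chol(kcov)
    new_theta <- matrix(NA_real_, n, d, dimnames = list(NULL, prior$names))
    new_dist <- numeric(n)
    attempts <- 0L
    stalled <- FALSE
    for (q in seq_len(n)) {
      accepted <- FALSE
      while (!accepted) {
        attempts <- attempts + 1L
        if (attempts > cfg$max_attempts * n) { stalled <- TRUE; break }
        idx <- sample.int(n, 1L, prob = prev$weights)
        cand <- prev$particles[idx, ] +
          as.vector(MASS::mvrnorm(1, rep(0, d), kcov))
        names(cand) <- prior$names
        if (!.prior_contains(prior, cand)) next
        dl <- sim_distance(cand)
        if (is.na(dl) || dl > eps) next
        new_theta[q, ] <- cand
        new_dist[q] <- dl
        accepted <- TRUE
      }
      if (stalled) break
    }
    if (stalled) {
      warning("ABC: generation ", gen, " stalled after ",
              attempts, " attempts; stopping early")
      break
    }
    mix <- .kde_density(new_theta, prev$particles, prev$weights, kchol)
    w <- vapply(seq_len(n), function(q)
      .prior_density(prior, new_theta[q, ]), numeric(1)) / mix
    w <- w / sum(w)
    pops[[length(pops) + 1L]] <- structure(
      list(particles = new_theta, weights = w, distances = new_dist,
           epsilon = eps, generation = gen, attempts = attempts),
      class = "particle_population")
  }
  pops
}

#' Maximum a posteriori estimate of a particle population
#'
#' The particle maximising the weighted multivariate-normal KDE density
#' evaluated at the particle locations.
#'
#' @param pop A `particle_population`.
#' @param bandwidth_mult KDE bandwidth multiplier (default 1).
#' @return Named numeric parameter vector.
#' @export
map_estimate <- function(pop, bandwidth_mult = 1) {
  theta <- pop$particles
  n <- nrow(theta)
  if (n == 1L) {
    warning("single-particle population: MAP is that particle")
    return(theta[1, ])
  }
  kchol <- chol(.kernel_cov(theta, pop$weights, bandwidth_mult))
  dens <- .kde_density(theta, theta, pop$weights, kchol)
  theta[which.max(dens), ]
}

#' Credible interval of a particle population
#'
#' Per-parameter weighted quantiles at `(1 - level)/2` and
#' `1 - (1 - level)/2`.
#'
#' @param pop A `particle_population`.
#' @param level Credible level (default 0.95).
#' @return Matrix with rows `lo`, `hi` and one column per parameter.
#' @export
credible_interval <- function(pop, level = 0.95) {
  a <- (1 - level) / 2
  theta <- pop$particles
  if (nrow(theta) == 1L)
    warning("single-particle population: degenerate credible interval")
  out <- apply(theta, 2, function(col)
    weighted_quantile(col, pop$weights, c(a, 1 - a)))
  rownames(out) <- c("lo", "hi")
  out
}

#' @export
print.particle_population <- function(x, ...) {
  cat("<particle_population> generation ", x$generation,
      ": n = ", nrow(x$particles),
      ", epsilon = ", format(x$epsilon, digits = 4),
      ", median distance = ",
      format(stats::median(x$distances), digits = 4), "\n", sep = "")
  invisible(x)
}
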