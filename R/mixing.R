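# Source-apportionment mixing model. The observed tank composition is
# modeled as a weighted sum of four sources:
#
#   T(t) = q * G(t) + x * In(t) + y * Gel(t) + z * Pellet(t)
#
# where G places the in-tank generation weights (J, K, ..., one per
# resolvable tank genus) on the tank genera and 0 elsewhere. The eight
# unknowns -- (q, x, y, z) and the generation weights -- live on two
# independent simplexes. The fit draws parameter sets from two independent
# flat Dirichlet distributions, scores each by the residual sum of squares
# against the observed composition, keeps the best `retain` sets as an
# ensemble, and reports the single best set with percentile credible
# intervals over the ensemble.

#' Mixing-model parameters
#'
#' @param source_weights numeric length-4 vector `(q, x, y, z)`: proportions
#'   of tank DNA that are tank-generated, intake-derived, gel-feed-derived
#'   and pellet-feed-derived. Must sum to 1.
#' @param genus_weights named numeric vector of in-tank generation
#'   proportions, one per tank genus. Must sum to 1.
#' @param tol simplex tolerance.
#' @return object of class `mixing_params`.
#' @export
mixing_params <- function(source_weights, genus_weights, tol = 1e-9) {
  source_weights <- as.numeric(source_weights)
  if (length(source_weights) != 4)
    stop_ednacensus("source_weights must be (q, x, y, z)")
  names(source_weights) <- c("q", "x", "y", "z")
  if (is.null(names(genus_weights)) || any(!nzchar(names(genus_weights))))
    stop_ednacensus("genus_weights must be named by genus")
  for (w in list(source_weights, genus_weights)) {
    if (any(w < 0 | w > 1)) stop_ednacensus("weights must lie in [0, 1]")
    if (abs(sum(w) - 1) > tol) stop_ednacensus("weights must sum to 1")
  }
  structure(list(source_weights = source_weights,
                 genus_weights = genus_weights),
            class = "mixing_params")
}

#' @export
print.mixing_params <- function(x, ...) {
  cat("<mixing_params>\n  q,x,y,z:",
      paste(sprintf("%s=%.4g", names(x$source_weights), x$source_weights),
            collapse = " "), "\n  generation:",
      paste(sprintf("%s=%.4g", names(x$genus_weights), x$genus_weights),
            collapse = " "), "\n")
  invisible(x)
}

#' Bundle the exogenous source profiles for the mixing model
#'
#' @param intake,gel,pellet [taxon_profile()]s of the three exogenous
#'   sources.
#' @param tank_genera ordered genus names receiving the in-tank generation
#'   weights.
#' @return object of class `source_set`.
#' @export
source_set <- function(intake, gel, pellet, tank_genera) {
  for (p in list(intake, gel, pellet))
    if (abs(sum(p) - 1) > 1e-9) stop_ednacensus("source profiles must sum to 1")
  stopifnot(is.character(tank_genera), length(tank_genera) >= 1)
  structure(list(intake = intake, gel = gel, pellet = pellet,
                 tank_genera = tank_genera),
            class = "source_set")
}

# taxon universe + design matrix: columns are (one per tank genus) the
# genus indicators, then intake, gel, pellet
.mixing_design <- function(observed, sources) {
  k <- length(sources$tank_genera)
  universe <- Reduce(union, list(names(observed), sources$tank_genera,
                                 names(sources$intake), names(sources$gel),
                                 names(sources$pellet)))
  as_vec <- function(p) {
    v <- stats::setNames(numeric(length(universe)), universe)
    v[names(p)] <- as.numeric(p)
    v
  }
  M <- cbind(vapply(sources$tank_genera, function(g) {
    v <- stats::setNames(numeric(length(universe)), universe)
    v[g] <- 1
    v
  }, numeric(length(universe))),
  intake = as_vec(sources$intake),
  gel = as_vec(sources$gel),
  pellet = as_vec(sources$pellet))
  list(universe = universe, M = M, obs = as_vec(observed), k = k)
}

#' Predicted tank composition under mixing parameters
#'
#' @param params a [mixing_params()]; the genus-weight names must match the
#'   source set's `tank_genera`.
#' @param sources a [source_set()].
#' @return a [taxon_profile()] over the union of taxa.
#' @export
predict_mixture <- function(params, sources) {
  stopifnot(inherits(params, "mixing_params"), inherits(sources, "source_set"))
  if (!identical(sort(names(params$genus_weights)), sort(sources$tank_genera)))
    stop_ednacensus("genus_weights do not match the source set's tank_genera")
  d <- .mixing_design(taxon_profile(stats::setNames(1, sources$tank_genera[1]),
                                    rank = "genus"), sources)
  w <- params$source_weights
  p <- c(w["q"] * params$genus_weights[sources$tank_genera],
         w["x"], w["y"], w["z"])
  v <- as.numeric(d$M %*% p)
  taxon_profile(stats::setNames(v, d$universe), rank = "genus", tol = 1e-6)
}

#' Residual sum of squares between two compositions
#'
#' Profiles are aligned on the union of their taxa (missing taxa count 0).
#'
#' @param observed,predicted [taxon_profile()]s or named numeric vectors.
#' @return non-negative RSS.
#' @export
mixing_rss <- function(observed, predicted) {
  m <- align_profiles(observed, predicted)
  sum((m[1, ] - m[2, ])^2)
}

#' Variance explained by a predicted composition
#'
#' `1 - RSS/TSS` with the total sum of squares centered on the mean observed
#' proportion over the shared taxon universe.
#'
#' @inheritParams mixing_rss
#' @return R-squared (at most 1).
#' @export
mixing_r2 <- function(observed, predicted) {
  if (length(observed) < 2) stop_ednacensus("need at least 2 observed taxa")
  m <- align_profiles(observed, predicted)
  tss <- sum((m[1, ] - mean(m[1, ]))^2)
  if (tss <= 0) stop_ednacensus("zero total sum of squares; R2 undefined")
  1 - sum((m[1, ] - m[2, ])^2) / tss
}

# Monte-Carlo RSS minimization over a supplied parameter sampler.
# sampler(m) must return list(W1 = m x 4, W2 = m x k).
.fit_core <- function(obs, M, k, sampler, n_samples, retain,
                      chunk_size = 250000L) {
  best_pool <- NULL
  done <- 0
  obs_ss <- sum(obs^2)
  while (done < n_samples) {
    m <- min(chunk_size, n_samples - done)
    s <- sampler(m)
    P <- cbind(s$W1[, 1] * s$W2, s$W1[, 2:4, drop = FALSE])
    pred <- P %*% t(M)
    rss <- rowSums(pred^2) - 2 * as.numeric(pred %*% obs) + obs_ss
    rss[rss < 0] <- 0 # numerical guard
    params <- cbind(s$W1, s$W2)
    pool <- if (is.null(best_pool)) {
      list(params = params, rss = rss)
    } else {
      list(params = rbind(best_pool$params, params),
           rss = c(best_pool$rss, rss))
    }
    keep <- order(pool$rss)[seq_len(min(retain, length(pool$rss)))]
    best_pool <- list(params = pool$params[keep, , drop = FALSE],
                      rss = pool$rss[keep])
    done <- done + m
  }
  best_pool
}

#' Fit the mixing model by Dirichlet Monte-Carlo sampling
#'
#' Draws `n_samples` parameter sets -- `(q, x, y, z)` and the genus weights
#' from two independent flat Dirichlet distributions -- scores each by
#' [mixing_rss()] against the observed composition, and keeps the
#' lowest-RSS `retain` sets. Reports the single best set, its R-squared,
#' and per-parameter 2.5/97.5 percentile intervals over the retained
#' ensemble. When some credible interval among (q, x, y, z) is wider than
#' 0.5 (as with degenerate, mutually proportional sources) the fit is
#' flagged non-identifiable.
#'
#' @param observed genus-rank [taxon_profile()] of the tank sample.
#' @param sources a [source_set()].
#' @param n_samples Monte-Carlo draws.
#' @param retain ensemble size (default the best 1% of draws).
#' @param seed integer seed.
#' @param chunk_size draws scored per block (memory control).
#' @return object of class `mixing_fit`: `best` ([mixing_params()]),
#'   `best_rss`, `r_squared`, `ensemble` (matrix of retained parameter
#'   sets), `ensemble_rss`, `ci` (2 x p matrix), `non_identifiable`,
#'   `n_samples`, `retain`, `seed`.
#' @export
fit_mixing <- function(observed, sources, n_samples = 1e5,
                       retain = ceiling(n_samples / 100), seed = 1,
                       chunk_size = 250000L) {
  stopifnot(inherits(sources, "source_set"))
  n_samples <- as.integer(n_samples)
  retain <- as.integer(retain)
  if (n_samples < retain || retain < 1)
    stop_ednacensus("need n_samples >= retain >= 1")
  d <- .mixing_design(observed, sources)
  sampler <- function(m) list(W1 = rdirichlet(m, rep(1, 4)),
                              W2 = rdirichlet(m, rep(1, d$k)))
  pool <- with_seed(seed, .fit_core(d$obs, d$M, d$k, sampler, n_samples,
                                    retain, chunk_size))
  colnames(pool$params) <- c("q", "x", "y", "z", sources$tank_genera)
  best <- pool$params[1, ]
  best_params <- mixing_params(best[1:4], best[-(1:4)], tol = 1e-6)
  pred <- predict_mixture(best_params, sources)
  ci <- apply(pool$params, 2, stats::quantile, probs = c(0.025, 0.975))
  structure(list(best = best_params,
                 best_rss = pool$rss[1],
                 r_squared = mixing_r2(observed, pred),
                 ensemble = pool$params,
                 ensemble_rss = pool$rss,
                 ci = ci,
                 non_identifiable = any(ci[2, 1:4] - ci[1, 1:4] > 0.5),
                 n_samples = n_samples, retain = retain, seed = seed),
            class = "mixing_fit")
}

#' @export
print.mixing_fit <- function(x, ...) {
  cat("<mixing_fit> n_samples=", x$n_samples, ", retained=", x$retain,
      "\n  best RSS=", signif(x$best_rss, 4),
      ", R2=", signif(x$r_squared, 4),
      if (x$non_identifiable) "  [non-identifiable]" else "", "\n", sep = "")
  b <- c(x$best$source_weights, x$best$genus_weights)
  for (nm in names(b))
    cat(sprintf("  %-12s %.4g  (%.3g-%.3g)\n", nm, b[nm],
                x$ci[1, nm], x$ci[2, nm]))
  invisible(x)
}

#' One-parameter constraint sweep
#'
#' Re-fits the model with one parameter clamped to each value of `grid`.
#' The clamped parameter's simplex partners are drawn from a flat Dirichlet
#' scaled to the residual mass; the other simplex is sampled freely.
#'
#' @inheritParams fit_mixing
#' @param param_name one of `"q"`, `"x"`, `"y"`, `"z"` or a tank genus name.
#' @param grid constraint values in [0, 1].
#' @return data frame with one row per grid value: the constrained value,
#'   best co-parameters, and best RSS.
#' @export
constrained_sweep <- function(observed, sources, param_name, grid,
                              n_samples = 2e4, seed = 1) {
  stopifnot(inherits(sources, "source_set"))
  d <- .mixing_design(observed, sources)
  par_names <- c("q", "x", "y", "z", sources$tank_genera)
  if (!param_name %in% par_names)
    stop_ednacensus("unknown parameter: ", param_name)
  if (any(grid < 0 | grid > 1))
    stop_ednacensus("grid values must lie in [0, 1]")
  in_sources <- param_name %in% c("q", "x", "y", "z")
  idx <- if (in_sources) match(param_name, c("q", "x", "y", "z"))
         else match(param_name, sources$tank_genera)
  retain <- max(1L, ceiling(n_samples / 100))
  rows <- lapply(seq_along(grid), function(gi) {
    v <- grid[gi]
    sampler <- function(m) {
      if (in_sources) {
        W1 <- matrix(0, m, 4)
        W1[, idx] <- v
        W1[, -idx] <- rdirichlet(m, rep(1, 3)) * (1 - v)
        list(W1 = W1, W2 = rdirichlet(m, rep(1, d$k)))
      } else {
        W2 <- matrix(0, m, d$k)
        W2[, idx] <- v
        if (d$k > 1) W2[, -idx] <- rdirichlet(m, rep(1, d$k - 1)) * (1 - v)
        list(W1 = rdirichlet(m, rep(1, 4)), W2 = W2)
      }
    }
    pool <- with_seed(seed + gi, .fit_core(d$obs, d$M, d$k, sampler,
                                           as.integer(n_samples), retain))
    best <- stats::setNames(pool$params[1, ], par_names)
    cbind(data.frame(param = param_name, value = v, rss = pool$rss[1]),
          as.data.frame(as.list(best)))
  })
  do.call(rbind, rows)
}

#' Marginal density of a retained-ensemble parameter
#'
#' Histogram and kernel density summary of one parameter across the
#' retained best-fit ensemble. Because the parameters are mutually
#' dependent, the jointly best-fitting set need not sit at any marginal
#' density mode.
#'
#' @param fit a [fit_mixing()] result.
#' @param param_name parameter to summarize.
#' @return object of class `parameter_density` with the kernel `density`
#'   (support clipped to [0, 1]), histogram `hist`, the `best` (joint
#'   best-fit) value, and the 2.5/97.5 percentile `ci`.
#' @export
parameter_density <- function(fit, param_name) {
  stopifnot(inherits(fit, "mixing_fit"))
  if (!param_name %in% colnames(fit$ensemble))
    stop_ednacensus("unknown parameter: ", param_name)
  v <- fit$ensemble[, param_name]
  dens <- if (stats::sd(v) > 0) stats::density(v, from = 0, to = 1) else NULL
  structure(list(param = param_name,
                 values = v,
                 density = dens,
                 hist = graphics::hist(v, breaks = seq(0, 1, by = 0.02),
                                       plot = FALSE),
                 best = unname(c(fit$best$source_weights,
                                 fit$best$genus_weights)[param_name]),
                 ci = fit$ci[, param_name]),
            class = "parameter_density")
}

#' @export
print.parameter_density <- function(x, ...) {
  cat("<parameter_density> ", x$param, ": best=", signif(x$best, 4),
      ", 95% ensemble interval (", signif(x$ci[1], 3), ", ",
      signif(x$ci[2], 3), ")\n", sep = "")
  invisible(x)
}
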