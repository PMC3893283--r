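# shared toy sources over five taxa
mk_sources <- function() {
  source_set(
    intake = taxon_profile(c(C = 0.7, D = 0.2, A = 0.1)),
    gel = taxon_profile(c(D = 0.6, E = 0.4)),
    pellet = taxon_profile(c(E = 0.9, C = 0.1)),
    tank_genera = c("A", "B")
  )
}

test_that("predict_mixture reproduces the weighted-sum arithmetic", {
  srcs <- mk_sources()
  p_tank <- mixing_params(c(1, 0, 0, 0), c(A = 0.6, B = 0.4))
  out <- predict_mixture(p_tank, srcs)
  expect_equal(as.numeric(out[c("A", "B")]), c(0.6, 0.4))
  expect_equal(sum(out), 1)

  p_in <- mixing_params(c(0, 1, 0, 0), c(A = 0.5, B = 0.5))
  out2 <- predict_mixture(p_in, srcs)
  expect_equal(as.numeric(out2[c("C", "D", "A")]), c(0.7, 0.2, 0.1))

  # hand-mixed five-taxon case
  p <- mixing_params(c(0.4, 0.3, 0.2, 0.1), c(A = 0.25, B = 0.75))
  out3 <- predict_mixture(p, srcs)
  expect_equal(as.numeric(out3[c("A", "B", "C", "D", "E")]),
               c(0.4 * 0.25 + 0.3 * 0.1,
                 0.4 * 0.75,
                 0.3 * 0.7 + 0.1 * 0.1,
                 0.3 * 0.2 + 0.2 * 0.6,
                 0.2 * 0.4 + 0.1 * 0.9),
               tolerance = 1e-12)

  # genus-weight names must match the tank genera
  bad <- mixing_params(c(1, 0, 0, 0), c(A = 0.5, Z = 0.5))
  expect_error(predict_mixture(bad, srcs), "tank_genera")
})

test_that("rss and r-squared follow their definitions", {
  a <- taxon_profile(c(A = 0.5, B = 0.5))
  expect_equal(mixing_rss(a, a), 0)
  expect_equal(mixing_rss(taxon_profile(c(A = 1)), taxon_profile(c(B = 1))), 2)

  obs <- taxon_profile(c(A = 0.5, B = 0.3, C = 0.2))
  pred <- taxon_profile(c(A = 0.4, B = 0.4, C = 0.2))
  expect_equal(mixing_rss(obs, pred), 0.01 + 0.01, tolerance = 1e-12)

  expect_equal(mixing_r2(obs, obs), 1)
  # predicting the observed mean explains nothing
  mean_pred <- taxon_profile(c(A = 1 / 3, B = 1 / 3, C = 1 / 3))
  expect_equal(mixing_r2(obs, mean_pred), 0, tolerance = 1e-12)
  # worked four-taxon case
  obs4 <- taxon_profile(c(A = 0.4, B = 0.3, C = 0.2, D = 0.1))
  pred4 <- taxon_profile(c(A = 0.35, B = 0.35, C = 0.2, D = 0.1))
  tss <- sum((as.numeric(obs4) - 0.25)^2)
  expect_equal(mixing_r2(obs4, pred4), 1 - 0.005 / tss, tolerance = 1e-12)
  expect_error(mixing_r2(taxon_profile(c(A = 1)), pred4), "2 observed")
})

test_that("the fit recovers known parameters from noiseless data", {
  srcs <- mk_sources()
  truth <- mixing_params(c(0.55, 0.3, 0.1, 0.05), c(A = 0.7, B = 0.3))
  obs <- predict_mixture(truth, srcs)
  fit <- fit_mixing(obs, srcs, n_samples = 1e6, retain = 1e4, seed = 11)
  got <- c(fit$best$source_weights, fit$best$genus_weights)
  want <- c(truth$source_weights, truth$genus_weights)
  expect_lt(max(abs(got - want)), 0.02)
  expect_gt(fit$r_squared, 0.99)
  expect_equal(fit$best_rss, min(fit$ensemble_rss))
  expect_equal(nrow(fit$ensemble), 1e4)
  expect_true(all(fit$ci >= 0 & fit$ci <= 1))
})

test_that("an observed profile equal to one source pins that weight", {
  srcs <- mk_sources()
  fit <- fit_mixing(srcs$intake, srcs, n_samples = 2e5, seed = 3)
  expect_gt(fit$best$source_weights[["x"]], 0.95)
  expect_lt(max(fit$best$source_weights[c("q", "y", "z")]), 0.05)
})

test_that("permuting taxon order leaves the fit unchanged", {
  srcs <- mk_sources()
  obs <- taxon_profile(c(A = 0.3, B = 0.2, C = 0.25, D = 0.15, E = 0.1))
  perm <- taxon_profile(obs[c("D", "A", "E", "C", "B")], rank = "genus")
  f1 <- fit_mixing(obs, srcs, n_samples = 2e4, seed = 7)
  f2 <- fit_mixing(perm, srcs, n_samples = 2e4, seed = 7)
  expect_equal(f1$best_rss, f2$best_rss, tolerance = 1e-12)
  expect_equal(f1$best$source_weights, f2$best$source_weights)
})

test_that("shrinking the retained ensemble tightens the mean CI width", {
  srcs <- mk_sources()
  truth <- mixing_params(c(0.5, 0.3, 0.15, 0.05), c(A = 0.6, B = 0.4))
  obs <- predict_mixture(truth, srcs)
  widths <- vapply(1:5, function(s) {
    f_big <- fit_mixing(obs, srcs, n_samples = 5e4, retain = 2000, seed = s)
    f_small <- fit_mixing(obs, srcs, n_samples = 5e4, retain = 500, seed = s)
    c(big = mean(f_big$ci[2, ] - f_big$ci[1, ]),
      small = mean(f_small$ci[2, ] - f_small$ci[1, ]))
  }, c(big = 0, small = 0))
  expect_lte(mean(widths["small", ]), mean(widths["big", ]) + 0.01)
})

test_that("degenerate sources are flagged non-identifiable", {
  same <- taxon_profile(c(A = 0.4, B = 0.3, C = 0.3))
  srcs <- source_set(same, same, same, tank_genera = c("A", "B"))
  obs <- taxon_profile(c(A = 0.4, B = 0.3, C = 0.3))
  fit <- fit_mixing(obs, srcs, n_samples = 2e4, seed = 2)
  expect_true(fit$non_identifiable)
})

test_that("constraint sweeps bracket the unconstrained optimum", {
  srcs <- mk_sources()
  truth <- mixing_params(c(0.5, 0.35, 0.1, 0.05), c(A = 0.65, B = 0.35))
  obs <- predict_mixture(truth, srcs)
  fit <- fit_mixing(obs, srcs, n_samples = 2e5, seed = 5)

  sweep <- constrained_sweep(obs, srcs, "q", grid = c(0, 0.25, 0.5, 0.75, 1),
                             n_samples = 2e4, seed = 5)
  # constrained fits can never beat the (well-converged) unconstrained best
  expect_true(all(sweep$rss >= fit$best_rss - 1e-6))
  # the sweep minimum sits at the true q
  expect_equal(sweep$value[which.min(sweep$rss)], 0.5)
  # constraining at the optimum reproduces the unconstrained RSS
  at_opt <- constrained_sweep(obs, srcs, "q", grid = 0.5,
                              n_samples = 5e4, seed = 6)
  expect_lt(abs(at_opt$rss - fit$best_rss), 5e-4)

  expect_error(constrained_sweep(obs, srcs, "nope", 0.5), "unknown")
  expect_error(constrained_sweep(obs, srcs, "q", c(-0.1, 0.5)), "\\[0, 1\\]")

  # sweeping a genus weight works too
  swg <- constrained_sweep(obs, srcs, "A", grid = c(0.25, 0.65, 0.95),
                           n_samples = 2e4, seed = 7)
  expect_equal(swg$value[which.min(swg$rss)], 0.65)
})

test_that("parameter densities summarize the retained ensemble", {
  srcs <- mk_sources()
  truth <- mixing_params(c(0.5, 0.3, 0.15, 0.05), c(A = 0.6, B = 0.4))
  obs <- predict_mixture(truth, srcs)
  fit <- fit_mixing(obs, srcs, n_samples = 5e4, retain = 1000, seed = 9)
  pd <- parameter_density(fit, "q")
  # ~95% of ensemble values lie within the CI by construction
  inside <- mean(pd$values >= pd$ci[1] & pd$values <= pd$ci[2])
  expect_gte(inside, 0.94)
  expect_equal(sum(pd$hist$counts), fit$retain)

  # an ensemble of identical sets gives a point mass
  fit2 <- fit
  fit2$ensemble[, "q"] <- 0.5
  pd2 <- parameter_density(fit2, "q")
  expect_null(pd2$density)
  expect_equal(sum(pd2$hist$counts > 0), 1)
  expect_error(parameter_density(fit, "zzz"), "unknown")
})
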