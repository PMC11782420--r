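test_that("free-parameter names address every parameter family", {
  p <- kinetic_parameters(entities = c("IgG", "HCP"))
  p2 <- apply_free_params(p, c("m9_prop:HCP" = 0.8,
                               "enz_total:GnTI" = 1.5,
                               "kf:ManI" = 500,
                               "km:HCP:b4GalT" = 4000,
                               "kmd:GnTI" = 99))
  expect_equal(p2$m9_prop[["HCP"]], 0.8)
  expect_equal(p2$enz_total[["GnTI"]], 1.5)
  expect_equal(p2$kf[["ManI"]], 500)
  expect_equal(p2$km$HCP$b4GalT, 4000)
  expect_equal(p2$kmd[["GnTI"]], 99)
  expect_error(apply_free_params(p, c("nonsense:x" = 1)), "unknown")
})

test_that("sequential fitting fixes stage MAPs for later stages", {
  tm <- toy_model_single()
  theta_star <- c("enz_total:GnTI" = 0.08, "enz_total:a6FucT" = 0.5)
  prof <- make_synthetic_profiles(tm$net, tm$params, tm$entities,
                                  noise_sd = 0.5, seed = 21,
                                  theta_star = theta_star)
  rep <- identify_critical_nodes(tm$net)
  plan <- derive_strategy(tm$net, rep, prof, estimate_m9 = FALSE)
  plan <- lapply(plan, function(st) {
    st$free_parameters <- intersect(st$free_parameters, names(theta_star))
    st
  })
  pri <- prior_spec(setNames(rep(0.001, 2), names(theta_star)),
                    setNames(rep(2, 2), names(theta_star)))
  fit <- run_sequential(tm$model, plan,
                        config = list(n = 30, max_generations = 4,
                                      seed = 5, max_attempts = 60,
                                      noise_sd = 0.5),
                        priors = pri)
  expect_length(fit$summaries, 2)
  # the stage-1 MAP is fixed into the cumulative vector and final params
  m1 <- fit$summaries[[1]]$map_estimate
  expect_equal(fit$fixed_values[["enz_total:GnTI"]],
               m1[["enz_total:GnTI"]])
  expect_equal(fit$params$enz_total[["GnTI"]], m1[["enz_total:GnTI"]])
  expect_equal(fit$params$enz_total[["a6FucT"]],
               fit$summaries[[2]]$map_estimate[["enz_total:a6FucT"]])
  # log is machine-readable and per stage
  expect_length(fit$log, 2)
  expect_true(all(vapply(fit$log, function(l)
    is.numeric(l$final_epsilon), TRUE)))
})

test_that("sequential fits reproduce bit-for-bit under a fixed seed", {
  tm <- toy_model_single()
  theta_star <- c("enz_total:GnTI" = 0.08)
  prof <- make_synthetic_profiles(tm$net, tm$params, tm$entities,
                                  noise_sd = 0.5, seed = 33,
                                  theta_star = theta_star)
  plan <- derive_strategy(tm$net, identify_critical_nodes(tm$net), prof,
                          estimate_m9 = FALSE)
  plan <- lapply(plan, function(st) {
    st$free_parameters <- intersect(st$free_parameters, names(theta_star))
    st
  })
  pri <- prior_spec(c("enz_total:GnTI" = 0.001), c("enz_total:GnTI" = 2))
  cfg <- list(n = 25, max_generations = 3, seed = 77, max_attempts = 60)
  f1 <- run_sequential(tm$model, plan, config = cfg, priors = pri)
  f2 <- run_sequential(tm$model, plan, config = cfg, priors = pri)
  expect_identical(f1$summaries[[1]]$populations,
                   f2$summaries[[1]]$populations)
  expect_identical(f1$fixed_values, f2$fixed_values)
})

test_that("stage acceptance floors reflect target noise and divergence", {
  net <- make_toy_grn()
  prof <- make_synthetic_profiles(net, kinetic_parameters(entities = "IgG"),
                                  list(protein_entity("IgG", 150)),
                                  noise_sd = 0)
  plan <- derive_strategy(net, identify_critical_nodes(net), prof)
  floors <- vapply(plan, glykin:::.stage_noise_floor, numeric(1),
                   noise_sd = 1)
  expect_true(all(floors > 1))        # above the per-tag noise sd
  expect_true(all(is.finite(floors)))
  # scaling the noise scales the pure-noise part of the floor
  f2 <- glykin:::.stage_noise_floor(plan[[4]], 2)
  expect_equal(f2, 2 * floors[4], tolerance = 1e-9)
})
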