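test_that("mirrored connectomes are exactly symmetric at asymmetry 0", {
  for (s in c(1, 17, 99)) {
    net <- gen_connectome(connectome_config(asymmetry_rate = 0, rng_seed = s))
    g <- circuit_graph(net$neurons, net$synapses)
    expect_identical(edge_key(list(edges = mirror_edges(g), nodes = g$nodes)$edges),
                     edge_key(g$edges))
  }
})

test_that("orphan rate 0 gives somata everywhere; rate > 0 plants excluded fragments", {
  net <- gen_connectome(connectome_config(orphan_fragment_rate = 0, rng_seed = 2))
  expect_true(all(net$neurons$has_soma))
  net2 <- gen_connectome(connectome_config(orphan_fragment_rate = 0.8, rng_seed = 2))
  frag <- net2$ground_truth$orphan_fragments
  expect_gt(length(frag), 0)
  expect_true(all(!net2$neurons$has_soma[match(frag, net2$neurons$neuron_id)]))
  # fragments pass the raw synapse rule but are not layer-1 members
  expect_true(all(frag %in% net2$ground_truth$rule_pass))
  expect_false(any(frag %in% net2$ground_truth$layer1_members))
})

test_that("selection recovers planted layer-1 membership exactly", {
  for (s in c(3, 31, 314)) {
    net <- gen_connectome(connectome_config(rng_seed = s,
                                            orphan_fragment_rate = 0.3,
                                            asymmetry_rate = 0.1))
    g <- circuit_graph(net$neurons, net$synapses)
    sel <- select_direct_targets(g, net$ground_truth$seed_ids)
    expect_identical(sel, net$ground_truth$rule_pass)
    kept <- exclude_unqualified(g, sel)$kept
    expect_identical(kept, net$ground_truth$layer1_members)
  }
})

test_that("generators are deterministic given rng_seed and round-trip through CSV", {
  cfg <- connectome_config(rng_seed = 11, asymmetry_rate = 0.2)
  a <- gen_connectome(cfg); b <- gen_connectome(cfg)
  expect_identical(a, b)

  dir <- withr::local_tempdir()
  paths <- write_connectome(a, dir)
  g <- read_circuit_tables(paths[["neurons"]], paths[["synapses"]])
  expect_identical(g$nodes$name, a$neurons$name)
  expect_identical(g$edges$synapse_count, a$synapses$synapse_count)
  gt <- read_ground_truth(paths[["ground_truth"]])
  expect_identical(gt$layer1_members, a$ground_truth$layer1_members)

  expect_identical(gen_behavior_trials(behavior_config(rng_seed = 5)),
                   gen_behavior_trials(behavior_config(rng_seed = 5)))
  expect_identical(gen_predation(predation_config(rng_seed = 5)),
                   gen_predation(predation_config(rng_seed = 5)))
})

test_that("behavior trials follow the configured mixture", {
  # degenerate mixture: all angles at one of the two means
  cfg0 <- behavior_config(mixture_sds = c(0, 0), rng_seed = 8)
  tr0 <- gen_behavior_trials(cfg0)
  expect_true(all(tr0$true_norm_angle %in% cfg0$mixture_means))

  # analytic mixture mean 0.5 recovered within 3 standard errors
  cfg <- behavior_config(n_larvae = 50, speeds = seq(5, 95, by = 5),
                         mixture_weights = c(0.5, 0.5),
                         mixture_means = c(0.2, 0.8),
                         mixture_sds = c(0.05, 0.05), rng_seed = 21)
  tr <- gen_behavior_trials(cfg)
  n <- nrow(tr)
  se <- sqrt((0.05^2 + 0.09) / n)  # Var = E[var] + Var[component mean]
  expect_lt(abs(mean(tr$true_norm_angle) - 0.5), 3 * se)

  # closure threshold at 0 puts the logistic model at its ceiling
  cfg_c <- behavior_config(closure_threshold_speed = 0,
                           speeds = seq(20, 95, by = 5), rng_seed = 9)
  tr_c <- gen_behavior_trials(cfg_c)
  expect_gt(mean(tr_c$prototroch_closed), 0.98)
})

test_that("trace generator: flat case, drift cancellation, planted peak", {
  flat <- gen_traces(trace_config(drift_amplitude = 0, noise_sd = 0,
                                  transient_amplitude = 0, rng_seed = 1))
  tr <- flat$traces[[1]]
  expect_equal(diff(range(tr$F_gcamp)), 0)
  expect_equal(diff(range(tr$F_tdtom)), 0)

  drift <- gen_traces(trace_config(noise_sd = 0, rng_seed = 3))
  clean <- gen_traces(trace_config(noise_sd = 0, drift_amplitude = 0, rng_seed = 3))
  r_d <- ratiometric(drift$traces[[1]])
  r_c <- ratiometric(clean$traces[[1]])
  expect_equal(r_d$ratio_series, r_c$ratio_series, tolerance = 1e-12)

  a <- drift$ground_truth$transient_amplitude
  expect_equal(max(r_d$ratio_series), 1 + a, tolerance = 1e-9)
})

test_that("predation generator respects degenerate configs", {
  cfg <- predation_config(baseline_consumption_prob = 0, mutant_effect = 0,
                          background_mortality = 0, rng_seed = 6)
  sim <- gen_predation(cfg)
  expect_true(all(sim$trials$Cf == sim$trials$Ci))
  rates <- with(sim$trials[sim$trials$condition == "copepods", ],
                predation_rate(Ci, Cf, n_predators_final, duration_days))
  expect_true(all(rates == 0))
})

test_that("config validation rejects invalid parameters", {
  expect_error(connectome_config(asymmetry_rate = 1.5), "probability")
  expect_error(connectome_config(synapse_count_distribution =
                                   list(family = "poisson", mean = 3)),
               "unsupported")
  expect_error(behavior_config(mixture_means = c(0.8, 0.2)), "ordered")
  expect_error(behavior_config(mixture_weights = c(0.3, 0.3)), "summing")
  expect_error(trace_config(baseline_g = 5, background_g = 10), "exceed")
  expect_error(predation_config(baseline_consumption_prob = 0.9,
                                mutant_effect = 0.3), "stay in")
})
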