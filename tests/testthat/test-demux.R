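control_events <- function(n = 20000L, seed = 99L) {
  simulate_events(sim_config(
    n_cells = n,
    reporters = dplyr::mutate(default_reporters(), p = 0),
    seed = seed))
}

test_that("simulation is seeded and respects transduction probabilities", {
  cfg <- sim_config(n_cells = 40000L, seed = 7L)
  a <- simulate_events(cfg)
  b <- simulate_events(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a), 40000L)

  # 4 reporters at p = 0.3: quadruple-positive fraction ~ 0.3^4
  quad <- mean(a$truth_Azurite & a$truth_GFP & a$truth_Ametrine &
                 a$truth_mCherry2)
  expect_equal(quad, 0.3^4, tolerance = 0.15)
  expect_equal(mean(a$truth_GFP), 0.3, tolerance = 0.03)
})

test_that("config validation rejects impossible parameters", {
  expect_error(sim_config(reporters = dplyr::mutate(default_reporters(),
                                                    p = 1.2)),
               "probabilities")
  expect_error(sim_config(targets = dplyr::mutate(default_targets(),
                                                  knockdown = -0.1)),
               "knockdown")
  expect_error(sim_config(reporters = dplyr::mutate(default_reporters(),
                                                    pos_mean = 1)),
               "exceed")
})

test_that("zero knockdown leaves stain MFI ratios at one", {
  cfg <- sim_config(n_cells = 60000L,
                    targets = dplyr::mutate(default_targets(),
                                            knockdown = 0),
                    seed = 3L)
  ev <- simulate_events(cfg)
  g <- gate_events(ev, control_events(), reporters = default_reporters()$name)
  kd <- quantify_knockdown(g, c(CD127 = "none"))
  est <- kd$knockdown_percent[kd$population == "Azurite+"]
  expect_lt(abs(est), 2)
})

test_that("gating thresholds behave like control quantiles", {
  ctrl <- control_events()
  # gating an all-negative sample: ~(1 - q) gated positive per reporter
  neg <- simulate_events(sim_config(
    n_cells = 50000L,
    reporters = dplyr::mutate(default_reporters(), p = 0), seed = 5L))
  g <- gate_events(neg, ctrl, reporters = default_reporters()$name,
                   quantile = 0.999)
  for (r in default_reporters()$name) {
    expect_equal(mean(g[[paste0("gate_", r)]]), 0.001, tolerance = 0.8)
  }
  expect_gt(mean(g$population == "none"), 0.99)

  # every event lands in exactly one of the 16 populations
  ev <- simulate_events(sim_config(n_cells = 30000L, seed = 11L))
  g2 <- gate_events(ev, ctrl, reporters = default_reporters()$name)
  expect_equal(length(levels(g2$population)), 16L)
  expect_equal(sum(table(g2$population)), 30000L)
  expect_false(any(is.na(g2$population)))

  # raising a positive mean never lowers that reporter's positive fraction
  hi <- simulate_events(sim_config(
    n_cells = 30000L,
    reporters = dplyr::mutate(default_reporters(), pos_mean = 4.2),
    seed = 11L))
  ghi <- gate_events(hi, ctrl, reporters = default_reporters()$name)
  expect_gte(mean(ghi$gate_GFP), mean(g2$gate_GFP))

  expect_error(gate_events(ev, ctrl[0, ]), "empty")
})

test_that("knockdown is recovered within two points at scale", {
  cfg <- sim_config(
    n_cells = 200000L,
    targets = dplyr::mutate(default_targets(),
                            knockdown = c(0.5, 0.7, 0.9, 0.9)),
    seed = 17L)
  ev <- simulate_events(cfg)
  g <- gate_events(ev, control_events(), reporters = default_reporters()$name)
  kd <- quantify_knockdown(g, setNames(rep("none", 4),
                                       default_targets()$stain))
  singles <- paste0(default_reporters()$name, "+")
  for (i in 1:4) {
    est <- kd$knockdown_percent[kd$population == singles[i] &
                                  kd$stain == default_targets()$stain[i]]
    expect_equal(est, 100 * cfg$targets$knockdown[i], tolerance = 0.04)
  }
})

test_that("knockdown estimates agree across populations sharing a reporter", {
  cfg <- sim_config(n_cells = 150000L, seed = 29L)
  ev <- simulate_events(cfg)
  g <- gate_events(ev, control_events(), reporters = default_reporters()$name)
  kd <- quantify_knockdown(g, c(CD127 = "none"))
  az_pops <- grep("Azurite", levels(g$population), value = TRUE)
  ests <- kd$knockdown_percent[kd$population %in% az_pops & !kd$flagged]
  expect_gt(length(ests), 4L)
  expect_lt(max(ests) - min(ests), 4)   # near-identical across barcodes
  expect_equal(mean(ests), 90, tolerance = 0.03)
})

test_that("quantification flags small populations and honours its controls", {
  cfg <- sim_config(n_cells = 5000L, seed = 31L)
  ev <- simulate_events(cfg)
  g <- gate_events(ev, control_events(), reporters = default_reporters()$name)
  kd <- quantify_knockdown(g, c(CD127 = "none"), min_events = 100L)
  expect_true(any(kd$flagged))
  expect_equal(nrow(kd), 16L)   # flagged, never dropped

  # a population used as its own control has exactly zero knockdown
  kd_self <- quantify_knockdown(g, c(CD127 = "Azurite+"))
  expect_equal(kd_self$knockdown_percent[kd_self$population == "Azurite+"],
               0)

  expect_error(quantify_knockdown(ev, c(CD127 = "none")), "gated")
  expect_error(quantify_knockdown(g, c(NotAStain = "none")), "not in events")
})

test_that("geometric and arithmetic MFI are both available and differ", {
  cfg <- sim_config(n_cells = 20000L, seed = 37L)
  g <- gate_events(simulate_events(cfg), control_events(),
                   reporters = default_reporters()$name)
  geo <- quantify_knockdown(g, c(CD127 = "none"), stat = "geometric")
  ari <- quantify_knockdown(g, c(CD127 = "none"), stat = "arithmetic")
  expect_false(isTRUE(all.equal(geo$mfi, ari$mfi)))
  # arithmetic mean of a log-normal exceeds its geometric mean
  expect_true(all(ari$mfi >= geo$mfi, na.rm = TRUE))
})

test_that("plot methods return ggplot objects", {
  cfg <- sim_config(n_cells = 5000L, seed = 41L)
  g <- gate_events(simulate_events(cfg), control_events(5000L),
                   reporters = default_reporters()$name)
  kd <- quantify_knockdown(g, c(CD127 = "none"))
  expect_s3_class(autoplot(kd), "ggplot")
  expect_s3_class(plot_events(g), "ggplot")
  a <- feasible_assignment(c("Azurite", "GFP"), instrument("4laser"))
  expect_s3_class(autoplot(a), "ggplot")
})
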