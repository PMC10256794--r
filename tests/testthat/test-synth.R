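test_that("contact generation respects separation and is seed-deterministic", {
  cfg <- synth_config(n_contacts = 2, box_extent = 100, seed = 3)
  cs <- generate_contacts(cfg)
  expect_equal(nrow(cs), 2)
  expect_gte(as.numeric(dist(contact_coords(cs))), 4)
  expect_identical(generate_contacts(cfg), cs)
  cfg40 <- synth_config(n_contacts = 40, box_extent = 120, seed = 9)
  d40 <- as.numeric(dist(contact_coords(generate_contacts(cfg40))))
  expect_length(d40, 780)
  expect_true(all(d40 >= 4))
  expect_true(all(contact_coords(generate_contacts(cfg40)) >= 0 &
                    contact_coords(generate_contacts(cfg40)) <= 120))
  # impossible packing fails with a diagnostic
  impossible <- synth_config(n_contacts = 10, box_extent = 20,
                             min_sep_mm = 15, seed = 1)
  expect_error(generate_contacts(impossible), "box is too small")
})

test_that("structural network limits, sparsity and exact round-trip hold", {
  # sc_density = 1 and no decay gives the complete graph
  cfg <- synth_config(n_contacts = 8, box_extent = 70, sc_density = 1,
                      distance_decay = 0, seed = 4)
  cs <- generate_contacts(cfg)
  net <- generate_structural_network(cs, cfg)
  expect_true(all(net$truth$sc_weights[upper.tri(net$truth$sc_weights)] >= 1))
  # counting the emitted streamlines recovers sc_weights exactly
  counted <- count_streamline_connections(net$streamlines, cs,
                                          roi_radius_mm = cfg$sc_roi_radius_mm)
  expect_equal(unname(counted$values), unname(net$truth$sc_weights))
  # degenerate decay raises a diagnostic
  dead <- synth_config(n_contacts = 6, box_extent = 70, sc_density = 0.01,
                       distance_decay = 2, seed = 5)
  expect_error(generate_structural_network(generate_contacts(dead), dead),
               "degenerate network")
})

test_that("edge probability declines across distance terciles", {
  cfg0 <- synth_config(n_contacts = 10, box_extent = 80, streamline_mean = 1,
                       seed = 1)
  cs <- generate_contacts(cfg0)
  d <- half_vectorize(euclidean_distance_matrix(cs))$values
  present <- matrix(0, 200, length(d))
  for (s in 1:200) {
    cfg <- synth_config(n_contacts = 10, box_extent = 80,
                        streamline_mean = 1, seed = 10000 + s)
    net <- tryCatch(generate_structural_network(cs, cfg),
                    error = function(e) NULL)
    if (!is.null(net))
      present[s, ] <- half_vectorize(conn_matrix(
        net$truth$sc_weights > 0, cs$contact_id, "sc"))$values
  }
  terc <- cut(d, quantile(d, c(0, 1 / 3, 2 / 3, 1)), include.lowest = TRUE)
  rate <- tapply(colMeans(present), terc, mean)
  expect_true(all(diff(rate) < 0))
})

test_that("dynamic coupling is a monotone image of structural weight", {
  cfg <- synth_config(n_contacts = 10, box_extent = 80, seed = 6)
  net <- generate_structural_network(generate_contacts(cfg), cfg)
  W <- net$truth$sc_weights; K <- net$truth$dynamic_coupling
  expect_equal(K, W * (K[which(W > 0)[1]] / W[which(W > 0)[1]]))
  expect_true(all(K[W == 0] == 0))
  expect_equal(max(abs(K - t(K))), 0)
})

test_that("uncoupled nodes are uncorrelated and coupled ones recover SC", {
  cfg0 <- tiny_synth(n_contacts = 10, coupling_strength = 0,
                     lfp_duration = 60, seed = 7)
  net <- generate_structural_network(generate_contacts(cfg0), cfg0)
  x <- simulate_neural_dynamics(net$truth, cfg0)
  fc <- pearson_fc(x)$values
  expect_lt(mean(abs(fc[upper.tri(fc)])), 0.05)
  # determinism: bit-identical panels from the same seed
  expect_identical(simulate_neural_dynamics(net$truth, cfg0)$values,
                   x$values)
  # broadband FC tracks structural weight when coupled
  for (s in 1:3) {
    cfgc <- tiny_synth(n_contacts = 12, coupling_strength = 0.5,
                       lfp_duration = 30, seed = 40 + s)
    netc <- generate_structural_network(generate_contacts(cfgc), cfgc)
    xc <- simulate_neural_dynamics(netc$truth, cfgc)
    sp <- spearman_edges(half_vectorize(conn_matrix(netc$truth$sc_weights,
                                                    xc$channel_ids, "sc")),
                         half_vectorize(pearson_fc(xc)))
    expect_gt(sp$r, 0)
    expect_lt(sp$p, 0.01)
  }
  # instability is rejected with a clear message
  hot <- tiny_synth(n_contacts = 10, coupling_strength = 5, seed = 8)
  neth <- generate_structural_network(generate_contacts(hot), hot)
  expect_error(simulate_neural_dynamics(neth$truth, hot), "unstable")
})

test_that("the hemodynamic transform obeys its identities", {
  # impulse envelope returns the HRF kernel sampled at dt
  dt <- 0.5
  imp <- c(1, rep(0, 99))
  h <- hrf_double_gamma(seq(0, 32, by = dt))
  got <- hrf_convolve(imp, dt = dt)
  expect_equal(got[seq_along(h)], h * dt, tolerance = 1e-10)
  expect_lt(max(abs(got[-seq_along(h)])), 1e-12)
  expect_equal(which.max(h) - 1, 5 / dt * 1)  # peak near 5 s
  expect_lt(min(h), 0)                        # undershoot exists
  # identical neural channels give BOLD correlation 1 without noise
  cfg <- tiny_synth(n_contacts = 2, noise_sd_bold = 0, seed = 9)
  set.seed(9)
  sig <- rnorm(15 * 1000) * (1 + 0.4 * sin(2 * pi * seq_len(15000) / 4000))
  twin <- ts_panel(rbind(sig, sig), 1000, c("c01", "c02"), "seeg")
  truth <- ground_truth(matrix(c(0, 1, 1, 0), 2), matrix(0, 2, 2), 0)
  b <- simulate_bold(twin, truth, cfg)
  expect_equal(ncol(b$values), cfg$bold_n_volumes)
  expect_equal(cor(b$values[1, ], b$values[2, ]), 1, tolerance = 1e-12)
})

test_that("rendered volumes paint exactly the 19-voxel spheres", {
  cfg <- tiny_synth(n_contacts = 3, noise_sd_bold = 0, seed = 10)
  contacts <- grid_contacts(3, spacing = 16, origin = 14)
  bold <- ts_panel(matrix(rnorm(3 * cfg$bold_n_volumes), 3), 0.5,
                   contacts$contact_id, "bold")
  vol <- render_bold_volume(contacts, bold, cfg)
  nz <- which(vol$data[, , , 1] != 0)
  expect_length(nz, 3 * 19)
  # zero-background round-trip: extraction recovers the signals exactly
  roi <- extract_roi_timeseries(vol, contacts, 19)
  expect_equal(roi$values, bold$values, ignore_attr = TRUE,
               tolerance = 1e-12)
  # overlapping neighborhoods are rejected
  close_pair <- contact_set(c("c01", "c02"),
                            rbind(c(20, 20, 20), c(23, 20, 20)))
  bold2 <- ts_panel(bold$values[1:2, ], 0.5, close_pair$contact_id, "bold")
  expect_error(render_bold_volume(close_pair, bold2, cfg), "overlap")
})

test_that("cross-modal recovery works at moderate coupling", {
  hits <- 0L
  for (s in 1:5) {
    cfg <- synth_config(n_contacts = 15, box_extent = 70,
                        coupling_strength = 0.5, lfp_duration = 120,
                        bold_n_volumes = 60, seed = 500 + s)
    part <- synth_participant(cfg, render_volume = FALSE)
    bfc <- bold_fc_pipeline(bold = part$bold)$fc
    sfc <- suppressWarnings(pearson_fc(crop_panel(part$neural, 60)))
    dist <- euclidean_distance_matrix(part$contacts)
    res <- couple_fc_fc(bfc, sfc, dist)
    if (res$r > 0 && res$p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("every generator stage is a pure function of config and seed", {
  cfg <- tiny_synth(seed = 77)
  p1 <- synth_participant(cfg, render_volume = TRUE)
  p2 <- synth_participant(cfg, render_volume = TRUE)
  expect_identical(p1$contacts, p2$contacts)
  expect_identical(p1$truth$sc_weights, p2$truth$sc_weights)
  expect_identical(p1$neural$values, p2$neural$values)
  expect_identical(p1$bold$values, p2$bold$values)
  expect_identical(p1$volume$data, p2$volume$data)
  # a different seed changes the realization
  p3 <- synth_participant(tiny_synth(seed = 78), render_volume = FALSE)
  expect_false(identical(p3$neural$values, p1$neural$values))
})
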