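#' Configuration of one synthetic participant
#'
#' Bundles every knob of the synthetic multimodal generator: contact
#' geometry, distance-dependent sparse structural network, stable linear
#' stochastic neural dynamics whose pairwise synchronization grows with
#' structural weight, and BOLD as a noisy hemodynamic transform of the neural
#' envelope. Defaults mirror a typical acquisition: LFP at 2000 Hz spanning
#' the 8 min scan, BOLD at TR 2 s for 240 volumes on a 2 mm grid, and about
#' thirty white-matter contacts per participant.
#'
#' @param n_contacts number of white-matter contacts (>= 2).
#' @param box_extent mm extent of the cubic implantation box per axis.
#' @param sc_density base edge probability scale in (0, 1]; the probability
#'   of a structural edge at distance d is
#'   `min(1, sc_density * exp(-distance_decay * d))`.
#' @param distance_decay 1/mm rate of edge-probability decline.
#' @param coupling_strength unitless gain mapping structural weight to
#'   dynamic coupling; 0 gives independent nodes.
#' @param lfp_fs LFP sampling rate in Hz.
#' @param lfp_duration LFP duration in seconds (`lfp_duration * lfp_fs` must
#'   be an integer). The default spans the whole BOLD acquisition (480 s =
#'   240 volumes at TR 2 s): the neural process evolves continuously through
#'   the scan, and the SEEG analysis later selects a 60 s excerpt from it,
#'   as one would from a chronic recording.
#' @param bold_tr BOLD repetition time in seconds.
#' @param bold_n_volumes number of BOLD volumes.
#' @param bold_voxel_mm isotropic BOLD voxel size in mm.
#' @param noise_sd_lfp SD of white measurement noise added to the LFP.
#' @param noise_sd_bold SD of white noise added to BOLD signals (and of the
#'   background voxels of rendered volumes).
#' @param seed study-level integer seed; every stage derives its own
#'   substream from it.
#' @param min_sep_mm minimum pairwise contact separation; the default,
#'   4 voxels (8 mm), guarantees that 19-voxel sphere neighborhoods of
#'   distinct contacts never share a voxel.
#' @param streamline_mean mean streamline count of a present edge (weights
#'   are `1 + Poisson(streamline_mean - 1)`).
#' @param ar_self autoregressive self-coupling of each node (stability and
#'   spectral shape; 0.85 keeps the lagged-coupling cross-spectrum positive
#'   throughout all seven analysis bands at 2000 Hz).
#' @param coupling_gain internal gain from `coupling_strength` to the
#'   spectral norm of the coupling matrix.
#' @param pink_mix,pink_pole low-frequency (1/f-like) shaping of the driving
#'   noise: unit-variance one-pole filtered noise mixed into the white drive
#'   with weight `pink_mix`.
#' @param burn_in_s seconds of simulation discarded before the recording
#'   starts.
#' @param env_window_s window (s) of the moving-RMS neural envelope feeding
#'   the hemodynamic model.
#' @param mod_depth,mod_tau_s,mod_fs,mod_mix_gain infra-slow excitability
#'   modulation: each node's fast signal is multiplied by
#'   `exp(mod_depth * s_i)`, where the slow fields `s_i` (autocorrelation
#'   time `mod_tau_s` s, simulated on a `mod_fs` Hz grid) are mixed across
#'   the structural network with gain `mod_mix_gain * coupling_strength`.
#'   This is the channel through which coupling reaches the hemodynamic
#'   (envelope) signal; `mod_depth = 0` or `coupling_strength = 0` removes
#'   shared slow fluctuations.
#' @param sc_roi_radius_mm sphere radius used when counting streamlines
#'   (1 voxel = 2 mm by default).
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_contacts = 30, box_extent = 80, sc_density = 0.8,
                         distance_decay = 0.04, coupling_strength = 0.5,
                         lfp_fs = 2000, lfp_duration = 480, bold_tr = 2,
                         bold_n_volumes = 240, bold_voxel_mm = 2,
                         noise_sd_lfp = 0.25, noise_sd_bold = 0.2, seed = 1,
                         min_sep_mm = 4 * bold_voxel_mm, streamline_mean = 4,
                         ar_self = 0.85, coupling_gain = 0.14, pink_mix = 1,
                         pink_pole = 0.98, burn_in_s = 10, env_window_s = 1,
                         mod_depth = 0.5, mod_tau_s = 3, mod_fs = 2,
                         mod_mix_gain = 3,
                         sc_roi_radius_mm = bold_voxel_mm) {
  cfg <- as.list(environment())
  if (n_contacts < 2 || bold_n_volumes < 2)
    stop("all counts must be >= 2")
  if (sc_density <= 0 || sc_density > 1)
    stop("sc_density must lie in (0, 1]")
  if (distance_decay < 0 || noise_sd_lfp < 0 || noise_sd_bold < 0 ||
      coupling_strength < 0)
    stop("rates, SDs and coupling_strength must be nonnegative")
  if (abs(lfp_duration * lfp_fs - round(lfp_duration * lfp_fs)) > 1e-9)
    stop("lfp_duration * lfp_fs must be an integer number of samples")
  if (box_extent <= min_sep_mm)
    stop("box_extent must exceed the minimum contact separation")
  if (ar_self <= 0 || ar_self >= 1) stop("ar_self must lie in (0, 1)")
  structure(cfg, class = "synth_config")
}

#' Ground-truth coupling of a synthetic participant
#'
#' Holds the generated streamline-count matrix and the dynamic coupling
#' matrix the simulator actually uses. The latter is a fixed positive
#' multiple of the former (`coupling_strength * coupling_gain / spectral
#' radius`), hence monotone in structural weight whenever
#' `coupling_strength > 0`.
#'
#' @param sc_weights symmetric nonnegative node x node matrix of streamline
#'   counts.
#' @param dynamic_coupling symmetric node x node coupling matrix used by the
#'   simulator.
#' @param coupling_strength the unitless gain that produced it.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(sc_weights, dynamic_coupling, coupling_strength) {
  sc_weights <- as.matrix(sc_weights)
  dynamic_coupling <- as.matrix(dynamic_coupling)
  for (m in list(sc_weights, dynamic_coupling)) {
    if (max(abs(m - t(m))) > 1e-12 || any(diag(m) != 0))
      stop("ground-truth matrices must be symmetric with zero diagonal")
  }
  if (any(sc_weights < 0)) stop("sc_weights must be nonnegative")
  structure(list(sc_weights = sc_weights,
                 dynamic_coupling = dynamic_coupling,
                 coupling_strength = coupling_strength),
            class = "ground_truth")
}

#' Scatter synthetic white-matter contacts in a box
#'
#' Rejection-samples `n_contacts` points uniformly in the cubic box
#' `[0, box_extent]^3` subject to a minimum pairwise separation
#' (`min_sep_mm`, at least twice the voxel size), so sphere ROIs of distinct
#' contacts never overlap. Reproducible from the config seed.
#'
#' @param cfg a [synth_config].
#' @return a [contact_set] with ids `c01`, `c02`, ... and tissue `"white"`.
#' @export
generate_contacts <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(derive_seed(cfg$seed, "contacts"), {
    pts <- matrix(NA_real_, cfg$n_contacts, 3)
    accepted <- 0L
    attempts <- 0L
    max_attempts <- 5000L * cfg$n_contacts
    while (accepted < cfg$n_contacts) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop("could not place contacts with the required separation; ",
             "the box is too small for n_contacts at min_sep_mm")
      cand <- runif(3, 0, cfg$box_extent)
      ok <- accepted == 0L ||
        min(sqrt(colSums((t(pts[seq_len(accepted), , drop = FALSE]) -
                            cand)^2))) >= cfg$min_sep_mm
      if (ok) {
        accepted <- accepted + 1L
        pts[accepted, ] <- cand
      }
    }
    contact_set(sprintf("c%02d", seq_len(cfg$n_contacts)), pts,
                tissue = "white")
  })
}

#' Generate the structural network and its streamlines
#'
#' Draws a sparse distance-dependent structural graph: an edge between
#' contacts i and j is present with probability
#' `min(1, sc_density * exp(-distance_decay * d_ij))`, and a present edge
#' gets an integer streamline count `1 + Poisson(streamline_mean - 1)`. For
#' every counted streamline a polyline is emitted whose endpoints lie inside
#' the two contacts' counting spheres and which avoids every other contact's
#' sphere, so [count_streamline_connections()] recovers `sc_weights` exactly.
#'
#' @param contacts a [contact_set].
#' @param cfg a [synth_config].
#' @return list with `truth` (a [ground_truth]) and `streamlines` (a
#'   [streamline_set]).
#' @export
generate_structural_network <- function(contacts, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  xyz <- contact_coords(contacts)
  n <- nrow(xyz)
  if (n < 2) stop("need at least two contacts")
  with_seed(derive_seed(cfg$seed, "network"), {
    d <- as.matrix(stats::dist(xyz))
    W <- matrix(0L, n, n, dimnames = list(rownames(xyz), rownames(xyz)))
    lines <- list()
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        pedge <- min(1, cfg$sc_density * exp(-cfg$distance_decay * d[i, j]))
        if (rbinom(1, 1, pedge) == 1) {
          w <- 1L + rpois(1, max(cfg$streamline_mean - 1, 0))
          W[i, j] <- W[j, i] <- w
          for (k in seq_len(w)) {
            lines[[length(lines) + 1L]] <-
              route_streamline(xyz, i, j, cfg$sc_roi_radius_mm)
          }
        }
      }
    }
    if (all(W == 0))
      stop("degenerate network: no structural edges were generated ",
           "(distance_decay too steep or sc_density too low)")
    K <- W * 0
    if (cfg$coupling_strength > 0) {
      rho <- max(abs(eigen(W, symmetric = TRUE,
                           only.values = TRUE)$values))
      K <- cfg$coupling_strength * cfg$coupling_gain * W / rho
    }
    list(truth = ground_truth(W, K, cfg$coupling_strength),
         streamlines = streamline_set(lines))
  })
}

# One synthetic streamline between contacts i and j: endpoints uniform
# inside 0.8 * radius balls around the contacts, a jittered midpoint for
# curvature, retried until the densified path stays clear of every other
# contact's counting sphere (margin covers the 0.5 mm densification step).
route_streamline <- function(xyz, i, j, radius) {
  others <- setdiff(seq_len(nrow(xyz)), c(i, j))
  clearance <- radius + 0.6
  for (attempt in seq_len(200)) {
    a <- xyz[i, ] + ball_point(0.8 * radius)
    b <- xyz[j, ] + ball_point(0.8 * radius)
    jitter_sd <- 0.5 + 0.5 * attempt
    mid <- (a + b) / 2 + rnorm(3, 0, jitter_sd)
    line <- rbind(a, mid, b)
    if (!length(others)) return(unname(line))
    pts <- densify_polyline(line, 0.5)
    dmin <- min(vapply(others, function(k)
      min(sqrt(colSums((t(pts) - xyz[k, ])^2))), numeric(1)))
    if (dmin > clearance) return(unname(line))
  }
  stop("could not route a streamline clear of other contact spheres")
}

# uniform point in a ball of given radius
ball_point <- function(radius) {
  repeat {
    p <- runif(3, -radius, radius)
    if (sum(p^2) <= radius^2) return(p)
  }
}

#' Simulate coupled neural dynamics
#'
#' Two-timescale generative model of the local field potentials. The fast
#' component is a discrete-time stable linear stochastic network at the LFP
#' sampling rate, `z_t = (ar_self * I + K) z_{t-1} + e_t`, where `K` is the
#' ground-truth dynamic coupling and `e_t` is independent per-node broadband
#' noise with a 1/f-shaped low-frequency boost (each node's white input mixed
#' with its one-pole filtered copy); its band-limited pairwise correlations increase
#' with `K` in every analysis band. On top of it, each node's amplitude is
#' modulated by an infra-slow excitability field, `x_i = exp(mod_depth *
#' s_i) * z_i`, where the `s_i` are slow processes mixed across the same
#' structural network — the physiological channel by which coupling reaches
#' slow activity envelopes and hence the hemodynamic signal. A burn-in of
#' `burn_in_s` seconds is discarded so the recorded segment is stationary;
#' white measurement noise of SD `noise_sd_lfp` is added on top.
#'
#' @param truth a [ground_truth].
#' @param cfg a [synth_config].
#' @return a [ts_panel] with modality `"seeg"`, `n_contacts` channels,
#'   `lfp_duration * lfp_fs` samples.
#' @export
simulate_neural_dynamics <- function(truth, cfg) {
  stopifnot(inherits(truth, "ground_truth"), inherits(cfg, "synth_config"))
  n <- nrow(truth$dynamic_coupling)
  A <- diag(cfg$ar_self, n) + truth$dynamic_coupling
  rho <- max(abs(eigen(A, only.values = TRUE)$values))
  if (rho >= 0.995)
    stop(sprintf(paste0("unstable coupling matrix: spectral radius %.3f ",
                        ">= 0.995; lower coupling_strength"), rho))
  nt <- round(cfg$lfp_duration * cfg$lfp_fs)
  burn <- round(cfg$burn_in_s * cfg$lfp_fs)
  with_seed(derive_seed(cfg$seed, "neural"), {
    w <- matrix(rnorm(n * (nt + burn)), n)
    x <- ar_simulate_cpp(A, w, cfg$pink_mix,
                         cfg$pink_pole)[, (burn + 1):(burn + nt),
                                        drop = FALSE]
    if (cfg$mod_depth > 0) {
      m <- slow_modulators(truth, cfg, nt)
      x <- x * m
    }
    if (cfg$noise_sd_lfp > 0)
      x <- x + matrix(rnorm(n * nt, 0, cfg$noise_sd_lfp), n)
    ids <- rownames(truth$sc_weights)
    if (is.null(ids)) ids <- sprintf("c%02d", seq_len(n))
    ts_panel(x, cfg$lfp_fs, ids, modality = "seeg")
  })
}

# Multiplicative infra-slow excitability fields, one row per node, at the
# LFP rate for the recorded segment. Independent unit-variance AR(1)
# processes on a mod_fs grid (autocorrelation time mod_tau_s) are mixed with
# B = I + mod_mix_gain * coupling_strength * W/rho(W) -- the same normalized
# structural weights that set the fast coupling -- then standardized,
# exponentiated with gain mod_depth and interpolated to the sample grid.
# With coupling_strength = 0 the fields are independent across nodes.
slow_modulators <- function(truth, cfg, nt) {
  n <- nrow(truth$sc_weights)
  n_slow <- max(4L, ceiling(nt / cfg$lfp_fs * cfg$mod_fs) + 1L)
  pole <- exp(-1 / (cfg$mod_fs * cfg$mod_tau_s))
  u <- matrix(rnorm(n * n_slow), n)
  u <- t(apply(u, 1, function(x)
    as.numeric(stats::filter(x, pole, method = "recursive")))) *
    sqrt(1 - pole^2)
  B <- diag(n)
  if (cfg$coupling_strength > 0 && any(truth$sc_weights > 0)) {
    rho <- max(abs(eigen(truth$sc_weights, symmetric = TRUE,
                         only.values = TRUE)$values))
    B <- B + cfg$mod_mix_gain * cfg$coupling_strength *
      truth$sc_weights / rho
  }
  s <- B %*% u
  s <- s / sqrt(rowSums(s^2) / ncol(s))
  t_slow <- seq(0, nt - 1, length.out = n_slow)
  m <- matrix(0, n, nt)
  for (i in seq_len(n))
    m[i, ] <- exp(cfg$mod_depth *
                    approx(t_slow, s[i, ], xout = seq_len(nt) - 1)$y)
  m
}

#' Canonical double-gamma hemodynamic response
#'
#' Difference of two gamma densities (unit rate): a response peaking near 5 s
#' and an undershoot peaking near 15 s, scaled by `undershoot_ratio`.
#'
#' @param t time in seconds (vector).
#' @param peak_shape,undershoot_shape gamma shape parameters of the response
#'   and undershoot lobes.
#' @param undershoot_ratio relative undershoot amplitude.
#' @return HRF values at `t`.
#' @export
hrf_double_gamma <- function(t, peak_shape = 6, undershoot_shape = 16,
                             undershoot_ratio = 1 / 6) {
  stats::dgamma(t, shape = peak_shape, rate = 1) -
    undershoot_ratio * stats::dgamma(t, shape = undershoot_shape, rate = 1)
}

#' Moving-RMS envelope of a panel
#'
#' Root-mean-square amplitude over consecutive non-overlapping windows — the
#' slow activity envelope that drives the hemodynamic model.
#'
#' @param panel a [ts_panel].
#' @param window_s window length in seconds.
#' @return a [ts_panel] at `1 / window_s` Hz, same channels and modality.
#' @export
envelope_rms <- function(panel, window_s = 1) {
  stopifnot(inherits(panel, "ts_panel"))
  nw <- round(window_s * panel$fs)
  if (floor(ncol(panel$values) / nw) < 2)
    stop("panel too short for the envelope window")
  env <- rms_envelope_cpp(panel$values, nw)
  ts_panel(env, 1 / window_s, panel$channel_ids, panel$modality)
}

#' Convolve an envelope with the canonical HRF
#'
#' Causal discrete convolution of an activity envelope (sampled every `dt`
#' seconds) with the double-gamma HRF, truncated to the input length. An
#' impulse input returns the HRF kernel itself.
#'
#' @param env numeric vector, envelope samples at spacing `dt`.
#' @param dt sample spacing in seconds.
#' @param kernel_duration_s HRF kernel support in seconds.
#' @param ... passed to [hrf_double_gamma()].
#' @return numeric vector, same length as `env`.
#' @export
hrf_convolve <- function(env, dt = 0.5, kernel_duration_s = 32, ...) {
  h <- hrf_double_gamma(seq(0, kernel_duration_s, by = dt), ...)
  out <- stats::convolve(c(env, rep(0, length(h))), rev(h), type = "open")
  out[seq_along(env)] * dt
}

#' Simulate BOLD signals from neural dynamics
#'
#' Per node: compute the moving-RMS envelope of the neural signal, stretch
#' its time base to span the BOLD acquisition (the envelope supplies the slow
#' fluctuation pattern; its absolute time scale is not interpreted), convolve
#' with the canonical double-gamma HRF on a 0.5 s grid, sample at the TR,
#' standardize, and add white noise of SD `noise_sd_bold`.
#'
#' @param neural a [ts_panel] from [simulate_neural_dynamics()].
#' @param truth a [ground_truth] (carried for provenance; the transform is
#'   per-node).
#' @param cfg a [synth_config].
#' @return a [ts_panel] with modality `"bold"`, `fs = 1/bold_tr`,
#'   `bold_n_volumes` samples.
#' @export
simulate_bold <- function(neural, truth, cfg) {
  stopifnot(inherits(neural, "ts_panel"), inherits(cfg, "synth_config"))
  env <- envelope_rms(neural, cfg$env_window_s)
  bold_dur <- cfg$bold_tr * cfg$bold_n_volumes
  dt <- 0.5
  t_fine <- seq(0, bold_dur, by = dt)
  t_env <- seq(0, bold_dur, length.out = ncol(env$values))
  vol_idx <- round((seq_len(cfg$bold_n_volumes) - 1) * cfg$bold_tr / dt) + 1
  with_seed(derive_seed(cfg$seed, "bold"), {
    out <- matrix(0, nrow(env$values), cfg$bold_n_volumes)
    for (i in seq_len(nrow(env$values))) {
      ef <- approx(t_env, env$values[i, ], xout = t_fine)$y
      ef <- ef - mean(ef)
      y <- hrf_convolve(ef, dt = dt)[vol_idx]
      s <- sd(y)
      if (s > 0) y <- y / s
      out[i, ] <- y
    }
    if (cfg$noise_sd_bold > 0)
      out <- out + matrix(rnorm(length(out), 0, cfg$noise_sd_bold),
                          nrow(out))
    ts_panel(out, 1 / cfg$bold_tr, neural$channel_ids, modality = "bold")
  })
}

#' Render BOLD signals into a synthetic 4D volume
#'
#' Writes each contact's BOLD series into all voxels of its 19-voxel sphere
#' neighborhood on a `bold_voxel_mm` grid covering the contact box; every
#' other voxel carries independent white noise of SD `noise_sd_bold`.
#' Overlapping neighborhoods are an error (prevented by the contact
#' separation constraint).
#'
#' @param contacts a [contact_set].
#' @param bold a [ts_panel] with modality `"bold"`, channels matching the
#'   contacts.
#' @param cfg a [synth_config].
#' @param neighborhood voxels painted per contact (default 19).
#' @return a [bold_volume].
#' @export
render_bold_volume <- function(contacts, bold, cfg, neighborhood = 19L) {
  stopifnot(inherits(contacts, "contact_set"), inherits(bold, "ts_panel"),
            inherits(cfg, "synth_config"))
  xyz <- contact_coords(contacts)
  if (!identical(rownames(xyz), bold$channel_ids))
    stop("contact ids and BOLD channel ids must match")
  vx <- cfg$bold_voxel_mm
  dims <- rep(floor(cfg$box_extent / vx) + 1L, 3)
  if (any(xyz < -vx / 2) || any(xyz > (cfg$box_extent + vx / 2)))
    stop("contact outside the rendering grid")
  nt <- ncol(bold$values)
  with_seed(derive_seed(cfg$seed, "volume"), {
    flat <- matrix(rnorm(prod(dims) * nt, 0, cfg$noise_sd_bold),
                   prod(dims), nt)
    painted <- integer(0)
    for (i in seq_len(nrow(xyz))) {
      vox <- sphere_voxels(xyz[i, ], neighborhood, vx, c(0, 0, 0),
                           grid_dim = dims)
      lin <- vox[, 1] + dims[1] * (vox[, 2] - 1) +
        dims[1] * dims[2] * (vox[, 3] - 1)
      if (any(lin %in% painted))
        stop("sphere neighborhoods of two contacts overlap")
      painted <- c(painted, lin)
      flat[lin, ] <- matrix(bold$values[i, ], length(lin), nt, byrow = TRUE)
    }
    bold_volume(array(flat, dim = c(dims, nt)), voxel_mm = vx,
                origin_mm = c(0, 0, 0), tr = cfg$bold_tr)
  })
}

#' Generate one complete synthetic participant
#'
#' Convenience wrapper running every generator stage: contacts, structural
#' network with streamlines, neural dynamics, BOLD panel and (optionally) the
#' rendered 4D volume.
#'
#' @param cfg a [synth_config].
#' @param render_volume also render the 4D volume (memory for large grids).
#' @return list with `contacts`, `truth`, `streamlines`, `neural`, `bold`
#'   and (optionally) `volume`.
#' @export
synth_participant <- function(cfg, render_volume = TRUE) {
  contacts <- generate_contacts(cfg)
  net <- generate_structural_network(contacts, cfg)
  neural <- simulate_neural_dynamics(net$truth, cfg)
  bold <- simulate_bold(neural, net$truth, cfg)
  out <- list(contacts = contacts, truth = net$truth,
              streamlines = net$streamlines, neural = neural, bold = bold)
  if (render_volume)
    out$volume <- render_bold_volume(contacts, bold, cfg)
  out
}
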