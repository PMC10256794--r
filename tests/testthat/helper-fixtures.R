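# shared fixtures: small panels, contact sets and configs built in code

random_panel <- function(n_ch = 4, n_s = 200, fs = 100, modality = "seeg",
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ts_panel(matrix(rnorm(n_ch * n_s), n_ch), fs,
           sprintf("ch%02d", seq_len(n_ch)), modality)
}

sine_panel <- function(freq, fs, duration_s, n_ch = 1, amplitude = 1) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  ts_panel(matrix(rep(amplitude * sin(2 * pi * freq * t), n_ch),
                  n_ch, byrow = TRUE),
           fs, sprintf("s%02d", seq_len(n_ch)), "seeg")
}

grid_contacts <- function(n, spacing = 12, origin = 10) {
  # deterministic interior contacts on a coarse lattice
  per_axis <- ceiling(n^(1 / 3))
  g <- as.matrix(expand.grid(x = seq_len(per_axis), y = seq_len(per_axis),
                             z = seq_len(per_axis)))[seq_len(n), , drop = FALSE]
  contact_set(sprintf("g%02d", seq_len(n)), origin + (g - 1) * spacing)
}

# steady-state amplitude ratio of a filtered sinusoid, trimming edges
amp_ratio <- function(filtered, original, trim = 0.2) {
  n <- ncol(original$values)
  keep <- seq(floor(n * trim) + 1, ceiling(n * (1 - trim)))
  sd(filtered$values[1, keep]) / sd(original$values[1, keep])
}

tiny_synth <- function(...) {
  args <- list(...)
  defaults <- list(n_contacts = 8, box_extent = 60, lfp_duration = 15,
                   lfp_fs = 1000, bold_n_volumes = 40, coupling_strength = 0.5,
                   seed = 1)
  do.call(synth_config, utils::modifyList(defaults, args))
}

local_tmpdir <- function() {
  d <- tempfile("wmcoupling-test-")
  dir.create(d)
  d
}
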