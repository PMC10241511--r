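# Shared fixtures, built once per test run and memoized. All fixtures are
# generated in code from fixed seeds; nothing is read from disk.

.fx <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fx, inherits = FALSE))
    assign(name, force(expr), envir = .fx)
  get(name, envir = .fx, inherits = FALSE)
}

fx_mesh3 <- function() memo("mesh3", make_mesh(3))
fx_geo3 <- function() memo("geo3", latentcortex:::mesh_geodesics(fx_mesh3()))
# finer mesh for smoothing-kernel work (edge length ~4 mm resolves 1-10 mm fwhm)
fx_mesh4 <- function() memo("mesh4", make_mesh(4))
fx_geo4 <- function() memo("geo4", latentcortex:::mesh_geodesics(fx_mesh4()))
fx_maps <- function() memo("maps",
  make_networks(fx_mesh3(), 5, 15, seed = 11, geo = fx_geo3()))
fx_truth <- function() memo("truth", synthetic_truth(fx_maps(), seed = 11))

# primary desk-scale cohort: 14 subjects x 160 frames
fx_cohort <- function() memo("cohort",
  simulate_cohort(fx_mesh3(), fx_truth(), n_subjects = 14, T = 160,
                  tr_seconds = 0.72, seed = 12, geo = fx_geo3()))

fx_mapping <- function() memo("mapping", build_grid_mapping(fx_mesh3(), c(32, 32)))

fx_frames <- function() memo("frames", {
  mp <- fx_mapping()
  do.call(rbind, lapply(fx_cohort()$scans,
                        function(s) latentcortex:::grid_to_batch(to_grid(s, mp))))
})

# the desk-scale training profile (see the methods vignette): beta at the
# variance-equivalent desk operating point, short-budget optimizer settings
fx_vae_config <- function(seed = 0L)
  vae_config(n_latent = 64L, channels = c(16L, 32L, 64L, 64L, 64L),
             beta = 0.3, learning_rate = 6e-3, batch_size = 32L,
             epochs = 20L, seed = seed)

# VAE trained for 20 epochs on the first 2000 cohort frames (shared across
# acceptance tests; ~2.5 min once per run)
fx_vae <- function() memo("vae", {
  valid <- to_grid(fx_cohort()$scans[[1]], fx_mapping())$valid
  m <- build_vae(fx_vae_config(0L), c(32L, 32L), valid = valid)
  train_vae(m, fx_frames()[1:2000, ])
})

# latent timeseries of every cohort subject under the trained VAE
fx_latents <- function() memo("latents", {
  m <- fx_vae()
  mp <- fx_mapping()
  lapply(fx_cohort()$scans, function(s)
    encode(m, to_grid(s, mp), subject_id = s$subject_id,
           session_id = s$session_id, age_weeks = s$age_weeks))
})

encode_cohort <- function(coh) {
  m <- fx_vae(); mp <- fx_mapping()
  lapply(coh$scans, function(s)
    encode(m, to_grid(s, mp), subject_id = s$subject_id,
           session_id = s$session_id, age_weeks = s$age_weeks))
}

# prediction-scale cohort (n = 300) under the configured age effect, plus a
# null twin with the age effect switched off; both encoded with the frozen
# trained VAE (the pretrained-encoder protocol). Simulated and encoded in
# chunks of 25 subjects so only FC vectors are retained.
fc_cohort_chunked <- function(truth, base_seed, n_total = 300L, chunk = 25L) {
  m <- fx_vae(); mp <- fx_mapping()
  Fs <- list(); ages <- numeric(0)
  for (ci in seq_len(n_total %/% chunk)) {
    coh <- simulate_cohort(fx_mesh3(), truth, n_subjects = chunk, T = 150,
                           tr_seconds = 0.72, seed = base_seed + ci,
                           geo = fx_geo3())
    Fs[[ci]] <- t(vapply(coh$scans, function(s) {
      z <- encode(m, to_grid(s, mp))
      latent_fc(z)$vector
    }, numeric(64 * 63 / 2)))
    ages <- c(ages, coh$table$age_weeks)
  }
  list(F = do.call(rbind, Fs), ages = ages)
}

fx_fc300 <- function() memo("fc300",
  fc_cohort_chunked(fx_truth(), base_seed = 100L))

fx_fc300_null <- function() memo("fc300_null", {
  truth0 <- synthetic_truth(fx_maps(), age_effect = matrix(0, 5, 5),
                            seed = 11)
  fc_cohort_chunked(truth0, base_seed = 200L)
})

# replication cohorts for the reproducibility analysis: same truth, new
# sampling seed; and a cohort from a different truth (new network maps)
fx_latents_same <- function() memo("latents_same", {
  coh <- simulate_cohort(fx_mesh3(), fx_truth(), n_subjects = 8, T = 160,
                         tr_seconds = 0.72, seed = 13, geo = fx_geo3())
  encode_cohort(coh)
})

fx_latents_diff <- function() memo("latents_diff", {
  maps2 <- make_networks(fx_mesh3(), 5, 15, seed = 21, geo = fx_geo3())
  truth2 <- synthetic_truth(maps2, seed = 21)
  coh <- simulate_cohort(fx_mesh3(), truth2, n_subjects = 8, T = 160,
                         tr_seconds = 0.72, seed = 14, geo = fx_geo3())
  encode_cohort(coh)
})
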