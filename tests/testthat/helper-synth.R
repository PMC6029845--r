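# Small synthetic cohorts shared across test files.

small_spec <- function(n_subjects = 1, n_conditions = 4, n_trials = 12,
                       n_channels = 12, time_lim = c(-100, 350),
                       time_step = 10,
                       id_env = envelope(40, 100, 60, amplitude = 1.2),
                       cat_env = envelope(110, 170, 80, amplitude = 1.5),
                       noise_sd = 1, seed = 1) {
  synth_spec(n_subjects = n_subjects, n_conditions = n_conditions,
             n_trials_per_condition = n_trials, n_channels = n_channels,
             time_lim = time_lim, time_step = time_step,
             identity_envelope = id_env, category_envelope = cat_env,
             noise_sd = noise_sd, seed = seed)
}

# epochs with hand-set per-condition channel values, constant over trials
manual_epochs <- function(values_by_cond, time = NULL, n_trials = 2,
                          n_channels = 1) {
  # values_by_cond: list(cond_id = matrix trials x time) for one channel
  conds <- names(values_by_cond)
  Tn <- ncol(values_by_cond[[1]])
  if (is.null(time)) time <- seq_len(Tn)
  n <- nrow(values_by_cond[[1]])
  dat <- array(0, c(n * length(conds), n_channels, Tn))
  labels <- rep(conds, each = n)
  for (ci in seq_along(conds))
    for (tr in seq_len(n))
      dat[(ci - 1) * n + tr, 1, ] <- values_by_cond[[ci]][tr, ]
  meg_epochs(dat, labels, time, sampling_rate = 1000,
             baseline = c(min(time), min(time)))
}

# subjects x time partition matrices from a list of per-subject RDMs
series_matrix <- function(rdms, pairs) {
  do.call(rbind, lapply(rdms, partition_mean, pairs = pairs))
}
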