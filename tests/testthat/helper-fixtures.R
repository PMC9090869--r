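# Builders for toy minute tables and HMM models used across tests.

# One or more full recorded days for one subject; per-minute vectors are
# recycled to n_days * 1440 minutes.
make_minutes <- function(subject_id = "A", n_days = 1L, mims = 1,
                         wear = "wake-wear", flags = 0L, start_dow = 1L) {
  T <- n_days * 1440L
  day_index <- rep(seq_len(n_days), each = 1440L)
  data.frame(subject_id = subject_id, day_index = day_index,
             minute_of_day = rep(0:1439, n_days),
             calendar_dow = ((start_dow - 1 + day_index - 1) %% 7) + 1,
             mims_triaxial = rep_len(mims, T),
             wear_pred = rep_len(wear, T),
             quality_flag_count = rep_len(flags, T),
             stringsAsFactors = FALSE)
}

rand_hmm <- function() {
  pi <- runif(2, 0.1, 0.9); pi <- pi / sum(pi)
  A <- matrix(runif(4, 0.05, 0.95), 2, 2); A <- A / rowSums(A)
  mu <- sort(rnorm(2, c(0, 2), 0.5))
  sleep_hmm_model(pi, A, mu, runif(2, 0.2, 1))
}

# decoded-label data.frame for one subject from explicit absolute sleep
# intervals (minutes 0-based from recording start, half-open)
make_decoded <- function(subject_id = "A", n_days = 7L, sleep_intervals,
                         start_dow = 1L) {
  T <- n_days * 1440L
  sleep <- logical(T)
  for (iv in sleep_intervals) {
    lo <- max(iv[1], 0L); hi <- min(iv[2], T)
    if (lo < hi) sleep[(lo + 1L):hi] <- TRUE
  }
  day_index <- rep(seq_len(n_days), each = 1440L)
  data.frame(subject_id = subject_id, day_index = day_index,
             minute_of_day = rep(0:1439, n_days),
             calendar_dow = ((start_dow - 1 + day_index - 1) %% 7) + 1,
             sleep = sleep, stringsAsFactors = FALSE)
}

# a small survey design with equal-size strata and alternating PSUs
make_design <- function(n, n_strata = 10L, weights = NULL) {
  st <- rep_len(seq_len(n_strata), n)
  ps <- stats::ave(seq_len(n), st, FUN = function(i) rep_len(1:2, length(i)))
  svy_design(st, ps, weights %||% rep(1, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
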