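# Shared fixtures: small classrooms and the beats -> features pipeline.

small_config <- function(seed = 1, n_dyads_per_class = c(3, 3),
                         session_length_s = 1800, ...) {
  classroom_config(n_dyads_per_class = n_dyads_per_class,
                   session_length_s = session_length_s, seed = seed, ...)
}

pipe_fsets <- function(cls, length_s = 300, min_beats = 10L) {
  nn <- lapply(names(cls$beats), function(id) {
    beats_to_nn(cls$beats[[id]], participant_id = as.integer(id))
  })
  names(nn) <- names(cls$beats)
  features_by_participant(nn, window_spec(length_s), min_beats = min_beats)
}

# build a feature_set by hand (for tests that bypass the NN pipeline)
fake_fset <- function(values, valid = rep(TRUE, length(values)),
                      length_s = 300, starts = NULL, id = NA_integer_) {
  m <- length(values)
  if (is.null(starts)) starts <- seq(0, by = 200, length.out = m)
  out <- data.frame(window_start_s = starts, n_beats = 999L, valid = valid,
                    HR = values, SDNN = values, rMSSD = values)
  attr(out, "spec") <- window_spec(length_s)
  attr(out, "participant_id") <- id
  class(out) <- c("feature_set", "data.frame")
  out
}

# brute-force Pearson correlation from the product-moment formula
brute_cor <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
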