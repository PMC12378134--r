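# Shared fixtures and independent oracles used across test files.

# A deterministic 17-value percent profile with a spread of defect depths.
fixture_profile <- function() {
  c(95, 88, 72, 65, 58, 44, 39, 100, 70, 60, 50, 40, 69.9, 59.9, 49.9,
    39.9, 81)
}

# Cohort data frame built directly from a matrix of profiles (one row per
# subject), bypassing the simulator.
make_cohort <- function(profiles, phase = "late", population = "Jp",
                        sex = "F", label = "none", hmr = NULL,
                        prefix = "S") {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  df <- data.frame(subject_id = sprintf("%s%03d", prefix, seq_len(n)),
                   population = population, sex = sex, phase = phase,
                   label = label)
  if (!is.null(hmr)) df$hmr <- hmr
  colnames(profiles) <- sprintf("seg%02d", 1:17)
  cbind(df, as.data.frame(profiles))
}

# Brute-force Mann-Whitney AUC: average over every case-control pair,
# ties counting one half.
auc_pairs_oracle <- function(values, is_case) {
  x <- values[is_case]; y <- values[!is_case]
  total <- 0
  for (a in x) for (b in y)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(x) * length(y))
}

# Band lookup for the visual rule, independent of the implementation.
visual_band_oracle <- function(u) 4L - findInterval(u, c(40, 50, 60, 70))

# Tie-corrected Kruskal-Wallis H from first principles (manual ranking).
kw_hand_oracle <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  groups <- factor(groups)
  h <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(ri) length(ri) * mean(ri)^2)) -
    3 * (N + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}
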