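# Independent oracles used across test files. Deliberately written from
# first principles, without calling the package's own code paths.

# average ranks (midranks), written out longhand
midrank <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }
  r
}

# Spearman as Pearson on midranks, via the explicit product-moment formula
oracle_spearman <- function(x, y) {
  rx <- midrank(x); ry <- midrank(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# hand evaluation of the two area-score formulas
oracle_irs <- function(w, m, s) (w + m * 5 + s * 10) / 100
oracle_hscore <- function(w, m, s) w + m * 2 + s * 3

profile_vec <- function(p) {
  c(p$pct_negative, p$pct_weak, p$pct_moderate, p$pct_strong)
}

max_profile_error <- function(profile, truth_fractions) {
  max(abs(profile_vec(profile) - truth_fractions))
}
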