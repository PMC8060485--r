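# Fixtures built in code: piecewise vein curves with exact onset/peak/clear
# grid times, the three published worked examples, and independent
# enumeration oracles for the exact tests.

# Piecewise-linear vein enhancement: below threshold before `onset`, exactly
# at the 50-HU visibility threshold at `onset`, unique maximum `amp` at
# `peak`, above threshold until just before `clear`, well below from `clear`
# on. Guarantees the within-5%-of-peak window contains only `peak` itself
# for the grids used here.
make_vein_tac <- function(times, onset, peak, clear, amp = 200,
                          baseline = 40) {
  enh <- numeric(length(times))
  rising <- times >= onset & times <= peak
  falling <- times > peak & times < clear
  enh[rising] <- 50 + (amp - 50) * (times[rising] - onset) / (peak - onset)
  enh[falling] <- 50 + (amp - 50) * (clear - times[falling]) / (clear - peak)
  enh[times >= clear] <- 10
  tac(times, baseline + enh, baseline = baseline)
}

# Triangular reference curve with its unique sampled maximum at `peak`.
make_tri_tac <- function(times, peak, width, amp = 300, baseline = 40) {
  tac(times, baseline + amp * pmax(0, 1 - abs(times - peak) / width),
      baseline = baseline)
}

# Irregular 19-volume grid containing every printed Case-1 reading.
case1_grid <- function() {
  c(8.0, 10.1, 12.2, 14.3, 16.2, 17.6, 19.0, 20.9, 22.8, 24.8, 26.8,
    28.8, 30.7, 32.7, 34.7, 36.7, 37.7, 39.7, 41.7)
}

# Long-format TAC table for a synthetic patient whose scored times equal the
# Case-1 readings: A-TAC 16.2 s, V-TAC 24.8 s, contralateral CVF 19.0 /
# 24.8 / 32.7 s, affected CVF 20.9 / 24.8 / 37.7 s, all veins present.
case1_tac_df <- function(patient_id = "C1", group = "symptomatic") {
  times <- case1_grid()
  curves <- list(
    MCA.affected = make_tri_tac(times, 16.2, 10),
    MCA.contralateral = make_tri_tac(times, 16.2, 10),
    SSS.affected = make_tri_tac(times, 24.8, 15, amp = 400)
  )
  for (v in c("SMCV", "VOT", "VOL")) {
    curves[[paste0(v, ".affected")]] <-
      make_vein_tac(times, 20.9, 24.8, 37.7)
    curves[[paste0(v, ".contralateral")]] <-
      make_vein_tac(times, 19.0, 24.8, 32.7)
  }
  do.call(rbind, lapply(names(curves), function(nm) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    data.frame(patient_id = patient_id, group = group,
               hemisphere = parts[2], structure = parts[1],
               time_s = times, attenuation_hu = curves[[nm]]$values)
  }))
}

# Two-sided Fisher p-value by exhaustive enumeration over all tables with
# the observed margins, hypergeometric probabilities from choose() only.
fisher_p_enum <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  k <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- choose(c1, k) * choose(n - c1, r1 - k) / choose(n, r1)
  sum(probs[probs <= probs[k == a] * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p-value by full enumeration of all
# choose(m+n, m) group labelings of the pooled sample.
mw_p_enum <- function(x, y) {
  m <- length(x)
  n <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  labelings <- utils::combn(m + n, m)
  u_all <- apply(labelings, 2, function(i) sum(r[i]) - m * (m + 1) / 2)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# Random valid 2x2 table with total at most n_max (at least one non-empty
# margin pair so that the table is non-degenerate).
random_2x2 <- function(n_max = 40) {
  repeat {
    cells <- as.vector(stats::rmultinom(1, sample(4:n_max, 1),
                                        prob = stats::runif(4, 0.05, 1)))
    tab <- matrix(cells, 2)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) return(cells)
  }
}
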