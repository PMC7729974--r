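# Independent oracles: deliberately naive implementations used only to check
# the package's results, never sharing code with them.

# Spearman rho by the textbook rank-difference formula (tie-free inputs).
oracle_spearman <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# AUC by exhaustive case/control pair counting, ties counted one half.
oracle_auc <- function(scores, labels) {
  x <- scores[labels == "ESRD"]
  y <- scores[labels == "noESRD"]
  tot <- 0
  for (a in x) for (b in y) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(x) * length(y))
}

# Clopper-Pearson bounds by bisection on the exact binomial tail.
oracle_cp <- function(s, n, conf = 0.95, tol = 1e-12) {
  a <- (1 - conf) / 2
  bisect <- function(f) {
    lo <- 0; hi <- 1
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
      if (hi - lo < tol) break
    }
    (lo + hi) / 2
  }
  lower <- if (s == 0) 0 else bisect(function(p) stats::pbinom(s - 1, n, p, lower.tail = FALSE) - a)
  upper <- if (s == n) 1 else bisect(function(p) a - stats::pbinom(s, n, p))
  c(lower = lower, upper = upper)
}

# Three-way partition by plain set algebra.
oracle_venn <- function(af_ids, fu_ids) {
  list(
    af_only = af_ids[!af_ids %in% fu_ids],
    common = af_ids[af_ids %in% fu_ids],
    fu_only = fu_ids[!fu_ids %in% af_ids]
  )
}

# Bond-by-bond cleavage scan for one simplified rule set.
oracle_sites <- function(sequence, rules) {
  res <- strsplit(sequence, "")[[1]]
  out <- integer(0)
  for (i in seq_len(length(res) - 1)) {
    p1 <- res[i]; p1p <- res[i + 1]
    cut <- (p1 %in% rules$p1 && !(p1p %in% rules$block_p1p)) ||
      (p1p %in% rules$p1_prime)
    if (cut) out <- c(out, i - 1L)
  }
  out
}

# Exhaustive per-bin detection-frequency filter.
oracle_filter <- function(abundance, samples, min_freq) {
  m <- as.matrix(abundance[-1])
  rownames(m) <- abundance$sample_id
  bins <- samples$ga_bin[match(rownames(m), samples$sample_id)]
  keep <- character(0)
  for (pep in colnames(m)) {
    ok <- FALSE
    for (b in unique(as.character(bins))) {
      v <- m[bins == b, pep]
      if (length(v) && mean(v > 0) >= min_freq && any(v > 0)) ok <- TRUE
    }
    if (ok) keep <- c(keep, pep)
  }
  keep
}

# Exact two-sided Mann-Whitney p by enumerating group assignments (tiny n).
oracle_mw_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  u_obs <- sum(rank(pooled)[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(n, na)
  us <- apply(combos, 2, function(idx) {
    sum(rank(pooled)[idx]) - na * (na + 1) / 2
  })
  mu <- na * (n - na) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Small deterministic two-fluid fixture: 6 AF + 6 FU samples (4 paired),
# 8 peptides with hand-set abundances.
tiny_cohort <- function() {
  peps <- paste0("p", 1:8)
  samples <- tibble::tibble(
    sample_id = c(paste0("A", 1:6), paste0("U", 1:6)),
    fluid = rep(c("AF", "FU"), each = 6),
    gestational_age_wa = rep(c(12, 16, 20, 23, 30, 37), 2),
    patient_id = c(paste0("pt", 1:6), paste0("pt", c(1:4, 7, 8)))
  )
  samples <- assign_ga_bins(samples)
  set.seed(99)
  af <- tibble::tibble(sample_id = paste0("A", 1:6))
  fu <- tibble::tibble(sample_id = paste0("U", 1:6))
  for (p in peps) {
    af[[p]] <- round(stats::rlnorm(6, 3, 0.5), 3)
    fu[[p]] <- round(stats::rlnorm(6, 3, 0.5), 3)
  }
  list(samples = samples, af = af, fu = fu, peptides = peps)
}

small_sim_config <- function(...) {
  args <- utils::modifyList(
    list(
      n_peptides_shared = 40, n_peptides_af_only = 10, n_peptides_fu_only = 10,
      n_af_samples = 24, n_fu_samples = 20, n_paired = 10,
      corr_subset_size = 10, n_outcome_peptides = 0, seed = 101
    ),
    list(...)
  )
  do.call(simulation_config, args)
}
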