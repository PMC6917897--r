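# Independent brute-force oracles and small fixture builders used across
# the suite. The oracles deliberately avoid the package's closed-form
# implementations: they walk every rank explicitly.

# Full running-sum walk over all N ranks; returns the signed maximum
# deviation, the rank at which it occurs, and the whole curve.
brute_running_sum <- function(weights, hit_ranks, p = 1) {
  N <- length(weights)
  hits <- sort(hit_ranks)
  k <- length(hits)
  w <- abs(weights[hits])^p
  n_r <- sum(w)
  steps <- rep(-1 / (N - k), N)
  steps[hits] <- w / n_r
  run <- cumsum(steps)
  m <- max(abs(run))
  near <- which(abs(run) >= m - 1e-12)
  i <- near[which.max(run[near])]
  es <- run[i]
  peak <- if (abs(es) < .Machine$double.eps) {
    0L
  } else i
  list(es = es, peak_rank = peak, running = run)
}

# Classic two-sample KS-style statistic between hit and miss rank
# distributions: signed maximum of F_hit - F_miss over ranks.
brute_ks_stat <- function(N, hit_ranks) {
  hits <- sort(hit_ranks)
  k <- length(hits)
  f_hit <- cumsum(as.numeric(seq_len(N) %in% hits)) / k
  f_miss <- cumsum(as.numeric(!seq_len(N) %in% hits)) / (N - k)
  d <- f_hit - f_miss
  m <- max(abs(d))
  near <- which(abs(d) >= m - 1e-12)
  d[near[which.max(d[near])]]
}

# A ranked list data frame from a vector of mean_r values (rank order as
# given).
make_ranked <- function(mean_r, gene_id = sprintf("g%03d", seq_along(mean_r))) {
  data.frame(rank = seq_along(mean_r), gene_id = gene_id, mean_r = mean_r,
             n_donors_used = 2L, stringsAsFactors = FALSE)
}

# Small but fully featured synthetic configuration for integration tests.
small_config <- function(seed = 7, ...) {
  defaults <- list(
    n_donors = 3, n_genes = 300, probes_per_gene = 2,
    n_samples_per_donor_per_compartment = 60,
    n_planted_per_sign = 20, n_planted_sets = 2,
    planted_set_size_range = c(25, 35), set_size_range = c(15, 40),
    n_gene_sets = 12, seed = seed
  )
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}

# Probe matrix with a single region-per-sample layout, used for the
# differential-stability unit tests.
region_probe_matrix <- function(donor, values_by_region) {
  n <- length(values_by_region)
  sample_ids <- sprintf("%s_S%d", donor, seq_len(n))
  vals <- matrix(values_by_region, nrow = 1,
                 dimnames = list("p1", sample_ids))
  probe_matrix("p1", "g1", donor, vals, matrix(TRUE, 1, n,
                                               dimnames = list("p1", sample_ids)))
}

region_samples <- function(donors, n_regions) {
  do.call(rbind, lapply(donors, function(d) {
    data.frame(sample_id = sprintf("%s_S%d", d, seq_len(n_regions)),
               donor_id = d, x_mm = 0, y_mm = 0, z_mm = 0,
               compartment = "cortical",
               region_label = sprintf("R%d", seq_len(n_regions)),
               stringsAsFactors = FALSE)
  }))
}
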