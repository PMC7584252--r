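# Independent brute-force oracles and small fixture builders.
# These deliberately avoid the package's own aggregation paths: plain
# loops over positions and lines, so they can cross-check the vectorized
# implementations.

# single-cytosine track as a 0-based data.frame (position -> ratio)
make_track <- function(pos0, ratio, chrom = "chrS") {
  data.frame(chrom = chrom, start = pos0, end = pos0 + 1L, score = ratio)
}

# brute-force region methylation from raw 0-based intervals:
# per-position loop, no interval libraries
oracle_region_meth <- function(track_df, regions_df) {
  inside <- vapply(seq_len(nrow(track_df)), function(i) {
    p <- track_df$start[i]
    any(p >= regions_df$start & p < regions_df$end)
  }, logical(1))
  # region length over the union, by per-bp sweep
  bp <- unique(unlist(lapply(seq_len(nrow(regions_df)), function(j)
    seq.int(regions_df$start[j], regions_df$end[j] - 1L))))
  n_c <- sum(inside)
  if (n_c == 0)
    return(list(mean_meth = NA_real_, density = NA_real_, n_c = 0L,
                length = length(bp)))
  m <- mean(track_df$score[inside])
  list(mean_meth = m, density = n_c * m / length(bp), n_c = n_c,
       length = length(bp))
}

# textbook R^2 with explicit loops
oracle_fve <- function(y, y_hat) {
  ybar <- sum(y) / length(y)
  ss_res <- 0; ss_tot <- 0
  for (i in seq_along(y)) {
    ss_res <- ss_res + (y[i] - y_hat[i])^2
    ss_tot <- ss_tot + (y[i] - ybar)^2
  }
  1 - ss_res / ss_tot
}

# per-bp mean of a piecewise-constant coverage track over one window
oracle_window_mean <- function(track_df, w_start, w_end) {
  total <- 0
  for (p in seq.int(w_start, w_end - 1L)) {
    j <- which(p >= track_df$start & p < track_df$end)
    if (length(j) == 1) total <- total + track_df$score[j]
  }
  total / (w_end - w_start)
}

# total bp of a 0-based half-open interval set (handles overlap by sweep)
oracle_bp <- function(df) {
  length(unique(unlist(lapply(seq_len(nrow(df)), function(i)
    seq.int(df$start[i], df$end[i] - 1L)))))
}

# one small simulated dataset shared by several tests
small_sim <- function(n_events = 30, seed = 42, fve_seq = 0.6,
                      fve_meth = 0, coverage = 50) {
  cfg <- sim_config(n_events = n_events, fve_seq = fve_seq,
                    fve_meth = fve_meth, coverage = coverage, seed = seed)
  ann <- generate_annotation(cfg)
  X <- generate_latent_features(cfg)
  set.seed(seed + 1)
  md <- rnorm(n_events)
  truth <- generate_psi_and_delta(X, md, cfg)
  list(cfg = cfg, ann = ann, X = X, md = md, truth = truth)
}
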