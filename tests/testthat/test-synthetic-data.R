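test_that("config validation rejects impossible settings", {
  expect_error(sim_config(n_events = 0), class = "invalid_config")
  expect_error(sim_config(n_events = -3), class = "invalid_config")
  expect_error(sim_config(fve_seq = 0.7, fve_meth = 0.5),
               class = "invalid_config")
  expect_error(sim_config(track_density = 0), class = "invalid_config")
  expect_s3_class(sim_config(n_events = 1), "sim_config")
})

test_that("annotation events are well-formed, disjoint and deterministic", {
  cfg <- sim_config(n_events = 100, seed = 7)
  ann <- generate_annotation(cfg)
  per_ev <- split(as.data.frame(ann), ann$event_id)
  expect_length(per_ev, 100)
  for (e in per_ev) {
    e <- e[order(e$start), ]
    expect_gte(nrow(e), 3)                       # >= 3 exons, >= 2 introns
    expect_equal(sum(e$is_ase), 1)
    expect_true(all(e$is_ase[c(1, nrow(e))] == FALSE))  # ASE is internal
    expect_true(all(e$end > e$start))
    expect_true(all(e$start[-1] > e$end[-nrow(e)]))     # disjoint exons
  }
  spans <- t(vapply(per_ev, function(e) c(min(e$start), max(e$end)),
                    numeric(2)))
  spans <- spans[order(spans[, 1]), ]
  expect_true(all(spans[-1, 1] >= spans[-nrow(spans), 2])) # genes disjoint

  f1 <- tempfile(fileext = ".bed"); f2 <- tempfile(fileext = ".bed")
  write_annotation_bed(generate_annotation(cfg), f1)
  write_annotation_bed(generate_annotation(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical rerun
})

test_that("every region category is derivable, non-empty and consistent", {
  ann <- generate_annotation(sim_config(n_events = 50, seed = 1))
  rs <- build_region_sets(ann)
  for (id in unique(ann$event_id)) {
    e <- as.data.frame(rs[rs$event_id == id])
    for (cat in c("ase", "exons_with_ase", "exons_without_ase", "introns",
                  "introns_without_ase"))
      expect_gt(nrow(e[e$category == cat, ]), 0)
    ase <- e[e$category == "ase", ]
    noase <- e[e$category == "exons_without_ase", ]
    # ASE excluded from "exons without ASE" (interval-arithmetic oracle)
    ase_bp <- seq.int(ase$start, ase$end - 1L)
    noase_bp <- unlist(lapply(seq_len(nrow(noase)), function(i)
      seq.int(noase$start[i], noase$end[i] - 1L)))
    expect_length(intersect(ase_bp, noase_bp), 0)
    # ase subset of exons_with_ase; bp additivity
    withase <- e[e$category == "exons_with_ase", ]
    expect_equal(oracle_bp(withase), oracle_bp(noase) + oracle_bp(ase))
    # categories internally disjoint
    for (cat in unique(e$category)) {
      g <- e[e$category == cat, ]
      g <- g[order(g$start), ]
      if (nrow(g) > 1) expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
    }
  }
})

test_that("latent features are standard normal columns, reproducibly", {
  cfg <- sim_config(n_events = 1000, n_features = 10, seed = 3)
  X <- generate_latent_features(cfg)
  expect_equal(dim(X), c(1000, 10))
  expect_identical(colnames(X), paste0("seq_", 1:10))
  expect_false(anyNA(X))
  expect_true(all(abs(colMeans(X)) < 0.15))
  expect_true(all(apply(X, 2, sd) > 0.9 & apply(X, 2, sd) < 1.1))
  expect_identical(X, generate_latent_features(cfg))
  X1 <- generate_latent_features(sim_config(n_events = 5, n_features = 1))
  expect_equal(ncol(X1), 1)
})

test_that("splicing variation decomposes into the requested fractions", {
  # pure noise: delta_y uncorrelated with every feature
  cfg0 <- sim_config(n_events = 1000, fve_seq = 0, fve_meth = 0, seed = 5)
  X0 <- generate_latent_features(cfg0)
  tr0 <- generate_psi_and_delta(X0, rnorm(1000), cfg0)
  expect_true(all(abs(cor(tr0$delta_y, X0)) < 0.1))

  # pure methylation: delta_y is meth_delta up to scale
  cfg1 <- sim_config(n_events = 1000, fve_seq = 0, fve_meth = 1, seed = 5)
  set.seed(8); md <- rnorm(1000)
  tr1 <- generate_psi_and_delta(generate_latent_features(cfg1), md, cfg1)
  expect_gt(abs(cor(tr1$delta_y, md)), 0.99)

  # mixed: realized sequence share of var(delta_y) near 0.3
  cfg2 <- sim_config(n_events = 2000, fve_seq = 0.3, fve_meth = 0.2,
                     seed = 5)
  set.seed(9); md2 <- rnorm(2000)
  tr2 <- generate_psi_and_delta(generate_latent_features(cfg2), md2, cfg2)
  share <- var(tr2$comp_seq) / var(tr2$delta_y)
  expect_gt(share, 0.25); expect_lt(share, 0.35)

  # structural invariants
  expect_equal(tr2$psi_ctrl, pnorm(tr2$y_ctrl), tolerance = 1e-12)
  expect_equal(tr2$psi_treat, pnorm(tr2$y_treat), tolerance = 1e-12)
  expect_identical(tr2$delta_y,
                   tr2$comp_seq + tr2$comp_meth + tr2$comp_noise)
  expect_true(all(tr2$psi_ctrl > 0 & tr2$psi_ctrl < 1))
  expect_true(all(tr2$psi_treat > 0 & tr2$psi_treat < 1))

  # errors
  X <- generate_latent_features(cfg0)
  bad <- cfg0; bad$fve_seq <- 0.8; bad$fve_meth <- 0.4
  expect_error(generate_psi_and_delta(X, rnorm(1000), bad),
               class = "invalid_config")
  cfg_m <- sim_config(n_events = 1000, fve_seq = 0, fve_meth = 0.5)
  expect_error(generate_psi_and_delta(X, rep(0, 1000), cfg_m),
               class = "degenerate_input")
})

test_that("realized variance fractions are calibrated over replicates", {
  fracs <- t(vapply(1:20, function(s) {
    cfg <- sim_config(n_events = 2000, fve_seq = 0.3, fve_meth = 0.2,
                      seed = 100 + s)
    set.seed(200 + s); md <- rnorm(2000)
    tr <- generate_psi_and_delta(generate_latent_features(cfg), md, cfg)
    c(var(tr$comp_seq), var(tr$comp_meth)) / var(tr$delta_y)
  }, numeric(2)))
  expect_lt(abs(mean(fracs[, 1]) - 0.3), 0.03)
  expect_lt(abs(mean(fracs[, 2]) - 0.2), 0.03)
})

test_that("methylation tracks realize the planted probit deltas", {
  cfg <- sim_config(n_events = 20, seed = 13)
  ann <- generate_annotation(cfg)
  rs <- build_region_sets(ann)
  ids <- unique(ann$event_id)

  # null case: no planted difference anywhere
  tr0 <- generate_methylation_tracks(ann, rep(0, 20), cfg)
  for (id in ids[1:5]) {
    one <- region_set(rs, id)
    m_c <- region_methylation(tr0$tracks$control$CG, one$ase)$mean_meth
    m_t <- region_methylation(tr0$tracks$treatment$CG, one$ase)$mean_meth
    expect_lt(abs(qnorm(m_t) - qnorm(m_c)), 0.05)
  }

  # planted delta of 1.0 from a 0.5 control mean lands near pnorm(1)
  cfg1 <- sim_config(n_events = 1, seed = 17)
  ann1 <- generate_annotation(cfg1)
  tr1 <- generate_methylation_tracks(ann1, 1.0, cfg1, ctrl_ase_mean = 0.5)
  rs1 <- build_region_sets(ann1)
  one <- region_set(rs1, unique(ann1$event_id))
  m_t <- region_methylation(tr1$tracks$treatment$CG, one$ase)$mean_meth
  expect_lt(abs(m_t - pnorm(1)), 0.03)

  # bedGraph round trip preserves the aggregate to 1e-9
  f <- tempfile(fileext = ".bedGraph")
  write_bedgraph(tr0$tracks$control$CA, f)
  reloaded <- read_bedgraph(f)
  one <- region_set(rs, ids[1])
  before <- region_methylation(tr0$tracks$control$CA, one$ase)
  after <- region_methylation(reloaded, one$ase)
  expect_equal(after$mean_meth, before$mean_meth, tolerance = 1e-9)
  expect_identical(after$n_c, before$n_c)

  # unreachable target: warns and records the clipped value
  expect_warning(
    tr_big <- generate_methylation_tracks(ann1, 8, cfg1,
                                          ctrl_ase_mean = 0.5),
    "unreachable")
  expect_true(all(tr_big$realized$clipped))
  expect_lt(max(tr_big$realized$realized_delta), 8)
})

test_that("read simulation matches binomial sampling at the true psi", {
  cfg_hi <- sim_config(n_events = 1, coverage = 10000, seed = 3)
  r <- simulate_reads(0.75, cfg_hi)
  expect_gt(r$n_inc / r$total, 0.74)
  expect_lt(r$n_inc / r$total, 0.76)

  cfg0 <- sim_config(n_events = 5, coverage = 0, seed = 3)
  r0 <- simulate_reads(rep(0.5, 5), cfg0)
  expect_true(all(r0$n_inc == 0 & r0$n_exc == 0))

  cfg <- sim_config(n_events = 50, coverage = 30, seed = 3)
  r1 <- simulate_reads(rep(1, 50), cfg)
  expect_true(all(r1$n_exc == 0))
  expect_identical(simulate_reads(rep(0.4, 50), cfg),
                   simulate_reads(rep(0.4, 50), cfg))
  expect_error(simulate_reads(c(0.5, 1.2), cfg), class = "invalid_input")
})
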