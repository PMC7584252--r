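three_exon_gene <- function(strand = "+") {
  data.frame(event_id = "g1", chrom = "chrS", strand = strand,
             exon_index = 1:3,
             start = c(100L, 500L, 900L), end = c(200L, 600L, 1000L),
             is_ase = c(FALSE, TRUE, FALSE))
}

test_that("region categories follow their definitions", {
  rs <- build_region_sets(three_exon_gene())
  e <- as.data.frame(rs)
  expect_equal(nrow(e[e$category == "exons_without_ase", ]), 2)
  # ASE is not an intron, so removing it leaves the introns unchanged
  expect_equal(e[e$category == "introns_without_ase", c("start", "end")],
               e[e$category == "introns", c("start", "end")],
               ignore_attr = TRUE)
  expect_equal(e[e$category == "introns", "start"], c(200L, 600L))
  expect_equal(e[e$category == "introns", "end"], c(500L, 900L))

  # single-exon "gene" cannot host a skipping event
  one <- three_exon_gene()[2, ]
  expect_error(build_region_sets(one), class = "malformed_annotation")

  # 5-exon gene: bp additivity of the exon categories
  five <- data.frame(event_id = "g5", chrom = "chrS", strand = "-",
                     exon_index = 1:5,
                     start = c(0L, 300L, 700L, 1200L, 1800L),
                     end = c(100L, 400L, 800L, 1300L, 1900L),
                     is_ase = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  rs5 <- as.data.frame(build_region_sets(five))
  bp <- function(cat) oracle_bp(rs5[rs5$category == cat, ])
  expect_equal(bp("exons_with_ase"), bp("exons_without_ase") + bp("ase"))
})

test_that("region methylation matches hand-computed values", {
  trk <- make_track(c(10L, 20L, 30L, 40L), c(1.0, 0.5, 0.0, 0.5))
  reg <- data.frame(chrom = "chrS", start = 5L, end = 45L)
  rm <- region_methylation(trk, reg)
  expect_identical(rm$n_c, 4L)
  expect_equal(rm$mean_meth, 0.5)
  expect_equal(rm$length, 40)
  expect_equal(rm$density, 4 * 0.5 / 40)

  # no cytosines: missing metrics, distinct from empty interval list
  empty <- region_methylation(trk, data.frame(chrom = "chrS", start = 100L,
                                              end = 200L))
  expect_identical(empty$n_c, 0L)
  expect_true(is.na(empty$mean_meth) && is.na(empty$density))
  expect_error(region_methylation(trk, trk[0, 1:3]),
               class = "invalid_input")

  # additivity under region splitting
  split_reg <- data.frame(chrom = "chrS", start = c(5L, 25L),
                          end = c(25L, 45L))
  expect_equal(region_methylation(trk, split_reg), rm)
})

test_that("feature vectors agree with a brute-force per-line oracle", {
  sim <- small_sim(n_events = 10, seed = 19)
  tr <- suppressWarnings(
    generate_methylation_tracks(sim$ann, sim$md, sim$cfg))
  rs <- build_region_sets(sim$ann)
  feats <- methylation_features(tr$tracks$control, rs)
  rs_df <- as.data.frame(rs)

  # independent re-reader: serialize the track, scan it line by line
  f <- tempfile(fileext = ".bedGraph")
  write_bedgraph(tr$tracks$control$CG, f)
  lines <- read.table(f, col.names = c("chrom", "start", "end", "score"))
  for (id in unique(sim$ann$event_id)[1:5]) {
    for (cat in c("ase", "introns", "exons_without_ase")) {
      reg <- rs_df[rs_df$event_id == id & rs_df$category == cat, ]
      oracle <- oracle_region_meth(lines, reg)
      got_mean <- feats[[paste0("meth_mean_CG_", cat)]][feats$event_id == id]
      got_dens <- feats[[paste0("meth_dens_CG_", cat)]][feats$event_id == id]
      if (oracle$n_c == 0) {
        expect_true(is.na(got_mean))
      } else {
        expect_equal(got_mean, oracle$mean_meth, tolerance = 1e-9)
        expect_equal(got_dens, oracle$density, tolerance = 1e-9)
      }
    }
  }

  # the one-event path agrees with the bulk path
  id1 <- unique(sim$ann$event_id)[1]
  i <- match(id1, feats$event_id)
  v <- methylation_feature_vector(tr$tracks$control, region_set(rs, id1))
  expect_length(v, 20)
  expect_equal(unname(v["meth_mean_CG_ase"]),
               feats$meth_mean_CG_ase[i], tolerance = 1e-12)
  expect_equal(unname(v["meth_dens_CA_introns"]),
               feats$meth_dens_CA_introns[i], tolerance = 1e-12)
})

test_that("feature vector handles empty and uniform tracks", {
  rs <- build_region_sets(three_exon_gene())
  one <- region_set(rs, "g1")
  empty <- GenomicRanges::GRanges()
  v <- methylation_feature_vector(list(CG = empty, CA = empty), one)
  expect_length(v, 20)
  expect_true(all(is.na(v)))

  pos <- seq(105L, 995L, by = 10L)
  uni <- make_track(pos, rep(0.8, length(pos)))
  v2 <- methylation_feature_vector(list(CG = uni, CA = uni), one)
  expect_equal(unname(v2[grepl("meth_mean_", names(v2))]), rep(0.8, 10))
})

test_that("delta features difference means on the probit scale", {
  treat <- c(meth_mean_CG_ase = 0.841344746, meth_dens_CG_ase = 0.08)
  ctrl <- c(meth_mean_CG_ase = 0.5, meth_dens_CG_ase = 0.05)
  d <- delta_methylation_features(treat, ctrl)
  expect_equal(unname(d["delta_meth_mean_CG_ase"]), 1.0, tolerance = 1e-6)
  expect_equal(unname(d["delta_meth_dens_CG_ase"]), 0.03)

  # identity gives an exact zero vector
  expect_equal(unname(delta_methylation_features(ctrl, ctrl)), c(0, 0))

  # boundary ratio is clipped before the probit
  top <- c(meth_mean_CG_ase = 1.0)
  base <- c(meth_mean_CG_ase = 0.5)
  d2 <- delta_methylation_features(top, base, eps = 1e-6)
  expect_equal(unname(d2), qnorm(1 - 1e-6), tolerance = 1e-4)
  expect_true(is.finite(d2))

  # missing propagates; mismatched columns rejected
  t_na <- c(meth_mean_CG_ase = NA_real_)
  expect_true(is.na(delta_methylation_features(t_na, base)))
  expect_error(
    delta_methylation_features(c(meth_mean_CG_ase = 0.5),
                               c(meth_mean_CA_ase = 0.5)),
    class = "invalid_input")
})

test_that("chip log2 ratios match direct arithmetic", {
  win <- data.frame(chrom = "chrS", start = 0L, end = 100L)
  chip <- data.frame(chrom = "chrS", start = 0L, end = 100L, score = 4.0)
  input <- data.frame(chrom = "chrS", start = 0L, end = 100L, score = 1.0)
  expect_equal(unname(chip_log2_ratio(chip, input, win)), 2.0,
               tolerance = 1e-3)
  expect_equal(unname(chip_log2_ratio(chip, chip, win)), 0.0)
  none <- data.frame(chrom = "chrS", start = 0L, end = 100L, score = 0.0)
  expect_equal(unname(chip_log2_ratio(none, none, win)), 0.0)
  expect_error(chip_log2_ratio(chip, input,
                               data.frame(chrom = "chrS", start = 5L,
                                          end = 5L)),
               class = "invalid_input")

  # partial coverage: per-bp average against a positional oracle
  chip2 <- data.frame(chrom = "chrS", start = c(0L, 50L), end = c(20L, 60L),
                      score = c(2, 10))
  m <- oracle_window_mean(chip2, 0L, 100L)
  expect_equal(unname(chip_log2_ratio(chip2, input, win,
                                      pseudocount = 1e-3)),
               log2((m + 1e-3) / (1 + 1e-3)), tolerance = 1e-9)
})

test_that("default chip windows flank the ASE inside its introns", {
  rs <- build_region_sets(three_exon_gene("+"))
  w <- chip_default_windows(region_set(rs, "g1"), flank = 300L)
  expect_identical(names(w), c("ase", "flank_up", "flank_down"))
  expect_equal(GenomicRanges::start(w["flank_up"]) - 1L, 200L)
  expect_equal(GenomicRanges::end(w["flank_up"]), 500L)
  # minus strand swaps the flank labels
  rs_m <- build_region_sets(three_exon_gene("-"))
  w_m <- chip_default_windows(region_set(rs_m, "g1"), flank = 300L)
  expect_equal(GenomicRanges::start(w_m["flank_down"]),
               GenomicRanges::start(w["flank_up"]))

  # bulk table agrees with the single-event path
  chip <- data.frame(chrom = "chrS", start = 0L, end = 1000L, score = 3)
  input <- data.frame(chrom = "chrS", start = 0L, end = 1000L, score = 1)
  tab <- chip_features(chip, input, rs)
  r <- chip_log2_ratio(chip, input, w)
  expect_equal(tab$chip_ase, unname(r["ase"]), tolerance = 1e-12)
  expect_equal(tab$chip_flank_up, unname(r["flank_up"]), tolerance = 1e-12)
})

test_that("features are invariant to translating event and tracks", {
  ev <- three_exon_gene()
  off <- 10000L
  ev_shift <- transform(ev, start = start + off, end = end + off)
  pos <- c(120L, 150L, 520L, 550L, 940L, 300L, 700L)
  val <- c(0.9, 0.1, 0.5, 0.7, 0.2, 0.4, 0.6)
  tr <- list(CG = make_track(pos, val), CA = make_track(pos + 3L, val))
  tr_shift <- list(CG = make_track(pos + off, val),
                   CA = make_track(pos + 3L + off, val))
  v1 <- methylation_feature_vector(tr, region_set(build_region_sets(ev), "g1"))
  v2 <- methylation_feature_vector(tr_shift,
                                   region_set(build_region_sets(ev_shift),
                                              "g1"))
  expect_equal(v1, v2)
})

test_that("density scales as 1/L while mean methylation does not", {
  trk <- make_track(c(10L, 20L), c(0.6, 0.2))
  short_reg <- data.frame(chrom = "chrS", start = 0L, end = 50L)
  long_reg <- data.frame(chrom = "chrS", start = 0L, end = 100L)
  a <- region_methylation(trk, short_reg)
  b <- region_methylation(trk, long_reg)
  expect_equal(a$mean_meth, b$mean_meth)
  expect_equal(a$density, 2 * b$density)
})
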