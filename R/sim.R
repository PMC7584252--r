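#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator. The generator
#' produces cassette-exon (ASE) events with known ground truth: latent
#' sequence-like features, a planted per-event methylation change, true
#' splicing ratios in two conditions, and an exact decomposition of the
#' variance of the splicing variation `delta_y = qnorm(psi_t) - qnorm(psi_c)`
#' into sequence, methylation and noise fractions.
#'
#' @param n_events number of skipping events (>= 1).
#' @param n_features number of latent sequence-like features (>= 1).
#' @param fve_seq fraction in \[0,1\] of `delta_y` variance (and of baseline
#'   `y` variance) attributable to sequence features.
#' @param fve_meth fraction in \[0,1\] of `delta_y` variance attributable to
#'   the methylation change. `fve_seq + fve_meth <= 1`; the remainder is
#'   noise.
#' @param coverage mean junction reads per event (Poisson mean, >= 0).
#' @param seed integer random seed; identical configs give bit-identical
#'   output.
#' @param n_conditions number of conditions; fixed at 2 (control, treatment).
#' @param track_density cytosines per 100 bp when laying methylation tracks.
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_events = 50, seed = 1)
sim_config <- function(n_events = 500L, n_features = 20L,
                       fve_seq = 0.6, fve_meth = 0,
                       coverage = 50, seed = 1L,
                       n_conditions = 2L, track_density = 5) {
  sf_assert(length(n_events) == 1 && is.finite(n_events) && n_events >= 1 &&
              n_events == floor(n_events),
            "invalid_config", "n_events must be a positive integer")
  sf_assert(length(n_features) == 1 && is.finite(n_features) &&
              n_features >= 1 && n_features == floor(n_features),
            "invalid_config", "n_features must be a positive integer")
  sf_assert(is.finite(fve_seq) && fve_seq >= 0 && fve_seq <= 1,
            "invalid_config", "fve_seq must be in [0, 1]")
  sf_assert(is.finite(fve_meth) && fve_meth >= 0 && fve_meth <= 1,
            "invalid_config", "fve_meth must be in [0, 1]")
  sf_assert(fve_seq + fve_meth <= 1 + 1e-12, "invalid_config",
            "fve_seq + fve_meth must not exceed 1 (remainder is noise)")
  sf_assert(is.finite(coverage) && coverage >= 0,
            "invalid_config", "coverage must be a nonnegative number")
  sf_assert(length(seed) == 1 && is.finite(seed) && seed == floor(seed),
            "invalid_config", "seed must be an integer")
  sf_assert(identical(as.integer(n_conditions), 2L),
            "invalid_config", "only two conditions (control, treatment) are supported")
  sf_assert(is.finite(track_density) && track_density > 0,
            "invalid_config", "track_density must be positive")
  structure(list(
    n_events = as.integer(n_events), n_features = as.integer(n_features),
    fve_seq = fve_seq, fve_meth = fve_meth, coverage = coverage,
    seed = as.integer(seed), n_conditions = 2L, track_density = track_density
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_events, "events,", x$n_features, "features;",
      sprintf("fve_seq=%.2f fve_meth=%.2f coverage=%g seed=%d\n",
              x$fve_seq, x$fve_meth, x$coverage, x$seed))
  invisible(x)
}

# Geometry defaults of the synthetic chromosome: arbitrary but fixed.
.sim_geom <- list(
  chrom = "chrS",
  exon_len = c(60L, 300L),      # uniform bounds, bp
  intron_len = c(200L, 2000L),  # uniform bounds, bp
  gene_gap = c(1000L, 5000L),   # spacing between events, bp
  n_exons = c(3L, 7L)           # exons per gene, uniform
)

#' Generate a synthetic cassette-exon annotation
#'
#' Lays `n_events` non-overlapping multi-exon genes on one synthetic
#' chromosome ("chrS"), each with at least three exons and one internal
#' alternatively spliced exon (ASE). Coordinates are 0-based half-open
#' (BED convention).
#'
#' @param config a [sim_config()].
#' @return a `data.table` of class `ase_annotation` with one row per exon:
#'   columns `event_id`, `chrom`, `strand`, `exon_index`, `start`, `end`
#'   (0-based half-open), `is_ase`.
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "annotation"))
  g <- .sim_geom
  n <- config$n_events
  rows <- vector("list", n)
  cursor <- 0L
  for (i in seq_len(n)) {
    n_ex <- sample(seq(g$n_exons[1], g$n_exons[2]), 1L)
    exon_w <- sample(seq(g$exon_len[1], g$exon_len[2]), n_ex, replace = TRUE)
    intron_w <- sample(seq(g$intron_len[1], g$intron_len[2]), n_ex - 1L,
                       replace = TRUE)
    ase_idx <- if (n_ex == 3L) 2L else sample(2:(n_ex - 1L), 1L)
    cursor <- cursor + sample(seq(g$gene_gap[1], g$gene_gap[2]), 1L)
    starts <- integer(n_ex)
    pos <- cursor
    for (e in seq_len(n_ex)) {
      starts[e] <- pos
      pos <- pos + exon_w[e] + if (e < n_ex) intron_w[e] else 0L
    }
    cursor <- starts[n_ex] + exon_w[n_ex]
    rows[[i]] <- data.table::data.table(
      event_id = sprintf("ev_%05d", i), chrom = g$chrom,
      strand = sample(c("+", "-"), 1L),
      exon_index = seq_len(n_ex), start = starts,
      end = starts + exon_w, is_ase = seq_len(n_ex) == ase_idx
    )
  }
  ann <- data.table::rbindlist(rows)
  data.table::setattr(ann, "class", c("ase_annotation", class(ann)))
  ann
}

#' Generate latent sequence-like features
#'
#' Stand-in for a splicing-code feature matrix: independent standard-normal
#' columns named `seq_1 ... seq_j`, one row per event.
#'
#' @param config a [sim_config()].
#' @return numeric matrix `n_events x n_features` with event-id rownames.
#' @export
generate_latent_features <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "features"))
  X <- matrix(rnorm(config$n_events * config$n_features),
              nrow = config$n_events)
  dimnames(X) <- list(sprintf("ev_%05d", seq_len(config$n_events)),
                      paste0("seq_", seq_len(config$n_features)))
  X
}

#' Generate true splicing ratios with a known variance decomposition
#'
#' Constructs the splicing variation on the probit scale as
#' `delta_y = sqrt(fve_seq) * z_X + sqrt(fve_meth) * z_m + sqrt(1 - fve_seq -
#' fve_meth) * z_eps`, where `z_X` is a standardized random linear
#' combination of the feature columns, `z_m` is standardized `meth_delta`,
#' and `z_eps` is standardized independent noise, so the realized variance
#' fractions match the requested ones up to Monte-Carlo error. The control
#' baseline is `y_c = sqrt(fve_seq) * z_Xc + sqrt(1 - fve_seq) * z` (its own
#' random feature combination plus noise, SD 1), treatment is
#' `y_t = y_c + delta_y`, and `psi = pnorm(y)` per condition. `y` is clipped
#' to `[-6, 6]` so psi is never exactly 0 or 1.
#'
#' @param features matrix from [generate_latent_features()].
#' @param meth_delta per-event methylation change on the probit scale
#'   (length `n_events`). Ignored (may be all zero) when `fve_meth = 0`.
#' @param config a [sim_config()].
#' @return a `data.table` of class `sim_truth`: `event_id`, `psi_ctrl`,
#'   `psi_treat`, `y_ctrl`, `y_treat`, `y_ctrl_seq` (the sequence-predicted
#'   part of the baseline, usable as an informative prior), `delta_y`, and
#'   the three realized components `comp_seq`, `comp_meth`, `comp_noise`
#'   summing exactly to `delta_y`.
#' @export
generate_psi_and_delta <- function(features, meth_delta, config) {
  stopifnot(inherits(config, "sim_config"), is.matrix(features))
  n <- nrow(features)
  sf_assert(length(meth_delta) == n, "invalid_input",
            "meth_delta must have one entry per event (%d)", n)
  sf_assert(config$fve_seq + config$fve_meth <= 1 + 1e-12, "invalid_config",
            "fve_seq + fve_meth must not exceed 1")
  if (config$fve_meth > 0 && stats::sd(meth_delta) == 0)
    sf_stop("degenerate_input",
            "meth_delta has zero variance but fve_meth > 0")
  set.seed(derive_seed(config$seed, "psi_delta"))
  fs <- config$fve_seq; fm <- config$fve_meth; fn <- max(0, 1 - fs - fm)

  unit_vec <- function(p) { w <- rnorm(p); w / sqrt(sum(w^2)) }
  w_delta <- unit_vec(ncol(features))
  w_base <- unit_vec(ncol(features))

  z_X <- if (fs > 0) standardize(drop(features %*% w_delta), "feature signal")
         else rep(0, n)
  z_m <- if (fm > 0) standardize(meth_delta, "meth_delta") else rep(0, n)
  z_e <- if (fn > 0) standardize(rnorm(n), "noise") else rep(0, n)

  comp_seq <- sqrt(fs) * z_X
  comp_meth <- sqrt(fm) * z_m
  comp_noise <- sqrt(fn) * z_e
  delta_y <- comp_seq + comp_meth + comp_noise

  z_Xc <- if (fs > 0) standardize(drop(features %*% w_base), "baseline signal")
          else rep(0, n)
  y_c <- sqrt(fs) * z_Xc + sqrt(max(0, 1 - fs)) * standardize(rnorm(n))
  y_c <- pmin(pmax(y_c, -6), 6)
  y_t <- pmin(pmax(y_c + delta_y, -6), 6)
  # keep the three-way additivity bit-exact after clipping: fold any
  # clipping loss into the noise component and rebuild delta_y as the sum
  comp_noise <- (y_t - y_c) - comp_seq - comp_meth
  delta_y <- comp_seq + comp_meth + comp_noise
  y_t <- y_c + delta_y

  truth <- data.table::data.table(
    event_id = rownames(features) %||% sprintf("ev_%05d", seq_len(n)),
    psi_ctrl = pnorm(y_c), psi_treat = pnorm(y_t),
    y_ctrl = y_c, y_treat = y_t, y_ctrl_seq = sqrt(fs) * z_Xc,
    delta_y = delta_y,
    comp_seq = comp_seq, comp_meth = comp_meth, comp_noise = comp_noise
  )
  data.table::setattr(truth, "class", c("sim_truth", class(truth)))
  truth
}

#' Generate per-cytosine methylation tracks realizing planted deltas
#'
#' Places cytosines at `track_density` per 100 bp within every exon and
#' intron of each event and assigns per-cytosine methylation ratios so that
#' the treatment-minus-control difference in ASE-region mean methylation,
#' on the probit scale, equals the event's `meth_delta` entry (up to
#' clipping of extreme targets, which is recorded and warned about). Both
#' CG and CA context tracks are produced for both conditions; outside the
#' ASE the two conditions share a per-event background mean, so differential
#' signal is confined to the ASE.
#'
#' @param events an `ase_annotation` from [generate_annotation()].
#' @param meth_delta per-event probit-scale target for the ASE mean
#'   methylation change.
#' @param config a [sim_config()].
#' @param ctrl_ase_mean optional per-event control ASE mean methylation in
#'   (0,1); default drawn uniformly in (0.35, 0.65).
#' @param ratio_clip per-cytosine ratios and region-mean targets are kept in
#'   `[ratio_clip, 1 - ratio_clip]`.
#' @return list with `tracks` (nested list `tracks[[condition]][[context]]`,
#'   each a `GRanges` with per-cytosine `score` in \[0,1\]) and `realized`
#'   (a `data.table` with `event_id`, `ctrl_ase_mean`, `treat_ase_mean`,
#'   `requested_delta`, `realized_delta`, `clipped` per context).
#' @export
generate_methylation_tracks <- function(events, meth_delta, config,
                                        ctrl_ase_mean = NULL,
                                        ratio_clip = 1e-3) {
  stopifnot(inherits(events, "ase_annotation"), inherits(config, "sim_config"))
  ids <- unique(events$event_id)
  sf_assert(length(ids) >= 1, "invalid_input", "events must be non-empty")
  sf_assert(length(meth_delta) == length(ids), "invalid_input",
            "meth_delta must have one entry per event (%d)", length(ids))
  set.seed(derive_seed(config$seed, "meth_tracks"))

  if (is.null(ctrl_ase_mean)) {
    ctrl_ase_mean <- runif(length(ids), 0.35, 0.65)
  } else {
    sf_assert(length(ctrl_ase_mean) == length(ids) &&
                all(ctrl_ase_mean > 0 & ctrl_ase_mean < 1),
              "invalid_input", "ctrl_ase_mean must be per-event in (0,1)")
  }

  # Ratios with exact mean: jitter, recentre, clip; constant near boundary.
  ratios_with_mean <- function(k, target, jitter_sd = 0.04) {
    if (k == 1L || target < 0.08 || target > 0.92) return(rep(target, k))
    r <- target + rnorm(k, sd = jitter_sd)
    for (it in 1:4) r <- pmin(pmax(r - mean(r) + target, 0), 1)
    r
  }

  intervals <- split(events, by = "event_id", keep.by = TRUE)
  conditions <- c("control", "treatment")
  contexts <- c("CG", "CA")
  out <- lapply(conditions, function(cd) lapply(contexts, function(cx) NULL))
  names(out) <- conditions
  realized <- vector("list", 2L * length(ids))
  acc <- list(control = list(CG = list(), CA = list()),
              treatment = list(CG = list(), CA = list()))

  for (i in seq_along(ids)) {
    ev <- intervals[[ids[i]]]
    # intervals of this gene: all exons plus the introns between them
    ex <- ev[order(ev$start)]
    segs <- data.table::data.table(start = ex$start, end = ex$end)
    if (nrow(ex) > 1)
      segs <- rbind(segs, data.table::data.table(
        start = ex$end[-nrow(ex)], end = ex$start[-1]))
    ase <- ex[ex$is_ase == TRUE]
    m_c <- ctrl_ase_mean[i]
    probit_t <- qnorm(m_c) + meth_delta[i]
    lim <- qnorm(1 - ratio_clip)
    clipped <- abs(probit_t) > lim
    probit_t_eff <- pmin(pmax(probit_t, -lim), lim)
    m_t <- pnorm(probit_t_eff)
    background <- runif(1, 0.2, 0.8)

    for (cx in contexts) {
      # lay positions once per context; both conditions share them
      pos <- unlist(lapply(seq_len(nrow(segs)), function(s) {
        len <- segs$end[s] - segs$start[s]
        k <- max(1L, round(len * config$track_density / 100))
        sort(sample(seq.int(segs$start[s], segs$end[s] - 1L), min(k, len)))
      }))
      pos <- sort(unique(pos))
      in_ase <- pos >= ase$start & pos < ase$end
      if (!any(in_ase)) {         # force at least one ASE cytosine
        extra <- ase$start + (ase$end - ase$start) %/% 2L
        pos <- sort(unique(c(pos, extra)))
        in_ase <- pos >= ase$start & pos < ase$end
      }
      n_ase <- sum(in_ase); n_bg <- sum(!in_ase)
      for (cd in conditions) {
        target <- if (cd == "control") m_c else m_t
        r <- numeric(length(pos))
        r[in_ase] <- ratios_with_mean(n_ase, target)
        if (n_bg > 0)
          r[!in_ase] <- pmin(pmax(background + rnorm(n_bg, sd = 0.1), 0), 1)
        acc[[cd]][[cx]][[ids[i]]] <- data.table::data.table(
          chrom = ase$chrom[1], start = pos, end = pos + 1L, score = r)
      }
      realized[[length(contexts) * (i - 1L) + match(cx, contexts)]] <-
        data.table::data.table(
          event_id = ids[i], context = cx,
          ctrl_ase_mean = m_c, treat_ase_mean = m_t,
          requested_delta = meth_delta[i],
          realized_delta = probit_t_eff - qnorm(m_c),
          clipped = clipped)
    }
  }

  realized <- data.table::rbindlist(realized)
  n_clip <- sum(realized$clipped) / length(contexts)
  if (n_clip > 0)
    warning(sprintf(
      "%d event(s) had unreachable meth_delta targets; clipped values recorded",
      as.integer(n_clip)), call. = FALSE)

  tracks <- lapply(acc, function(by_cd) lapply(by_cd, function(by_cx) {
    dt <- data.table::rbindlist(by_cx)
    data.table::setorder(dt, chrom, start)
    GenomicRanges::GRanges(dt$chrom,
                           IRanges::IRanges(dt$start + 1L, dt$end),
                           score = dt$score)
  }))
  list(tracks = tracks, realized = realized)
}

#' Simulate inclusion/exclusion junction reads
#'
#' Per event, a Poisson total read count around the mean coverage, and
#' binomial inclusion reads at the true splicing ratio. Reads are
#' junction-informative only, so `n_inc / total` is an unbiased estimator
#' of psi.
#'
#' @param true_psi vector of true splicing ratios in \[0,1\].
#' @param config a [sim_config()] (uses `coverage` and `seed`).
#' @param stage label mixed into the derived seed so that independent
#'   conditions get independent reads.
#' @return `data.table` with `event_id`, `n_inc`, `n_exc`, `total`.
#' @export
simulate_reads <- function(true_psi, config, stage = "reads") {
  stopifnot(inherits(config, "sim_config"))
  sf_assert(all(is.finite(true_psi) & true_psi >= 0 & true_psi <= 1),
            "invalid_input", "true_psi entries must lie in [0,1]")
  set.seed(derive_seed(config$seed, stage))
  n <- length(true_psi)
  total <- rpois(n, config$coverage)
  n_inc <- rbinom(n, total, true_psi)
  data.table::data.table(
    event_id = names(true_psi) %||% sprintf("ev_%05d", seq_len(n)),
    n_inc = n_inc, n_exc = total - n_inc, total = total)
}
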