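#' Build the five exon-centred region categories for each event
#'
#' For every cassette-exon event the following region categories are
#' derived from its gene's exon/intron structure:
#' `ase` (the alternatively spliced exon), `exons_with_ase` (union of all
#' exons, ASE included), `exons_without_ase` (union of all exons minus the
#' ASE), `introns` (union of all introns), and `introns_without_ase`
#' (union of all introns minus any ASE overlap; identical to `introns`
#' when, as in a standard annotation, the ASE is exonic).
#'
#' The result is a long interval table (one row per interval, 0-based
#' half-open), which also serves as the on-disk manifest format; use
#' [region_set()] to materialize one event's categories as `GRanges`.
#'
#' @param events an `ase_annotation` (see [generate_annotation()]), or any
#'   data.frame with columns `event_id`, `chrom`, `strand`, `start`, `end`
#'   (0-based half-open exon intervals) and logical `is_ase`.
#' @return a `data.table` of class `region_sets` with columns `event_id`,
#'   `category`, `chrom`, `start`, `end`, `strand`.
#' @export
build_region_sets <- function(events) {
  ev <- data.table::as.data.table(events)
  need <- c("event_id", "chrom", "strand", "start", "end", "is_ase")
  sf_assert(all(need %in% names(ev)), "invalid_input",
            "annotation must have columns %s", paste(need, collapse = ", "))
  rows <- lapply(split(ev, by = "event_id", keep.by = TRUE), function(e) {
    e <- e[order(e$start)]
    sf_assert(nrow(e) >= 2, "malformed_annotation",
              "event %s has fewer than two exons; no skipping event possible",
              e$event_id[1])
    sf_assert(sum(e$is_ase) == 1, "malformed_annotation",
              "event %s must have exactly one ASE", e$event_id[1])
    ase <- c(e$start[e$is_ase], e$end[e$is_ase])
    span <- c(min(e$start), max(e$end))
    sf_assert(ase[1] >= span[1] && ase[2] <= span[2], "malformed_annotation",
              "event %s: ASE not contained in gene span", e$event_id[1])
    exons <- merge_intervals(e$start, e$end)
    introns <- interval_gaps(exons, span)
    cat_list <- list(
      ase = matrix(ase, ncol = 2),
      exons_with_ase = exons,
      exons_without_ase = subtract_interval(exons, ase),
      introns = introns,
      introns_without_ase = subtract_interval(introns, ase))
    data.table::rbindlist(lapply(names(cat_list), function(cat) {
      m <- cat_list[[cat]]
      if (is.null(m) || nrow(m) == 0) return(NULL)
      data.table::data.table(event_id = e$event_id[1], category = cat,
                             chrom = e$chrom[1], start = m[, 1],
                             end = m[, 2], strand = e$strand[1])
    }))
  })
  rs <- data.table::rbindlist(rows)
  data.table::setattr(rs, "class", c("region_sets", class(rs)))
  rs
}

# --- plain-integer interval arithmetic on (start, end) 0-based half-open ---

# union of possibly overlapping/adjacent intervals -> disjoint sorted matrix
merge_intervals <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) me <- max(me, end[i])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me)
           ms <- start[i]; me <- end[i] }
  }
  cbind(c(out_s, ms), c(out_e, me))
}

# gaps between disjoint sorted intervals, within span
interval_gaps <- function(m, span) {
  if (nrow(m) < 2) return(matrix(integer(0), ncol = 2))
  s <- m[-nrow(m), 2]; e <- m[-1, 1]
  keep <- e > s
  cbind(s[keep], e[keep])
}

# set difference: intervals m minus one interval ab
subtract_interval <- function(m, ab) {
  if (nrow(m) == 0) return(m)
  out <- matrix(integer(0), ncol = 2)
  for (i in seq_len(nrow(m))) {
    s <- m[i, 1]; e <- m[i, 2]
    if (ab[2] <= s || ab[1] >= e) { out <- rbind(out, c(s, e)); next }
    if (ab[1] > s) out <- rbind(out, c(s, ab[1]))
    if (ab[2] < e) out <- rbind(out, c(ab[2], e))
  }
  out
}

region_category_names <- function() {
  c("ase", "exons_with_ase", "exons_without_ase", "introns",
    "introns_without_ase")
}

#' Materialize one event's region categories as GRanges
#'
#' @param region_sets a [build_region_sets()] table.
#' @param event_id the event to extract.
#' @return named list of five `GRanges` (1-based closed, converted from
#'   the 0-based half-open table).
#' @export
region_set <- function(region_sets, event_id) {
  stopifnot(inherits(region_sets, "region_sets"))
  wanted <- event_id   # plain variable so data.table scoping can't shadow it
  e <- region_sets[region_sets$event_id == wanted]
  sf_assert(nrow(e) > 0, "invalid_input", "unknown event_id: %s", event_id)
  out <- lapply(stats::setNames(nm = region_category_names()), function(cat) {
    g <- e[e$category == cat]
    GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start + 1L, g$end),
                           strand = g$strand)
  })
  out
}

#' Region-specific mean methylation and methylation density
#'
#' Aggregates a sparse per-cytosine methylation track over a set of
#' intervals: `mean_meth` is the average ratio over the `n_c` cytosines in
#' the region union, and `density` is `n_c * mean_meth / length` where
#' `length` is the summed interval length in bp. With no cytosines both
#' metrics are `NA` (missing, not zero: "no cytosines" is not
#' "unmethylated").
#'
#' @param track `GRanges` of single-base cytosines with a numeric `score`
#'   in \[0,1\] (the methylation ratio), or a data.frame with `chrom`,
#'   `start`, `end` (0-based half-open), `score`.
#' @param regions `GRanges` of intervals (or a data.frame as above); must
#'   be non-empty.
#' @return list with `mean_meth`, `density`, `n_c`, `length`.
#' @export
region_methylation <- function(track, regions) {
  track <- as_track_granges(track)
  regions <- as_track_granges(regions, score = FALSE)
  sf_assert(length(regions) > 0, "invalid_input",
            "regions must contain at least one interval")
  sf_assert(all(GenomicRanges::width(regions) > 0), "invalid_input",
            "regions must have positive width")
  u <- GenomicRanges::reduce(regions, ignore.strand = TRUE)
  L <- sum(GenomicRanges::width(u))
  hit <- IRanges::overlapsAny(track, u, ignore.strand = TRUE)
  n_c <- sum(hit)
  if (n_c == 0) return(list(mean_meth = NA_real_, density = NA_real_,
                            n_c = 0L, length = L))
  m <- mean(track$score[hit])
  list(mean_meth = m, density = n_c * m / L, n_c = as.integer(n_c),
       length = L)
}

#' Twenty methylation features for one event
#'
#' 5 region categories x 2 dinucleotide contexts (CG, CA) x 2 metrics
#' (mean methylation, methylation density), with systematic names such as
#' `meth_mean_CG_ase` and `meth_dens_CA_introns`. Missing (`NA`) where a
#' region contains no cytosines of that context.
#'
#' @param tracks named list `list(CG = <track>, CA = <track>)`; either may
#'   be an empty `GRanges`.
#' @param rs named list of five `GRanges` (see [region_set()]).
#' @return named numeric vector of length 20.
#' @export
methylation_feature_vector <- function(tracks, rs) {
  sf_assert(all(c("CG", "CA") %in% names(tracks)), "invalid_input",
            "tracks must be a named list with CG and CA elements")
  cats <- region_category_names()
  out <- numeric(0)
  for (cx in c("CG", "CA")) {
    trk <- as_track_granges(tracks[[cx]])
    for (cat in cats) {
      rm <- region_methylation(trk, rs[[cat]])
      v <- c(rm$mean_meth, rm$density)
      names(v) <- paste0(c("meth_mean_", "meth_dens_"), cx, "_", cat)
      out <- c(out, v)
    }
  }
  out
}

#' Methylation feature table for many events
#'
#' Computes the same 20 features as [methylation_feature_vector()] for
#' every event at once, using a single overlap query per context.
#'
#' @param tracks named list `list(CG = , CA = )` of tracks.
#' @param region_sets result of [build_region_sets()].
#' @return `data.table` with `event_id` plus 20 feature columns.
#' @export
methylation_features <- function(tracks, region_sets) {
  stopifnot(inherits(region_sets, "region_sets"))
  sf_assert(all(c("CG", "CA") %in% names(tracks)), "invalid_input",
            "tracks must be a named list with CG and CA elements")
  rs <- data.table::as.data.table(region_sets)
  ids <- unique(rs$event_id)
  cats <- region_category_names()
  all_int <- GenomicRanges::GRanges(
    rs$chrom, IRanges::IRanges(rs$start + 1L, rs$end))
  len_dt <- rs[, list(L = sum(end - start)), by = c("event_id", "category")]

  grid <- data.table::CJ(event_id = ids, category = cats,
                         context = c("CG", "CA"), sorted = FALSE)
  pieces <- list()
  for (cx in c("CG", "CA")) {
    trk <- as_track_granges(tracks[[cx]])
    hits <- GenomicRanges::findOverlaps(trk, all_int, ignore.strand = TRUE)
    sh <- S4Vectors::subjectHits(hits)
    dt <- data.table::data.table(
      event_id = rs$event_id[sh], category = rs$category[sh],
      score = trk$score[S4Vectors::queryHits(hits)])
    agg <- dt[, list(n_c = .N, mean_meth = mean(score)),
              by = c("event_id", "category")]
    agg$context <- cx
    pieces[[cx]] <- agg
  }
  agg <- data.table::rbindlist(pieces)
  full <- merge(grid, agg, by = c("event_id", "category", "context"),
                all.x = TRUE, sort = FALSE)
  full <- merge(full, len_dt, by = c("event_id", "category"),
                all.x = TRUE, sort = FALSE)
  full$density <- full$n_c * full$mean_meth / full$L

  out <- data.table::data.table(event_id = ids)
  for (cx in c("CG", "CA")) for (cat in cats) {
    sel <- full[full$context == cx & full$category == cat]
    sel <- sel[match(ids, sel$event_id)]
    out[[paste0("meth_mean_", cx, "_", cat)]] <- sel$mean_meth
    out[[paste0("meth_dens_", cx, "_", cat)]] <- sel$density
  }
  out
}

#' Between-condition differences of methylation features
#'
#' Mean-methylation columns are differenced on the probit scale,
#' `qnorm(clip(m_t)) - qnorm(clip(m_c))`; density columns are differenced
#' directly, `dens_t - dens_c`. Missing values propagate. Differenced
#' columns are prefixed `delta_`.
#'
#' @param treat,ctrl matched feature tables (data.frames with `event_id`
#'   and `meth_mean_*` / `meth_dens_*` columns) or matched named numeric
#'   vectors.
#' @param eps clipping bound applied to mean-methylation ratios before the
#'   probit transform.
#' @return object of the same shape with `delta_`-prefixed columns/names.
#' @export
delta_methylation_features <- function(treat, ctrl, eps = 1e-6) {
  if (is.numeric(treat) && !is.null(names(treat))) {
    sf_assert(identical(names(treat), names(ctrl)), "invalid_input",
              "treat and ctrl feature names must match")
    out <- delta_meth_cols(as.list(treat), as.list(ctrl), names(treat), eps)
    return(stats::setNames(unlist(out), paste0("delta_", names(treat))))
  }
  t_dt <- data.table::as.data.table(treat)
  c_dt <- data.table::as.data.table(ctrl)
  sf_assert(identical(names(t_dt), names(c_dt)), "invalid_input",
            "treat and ctrl feature columns must match")
  sf_assert("event_id" %in% names(t_dt) &&
              identical(t_dt$event_id, c_dt$event_id), "invalid_input",
            "treat and ctrl must cover the same events in the same order")
  cols <- setdiff(names(t_dt), "event_id")
  out <- delta_meth_cols(t_dt[, cols, with = FALSE],
                         c_dt[, cols, with = FALSE], cols, eps)
  data.table::as.data.table(c(list(event_id = t_dt$event_id),
                              stats::setNames(out, paste0("delta_", cols))))
}

delta_meth_cols <- function(t_list, c_list, cols, eps) {
  lapply(stats::setNames(cols, cols), function(cl) {
    tv <- t_list[[cl]]; cv <- c_list[[cl]]
    if (grepl("^meth_mean_", cl)) {
      qnorm(clip_unit(tv, eps)) - qnorm(clip_unit(cv, eps))
    } else if (grepl("^meth_dens_", cl)) {
      tv - cv
    } else {
      sf_stop("invalid_input",
              "column %s is not a methylation feature (meth_mean_*/meth_dens_*)",
              cl)
    }
  })
}

#' log2 ChIP/Input ratio over windows
#'
#' Per window, `log2((mean_chip + pseudocount) / (mean_input + pseudocount))`
#' where the mean is the base-pair average of a piecewise-constant coverage
#' track over the window (uncovered bases count as 0).
#'
#' @param chip,input coverage tracks: `GRanges` with numeric `score`, or
#'   data.frames with `chrom`, `start`, `end` (0-based half-open), `score`.
#' @param windows `GRanges` (or data.frame) of scoring windows.
#' @param pseudocount positive stabilizer added to both means.
#' @return numeric vector of per-window log2 ratios (named if windows are).
#' @export
chip_log2_ratio <- function(chip, input, windows, pseudocount = 1e-3) {
  sf_assert(is.numeric(pseudocount) && pseudocount > 0, "invalid_input",
            "pseudocount must be positive")
  windows <- as_track_granges(windows, score = FALSE)
  sf_assert(length(windows) > 0 && all(GenomicRanges::width(windows) > 0),
            "invalid_input", "windows must be non-empty with positive width")
  m_chip <- track_window_mean(as_track_granges(chip), windows)
  m_input <- track_window_mean(as_track_granges(input), windows)
  r <- log2((m_chip + pseudocount) / (m_input + pseudocount))
  names(r) <- names(windows)
  r
}

# Base-pair mean of a piecewise-constant track over each window.
track_window_mean <- function(track, windows) {
  hits <- GenomicRanges::findOverlaps(windows, track, ignore.strand = TRUE)
  ov <- IRanges::pintersect(windows[S4Vectors::queryHits(hits)],
                            track[S4Vectors::subjectHits(hits)],
                            ignore.strand = TRUE)
  contrib <- GenomicRanges::width(ov) *
    track$score[S4Vectors::subjectHits(hits)]
  sums <- rep(0, length(windows))
  agg <- tapply(contrib, S4Vectors::queryHits(hits), sum)
  sums[as.integer(names(agg))] <- agg
  sums / GenomicRanges::width(windows)
}

#' Default ChIP scoring windows around the alternative exon
#'
#' The ASE body plus fixed-width flanks into the two adjacent introns
#' (truncated at the intron boundary when the intron is shorter than the
#' flank). Flanks are named by gene orientation: `flank_up` is 5' of the
#' ASE.
#'
#' @param rs named list of five `GRanges` for one event ([region_set()]).
#' @param flank flank width in bp (default 300).
#' @return named `GRanges` with windows `ase`, `flank_up`, `flank_down`.
#' @export
chip_default_windows <- function(rs, flank = 300L) {
  ase <- rs$ase
  introns <- rs$introns
  left <- GenomicRanges::flank(ase, flank, start = TRUE, ignore.strand = TRUE)
  right <- GenomicRanges::flank(ase, flank, start = FALSE,
                                ignore.strand = TRUE)
  left <- GenomicRanges::intersect(left, introns, ignore.strand = TRUE)
  right <- GenomicRanges::intersect(right, introns, ignore.strand = TRUE)
  minus <- as.character(GenomicRanges::strand(ase)) == "-"
  w <- c(ase, left, right)
  names(w) <- if (minus) c("ase", "flank_down", "flank_up")
              else c("ase", "flank_up", "flank_down")
  w[c("ase", "flank_up", "flank_down")]
}

#' ChIP feature table for many events
#'
#' Builds the default windows for every event and scores both tracks in a
#' single overlap pass per track.
#'
#' @param chip,input coverage tracks (see [chip_log2_ratio()]).
#' @param region_sets result of [build_region_sets()].
#' @param flank flank width in bp.
#' @param pseudocount stabilizer for the log2 ratio.
#' @return `data.table` with `event_id`, `chip_ase`, `chip_flank_up`,
#'   `chip_flank_down`.
#' @export
chip_features <- function(chip, input, region_sets, flank = 300L,
                          pseudocount = 1e-3) {
  stopifnot(inherits(region_sets, "region_sets"))
  rs <- data.table::as.data.table(region_sets)
  ase <- rs[rs$category == "ase"]
  intr <- rs[rs$category == "introns"]
  win <- list()
  for (i in seq_len(nrow(ase))) {
    id <- ase$event_id[i]
    ii <- intr[intr$event_id == id]
    up_i <- ii[ii$end == ase$start[i]]      # intron abutting ASE start
    dn_i <- ii[ii$start == ase$end[i]]      # intron abutting ASE end
    left <- if (nrow(up_i))
      c(max(up_i$start[1], ase$start[i] - flank), ase$start[i]) else NULL
    right <- if (nrow(dn_i))
      c(ase$end[i], min(dn_i$end[1], ase$end[i] + flank)) else NULL
    minus <- ase$strand[i] == "-"
    add <- function(name, iv) if (!is.null(iv) && iv[2] > iv[1])
      data.table::data.table(event_id = id, window = name,
                             chrom = ase$chrom[i], start = iv[1],
                             end = iv[2]) else NULL
    win[[length(win) + 1L]] <- data.table::rbindlist(list(
      add("ase", c(ase$start[i], ase$end[i])),
      add(if (minus) "flank_down" else "flank_up", left),
      add(if (minus) "flank_up" else "flank_down", right)))
  }
  win <- data.table::rbindlist(win)
  wgr <- GenomicRanges::GRanges(win$chrom,
                                IRanges::IRanges(win$start + 1L, win$end))
  win$ratio <- log2(
    (track_window_mean(as_track_granges(chip), wgr) + pseudocount) /
      (track_window_mean(as_track_granges(input), wgr) + pseudocount))
  wide <- data.table::dcast(win, event_id ~ window, value.var = "ratio")
  data.table::setnames(
    wide, old = c("ase", "flank_up", "flank_down"),
    new = c("chip_ase", "chip_flank_up", "chip_flank_down"),
    skip_absent = TRUE)
  for (cl in c("chip_ase", "chip_flank_up", "chip_flank_down"))
    if (!cl %in% names(wide)) wide[[cl]] <- NA_real_
  wide[, c("event_id", "chip_ase", "chip_flank_up", "chip_flank_down"),
       with = FALSE]
}

# Accept GRanges directly, or a 0-based half-open data.frame
# (chrom/start/end[/score]) and convert.
as_track_granges <- function(x, score = TRUE) {
  if (methods::is(x, "GRanges")) return(x)
  dt <- data.table::as.data.table(x)
  sf_assert(all(c("chrom", "start", "end") %in% names(dt)), "invalid_input",
            "track/region tables need chrom, start, end columns (0-based half-open)")
  gr <- GenomicRanges::GRanges(dt$chrom,
                               IRanges::IRanges(dt$start + 1L, dt$end))
  if (score && "score" %in% names(dt)) gr$score <- dt$score
  gr
}
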