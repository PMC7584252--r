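#' Default pipeline configuration
#'
#' Nested list mirroring the pipeline stages. Any subset can be overridden
#' via `overrides`; unspecified values keep their defaults. The effective
#' (fully resolved) config is written alongside every run's outputs.
#'
#' @param overrides nested list of values to override.
#' @return list of class `run_config`.
#' @export
default_run_config <- function(overrides = list()) {
  cfg <- list(
    seed = 1L,
    stages = list(simulate = TRUE, quantify = TRUE, features = TRUE,
                  regress = TRUE, correlations = TRUE),
    sim = list(n_events = 500L, n_features = 20L, fve_seq = 0.6,
               fve_meth = 0, coverage = 50, track_density = 5),
    paths = list(counts_control = NULL, counts_treatment = NULL,
                 annotation = NULL, regions = NULL, tracks_dir = NULL,
                 seq_features = NULL),
    estimator = list(method = "shrink", prior_mean = 0.5,
                     prior_strength = 4, bf_threshold = 3),
    regression = list(models = c("linear_reg", "random_forest"),
                      n_splits = 5L, test_fraction = 0.25, eps = 1e-6,
                      n_trees = 100L)
  )
  cfg <- utils::modifyList(cfg, overrides)
  structure(cfg, class = "run_config")
}

stage_error <- function(stage, parent) {
  sf_stop("stage_error", "stage '%s' failed: %s", stage,
          conditionMessage(parent))
}

run_stage <- function(stage, outdir, expr) {
  tryCatch(expr, error = function(e) {
    writeLines(conditionMessage(e),
               file.path(outdir, sprintf("FAILED_%s", stage)))
    stage_error(stage, e)
  })
}

#' Run the full simulate-quantify-features-regress pipeline
#'
#' Executes the enabled stages in order, persisting every intermediate as
#' plain text (TSV / BED / bedGraph) under `outdir`, and writes a
#' `report.json` whose every number is recomputable from those files.
#' Identical config (including seed) gives byte-identical outputs. A stage
#' failure aborts with a stage-tagged error and leaves a `FAILED_<stage>`
#' marker file next to the partial outputs.
#'
#' @param config a [default_run_config()] (or overrides list accepted by
#'   it).
#' @param outdir output directory (created if needed).
#' @return the run report, invisibly (also stored as `report.json`).
#' @export
run_pipeline <- function(config = default_run_config(), outdir) {
  if (!inherits(config, "run_config")) config <- default_run_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  eff <- unclass(config)
  eff$package_version <- as.character(utils::packageVersion("splicefve"))
  yaml::write_yaml(eff, file.path(outdir, "config.yaml"))

  sim_cfg <- sim_config(
    n_events = config$sim$n_events, n_features = config$sim$n_features,
    fve_seq = config$sim$fve_seq, fve_meth = config$sim$fve_meth,
    coverage = config$sim$coverage, seed = config$seed,
    track_density = config$sim$track_density)

  ann <- NULL; region_sets <- NULL; seq_X <- NULL; truth <- NULL
  tracks <- NULL
  counts <- list()

  if (isTRUE(config$stages$simulate)) {
    run_stage("simulate", outdir, {
      ann <- generate_annotation(sim_cfg)
      seq_X <- generate_latent_features(sim_cfg)
      set.seed(derive_seed(sim_cfg$seed, "meth_delta"))
      meth_delta <- rnorm(sim_cfg$n_events)
      tr <- suppressWarnings(
        generate_methylation_tracks(ann, meth_delta, sim_cfg))
      tracks <- tr$tracks
      truth <- generate_psi_and_delta(seq_X, meth_delta, sim_cfg)
      counts$control <- simulate_reads(
        stats::setNames(truth$psi_ctrl, truth$event_id), sim_cfg,
        stage = "reads_control")
      counts$treatment <- simulate_reads(
        stats::setNames(truth$psi_treat, truth$event_id), sim_cfg,
        stage = "reads_treatment")
      region_sets <- build_region_sets(ann)

      write_annotation_bed(ann, file.path(outdir, "annotation.bed"))
      write_annotation_tsv(ann, file.path(outdir, "annotation.tsv"))
      write_region_manifest(region_sets, file.path(outdir, "regions.tsv"))
      write_tsv(data.table::data.table(event_id = rownames(seq_X), seq_X),
                file.path(outdir, "seq_features.tsv"))
      write_tsv(truth, file.path(outdir, "truth.tsv"))
      write_tsv(tr$realized, file.path(outdir, "meth_realized.tsv"))
      dir.create(file.path(outdir, "tracks"), showWarnings = FALSE)
      for (cd in names(tracks)) for (cx in names(tracks[[cd]]))
        write_bedgraph(tracks[[cd]][[cx]],
                       file.path(outdir, "tracks",
                                 sprintf("%s_%s.bedGraph", cd, cx)))
      write_tsv(counts$control, file.path(outdir, "counts_control.tsv"))
      write_tsv(counts$treatment, file.path(outdir, "counts_treatment.tsv"))
    })
  } else {
    run_stage("load_inputs", outdir, {
      p <- config$paths
      for (f in c("counts_control", "counts_treatment", "annotation",
                  "seq_features"))
        sf_assert(!is.null(p[[f]]) && file.exists(p[[f]] %||% ""),
                  "file_not_found",
                  "stage 'load_inputs': missing input '%s'", f)
      ann <- read_annotation_tsv(p$annotation)
      counts$control <- read_tsv(p$counts_control)
      counts$treatment <- read_tsv(p$counts_treatment)
      sq <- read_tsv(p$seq_features)
      seq_X <- as.matrix(sq[, -1]); rownames(seq_X) <- sq$event_id
      region_sets <- if (!is.null(p$regions)) read_region_manifest(p$regions)
                      else build_region_sets(ann)
      if (!is.null(p$tracks_dir)) {
        tracks <- lapply(
          stats::setNames(nm = c("control", "treatment")),
          function(cd) lapply(stats::setNames(nm = c("CG", "CA")),
            function(cx) read_bedgraph(
              file.path(p$tracks_dir, sprintf("%s_%s.bedGraph", cd, cx)))))
      }
      # persist the consumed inputs so the run report stays recomputable
      write_annotation_tsv(ann, file.path(outdir, "annotation.tsv"))
      write_region_manifest(region_sets, file.path(outdir, "regions.tsv"))
      write_tsv(counts$control, file.path(outdir, "counts_control.tsv"))
      write_tsv(counts$treatment, file.path(outdir, "counts_treatment.tsv"))
    })
  }

  psi <- list()
  diff_calls <- NULL
  if (isTRUE(config$stages$quantify)) {
    run_stage("quantify", outdir, {
      est <- config$estimator
      for (cd in c("control", "treatment")) {
        psi[[cd]] <- psi_table(counts[[cd]], estimator = est$method,
                                prior_mean = est$prior_mean,
                                prior_strength = est$prior_strength)
        write_tsv(psi[[cd]], file.path(outdir, sprintf("psi_%s.tsv", cd)))
      }
      diff_calls <- cbind(
        data.table::data.table(event_id = counts$control$event_id),
        bayes_factor_diff(counts$treatment$n_inc, counts$treatment$n_exc,
                          counts$control$n_inc, counts$control$n_exc,
                          threshold = est$bf_threshold))
      write_tsv(diff_calls, file.path(outdir, "diff_splicing.tsv"))
    })
  }

  meth_feat <- list(); delta_meth <- NULL
  if (isTRUE(config$stages$features) && !is.null(tracks)) {
    run_stage("features", outdir, {
      for (cd in c("control", "treatment")) {
        meth_feat[[cd]] <- methylation_features(tracks[[cd]], region_sets)
        write_tsv(meth_feat[[cd]],
                  file.path(outdir, sprintf("meth_features_%s.tsv", cd)))
      }
      delta_meth <- delta_methylation_features(
        meth_feat$treatment, meth_feat$control,
        eps = config$regression$eps)
      write_tsv(delta_meth, file.path(outdir, "delta_meth_features.tsv"))
    })
  }

  fve_tab <- NULL
  if (isTRUE(config$stages$regress)) {
    run_stage("regress", outdir, {
      rg <- config$regression
      stopifnot(identical(psi$control$event_id, rownames(seq_X)))
      y_level <- probit_transform(psi$control$psi, rg$eps)
      y_delta <- delta_response(psi$treatment$psi, psi$control$psi, rg$eps)
      dm <- NULL
      if (!is.null(delta_meth)) {
        dm <- as.matrix(delta_meth[, -1])
        rownames(dm) <- delta_meth$event_id
        dm <- dm[rownames(seq_X), , drop = FALSE]
      }
      analyses <- list(list(response = "psi_level", y = y_level,
                            feature_set = "seq", X = seq_X))
      analyses <- c(analyses, list(
        list(response = "psi_delta", y = y_delta, feature_set = "seq",
             X = seq_X)))
      if (!is.null(dm)) analyses <- c(analyses, list(
        list(response = "psi_delta", y = y_delta, feature_set = "seq+meth",
             X = cbind(seq_X, dm)),
        list(response = "psi_delta", y = y_delta, feature_set = "meth_only",
             X = dm)))
      rows <- list()
      for (an in analyses) for (md in rg$models) {
        res <- suppressWarnings(evaluate_fve(
          an$X, an$y, model = md, n_splits = rg$n_splits,
          test_fraction = rg$test_fraction,
          seed = derive_seed(config$seed,
                             paste("fve", md, an$feature_set, an$response)),
          feature_set = an$feature_set, n_trees = rg$n_trees))
        df <- as.data.frame(res)
        df$response <- an$response
        rows[[length(rows) + 1L]] <- df
      }
      fve_tab <- data.table::rbindlist(rows)
      write_tsv(fve_tab, file.path(outdir, "fve_results.tsv"))
    })
  }

  cor_tab <- NULL
  if (isTRUE(config$stages$correlations) && !is.null(delta_meth) &&
      !is.null(diff_calls)) {
    run_stage("correlations", outdir, {
      delta_psi <- psi$treatment$psi - psi$control$psi
      feats <- c("delta_meth_mean_CG_ase", "delta_meth_mean_CA_ase",
                 "delta_meth_dens_CG_ase", "delta_meth_dens_CA_ase")
      sig <- diff_calls$significant
      rows <- list()
      for (f in feats) for (subset in c("all", "significant")) {
        keep <- if (subset == "all") rep(TRUE, length(delta_psi)) else sig
        res <- tryCatch(
          pearson_delta_correlation(delta_psi[keep], delta_meth[[f]][keep]),
          splicefve_error = function(e) list(r = NA_real_, p = NA_real_,
                                             n = sum(keep)))
        rows[[length(rows) + 1L]] <- data.table::data.table(
          comparison = f, subset = subset, r = res$r, p = res$p, n = res$n)
      }
      cor_tab <- data.table::rbindlist(rows)
      cor_tab$p_adj <- stats::p.adjust(cor_tab$p, method = "BH")
      write_tsv(cor_tab, file.path(outdir, "correlations.tsv"))
    })
  }

  report <- build_report(outdir)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

# Compute every report number from the persisted stage outputs.
build_report <- function(run_dir) {
  f <- function(name) file.path(run_dir, name)
  report <- list(seed = NA, n_events = NA)
  cfg_path <- f("config.yaml")
  if (file.exists(cfg_path)) {
    cfg <- yaml::read_yaml(cfg_path)
    report$seed <- cfg$seed
    report$package_version <- cfg$package_version
  }
  if (file.exists(f("annotation.tsv"))) {
    ann <- read_tsv(f("annotation.tsv"))
    report$n_events <- length(unique(ann$event_id))
  }
  for (cd in c("control", "treatment")) {
    p <- f(sprintf("counts_%s.tsv", cd))
    if (file.exists(p))
      report[[sprintf("n_counts_%s", cd)]] <- nrow(read_tsv(p))
  }
  if (file.exists(f("diff_splicing.tsv"))) {
    dc <- read_tsv(f("diff_splicing.tsv"))
    report$n_significant <- sum(dc$significant)
  }
  if (file.exists(f("fve_results.tsv"))) {
    fv <- read_tsv(f("fve_results.tsv"))
    agg <- fv[, list(mean_fve = mean(fve, na.rm = TRUE)),
              by = c("model", "feature_set", "response")]
    report$fve_summary <- lapply(seq_len(nrow(agg)), function(i) as.list(agg[i]))
  }
  if (file.exists(f("correlations.tsv"))) {
    ct <- read_tsv(f("correlations.tsv"))
    report$correlations <- lapply(seq_len(nrow(ct)), function(i)
      as.list(ct[i, c("comparison", "subset", "r", "n")]))
  }
  report
}

#' Rebuild and verify a run report
#'
#' Recomputes every summary number from the persisted stage outputs in
#' `run_dir` and compares with the stored `report.json`. Any mismatch (a
#' tampered or corrupted intermediate) raises an integrity error listing
#' the offending fields. Internal consistency of the FVE table
#' (`mean_fve` vs the per-split values) is checked too.
#'
#' @param run_dir directory produced by [run_pipeline()].
#' @return the recomputed report (invisibly) when everything matches.
#' @export
make_report <- function(run_dir) {
  sf_assert(dir.exists(run_dir), "integrity_error",
            "run directory does not exist: %s", run_dir)
  stored_path <- file.path(run_dir, "report.json")
  sf_assert(file.exists(stored_path), "integrity_error",
            "no report.json in %s", run_dir)
  stored <- jsonlite::read_json(stored_path, simplifyVector = FALSE)
  fresh <- build_report(run_dir)

  bad <- character(0)
  flat <- function(x, prefix = "") {
    if (is.list(x)) {
      nm <- names(x) %||% as.character(seq_along(x))
      out <- list()
      for (i in seq_along(x))
        out <- c(out, flat(x[[i]], paste0(prefix, nm[i], ".")))
      out
    } else stats::setNames(list(x), sub("\\.$", "", prefix))
  }
  a <- flat(stored); b <- flat(fresh)
  missing_val <- function(v) is.null(v) || (length(v) == 1 && is.na(v))
  for (k in union(names(a), names(b))) {
    va <- a[[k]]; vb <- b[[k]]
    same <- if (missing_val(va) || missing_val(vb))
      missing_val(va) && missing_val(vb)
    else if (is.numeric(va) && is.numeric(vb))
      isTRUE(abs(va - vb) < 1e-9)
    else identical(as.character(va), as.character(vb))
    if (!isTRUE(same)) bad <- c(bad, k)
  }
  fve_path <- file.path(run_dir, "fve_results.tsv")
  if (file.exists(fve_path)) {
    fv <- read_tsv(fve_path)
    chk <- fv[, list(ok = abs(mean(fve, na.rm = TRUE) - mean_fve[1]) < 1e-9),
              by = c("model", "feature_set", "response")]
    if (any(!chk$ok))
      bad <- c(bad, paste0("fve_results.mean_fve:",
                           paste(chk$model[!chk$ok], chk$feature_set[!chk$ok],
                                 sep = "|")))
  }
  sf_assert(length(bad) == 0, "integrity_error",
            "report does not match persisted outputs; mismatched fields: %s",
            paste(bad, collapse = ", "))
  invisible(fresh)
}
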