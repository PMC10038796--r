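#' Read a multi-subject BOLD group from NIfTI files
#'
#' Loads one 4-D NIfTI per subject plus a 3-D analysis mask, checks that all
#' grids and affines agree, and flattens the in-mask voxels in ascending
#' linear index order (the package's documented voxel ordering; the inverse
#' mapping is retained in the group's geometry for map writing).
#'
#' @param paths character vector of per-subject 4-D NIfTI paths.
#' @param mask_path 3-D mask NIfTI; voxels with value > 0 are analysed.
#' @param tr_seconds repetition time.
#' @param run_lengths per-run timepoint counts.
#' @param condition,population labels stored on the group.
#' @return a [bold_group()] with geometry (`dim`, `mask_idx`, `affine`).
#' @export
read_bold_group <- function(paths, mask_path, tr_seconds, run_lengths,
                            condition = NA_character_,
                            population = NA_character_) {
  mask_img <- RNifti::readNifti(mask_path)
  mdim <- dim(mask_img)[1:3]
  maff <- RNifti::xform(mask_img)
  mask_idx <- which(as.array(mask_img) > 0)
  if (!length(mask_idx)) .stopf("mask '%s' selects no voxels", mask_path)
  data <- lapply(paths, function(p) {
    img <- RNifti::readNifti(p)
    d <- dim(img)
    if (length(d) != 4L || !all(d[1:3] == mdim))
      .stopf("grid of '%s' (%s) does not match the mask (%s)", p,
             paste(d, collapse = "x"), paste(mdim, collapse = "x"))
    if (max(abs(RNifti::xform(img) - maff)) > 1e-4)
      .stopf("affine of '%s' does not match the mask", p)
    arr <- as.array(img)
    m <- matrix(arr, prod(mdim), d[4L])[mask_idx, , drop = FALSE]
    storage.mode(m) <- "double"
    m
  })
  bold_group(data, tr_seconds, run_lengths,
             subject_ids = sub("\\.nii(\\.gz)?$", "", basename(paths)),
             condition = condition, population = population,
             geometry = list(dim = mdim, mask_idx = mask_idx, affine = maff))
}

## Unfold a per-voxel vector into a 3-D array on the geometry grid.
.vec_to_volume <- function(x, geometry, background = 0) {
  arr <- array(background, geometry$dim)
  arr[geometry$mask_idx] <- x
  arr
}

.write_volume <- function(x, geometry, path) {
  img <- RNifti::asNifti(.vec_to_volume(as.numeric(x), geometry, NA_real_))
  RNifti::writeNifti(img, path)
  path
}

#' Write a synthetic group as per-subject NIfTI volumes plus mask
#'
#' Lays the group's voxels out on its geometry grid and writes one 4-D
#' NIfTI per subject and the 3-D mask, so synthetic datasets round-trip
#' through [read_bold_group()].
#'
#' @param group a [bold_group()] with geometry.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, a list with `paths` and `mask_path`.
#' @export
write_bold_group <- function(group, dir, prefix = "sub") {
  if (is.null(group$geometry)) .stopf("group carries no geometry")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- group$geometry
  nt <- n_timepoints(group)
  paths <- vapply(seq_along(group$data), function(s) {
    arr <- array(0, c(g$dim, nt))
    flat <- matrix(arr, prod(g$dim), nt)
    flat[g$mask_idx, ] <- group$data[[s]]
    p <- file.path(dir, sprintf("%s-%02d.nii", prefix, s))
    RNifti::writeNifti(RNifti::asNifti(array(flat, c(g$dim, nt))), p)
    p
  }, "")
  mask <- array(0L, g$dim)
  mask[g$mask_idx] <- 1L
  mask_path <- file.path(dir, paste0(prefix, "-mask.nii"))
  RNifti::writeNifti(RNifti::asNifti(mask), mask_path)
  invisible(list(paths = paths, mask_path = mask_path))
}

#' Write an ISC map's volumes and summary table
#'
#' Emits unthresholded statistic volumes (mean r, t, p where available)
#' plus the significance mask, and a TSV summary with one row per voxel, so
#' thresholds can be revised without recomputation.
#'
#' @param map an `isc_map` (or `mediation_result`) carrying geometry.
#' @param prefix output path prefix.
#' @return invisibly, the written file paths.
#' @export
write_isc_map <- function(map, prefix) {
  g <- map$geometry
  if (is.null(g)) .stopf("map carries no geometry")
  dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  fields <- if (inherits(map, "mediation_result"))
    list(isc_original = map$isc_original, isc_mediated = map$isc_mediated,
         drop = map$drop, p = map$p_drop)
  else list(mean_r = map$mean_r, t = map$t_stat, p = map$p)
  for (nm in names(fields)) {
    if (is.null(fields[[nm]])) next
    files <- c(files, .write_volume(fields[[nm]], g, paste0(prefix, "_", nm, ".nii")))
  }
  if (!is.null(map$significant_mask))
    files <- c(files, .write_volume(as.integer(map$significant_mask), g,
                                    paste0(prefix, "_sigmask.nii")))
  tab <- data.frame(voxel = seq_along(fields[[1L]]), fields[!vapply(fields, is.null, TRUE)])
  tsv <- paste0(prefix, "_summary.tsv")
  utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(files, tsv))
}

#' Read / write feature models as TSV
#'
#' Tab-separated tables whose first column is `time_s`, remaining columns
#' the features.
#'
#' @param path TSV path.
#' @param level model level (see [feature_model()]).
#' @param name model label (default: file stem).
#' @return a [feature_model()].
#' @export
read_feature_model <- function(path, level, name = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE)
  if (names(tab)[1L] != "time_s") .stopf("'%s': first column must be time_s", path)
  t_s <- tab[[1L]]
  rate <- 1 / stats::median(diff(t_s))
  feature_model(if (is.null(name)) sub("\\.tsv$", "", basename(path)) else name,
                level, t_s, as.matrix(tab[-1L]), rate)
}

#' @rdname read_feature_model
#' @param model a [feature_model()].
#' @export
write_feature_model <- function(model, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  tab <- data.frame(time_s = model$times_s, model$matrix, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Reads (YAML or JSON) or assembles the configuration driving
#' [run_pipeline()]: file locations per condition, feature-model table,
#' surrogate settings, thresholds and the output directory.
#'
#' @param x a path to a YAML/JSON file, or a named list.
#' @return a validated `pipeline_config`.
#' @export
pipeline_config <- function(x) {
  cfg <- if (is.character(x)) {
    if (grepl("\\.json$", x)) jsonlite::read_json(x, simplifyVector = TRUE)
    else yaml::read_yaml(x)
  } else x
  defaults <- list(alpha = 0.05, min_cluster = 20L, connectivity = 18L,
                   widths_s = seq(2, 240, by = 2), n_permutations = 1000L,
                   chunks_per_run = 3L, allow_time_reversal = TRUE,
                   n_null_maps = 200L, seed = 1L)
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  for (nm in c("tr_seconds", "run_lengths", "mask", "groups", "out_dir"))
    if (is.null(cfg[[nm]])) .stopf("config is missing required field '%s'", nm)
  if (cfg$alpha <= 0 || cfg$alpha >= 1) .stopf("alpha must lie in (0, 1)")
  for (g in names(cfg$groups)) {
    missing <- cfg$groups[[g]][!file.exists(cfg$groups[[g]])]
    if (length(missing))
      .stopf("group '%s': missing file(s) %s", g, paste(missing, collapse = ", "))
  }
  if (!file.exists(cfg$mask)) .stopf("mask file '%s' does not exist", cfg$mask)
  structure(cfg, class = "pipeline_config")
}

.log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(fmt, ...)))
}

#' Run the three-experiment ISC pipeline
#'
#' Orchestrates the full analysis on the configured datasets: (1)
#' within-condition ISC of the audiovisual group; (2) across-condition ISC
#' of the two unimodal groups; (3) their conjunction; (4) across-condition
#' ISC of a second (e.g. sensory-deprived) population restricted to the
#' conjunction voxels; (5) model-mediated ISC with cross-modal low-level
#' assignment and shared high-level models, plus the low-versus-high
#' signed-rank contrast; (6) TRW profiles per condition and their map
#' similarities. Stages whose inputs are absent are skipped with an
#' explicit log line; every artifact is written under the output directory
#' and listed in a JSON manifest together with versions, seeds and
#' parameters.
#'
#' @param config a [pipeline_config()] (or path / list coercible to one).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  spec <- surrogate_spec(cfg$chunks_per_run, cfg$allow_time_reversal,
                         cfg$n_permutations, cfg$seed)
  manifest <- list(package_version = as.character(utils::packageVersion("iscor")),
                   r_version = R.version.string,
                   seed = cfg$seed,
                   parameters = cfg[c("alpha", "min_cluster", "connectivity",
                                      "n_permutations", "chunks_per_run",
                                      "tr_seconds", "run_lengths")],
                   outputs = list(), skipped = list())
  read_grp <- function(nm, population) {
    if (is.null(cfg$groups[[nm]])) return(NULL)
    read_bold_group(cfg$groups[[nm]], cfg$mask, cfg$tr_seconds,
                    cfg$run_lengths, condition = nm, population = population)
  }
  stage <- function(name, expr) {
    .log_stage(name, "started (seed %d, %d permutations)", cfg$seed, cfg$n_permutations)
    tryCatch(expr, error = function(e)
      .stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  av <- read_grp("AV", "TD"); a_td <- read_grp("A", "TD"); v_td <- read_grp("V", "TD")
  a_sd <- read_grp("A_SD", "SD"); v_sd <- read_grp("V_SD", "SD")

  thr <- function(map, null) threshold_map(map, null, cfg$alpha,
                                           cfg$min_cluster, cfg$connectivity)
  maps <- list()
  if (!is.null(av)) {
    maps$within_av <- stage("isc_within_AV", {
      m <- isc_within(av)
      thr(m, null_distribution(isc_stat_within, list(av), spec))
    })
    manifest$outputs$within_av <- write_isc_map(maps$within_av, file.path(out, "isc_within_AV"))
  }
  if (!is.null(a_td) && !is.null(v_td)) {
    maps$across_td <- stage("isc_across_TD", {
      m <- isc_across(a_td, v_td)
      thr(m, null_distribution(isc_stat_across, list(a_td, v_td), spec))
    })
    manifest$outputs$across_td <- write_isc_map(maps$across_td, file.path(out, "isc_across_TD"))
  }
  conj <- NULL
  if (!is.null(maps$within_av) && !is.null(maps$across_td)) {
    conj <- stage("conjunction", conjunction(maps[c("within_av", "across_td")]))
    manifest$outputs$conjunction <- .write_volume(as.integer(conj),
                                                  av$geometry,
                                                  file.path(out, "conjunction.nii"))
  }
  if (!is.null(a_sd) && !is.null(v_sd)) {
    maps$across_sd <- stage("isc_across_SD", {
      asd <- a_sd; vsd <- v_sd
      if (!is.null(conj) && any(conj)) {
        asd <- subset_voxels(a_sd, conj); vsd <- subset_voxels(v_sd, conj)
      }
      m <- isc_across(asd, vsd)
      thr(m, null_distribution(isc_stat_across, list(asd, vsd), spec))
    })
    manifest$outputs$across_sd <- write_isc_map(maps$across_sd, file.path(out, "isc_across_SD"))
  }
  ## --- model mediation ---------------------------------------------------
  feats <- NULL
  if (!is.null(cfg$features)) {
    present <- vapply(cfg$features, function(f) file.exists(f$path), TRUE)
    if (all(present)) {
      feats <- lapply(cfg$features, function(f)
        read_feature_model(f$path, f$level, f$name))
      names(feats) <- vapply(feats, `[[`, "", "name")
    } else {
      .log_stage("mediation", "skipped: missing feature TSV(s) %s",
                 paste(vapply(cfg$features[!present], `[[`, "", "path"), collapse = ", "))
      manifest$skipped$mediation <- "missing feature TSVs"
    }
  } else manifest$skipped$mediation <- "no features configured"
  if (!is.null(feats) && !is.null(a_td) && !is.null(v_td)) {
    med <- stage("mediation", {
      editing <- Filter(function(f) f$level == "editing", feats)
      lows_a <- Filter(function(f) f$level == "low_auditory", feats)
      lows_v <- Filter(function(f) f$level == "low_visual", feats)
      highs <- Filter(function(f) f$level == "high_semantic", feats)
      ortho <- function(fs) lapply(fs, function(f)
        if (length(editing)) orthogonalize(f, editing[[1L]]) else f)
      dsn <- function(fs) {
        if (!length(fs)) return(NULL)
        d <- do.call(cbind, c(lapply(ortho(fs), function(f)
          build_design(f, cfg$tr_seconds, sum(cfg$run_lengths), cfg$run_lengths)[,
            seq_len(ncol(f$matrix)), drop = FALSE]),
          list(.run_intercepts(cfg$run_lengths))))
        attr(d, "run_intercepts") <- TRUE
        d
      }
      ## cross-modal: visual features out of listeners, acoustic out of viewers
      low <- mediated_isc(a_td, v_td, dsn(lows_v), dsn(lows_a))
      low <- drop_significance(low, a_td, v_td, dsn(lows_v), dsn(lows_a),
                               spec, cfg$alpha, cfg$min_cluster, cfg$connectivity)
      high <- mediated_isc(a_td, v_td, dsn(highs), dsn(highs))
      high <- drop_significance(high, a_td, v_td, dsn(highs), dsn(highs),
                                spec, cfg$alpha, cfg$min_cluster, cfg$connectivity)
      contrast <- compare_model_drops(
        pairwise_drops(a_td, v_td, dsn(lows_v), dsn(lows_a)),
        pairwise_drops(a_td, v_td, dsn(highs), dsn(highs)),
        n_permutations = cfg$n_permutations, seed = cfg$seed)
      list(low = low, high = high, contrast = contrast)
    })
    manifest$outputs$mediation_low <- write_isc_map(med$low, file.path(out, "mediated_low"))
    manifest$outputs$mediation_high <- write_isc_map(med$high, file.path(out, "mediated_high"))
    wtab <- data.frame(voxel = seq_along(med$contrast$W), W = med$contrast$W,
                       p = med$contrast$p,
                       low_gt_high = med$contrast$mask_low_gt_high,
                       high_gt_low = med$contrast$mask_high_gt_low)
    wpath <- file.path(out, "model_contrast.tsv")
    utils::write.table(wtab, wpath, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$outputs$model_contrast <- wpath
  }
  ## --- TRW ---------------------------------------------------------------
  trw_sets <- list()
  if (!is.null(av)) trw_sets$AV <- list(av, NULL)
  if (!is.null(a_td) && !is.null(v_td)) trw_sets$TD <- list(a_td, v_td)
  if (!is.null(a_sd) && !is.null(v_sd)) trw_sets$SD <- list(a_sd, v_sd)
  profiles <- list()
  for (nm in names(trw_sets)) {
    profiles[[nm]] <- stage(paste0("trw_", nm), {
      pr <- trw_profile(trw_sets[[nm]][[1L]], trw_sets[[nm]][[2L]], cfg$widths_s)
      trw_significance(pr, trw_sets[[nm]][[1L]], trw_sets[[nm]][[2L]], spec,
                       cfg$alpha, cfg$min_cluster, cfg$connectivity)
    })
    g <- trw_sets[[nm]][[1L]]$geometry
    ppath <- file.path(out, sprintf("trw_peak_%s.nii", nm))
    .write_volume(profiles[[nm]]$peak_width_s, g, ppath)
    manifest$outputs[[paste0("trw_", nm)]] <- ppath
  }
  if (length(profiles) >= 2L && !is.null(profiles$SD) &&
      any(profiles$SD$significant_mask)) {
    sims <- stage("trw_similarity", {
      mask <- profiles$SD$significant_mask
      if (sum(mask) < 10L) mask <- rep(TRUE, length(mask))
      nulls <- trw_null_maps(trw_sets[[1L]][[1L]], trw_sets[[1L]][[2L]],
                             cfg$widths_s, cfg$n_null_maps, spec)
      other <- setdiff(names(profiles), names(profiles)[1L])
      lapply(other, function(nm)
        map_similarity(profiles[[1L]]$peak_width_s, profiles[[nm]]$peak_width_s,
                       mask, nulls))
    })
    spath <- file.path(out, "trw_similarity.tsv")
    utils::write.table(
      data.frame(pair = paste(names(profiles)[1L], setdiff(names(profiles), names(profiles)[1L]), sep = "-"),
                 rho = vapply(sims, `[[`, 0, "rho"),
                 p = vapply(sims, `[[`, 0, "p")),
      spath, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$outputs$trw_similarity <- spath
  }
  mpath <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  .log_stage("pipeline", "finished; manifest at %s", mpath)
  invisible(manifest)
}

.run_intercepts <- function(run_lengths) {
  run_id <- rep(seq_along(run_lengths), run_lengths)
  m <- matrix(0, sum(run_lengths), length(run_lengths))
  m[cbind(seq_along(run_id), run_id)] <- 1
  colnames(m) <- paste0("run", seq_along(run_lengths))
  m
}
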