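# Readers, writers, and the end-to-end pipeline driver.
#
# Tabular interchange is tidy CSV (subject, group, treatment, endpoint, day,
# value) and TSV for expression matrices (transcript ids in the first
# column) with a separate metadata TSV keyed by sample id. Videos travel as
# multi-page 32-bit float TIFF, affine-scaled to [0, 1], with a sidecar JSON
# recording the frame rate and the original intensity range (TIFF cannot
# carry the frame rate or out-of-range floats).

sidecar_path <- function(path) paste0(path, ".json")

#' Write a video stack as multi-page TIFF plus sidecar JSON
#'
#' Intensities are affine-scaled to \[0, 1\] and stored as 32-bit float; the
#' sidecar (`<path>.json`) records `fps` and the original range so
#' [read_video_stack()] can invert the scaling (exact to single precision).
#'
#' @param stack a [video_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_video_stack <- function(stack, path) {
  stop_if(!inherits(stack, "video_stack"), "'stack' must be a video_stack")
  lo <- min(stack$frames); hi <- max(stack$frames)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(stack$frames)[1]),
                  function(t) (stack$frames[t, , ] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(list(fps = stack$fps, intensity_min = lo,
                            intensity_max = hi,
                            n_frames = dim(stack$frames)[1],
                            height = dim(stack$frames)[2],
                            width = dim(stack$frames)[3]),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a video stack from multi-page TIFF
#'
#' @param path TIFF path; a sidecar `<path>.json` written by
#'   [write_video_stack()] supplies `fps` and the intensity range. Without a
#'   sidecar, `fps` must be given and intensities are used as stored.
#' @param fps frame rate in Hz, overriding/replacing the sidecar value.
#' @return a [video_stack()].
#' @export
read_video_stack <- function(path, fps = NULL) {
  stop_if(!file.exists(path), sprintf("no such file: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  shapes <- vapply(pages, function(p) paste(dim(p), collapse = "x"), "")
  stop_if(length(unique(shapes)) != 1,
          paste("non-uniform frame shapes:", paste(unique(shapes), collapse = ", ")))
  side <- NULL
  if (file.exists(sidecar_path(path)))
    side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  fps <- fps %||% side$fps
  stop_if(is.null(fps),
          paste("frame rate unknown: pass fps= or provide a sidecar JSON",
                "(written by write_video_stack) next to the TIFF"))
  frames <- aperm(simplify2array(pages), c(3L, 1L, 2L))
  if (!is.null(side) && !is.null(side$intensity_min))
    frames <- frames * (side$intensity_max - side$intensity_min) +
      side$intensity_min
  video_stack(frames, fps)
}

#' Write a frequency map as TSV (NA = inactive) plus sidecar JSON
#'
#' @param map a `"frequency_map"`.
#' @param path output TSV path.
#' @export
write_frequency_map <- function(map, path) {
  stop_if(!inherits(map, "frequency_map"), "'map' must be a frequency_map")
  utils::write.table(map$values, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(c(list(fps = map$fps), unclass(map$config)),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an expression matrix TSV and its sample-metadata TSV
#'
#' The matrix TSV carries transcript ids in the first column and one column
#' per sample; the metadata TSV is keyed by a `sample` column. Duplicate
#' transcript ids and samples without metadata are errors; surplus metadata
#' rows only warn.
#'
#' @param matrix_path,metadata_path input TSV paths.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(matrix_path, metadata_path) {
  raw <- read.delim(matrix_path, check.names = FALSE)
  stop_if(ncol(raw) < 2, "matrix TSV needs an id column plus sample columns")
  values <- as.matrix(raw[, -1, drop = FALSE])
  rownames(values) <- as.character(raw[[1]])
  stop_if(anyDuplicated(rownames(values)) > 0,
          paste("duplicate transcript ids in", matrix_path, ":",
                paste(unique(rownames(values)[duplicated(rownames(values))]),
                      collapse = ", ")))
  metadata <- read.delim(metadata_path, check.names = FALSE)
  expression_matrix(values, metadata)
}

#' Write an expression matrix and its metadata as TSV
#'
#' @param mat an [expression_matrix()].
#' @param matrix_path,metadata_path output TSV paths.
#' @export
write_expression <- function(mat, matrix_path, metadata_path) {
  stop_if(!inherits(mat, "expression_matrix"), "'mat' must be an expression_matrix")
  out <- data.frame(transcript = rownames(mat$values), mat$values,
                    check.names = FALSE)
  utils::write.table(out, matrix_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(mat$metadata, metadata_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(matrix_path)
}

#' Write a DE result as TSV
#'
#' @param de a `"de_result"`.
#' @param path output path.
#' @export
write_de_result <- function(de, path) {
  stop_if(!inherits(de, "de_result"), "'de' must be a de_result")
  utils::write.table(as.data.frame(de), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# -- pipeline -----------------------------------------------------------------

#' Demo pipeline configuration
#'
#' A small, fully seeded configuration exercising every stage on synthetic
#' data: one cilia video with two beating regions, a paired longitudinal
#' TEER-like endpoint, and a concordant two-cohort expression experiment.
#'
#' @return nested configuration list for [run_pipeline()].
#' @export
demo_config <- function() {
  list(
    seeds = list(video = 101L, longitudinal = 202L, expression = 303L,
                 classifier = 404L),
    video = list(height = 60L, width = 60L, n_frames = 256L, fps = 30,
                 noise_sd = 4, background_level = 100,
                 regions = list(
                   list(rows = c(6L, 25L), cols = c(6L, 25L), frequency = 8,
                        amplitude = 20, phase_jitter_sd = 0.5),
                   list(rows = c(36L, 50L), cols = c(31L, 55L), frequency = 12,
                        amplitude = 20, phase_jitter_sd = 0.5))),
    spectral = list(band_low = 2, band_high = 14, snr_threshold = 30),
    longitudinal = list(n_subjects_per_group = 3L, days = c(7, 14, 21, 28),
                        subject_sd = 40, residual_sd = 30,
                        within_subject_correlation = 0.5,
                        endpoint = "teer",
                        mean_curves = list(
                          HC.Air = c(420, 500, 560, 600),
                          HC.CS = c(300, 340, 370, 390),
                          COPD.Air = c(400, 470, 530, 570),
                          COPD.CS = c(290, 330, 360, 380))),
    expression = list(n_transcripts = 300L, n_signature = 40L,
                      effect_size = 2, invitro_donors = 4L,
                      invivo_smokers = 15L, invivo_nonsmokers = 15L,
                      platform_shift_sd = 2, noise_sd = 0.5,
                      discordant_fraction = 0.1),
    classification = list(folds = 10L, n_trees = 100L,
                          features_per_split = 10L, k_remove = 10L),
    q_cut = 0.05)
}

validate_config <- function(config) {
  stop_if(!is.list(config), "'config' must be a list (or a JSON/YAML path)")
  need_seeds <- c("video", "longitudinal", "expression", "classifier")
  have <- names(config$seeds %||% list())
  missing <- setdiff(need_seeds, have)
  stop_if(length(missing) > 0,
          paste("config is missing seed(s) for:", paste(missing, collapse = ", ")))
  for (s in need_seeds) check_number(config$seeds[[s]], paste0("seeds$", s))
  invisible(config)
}

read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    stop_if(!file.exists(config), sprintf("no such config file: %s", config))
    if (grepl("\\.ya?ml$", config)) {
      stop_if(!requireNamespace("yaml", quietly = TRUE),
              "the 'yaml' package is needed for YAML configs")
      config <- yaml::read_yaml(config)
    } else {
      config <- jsonlite::read_json(config, simplifyVector = TRUE,
                                    simplifyDataFrame = FALSE)
    }
  }
  validate_config(config)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full synthetic-data pipeline
#'
#' Executes the stages in order — simulate videos / longitudinal tables /
#' expression cohorts, compute the beat-frequency map and cilia summary,
#' adjusted-AUC contrast statistics, per-cohort differential expression, and
#' signature transfer (join + UPGMA clustering, random-forest classification
#' with top-k ablation, direction overlap) — writing every artifact plus a
#' manifest of inputs, seeds and versions to `out_dir`. Reruns with the same
#' configuration produce byte-identical outputs.
#'
#' @param config configuration list (see [demo_config()]) or path to a
#'   JSON/YAML file. Every stochastic stage must have a seed.
#' @param out_dir output directory (created if needed).
#' @return list of the in-memory stage results, invisibly; files in
#'   `out_dir` are the primary product.
#' @export
run_pipeline <- function(config = demo_config(), out_dir) {
  config <- read_config(config)
  stop_if(missing(out_dir), "'out_dir' is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)

  # -- stage: simulate --------------------------------------------------------
  sim <- run_stage("simulate", {
    vs <- config$video
    regions <- lapply(vs$regions, function(r)
      rect_region(vs$height, vs$width, r$rows[1]:r$rows[2],
                  r$cols[1]:r$cols[2], r$frequency, r$amplitude,
                  r$phase_jitter_sd %||% 0))
    video <- generate_cilia_video(cilia_video_spec(
      height = vs$height, width = vs$width, n_frames = vs$n_frames,
      fps = vs$fps, regions = regions,
      background_level = vs$background_level %||% 100,
      noise_sd = vs$noise_sd %||% 0, seed = config$seeds$video))
    ls_ <- config$longitudinal
    endpoints <- generate_longitudinal(longitudinal_spec(
      n_subjects_per_group = ls_$n_subjects_per_group, days = ls_$days,
      subject_sd = ls_$subject_sd, residual_sd = ls_$residual_sd,
      within_subject_correlation = ls_$within_subject_correlation,
      mean_curves = ls_$mean_curves, endpoint = ls_$endpoint,
      seed = config$seeds$longitudinal))
    es <- config$expression
    cohorts <- generate_two_cohort_expression(two_cohort_spec(
      n_transcripts = es$n_transcripts, n_signature = es$n_signature,
      effect_size = es$effect_size, invitro_donors = es$invitro_donors,
      invivo_smokers = es$invivo_smokers,
      invivo_nonsmokers = es$invivo_nonsmokers,
      platform_shift_sd = es$platform_shift_sd, noise_sd = es$noise_sd,
      discordant_fraction = es$discordant_fraction %||% 0,
      seed = config$seeds$expression))
    write_video_stack(video$stack, p("video.tif"))
    write.csv(endpoints, p("endpoints.csv"), row.names = FALSE)
    list(video = video, endpoints = endpoints, cohorts = cohorts)
  })

  # -- stage: cilia -----------------------------------------------------------
  cilia <- run_stage("cilia", {
    sc <- config$spectral
    cfg <- spectral_config(band_low = sc$band_low, band_high = sc$band_high,
                           snr_threshold = sc$snr_threshold)
    map <- compute_frequency_map(sim$video$stack, cfg)
    s <- summarize_cilia(map)
    write_frequency_map(map, p("frequency_map.tsv"))
    jsonlite::write_json(unclass(s), p("cilia_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    list(map = map, summary = s)
  })

  # -- stage: stats -----------------------------------------------------------
  stats_res <- run_stage("stats", {
    auc_tab <- adjusted_auc_table(sim$endpoints)
    fit <- fit_repeated_measures(auc_tab)
    contrasts <- lapply(fit$groups, function(g)
      unclass(test_one_sided(fit, g, direction = "lower")))
    names(contrasts) <- fit$groups
    write.csv(auc_tab, p("adjusted_auc.csv"), row.names = FALSE)
    jsonlite::write_json(contrasts, p("contrasts.json"), auto_unbox = TRUE,
                         digits = NA)
    list(auc = auc_tab, fit = fit, contrasts = contrasts)
  })

  # -- stage: de --------------------------------------------------------------
  de <- run_stage("de", {
    a <- expression_matrix(sim$cohorts$invitro$values,
                           sim$cohorts$invitro$metadata)
    b <- expression_matrix(sim$cohorts$invivo$values,
                           sim$cohorts$invivo$metadata)
    de_a <- fit_linear_de(a, c("smoke", "air"))
    de_b <- fit_linear_de(b, c("smoker", "nonsmoker"), donor_col = NULL)
    write_de_result(de_a, p("de_invitro.tsv"))
    write_de_result(de_b, p("de_invivo.tsv"))
    list(mat_a = a, mat_b = b, de_a = de_a, de_b = de_b)
  })

  # -- stage: transfer --------------------------------------------------------
  transfer <- run_stage("transfer", {
    cl <- config$classification
    joined <- join_and_cluster(de$de_a, de$de_b, de$mat_a, de$mat_b,
                               config$q_cut)
    labels <- factor(ifelse(
      c(de$mat_a$metadata$condition, de$mat_b$metadata$condition) %in%
        c("smoke", "smoker"), "exposed", "control"),
      levels = c("control", "exposed"))
    ab <- ablate_and_reclassify(
      joined$values, labels, signature = joined$transcripts,
      k_remove = min(cl$k_remove, length(joined$transcripts) - 1L),
      folds = cl$folds, n_trees = cl$n_trees,
      features_per_split = cl$features_per_split,
      seed = config$seeds$classifier)
    overlap <- direction_overlap(de$de_a, de$de_b, config$q_cut)
    utils::write.table(
      data.frame(transcript = rownames(joined$values), joined$values,
                 check.names = FALSE),
      p("joined_matrix.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(joined$clustering))
      write_newick(joined$clustering, p("dendrogram.nwk"))
    write.csv(ab$full$roc_points, p("roc_points.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(auc_full = ab$full$auc, auc_reduced = ab$reduced$auc,
           removed_features = ab$removed,
           confusion_full = as.data.frame(ab$full$confusion_matrix),
           cv_scheme = ab$full$cv_scheme, n_trees = ab$full$n_trees,
           features_per_split = ab$full$features_per_split,
           seed = ab$full$seed),
      p("classification.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(n_only_invitro = overlap$n_only_a, n_only_invivo = overlap$n_only_b,
           n_shared = overlap$n_shared, n_consistent = overlap$n_consistent,
           consistent_fraction = overlap$consistent_fraction),
      p("overlap.json"), auto_unbox = TRUE, digits = NA)
    list(joined = joined, classification = ab, overlap = overlap)
  })

  # -- manifest ---------------------------------------------------------------
  outputs <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    package = "aliSmoke",
    version = as.character(utils::packageVersion("aliSmoke")),
    seeds = config$seeds,
    config = config,
    outputs = lapply(setNames(outputs, outputs), function(f)
      unname(tools::md5sum(file.path(out_dir, f)))))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(simulate = sim, cilia = cilia, stats = stats_res, de = de,
                 transfer = transfer, manifest = manifest))
}
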