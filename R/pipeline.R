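# End-to-end orchestration: cohort -> ROI derivation -> feature extraction
# -> similarity -> robustness reporting.

#' Pipeline configuration
#'
#' Collects every setting of the analysis in one validated object. Exactly
#' one input mode is active: `"synthetic"` (phantom cohort generated from
#' `master_seed`) or `"labelmap"` (NIfTI volumes and reader labelmaps
#' listed in a JSON manifest).
#'
#' @param mode `"synthetic"` or `"labelmap"`.
#' @param n_lesions,master_seed,population_ranges,reader1,reader2 synthetic
#'   cohort settings, see [generate_cohort()].
#' @param input_dir directory containing `manifest.json` plus the NIfTI
#'   files (labelmap mode).
#' @param discretization a [discretization_config()].
#' @param do_2d,do_3d,do_circles analysis toggles.
#' @param icc_robust,mrc_robust robustness thresholds (ICC > 0.90,
#'   MRC < 10 percent).
#' @param min_diameter lesion exclusion threshold, mm.
#' @param out_dir output directory for report files, or `NULL` to skip
#'   writing.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "labelmap"),
                            n_lesions = 70L, master_seed = 1L,
                            population_ranges = list(),
                            reader1 = reader_perturbation(radial_bias = 0.3,
                                                          reader_id = "R1"),
                            reader2 = reader_perturbation(radial_bias = -0.3,
                                                          reader_id = "R2"),
                            input_dir = NULL,
                            discretization = discretization_config(),
                            do_2d = TRUE, do_3d = TRUE, do_circles = TRUE,
                            icc_robust = 0.90, mrc_robust = 10,
                            min_diameter = 10, out_dir = NULL) {
  mode <- match.arg(mode)
  if (mode == "labelmap" && is.null(input_dir))
    stop("labelmap mode requires input_dir")
  if (icc_robust <= 0 || mrc_robust <= 0 || min_diameter <= 0)
    stop("thresholds must be positive")
  if (!do_2d && !do_3d) stop("at least one of do_2d / do_3d must be TRUE")
  structure(list(mode = mode, n_lesions = as.integer(n_lesions),
                 master_seed = as.integer(master_seed),
                 population_ranges = population_ranges,
                 reader1 = reader1, reader2 = reader2,
                 input_dir = input_dir, discretization = discretization,
                 do_2d = do_2d, do_3d = do_3d, do_circles = do_circles,
                 icc_robust = icc_robust, mrc_robust = mrc_robust,
                 min_diameter = min_diameter, out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat keys mirror the [pipeline_config()] arguments; nested keys
#' `discretization:` (hu_min, hu_max, n_bins), `reader1:`/`reader2:`
#' (radial_bias, radial_jitter_sd, jitter_smoothness) and
#' `population_ranges:` override the respective defaults.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (k in c("mode", "n_lesions", "master_seed", "input_dir", "do_2d",
              "do_3d", "do_circles", "icc_robust", "mrc_robust",
              "min_diameter", "out_dir"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  if (!is.null(y$discretization))
    args$discretization <- do.call(discretization_config, y$discretization)
  for (r in c("reader1", "reader2"))
    if (!is.null(y[[r]]))
      args[[r]] <- do.call(reader_perturbation,
                           c(y[[r]], list(reader_id = toupper(r))))
  if (!is.null(y$population_ranges))
    args$population_ranges <- lapply(y$population_ranges, as.numeric)
  do.call(pipeline_config, args)
}

read_labelmap_cohort <- function(input_dir) {
  mf <- file.path(input_dir, "manifest.json")
  if (!file.exists(mf)) stop(sprintf("manifest not found: %s", mf))
  man <- jsonlite::read_json(mf)
  volumes <- r1 <- r2 <- list()
  ids <- character(0)
  patients <- character(0)
  errors <- list()
  for (les in man$lesions) {
    id <- les$id %||% sprintf("lesion%03d", length(ids) + 1L)
    res <- tryCatch({
      vol <- read_volume(file.path(input_dir, les$volume))
      m1 <- read_labelmap(file.path(input_dir, les$reader1_mask), vol,
                          reader_id = "R1")
      m2 <- read_labelmap(file.path(input_dir, les$reader2_mask), vol,
                          reader_id = "R2")
      list(vol = vol, m1 = m1, m2 = m2)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[id]] <- conditionMessage(res)
      next
    }
    volumes[[length(volumes) + 1L]] <- res$vol
    r1[[length(r1) + 1L]] <- res$m1
    r2[[length(r2) + 1L]] <- res$m2
    ids <- c(ids, id)
    patients <- c(patients, les$patient %||% id)
  }
  list(volumes = volumes, reader1_masks = r1, reader2_masks = r2,
       lesion_ids = ids, patients = patients, errors = errors)
}

features_to_row <- function(fv, lesion_id, reader_id, shape_tag, mode) {
  cbind(data.frame(lesion_id = lesion_id, reader_id = reader_id,
                   roi_shape = shape_tag, mode = mode,
                   stringsAsFactors = FALSE),
        as.data.frame(as.list(unclass(fv))))
}

#' Run the full robustness analysis pipeline
#'
#' Generates or ingests a two-reader cohort, applies the lesion exclusion
#' criterion, extracts the texture and morphology features from 3D ROIs,
#' largest-axial-slice 2D ROIs and (for the main lesions) the two circular
#' ROIs derived from reader 1's 2D ROI, computes contour similarity and the
#' per-feature robustness statistics, and writes the report bundle (CSV
#' tables, summary JSON, exclusion log, run manifest) to
#' `config$out_dir` when set. Synthetic-mode reruns with an identical
#' configuration are bit-identical.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with the cohort bookkeeping, feature table,
#'   similarity results, robustness tables, statistical tests, circular-ROI
#'   comparison and the per-stage log.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- list()
  if (config$mode == "synthetic") {
    cohort <- generate_cohort(config$n_lesions, config$master_seed,
                              config$population_ranges,
                              reader1 = config$reader1,
                              reader2 = config$reader2)
    volumes <- cohort$volumes
    m1 <- cohort$reader1_masks; m2 <- cohort$reader2_masks
    ids <- sprintf("lesion%03d", seq_along(volumes))
    patients <- ids  # one synthetic lesion per virtual patient
    log$input_errors <- list()
  } else {
    lm <- read_labelmap_cohort(config$input_dir)
    if (length(lm$volumes) == 0L)
      stop("no lesion could be read from the labelmap manifest")
    volumes <- lm$volumes; m1 <- lm$reader1_masks; m2 <- lm$reader2_masks
    ids <- lm$lesion_ids; patients <- lm$patients
    log$input_errors <- lm$errors
    cohort <- NULL
  }
  log$n_input <- length(volumes)

  # exclusion by reader 1 axial diameter (empty masks excluded outright)
  excl <- apply_exclusion_criteria(m1, min_diameter = config$min_diameter)
  excl$log$lesion_id <- ids
  keep <- excl$kept & vapply(m2, function(m) any(m$values), TRUE)
  volumes <- volumes[keep]; m1 <- m1[keep]; m2 <- m2[keep]
  ids <- ids[keep]; patients <- patients[keep]
  log$n_retained <- length(volumes)
  if (length(volumes) == 0L) stop("no lesion survived the exclusion criteria")

  dc <- config$discretization
  feat_rows <- list()
  f3_1 <- f3_2 <- f2_1 <- f2_2 <- list()
  m1_2d <- m2_2d <- list()
  for (i in seq_along(volumes)) {
    if (config$do_3d) {
      f3_1[[i]] <- extract_features(volumes[[i]], m1[[i]], dc, mode = "3D")
      f3_2[[i]] <- extract_features(volumes[[i]], m2[[i]], dc, mode = "3D")
      feat_rows[[length(feat_rows) + 1L]] <-
        features_to_row(f3_1[[i]], ids[i], "R1", "manual", "3D")
      feat_rows[[length(feat_rows) + 1L]] <-
        features_to_row(f3_2[[i]], ids[i], "R2", "manual", "3D")
    }
    if (config$do_2d) {
      m1_2d[[i]] <- largest_axial_cross_section(m1[[i]])
      m2_2d[[i]] <- largest_axial_cross_section(m2[[i]])
      f2_1[[i]] <- extract_features(volumes[[i]], m1_2d[[i]], dc, mode = "2D")
      f2_2[[i]] <- extract_features(volumes[[i]], m2_2d[[i]], dc, mode = "2D")
      feat_rows[[length(feat_rows) + 1L]] <-
        features_to_row(f2_1[[i]], ids[i], "R1", "manual", "2D")
      feat_rows[[length(feat_rows) + 1L]] <-
        features_to_row(f2_2[[i]], ids[i], "R2", "manual", "2D")
    }
  }
  log$n_clamped_voxels <- sum(vapply(c(f3_1, f3_2, f2_1, f2_2),
                                     function(f) attr(f, "n_clamped") %||% 0L, 0L))

  to_matrix <- function(lst) {
    m <- do.call(rbind, lapply(lst, unclass))
    rownames(m) <- ids
    m
  }

  similarity <- list(); tests <- list(); robustness <- list()
  size_report <- list()
  if (config$do_3d) {
    similarity$`3D` <- cohort_similarity(m1, m2, mode = "3D", lesion_ids = ids)
    tab3 <- paired_feature_table(to_matrix(f3_1), to_matrix(f3_2),
                                 lesion_ids = ids, roi_mode = "3D")
    robustness$`3D` <- robustness_table(tab3, config$icc_robust,
                                        config$mrc_robust)
    tests$spearman_dc_hd_3d <-
      spearman_rho(similarity$`3D`$per_lesion$dice,
                   similarity$`3D`$per_lesion$avg_hausdorff_mm)
    sizes3 <- data.frame(
      axial_diameter_mm = vapply(m1, axial_diameter_mm, 0),
      max_3d_diameter_mm = vapply(m1, max_3d_diameter_mm, 0),
      volume_or_area = vapply(m1, function(m)
        n_foreground(m) * prod(m$spacing) / 1000, 0))
    size_report$`3D` <- size_agreement_analysis(
      sizes3, similarity$`3D`$per_lesion, roi_mode = "3D")
  }
  if (config$do_2d) {
    similarity$`2D` <- cohort_similarity(m1_2d, m2_2d, mode = "2D",
                                         lesion_ids = ids)
    tab2 <- paired_feature_table(to_matrix(f2_1), to_matrix(f2_2),
                                 lesion_ids = ids, roi_mode = "2D")
    robustness$`2D` <- robustness_table(tab2, config$icc_robust,
                                        config$mrc_robust)
    tests$spearman_dc_hd_2d <-
      spearman_rho(similarity$`2D`$per_lesion$dice,
                   similarity$`2D`$per_lesion$avg_hausdorff_mm)
    sizes2 <- data.frame(
      axial_diameter_mm = vapply(m1_2d, axial_diameter_mm, 0),
      max_3d_diameter_mm = vapply(m1, max_3d_diameter_mm, 0),
      volume_or_area = vapply(m1_2d, function(m)
        n_foreground(m) * prod(m$spacing[1:2]) / 100, 0))
    size_report$`2D` <- size_agreement_analysis(
      sizes2, similarity$`2D`$per_lesion, roi_mode = "2D")
  }
  if (config$do_2d && config$do_3d) {
    tests$wilcoxon_dice_2d_vs_3d <-
      wilcoxon_signed_rank(similarity$`2D`$per_lesion$dice,
                           similarity$`3D`$per_lesion$dice)
    tests$wilcoxon_hd_2d_vs_3d <-
      wilcoxon_signed_rank(similarity$`2D`$per_lesion$avg_hausdorff_mm,
                           similarity$`3D`$per_lesion$avg_hausdorff_mm)
  }

  circular <- NULL
  if (config$do_circles && config$do_2d) {
    # main lesion per patient: largest reader-1 3D volume
    vol_vox <- vapply(m1, n_foreground, 0L)
    main_idx <- vapply(split(seq_along(ids), patients),
                       function(g) g[which.max(vol_vox[g])], 0L)
    main_idx <- sort(unname(main_idx))
    fe <- fi <- list()
    skipped <- character(0)
    for (i in main_idx) {
      res <- tryCatch({
        enc <- min_enclosing_circle_roi(m1_2d[[i]])
        ins <- max_inscribed_circle_roi(m1_2d[[i]])
        list(enc = extract_features(volumes[[i]], enc, dc, mode = "2D"),
             ins = extract_features(volumes[[i]], ins, dc, mode = "2D"))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        skipped <- c(skipped, ids[i])
        next
      }
      fe[[length(fe) + 1L]] <- res$enc
      fi[[length(fi) + 1L]] <- res$ins
      attr(fe[[length(fe)]], "lesion") <- i
    }
    used <- vapply(fe, function(f) attr(f, "lesion"), 0L)
    if (length(used)) {
      mm <- function(lst) do.call(rbind, lapply(lst, unclass))
      circular <- circular_roi_comparison(
        mm(f2_1[used]), mm(f2_2[used]), mm(fe), mm(fi))
    }
    log$circular_main_lesions <- length(used)
    log$circular_skipped <- skipped
  }

  features <- do.call(rbind, feat_rows)
  result <- list(config = config, lesion_ids = ids,
                 features = features, similarity = similarity,
                 robustness = robustness, tests = tests,
                 size_agreement = size_report, circular = circular,
                 exclusion_log = excl$log, log = log, cohort = cohort)
  if (!is.null(config$out_dir)) write_report_bundle(result, config$out_dir)
  invisible(result)
}

write_report_bundle <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  wcsv(result$features, "features.csv")
  sim <- do.call(rbind, lapply(result$similarity, `[[`, "per_lesion"))
  if (!is.null(sim)) wcsv(sim, "similarity.csv")
  for (mode in names(result$robustness))
    wcsv(result$robustness[[mode]],
         sprintf("robustness_%s.csv", tolower(mode)))
  if (!is.null(result$circular)) wcsv(result$circular, "circular_comparison.csv")
  sz <- do.call(rbind, result$size_agreement)
  if (!is.null(sz)) wcsv(sz, "size_agreement.csv")
  wcsv(result$exclusion_log, "exclusion_log.csv")
  summaries <- list(
    similarity = lapply(result$similarity, `[[`, "summary"),
    tests = result$tests, log = result$log)
  jsonlite::write_json(summaries, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("texrob")),
    mode = result$config$mode,
    master_seed = result$config$master_seed,
    n_lesions_requested = result$config$n_lesions,
    lesion_ids = result$lesion_ids,
    thresholds = list(icc_robust = result$config$icc_robust,
                      mrc_robust = result$config$mrc_robust,
                      min_diameter = result$config$min_diameter),
    discretization = unclass(result$config$discretization))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}
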