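# Readers/writers for the pipeline's on-disk formats (NIfTI, counts TSV,
# GMT, labels CSV) and the end-to-end orchestrator.

#' Read an aligned NIfTI volume/mask pair
#'
#' Validates grid alignment, binarizes the mask at `> 0`, and carries voxel
#' spacing (mm) from the volume header.
#'
#' @param volume_path,mask_path Paths to NIfTI files.
#' @param case_id Case identifier (defaults to the volume file stem).
#' @return List with `volume` ([image_volume()]) and `mask`
#'   ([tumor_mask()]).
#' @export
read_nifti_pair <- function(volume_path, mask_path, case_id = NULL) {
  for (p in c(volume_path, mask_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  v <- RNifti::readNifti(volume_path)
  m <- RNifti::readNifti(mask_path)
  if (!identical(dim(v), dim(m))) {
    stop(sprintf("volume grid %s and mask grid %s are not aligned (%s, %s)",
                 paste(dim(v), collapse = "x"), paste(dim(m), collapse = "x"),
                 volume_path, mask_path))
  }
  if (any(!is.finite(v))) stop("non-finite voxels in ", volume_path)
  cid <- case_id %||% sub("\\.nii(\\.gz)?$", "", basename(volume_path))
  sp <- RNifti::pixdim(v)[1:3]
  list(volume = image_volume(array(as.numeric(v), dim(v)), sp, cid),
       mask = tumor_mask(array(m > 0, dim(m)), cid))
}

#' Write a volume/mask pair as NIfTI
#'
#' @param volume An [image_volume()].
#' @param mask A [tumor_mask()].
#' @param volume_path,mask_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_nifti_pair <- function(volume, mask, volume_path, mask_path) {
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, volume_path)
  mi <- RNifti::asNifti(array(as.integer(mask$data), dim(mask$data)))
  RNifti::pixdim(mi) <- volume$spacing
  RNifti::writeNifti(mi, mask_path)
  invisible(c(volume_path, mask_path))
}

#' Read a genes-by-samples count matrix (TSV)
#'
#' First column = gene ids, header row = sample ids. Negative entries and
#' duplicate identifiers are rejected.
#'
#' @param path TSV file path.
#' @return Integer matrix with gene rownames and sample colnames.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "numeric"
  if (any(!is.finite(m)) || any(m < 0) || any(m != round(m))) {
    stop("counts must be non-negative integers: ", path)
  }
  if (anyDuplicated(genes)) stop("duplicate gene ids in ", path)
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids in ", path)
  rownames(m) <- genes
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_counts
#' @param counts Integer matrix to write.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write GMT gene-set collections
#'
#' One set per line: `name<TAB>description<TAB>gene1<TAB>gene2...`. Empty
#' sets are rejected.
#'
#' @param path GMT file path.
#' @return Named list of character gene vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("GMT line with empty gene set: ", f[1])
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  if (anyDuplicated(names(sets))) stop("duplicate set names in ", path)
  sets
}

#' @rdname read_gmt
#' @param sets Named list of gene vectors to write.
#' @export
write_gmt <- function(sets, path) {
  writeLines(vapply(names(sets), function(nm) {
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t")
  }, ""), path)
  invisible(path)
}

#' Read stage labels, mapping raw TNM stages to the binary convention
#'
#' CSV with columns `case_id` and `stage`. Stages may be given directly as
#' `intra`/`extra` or as TNM codes, mapped per the adopted convention:
#' Ta, Tis, T1, T2 are intra-vesical; T3, T4, N+ and M+ are extra-vesical.
#'
#' @param path CSV file path.
#' @return Named character vector of `"intra"`/`"extra"` labels.
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("case_id", "stage") %in% names(df))) {
    stop("labels file needs columns case_id and stage: ", path)
  }
  if (anyDuplicated(df$case_id)) stop("duplicate case ids in ", path)
  stats::setNames(vapply(df$stage, map_stage_label, ""), df$case_id)
}

map_stage_label <- function(stage) {
  s <- toupper(trimws(stage))
  if (s %in% c("INTRA", "INTRA_VESICAL")) return("intra")
  if (s %in% c("EXTRA", "EXTRA_VESICAL")) return("extra")
  if (s %in% c("TA", "TIS", "T1", "T2")) return("intra")
  if (s %in% c("T3", "T4", "N+", "M+")) return("extra")
  stop("unknown stage label: ", stage)
}

#' @rdname read_labels
#' @param labels Named label vector to write.
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(data.frame(case_id = names(labels), stage = unname(labels)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a synthetic cohort to disk
#'
#' NIfTI volume/mask pairs, counts TSV, labels CSV, GMT gene sets and a
#' truth JSON, in the layout the pipeline readers expect.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(cohort$volumes)) {
    img_dir <- file.path(dir, "images"); msk_dir <- file.path(dir, "masks")
    dir.create(img_dir, showWarnings = FALSE); dir.create(msk_dir, showWarnings = FALSE)
    for (cid in names(cohort$volumes)) {
      write_nifti_pair(cohort$volumes[[cid]], cohort$masks[[cid]],
                       file.path(img_dir, paste0(cid, ".nii")),
                       file.path(msk_dir, paste0(cid, ".nii")))
    }
  }
  write_counts(cohort$counts, file.path(dir, "counts.tsv"))
  write_labels(cohort$labels, file.path(dir, "labels.csv"))
  write_gmt(cohort$gene_sets, file.path(dir, "gene_sets.gmt"))
  truth <- cohort$truth
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Default end-to-end pipeline configuration
#'
#' Built from the structured text default shipped with the package
#' (`inst/config/default.yaml`): a compact synthetic run with small cohort
#' volumes, a restricted radiomic grid and the NB classifier. A custom
#' YAML file may supply any subset of the same keys; function arguments
#' override the file. Every randomized stage derives its stream from
#' `seed`.
#'
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @param config_file Optional YAML file overriding the packaged default.
#' @param ... Overrides for any top-level config entry.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, out_dir = tempfile("rgstage_run_"),
                            config_file = NULL, ...) {
  y <- yaml::read_yaml(system.file("config", "default.yaml",
                                   package = "rgstage"))
  if (!is.null(config_file)) {
    y <- utils::modifyList(y, yaml::read_yaml(config_file))
  }
  mk_cohort <- function(over, seed) {
    args <- utils::modifyList(y$cohort, over)
    args$volume_shape <- unlist(args$volume_shape)
    args$voxel_spacing <- unlist(args$voxel_spacing)
    args$seed <- seed
    do.call(cohort_config, args)
  }
  cfg <- list(
    seed = as.integer(seed),
    out_dir = out_dir,
    cohort = mk_cohort(list(), seed),
    test_cohort = mk_cohort(y$test_cohort, seed + 1),
    grid = radiomic_grid(bin_exponents = unlist(y$grid$bin_exponents),
                         kernels = unlist(y$grid$kernels),
                         angles = unlist(y$grid$angles),
                         families = unlist(y$grid$families)),
    k_target = y$selection$k_target, alpha = y$selection$alpha,
    r_threshold = y$selection$r_threshold,
    family = y$model$family,
    model = model_config(cap = y$model$cap, folds = y$model$folds,
                         seed = seed))
  over <- list(...)
  cfg[names(over)] <- over
  class(cfg) <- "pipeline_config"
  cfg
}

extract_cohort_features <- function(cohort, grid) {
  do.call(rbind, lapply(names(cohort$volumes), function(cid) {
    extract_all(cohort$volumes[[cid]], cohort$masks[[cid]], grid)
  }))
}

# Genomic predictors for the staging model: normalized log expression of
# the screened DEGs (smallest adjusted p first, capped at k_target).
genomic_feature_matrix <- function(counts, de, k_target) {
  de_ok <- de[!de$skipped & !is.na(de$adj_p), , drop = FALSE]
  de_ok <- de_ok[order(de_ok$adj_p, de_ok$p_value, de_ok$gene), , drop = FALSE]
  genes <- utils::head(de_ok$gene, k_target)
  t(normalize_expression(counts)[genes, , drop = FALSE])
}

#' Run the whole radiogenomic pipeline on a synthetic cohort
#'
#' Simulate (train + external test cohorts) -> radiomic extraction ->
#' genomic analysis (DE, ssGSEA, stage test) -> feature screening and
#' selection -> capped RFE training -> external evaluation. Every stage
#' writes its outputs before the next starts; a manifest with per-file
#' checksums makes reruns diffable, and a rerun with the same configuration
#' reproduces every output checksum.
#'
#' @param config A [pipeline_config()].
#' @return The manifest (list), invisibly written as `manifest.json`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  emit <- function(p) { paths <<- c(paths, p); p }

  # stage 1: simulate
  train <- generate_cohort(config$cohort)
  test <- generate_cohort(config$test_cohort, truth = train$truth$de_genes,
                          baseline = train$baseline_q)
  write_cohort(train, emit(file.path(out, "train")))
  write_cohort(test, emit(file.path(out, "test")))

  # stage 2: radiomics
  feat_train <- extract_cohort_features(train, config$grid)
  feat_test <- extract_cohort_features(test, config$grid)
  utils::write.csv(feat_train, emit(file.path(out, "features_train.csv")),
                   row.names = FALSE)
  utils::write.csv(feat_test, emit(file.path(out, "features_test.csv")),
                   row.names = FALSE)

  # stage 3: genomics
  de <- nb_wald_de(train$counts, train$labels)
  utils::write.csv(de, emit(file.path(out, "de_results.csv")), row.names = FALSE)
  expr <- normalize_expression(train$counts)
  scores <- ssgsea_scores(expr, train$gene_sets)
  utils::write.csv(data.frame(signature = rownames(scores), scores,
                              check.names = FALSE),
                   emit(file.path(out, "ssgsea_scores.csv")), row.names = FALSE)
  stage_test <- signature_stage_test(scores, train$labels)
  utils::write.csv(stage_test, emit(file.path(out, "signature_stage_test.csv")),
                   row.names = FALSE)

  # stage 4: radiomic feature selection
  sel <- select_radiomic_features(feat_train, train$labels,
                                  k_target = config$k_target,
                                  alpha = config$alpha,
                                  r_threshold = config$r_threshold,
                                  seed = config$seed)
  utils::write.csv(sel$screening, emit(file.path(out, "screening.csv")),
                   row.names = FALSE)
  utils::write.csv(sel$manhattan, emit(file.path(out, "manhattan.csv")),
                   row.names = FALSE)
  jsonlite::write_json(sel$selected$feature_id,
                       emit(file.path(out, "selected_features.json")),
                       auto_unbox = FALSE)

  # stage 5: train
  g_train <- genomic_feature_matrix(train$counts, de, config$k_target)
  r_train <- features_wide(feat_train)[, sel$selected$feature_id, drop = FALSE]
  model <- train_rfe(g_train, r_train, train$labels, config$family, config$model)
  jsonlite::write_json(
    list(family = model$family, selected_genomic = model$selected_genomic,
         selected_radiomic = model$selected_radiomic,
         metadata = model$metadata),
    emit(file.path(out, "model.json")), auto_unbox = TRUE, digits = NA)

  # stage 6: external evaluation (frozen predictor set)
  g_test <- t(normalize_expression(test$counts)[colnames(g_train), , drop = FALSE])
  r_test <- features_wide(feat_test)[, sel$selected$feature_id, drop = FALSE]
  x_test <- cbind(g_test, r_test)
  pred <- predict(model, x_test)
  metrics <- evaluate_predictions(pred, test$labels)
  jsonlite::write_json(metrics, emit(file.path(out, "metrics.json")),
                       auto_unbox = TRUE, digits = NA)

  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out, "manifest.json"))
  manifest <- list(
    config_hash = unname(tools::md5sum(write_config_tmp(config))),
    package_version = as.character(utils::packageVersion("rgstage")),
    seed = config$seed,
    timestamp = format(Sys.time(), tz = "UTC"),
    checksums = as.list(stats::setNames(unname(tools::md5sum(files)),
                                        substring(files, nchar(out) + 2L))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

write_config_tmp <- function(config) {
  tmp <- tempfile(fileext = ".json")
  cfg <- config
  cfg$out_dir <- NULL    # the hash identifies the analysis, not its location
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  tmp
}
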