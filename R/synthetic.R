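# Seeded synthetic radiogenomic cohorts with known ground truth.
#
# The generator emulates the structure of a two-center bladder-cancer study:
# per-case T2-weighted-like MR volumes with delineated tumors, a bulk
# RNA-seq count matrix over the same cases, and a catalog of gene sets.
# Class-discriminative signal is planted where the configuration asks for
# it: tumor texture (correlation length and marginal variance of the
# intensity field) separates the classes while tumor size does not, and a
# configurable number of genes carry a planted log2 fold change.

# Genes reported stage-associated in bladder cancer; always present in the
# synthetic gene universe and planted with these directions whenever effects
# are planted at all.
STAGE_GENES_UP_IN_LOW <- c("HOXB5", "DHRS3", "FABP4")
STAGE_GENES_UP_IN_HIGH <- c("TAGLN2", "HIST1H1D", "HIST1H2BD", "H2AFX",
                            "CLDN3", "PLAUR")

#' Configuration for a synthetic radiogenomic cohort
#'
#' Defaults mirror the study conditions: 18 intra-vesical and 10
#' extra-vesical training cases, modest MR volumes, a clearly detectable
#' texture separation, 2000 genes with 50 planted DEGs at log2 fold change
#' 2, NB dispersion 0.1 (typical bulk RNA-seq), and 20 gene sets of 25
#' genes.
#'
#' @param n_intra,n_extra Cases per class (each >= 2).
#' @param volume_shape Integer length-3 voxel grid (slice, row, col), each
#'   >= 16 for volume generation.
#' @param voxel_spacing Numeric length-3 spacing in mm.
#' @param texture_effect Dimensionless separation of the class texture
#'   parameters; 0 means the classes are exchangeable.
#' @param n_genes,n_de_genes Gene universe size and planted DEG count
#'   (`n_de_genes` must be 0 or >= 9 so the nine canonical stage genes are
#'   always part of the planted set).
#' @param log2fc Planted log2 fold change magnitude (0 disables planting).
#' @param nb_dispersion NB dispersion alpha >= 0 (0 = Poisson limit).
#' @param n_gene_sets,set_size Gene-set catalog dimensions.
#' @param seed Integer master seed; every sub-stream is derived from it.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_intra = 18, n_extra = 10,
                          volume_shape = c(16, 32, 32),
                          voxel_spacing = c(3, 1, 1),
                          texture_effect = 1.5,
                          n_genes = 2000, n_de_genes = 50, log2fc = 2,
                          nb_dispersion = 0.1,
                          n_gene_sets = 20, set_size = 25,
                          seed = 1) {
  cfg <- list(n_intra = as.integer(n_intra), n_extra = as.integer(n_extra),
              volume_shape = as.integer(volume_shape),
              voxel_spacing = as.numeric(voxel_spacing),
              texture_effect = as.numeric(texture_effect),
              n_genes = as.integer(n_genes),
              n_de_genes = as.integer(n_de_genes),
              log2fc = as.numeric(log2fc),
              nb_dispersion = as.numeric(nb_dispersion),
              n_gene_sets = as.integer(n_gene_sets),
              set_size = as.integer(set_size),
              seed = as.integer(seed))
  if (cfg$n_intra < 2 || cfg$n_extra < 2) {
    stop("cohort_config: need at least 2 cases per class")
  }
  if (length(cfg$volume_shape) != 3 || any(cfg$volume_shape <= 0) ||
      length(cfg$voxel_spacing) != 3 || any(cfg$voxel_spacing <= 0)) {
    stop("cohort_config: volume_shape and voxel_spacing must be 3 positive values")
  }
  if (cfg$n_de_genes > cfg$n_genes) {
    stop("cohort_config: n_de_genes must not exceed n_genes")
  }
  if (cfg$n_de_genes != 0 && cfg$n_de_genes < 9) {
    stop("cohort_config: n_de_genes must be 0 or >= 9 (the nine canonical stage genes are always planted)")
  }
  if (cfg$nb_dispersion < 0 || cfg$texture_effect < 0) {
    stop("cohort_config: texture_effect and nb_dispersion must be >= 0")
  }
  if (cfg$set_size > cfg$n_genes) {
    stop("cohort_config: set_size must not exceed n_genes")
  }
  class(cfg) <- "cohort_config"
  cfg
}

#' Generate one synthetic tumor volume and mask
#'
#' The mask is a randomly oriented ellipsoid-like blob (boundary perturbed
#' by a smooth random field) whose size distribution does not depend on the
#' class, so tumor size carries no signal. Intensities inside the mask are
#' a stationary correlated Gaussian random field (smoothed white noise)
#' whose correlation length and marginal standard deviation both grow with
#' `texture_effect` for extra-vesical cases; texture therefore carries the
#' class signal.
#'
#' @param class_label `"intra"` or `"extra"`.
#' @param config A [cohort_config()] with `volume_shape >= 16` per axis.
#' @param case_seed Integer seed for this case.
#' @return List with elements `volume` ([image_volume()]) and `mask`
#'   ([tumor_mask()]).
#' @export
generate_tumor_volume <- function(class_label, config, case_seed) {
  if (any(config$volume_shape < 16)) {
    stop("volume generation needs volume_shape >= 16 voxels per axis")
  }
  is_extra <- identical(class_label, "extra")
  for (attempt in 0:4) {
    set.seed((case_seed + attempt * 7777) %% 2147483647)
    out <- try(make_tumor_volume(is_extra, config), silent = TRUE)
    if (!inherits(out, "try-error")) return(out)
  }
  stop("degenerate tumor volume after 5 attempts: ", attr(out, "condition")$message)
}

make_tumor_volume <- function(is_extra, config) {
  d <- config$volume_shape
  # class-independent ellipsoid: semi-axes ~ 22-34% of each extent
  semi <- d * stats::runif(3, 0.22, 0.34)
  ctr <- d / 2 + stats::runif(3, -1.5, 1.5)
  ax <- array(rep(seq_len(d[1]), times = d[2] * d[3]), d)
  ay <- array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), d)
  az <- array(rep(seq_len(d[3]), each = d[1] * d[2]), d)
  r2 <- ((ax - ctr[1]) / semi[1])^2 + ((ay - ctr[2]) / semi[2])^2 +
        ((az - ctr[3]) / semi[3])^2
  bump <- smooth3d(array(stats::rnorm(prod(d)), d), 2.0)
  bump <- bump / max(stats::sd(bump), 1e-12)
  m <- r2 <= 1 + 0.15 * bump
  if (sum(m) < 100) stop("mask below 100 voxels")
  # texture: correlation length and amplitude scale with the class effect
  te <- if (is_extra) config$texture_effect else 0
  sigma <- 0.8 * (1 + 0.5 * te)
  amp <- 0.12 * (1 + 0.25 * te)
  field <- smooth3d(array(stats::rnorm(prod(d)), d), sigma)
  field <- field / max(stats::sd(field), 1e-12)
  vox <- 0.5 + amp * field
  vox[!m] <- 0.15 + 0.03 * stats::rnorm(sum(!m))   # dim background
  if (length(unique(vox[m])) < 2) stop("mask has fewer than 2 distinct intensities")
  list(volume = image_volume(vox, config$voxel_spacing),
       mask = tumor_mask(m))
}

#' Generate a synthetic RNA-seq count matrix with planted DEGs
#'
#' Counts follow `K_gj ~ NB(mean = s_j * q_g * 2^(beta_g * x_j), dispersion
#' alpha)` with `x_j = 1` for extra-vesical samples, baseline abundances
#' `q_g` log-normal, and library-size factors `s_j` log-uniform in
#' `[0.5, 2]`. Planted DEGs split between up-in-high and up-in-low; the
#' nine canonical stage genes are always present and, when effects are
#' planted, carry their reported directions.
#'
#' @param config A [cohort_config()].
#' @param labels Character vector of `"intra"`/`"extra"` per sample.
#' @param truth Optional planted-DEG data.frame (columns `gene`,
#'   `direction`) from a previous cohort, so an external-validation cohort
#'   shares the training cohort's biology while drawing new patients.
#' @param baseline Optional named vector of baseline abundances `q_g` to
#'   reuse (per-gene expression level is transcriptome biology, shared by
#'   training and external cohorts).
#' @return List with `counts` (integer genes x samples matrix), `truth`
#'   (data.frame gene/direction of planted DEGs), `baseline_q` and
#'   `size_factors_true`.
#' @export
generate_counts <- function(config, labels, truth = NULL, baseline = NULL) {
  stopifnot(all(labels %in% c("intra", "extra")))
  set.seed(derive_seed(config$seed, "counts"))
  ng <- config$n_genes
  ns <- length(labels)
  nine <- c(STAGE_GENES_UP_IN_LOW, STAGE_GENES_UP_IN_HIGH)
  genes <- c(nine, sprintf("GENE%05d", seq_len(ng - length(nine))))
  beta <- stats::setNames(rep(0, ng), genes)
  if (!is.null(truth)) {
    stopifnot(all(truth$gene %in% genes))
    beta[truth$gene[truth$direction == "up_in_high"]] <- config$log2fc
    beta[truth$gene[truth$direction == "up_in_low"]] <- -config$log2fc
  } else if (config$log2fc > 0 && config$n_de_genes > 0) {
    extra_n <- config$n_de_genes - length(nine)
    others <- if (extra_n > 0) sample(genes[-seq_along(nine)], extra_n) else character(0)
    up_low <- c(STAGE_GENES_UP_IN_LOW, others[seq_len(floor(length(others) / 2))])
    up_high <- c(STAGE_GENES_UP_IN_HIGH, setdiff(others, up_low))
    beta[up_high] <- config$log2fc
    beta[up_low] <- -config$log2fc
    truth <- data.frame(
      gene = c(up_high, up_low),
      direction = rep(c("up_in_high", "up_in_low"), c(length(up_high), length(up_low))),
      stringsAsFactors = FALSE)
  }
  if (is.null(truth)) {
    truth <- data.frame(gene = character(0), direction = character(0),
                        stringsAsFactors = FALSE)
  }
  q <- baseline %||% stats::setNames(
    stats::rlnorm(ng, meanlog = log(200), sdlog = 1.2), genes)
  stopifnot(identical(names(q), genes))
  s <- exp(stats::runif(ns, log(0.5), log(2)))
  x <- as.numeric(labels == "extra")
  mu <- outer(unname(q), s) * 2^(outer(beta, x))
  k <- if (config$nb_dispersion > 0) {
    stats::rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
  } else {
    stats::rpois(length(mu), lambda = mu)
  }
  counts <- matrix(as.integer(k), ng, ns,
                   dimnames = list(genes, names(labels) %||%
                                     sprintf("S%03d", seq_len(ns))))
  list(counts = counts, truth = truth, baseline_q = q,
       size_factors_true = s)
}

#' Generate a gene-set catalog with planted enriched sets
#'
#' When DEG truth is non-empty the catalog contains one set enriched in
#' up-in-high genes (`SIG_UP_HIGH`) and one in up-in-low genes
#' (`SIG_UP_LOW`), padded with random genes up to `set_size`; remaining
#' sets are random draws from the gene universe. With empty truth all sets
#' are random.
#'
#' @param truth DEG truth data.frame from [generate_counts()].
#' @param config A [cohort_config()].
#' @param genes Character vector, the gene universe.
#' @return Named list of character vectors (a `SignatureCollection`);
#'   attribute `enriched` names the planted sets.
#' @export
generate_gene_sets <- function(truth, config, genes) {
  if (config$set_size > length(genes)) {
    stop("set_size exceeds the gene universe")
  }
  set.seed(derive_seed(config$seed, "sets"))
  sets <- list()
  enriched <- character(0)
  pad <- function(core) {
    pool <- setdiff(genes, core)
    c(core, sample(pool, max(0, config$set_size - length(core))))[
      seq_len(min(config$set_size, length(genes)))]
  }
  if (nrow(truth) > 0) {
    up_high <- truth$gene[truth$direction == "up_in_high"]
    up_low <- truth$gene[truth$direction == "up_in_low"]
    sets[["SIG_UP_HIGH"]] <- pad(up_high[seq_len(min(length(up_high), config$set_size))])
    sets[["SIG_UP_LOW"]] <- pad(up_low[seq_len(min(length(up_low), config$set_size))])
    enriched <- c("SIG_UP_HIGH", "SIG_UP_LOW")
  }
  while (length(sets) < config$n_gene_sets) {
    sets[[sprintf("SIG_RANDOM_%02d", length(sets) - length(enriched) + 1L)]] <-
      sample(genes, config$set_size)
  }
  sets <- sets[seq_len(config$n_gene_sets)]
  attr(sets, "enriched") <- intersect(enriched, names(sets))
  sets
}

#' Generate a full synthetic radiogenomic cohort
#'
#' Assembles per-case tumor volumes and masks, an NB count matrix, stage
#' labels and a gene-set catalog, with ground truth for every planted
#' effect. The same configuration (including seed) reproduces the cohort
#' bit for bit; per-case sub-seeds are derived by fixed arithmetic so the
#' cases are independent streams.
#'
#' @param config A [cohort_config()].
#' @param volumes Set `FALSE` to skip image generation (counts-only
#'   cohorts are much faster when images are not needed).
#' @param truth Optional planted-DEG truth to reuse (external-validation
#'   cohorts share the training cohort's biology).
#' @param baseline Optional baseline abundances to reuse (see
#'   [generate_counts()]).
#' @return A list of class `synthetic_cohort` with elements `volumes`,
#'   `masks`, `counts`, `labels`, `gene_sets`, `truth`, `baseline_q` and
#'   `config`.
#' @export
generate_cohort <- function(config, volumes = TRUE, truth = NULL,
                            baseline = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_intra + config$n_extra
  case_ids <- sprintf("CASE%03d", seq_len(n))
  labels <- stats::setNames(
    rep(c("intra", "extra"), c(config$n_intra, config$n_extra)), case_ids)
  vols <- masks <- NULL
  if (volumes) {
    vols <- vector("list", n); masks <- vector("list", n)
    for (i in seq_len(n)) {
      vm <- generate_tumor_volume(labels[[i]], config,
                                  derive_seed(config$seed, "volume", i))
      vm$volume$case_id <- case_ids[i]
      vm$mask$case_id <- case_ids[i]
      vols[[i]] <- vm$volume; masks[[i]] <- vm$mask
    }
    names(vols) <- names(masks) <- case_ids
  }
  cnt <- generate_counts(config, labels, truth = truth, baseline = baseline)
  sets <- generate_gene_sets(cnt$truth, config, rownames(cnt$counts))
  truth <- list(
    de_genes = cnt$truth,
    enriched_sets = attr(sets, "enriched"),
    texture_effect = config$texture_effect,
    discriminative_texture = config$texture_effect > 0)
  structure(list(volumes = vols, masks = masks, counts = cnt$counts,
                 labels = labels, gene_sets = sets, truth = truth,
                 baseline_q = cnt$baseline_q, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_cohort: %d intra + %d extra cases, %d genes ",
                     "(%d planted DEGs), %d gene sets%s>\n"),
              x$config$n_intra, x$config$n_extra, nrow(x$counts),
              nrow(x$truth$de_genes), length(x$gene_sets),
              if (is.null(x$volumes)) ", no volumes" else ""))
  invisible(x)
}
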