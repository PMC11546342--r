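#' Simulation configuration for a multi-sample single-cell dataset
#'
#' Counts follow a negative binomial with variance
#' `mean + mean^2 / dispersion`, thinned by independent Bernoulli dropout.
#' All genes share the baseline mean `nb_mean`; abundance differences
#' between genes are deliberately not modelled, so the planted effects
#' are the only structure. Each planted ligand-receptor
#' channel elevates the ligand mean in the sender type and the receptor
#' mean in the receiver type by a factor `1 + (fold_elevation - 1) * u_s`,
#' where `u_s ~ Uniform(0, 1)` is the sample's latent interaction
#' strength (shared by all planted channels and reported as ground
#' truth).
#'
#' @param n_samples number of samples (each gets its own matrix).
#' @param n_cell_types number of cell types, labelled `type01`, `type02`, ...
#' @param cells_per_type cells per type per sample.
#' @param n_genes number of genes, labelled `gene0001`, ...
#' @param nb_mean overall mean of per-gene baseline expression (counts).
#' @param nb_dispersion negative-binomial dispersion (`size`); smaller is
#'   noisier.
#' @param dropout_rate probability in `[0, 1)` that an observed count is
#'   zeroed.
#' @param planted_pairs data.frame with columns `ligand`, `receptor`,
#'   `sender`, `receiver`, `fold_elevation` (each fold > 1), or `NULL`.
#' @param phenotype_slope,phenotype_noise_sd parameters forwarded to
#'   [simulate_phenotype_series()] by [run_pipeline()].
#' @param seed integer seed; all generators are pure functions of
#'   (config, seed).
#' @return A validated `SimulationConfig` list.
#' @export
simulation_config <- function(n_samples = 6, n_cell_types = 8,
                              cells_per_type = 50, n_genes = 200,
                              nb_mean = 2, nb_dispersion = 1,
                              dropout_rate = 0.3, planted_pairs = NULL,
                              phenotype_slope = 1, phenotype_noise_sd = 0.1,
                              seed = 1L) {
  stopifnot(n_samples >= 1, n_cell_types >= 1, cells_per_type >= 1,
            n_genes >= 1, nb_mean > 0, nb_dispersion > 0,
            dropout_rate >= 0, dropout_rate < 1, phenotype_noise_sd >= 0)
  if (!is.null(planted_pairs)) {
    need <- c("ligand", "receptor", "sender", "receiver", "fold_elevation")
    stopifnot(all(need %in% colnames(planted_pairs)))
    if (any(planted_pairs$fold_elevation <= 1)) {
      stop("fold_elevation must exceed 1")
    }
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_cell_types = as.integer(n_cell_types),
                 cells_per_type = as.integer(cells_per_type),
                 n_genes = as.integer(n_genes),
                 nb_mean = nb_mean, nb_dispersion = nb_dispersion,
                 dropout_rate = dropout_rate, planted_pairs = planted_pairs,
                 phenotype_slope = phenotype_slope,
                 phenotype_noise_sd = phenotype_noise_sd,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Simulate a multi-sample single-cell count dataset with planted signal
#'
#' @param config a [simulation_config()].
#' @return A list with elements `matrices` (named list of per-sample count
#'   `ExpressionMatrix` objects), `annotation` (cell metadata across all
#'   samples), and `truth` (a `GroundTruth` list: `planted_pairs`,
#'   per-sample `strength`, per-gene baseline means).
#' @export
simulate_single_cell_dataset <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  genes <- sprintf("gene%04d", seq_len(config$n_genes))
  types <- sprintf("type%02d", seq_len(config$n_cell_types))
  samples <- sprintf("sample%02d", seq_len(config$n_samples))
  pp <- config$planted_pairs
  if (!is.null(pp)) {
    bad <- setdiff(c(pp$ligand, pp$receptor), genes)
    if (length(bad)) stop("planted gene(s) not in universe: ",
                          paste(bad, collapse = ", "))
    bad <- setdiff(c(pp$sender, pp$receiver), types)
    if (length(bad)) stop("planted cell type(s) not in universe: ",
                          paste(bad, collapse = ", "))
  }

  set.seed(config$seed)
  base_mean <- stats::setNames(rep(config$nb_mean, config$n_genes), genes)
  strength <- stats::runif(config$n_samples)
  names(strength) <- samples

  n_cells <- config$n_cell_types * config$cells_per_type
  type_of_cell <- rep(types, each = config$cells_per_type)
  matrices <- vector("list", config$n_samples)
  names(matrices) <- samples
  ann <- vector("list", config$n_samples)

  for (s in seq_along(samples)) {
    mu <- matrix(base_mean, nrow = config$n_genes, ncol = n_cells)
    if (!is.null(pp)) {
      mult <- 1 + (pp$fold_elevation - 1) * strength[s]
      for (k in seq_len(nrow(pp))) {
        li <- match(pp$ligand[k], genes)
        ri <- match(pp$receptor[k], genes)
        mu[li, type_of_cell == pp$sender[k]] <-
          mu[li, type_of_cell == pp$sender[k]] * mult[k]
        mu[ri, type_of_cell == pp$receiver[k]] <-
          mu[ri, type_of_cell == pp$receiver[k]] * mult[k]
      }
    }
    cnt <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                 size = config$nb_dispersion),
                  nrow = config$n_genes)
    if (config$dropout_rate > 0) {
      keep <- stats::rbinom(length(cnt), 1, 1 - config$dropout_rate)
      cnt <- cnt * keep
    }
    cell_ids <- sprintf("%s_%s_c%03d", samples[s], type_of_cell,
                        sequence(rep(config$cells_per_type,
                                     config$n_cell_types)))
    matrices[[s]] <- expression_matrix(cnt, genes, cell_ids, layer = "counts")
    ann[[s]] <- data.frame(cell_id = cell_ids, cell_type = type_of_cell,
                           sample_id = samples[s], stringsAsFactors = FALSE)
  }
  annotation <- do.call(rbind, ann)
  rownames(annotation) <- NULL
  list(matrices = matrices, annotation = annotation,
       truth = list(planted_pairs = pp, strength = strength,
                    base_mean = base_mean))
}

#' Simulate a per-sample scalar phenotype coupled to interaction strength
#'
#' `phenotype_s = slope * strength_s + Normal(0, noise_sd)`. With three or
#' fewer samples a rank correlation against the phenotype is useless, so
#' at least three are required.
#'
#' @param truth the `truth` element returned by
#'   [simulate_single_cell_dataset()] (or any list with a named `strength`
#'   vector).
#' @param slope linear coupling of phenotype to latent strength.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param seed integer seed.
#' @return A `data.frame` with columns `sample_id`, `phenotype`.
#' @export
simulate_phenotype_series <- function(truth, slope = 1, noise_sd = 0.1,
                                      seed = 1L) {
  strength <- truth$strength
  if (length(strength) < 3) stop("need at least 3 samples")
  stopifnot(noise_sd >= 0)
  set.seed(seed)
  data.frame(sample_id = names(strength),
             phenotype = slope * as.numeric(strength) +
               stats::rnorm(length(strength), 0, noise_sd),
             stringsAsFactors = FALSE)
}

#' Simulate a bulk expression matrix with planted co-expression modules
#'
#' Module genes load on a shared latent factor: with loading
#' `lambda = sqrt(r)` and unit residual scale, the expected pairwise
#' Pearson correlation within a module is `r`. A binary trait (two equal
#' groups of samples) is coupled to the first module's factor, and the
#' requested differential effects are added to dedicated genes between
#' trait groups. Values are on a log2-like Gaussian scale shifted to a
#' positive baseline.
#'
#' @param n_samples number of samples (even; split into two trait groups).
#' @param modules list of `list(size =, within_correlation =)` entries;
#'   `within_correlation` strictly inside (0, 1).
#' @param n_noise_genes independent background genes.
#' @param deg_effects numeric vector of true log2 effects planted on
#'   dedicated genes (added to the trait-1 group).
#' @param trait_coupling correlation between the first module's factor and
#'   the (standardized) trait; 0 disables.
#' @param seed integer seed.
#' @return A list: `matrix` (an `ExpressionMatrix`, layer `"normalized"`,
#'   samples as columns, values on a log2-like scale), `trait` (0/1 per
#'   sample), `truth` (`modules`: gene -> label with `"noise"` for
#'   background, `deg_genes`, `deg_effects`).
#' @export
simulate_bulk_coexpression_dataset <- function(n_samples = 50,
                                               modules = list(
                                                 list(size = 20, within_correlation = 0.8),
                                                 list(size = 15, within_correlation = 0.8)),
                                               n_noise_genes = 50,
                                               deg_effects = numeric(0),
                                               trait_coupling = 0.8,
                                               seed = 1L) {
  stopifnot(n_samples >= 4)
  for (m in modules) {
    if (m$within_correlation <= 0 || m$within_correlation >= 1) {
      stop("within_correlation must lie strictly inside (0, 1)")
    }
    stopifnot(m$size >= 1)
  }
  set.seed(seed)
  trait <- rep(c(0L, 1L), length.out = n_samples)
  z_trait <- as.numeric(scale(trait))
  blocks <- list()
  labels <- character(0)
  baseline <- 8  # keeps the Gaussian scale comfortably positive
  for (i in seq_along(modules)) {
    m <- modules[[i]]
    f <- stats::rnorm(n_samples)
    if (i == 1 && trait_coupling != 0) {
      f <- trait_coupling * z_trait + sqrt(1 - trait_coupling^2) * f
    }
    lambda <- sqrt(m$within_correlation)
    eps <- matrix(stats::rnorm(n_samples * m$size, sd = sqrt(1 - lambda^2)),
                  nrow = m$size, byrow = TRUE)
    blocks[[i]] <- baseline + lambda * matrix(f, nrow = m$size,
                                              ncol = n_samples,
                                              byrow = TRUE) + eps
    labels <- c(labels, rep(paste0("module", i), m$size))
  }
  n_deg <- length(deg_effects)
  n_bg <- n_noise_genes + n_deg
  if (n_bg > 0) {
    bg <- baseline + matrix(stats::rnorm(n_samples * n_bg), nrow = n_bg)
    if (n_deg > 0) {
      bg[seq_len(n_deg), trait == 1L] <-
        bg[seq_len(n_deg), trait == 1L] + deg_effects
    }
    blocks <- c(blocks, list(bg))
    labels <- c(labels,
                if (n_deg) paste0("deg", seq_len(n_deg)) else character(0),
                rep("noise", n_noise_genes))
  }
  values <- do.call(rbind, blocks)
  values <- pmax(values, 0)  # astronomically rare at baseline 8, keeps the invariant
  genes <- sprintf("gene%04d", seq_len(nrow(values)))
  deg_genes <- if (n_deg) genes[length(labels) - n_bg + seq_len(n_deg)] else character(0)
  module_labels <- ifelse(startsWith(labels, "deg"), "noise", labels)
  names(module_labels) <- genes
  em <- expression_matrix(values, genes,
                          sprintf("sample%03d", seq_len(n_samples)),
                          layer = "normalized")
  list(matrix = em, trait = trait,
       truth = list(modules = module_labels, deg_genes = deg_genes,
                    deg_effects = deg_effects))
}
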