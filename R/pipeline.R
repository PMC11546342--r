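#' Run the communication-scoring pipeline end to end
#'
#' Executes the enabled stages in order — `simulate`, `qc`, `normalize`,
#' `deg`, `coexpr`, `graph`, `commscore` — from a single flat
#' configuration, writing every stage's tables as TSV under the output
#' directory plus a `manifest.json` recording the package version, seeds,
#' parameter echo, per-stage status and row counts. All randomness flows
#' from the configured seed, so rerunning an identical configuration
#' reproduces identical outputs. Configuration is validated before any
#' stage runs (fail-fast: no partial outputs on a config error); a stage
#' failure is recorded in the manifest and stages depending on its
#' outputs are skipped.
#'
#' @param config a named list (or path to a YAML file) with elements:
#'   `stages` (character subset of the stage names above), `output_dir`,
#'   `seed`, and optional `paths` (named: `matrix`, `metadata`, `pairs`,
#'   `phenotype`, `ppi` — required by a stage when `simulate` is off) and
#'   `params` (named list of stage parameter overrides, e.g.
#'   `params$qc$min_features`, `params$deg$lfc_threshold`,
#'   `params$coexpr$cut_height`, `params$simulate$n_samples`).
#' @return The run manifest (a list), invisibly; also written as JSON.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  cfg <- validate_pipeline_config(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "lrcomms",
                   version = as.character(utils::packageVersion("lrcomms")),
                   seed = cfg$seed, stages = cfg$stages,
                   params = cfg$params, status = list(), rows = list())
  state <- list()
  run_stage <- function(name, deps, fun) {
    if (!name %in% cfg$stages) return()
    missing_deps <- setdiff(deps, names(state))
    if (length(missing_deps)) {
      manifest$status[[name]] <<- paste("skipped: needs",
                                        paste(missing_deps, collapse = ", "))
      return()
    }
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$status[[name]] <<- paste("failed:", conditionMessage(res))
    } else {
      manifest$status[[name]] <<- "ok"
    }
  }

  run_stage("simulate", character(0), function() {
    p <- cfg$params$simulate
    p$seed <- NULL
    if (!is.null(p$planted_pairs)) {
      p$planted_pairs <- as.data.frame(p$planted_pairs,
                                       stringsAsFactors = FALSE)
    }
    sc <- do.call(simulation_config, c(p, list(seed = cfg$seed)))
    sim <- simulate_single_cell_dataset(sc)
    phen <- simulate_phenotype_series(sim$truth, slope = sc$phenotype_slope,
                                      noise_sd = sc$phenotype_noise_sd,
                                      seed = cfg$seed + 1L)
    state$counts <<- sim$matrices
    state$annotation <<- sim$annotation
    state$phenotype <<- phen
    state$truth <<- sim$truth
    write_tsv_report(sim$annotation, file.path(cfg$output_dir, "metadata.tsv"))
    write_tsv_report(phen, file.path(cfg$output_dir, "phenotype.tsv"))
    for (s in names(sim$matrices)) {
      write_expression_matrix(sim$matrices[[s]],
                              file.path(cfg$output_dir,
                                        paste0("counts_", s, ".mtx")))
    }
    manifest$rows$simulate <<- nrow(sim$annotation)
  })

  if (!"simulate" %in% cfg$stages) {
    if (!is.null(cfg$paths$matrix)) {
      em <- read_expression_matrix(cfg$paths$matrix)
      ann <- read_cell_metadata(cfg$paths$metadata)
      state$counts <- split_by_sample(em, ann)
      state$annotation <- ann
    }
    if (!is.null(cfg$paths$phenotype)) {
      state$phenotype <- utils::read.table(cfg$paths$phenotype, header = TRUE,
                                           sep = "\t",
                                           stringsAsFactors = FALSE)
    }
  }
  if (!is.null(cfg$paths$pairs)) state$pairs <- read_lr_pairs(cfg$paths$pairs)

  run_stage("qc", "counts", function() {
    p <- cfg$params$qc
    qp <- do.call(qc_params, p)
    removed_all <- list()
    state$counts <<- lapply(state$counts, function(m) {
      res <- qc_filter_cells(m, qp)
      removed_all[[length(removed_all) + 1]] <<- res$removed
      res$matrix
    })
    removed <- do.call(rbind, removed_all)
    write_tsv_report(removed, file.path(cfg$output_dir, "qc_removed.tsv"))
    state$annotation <<- state$annotation[
      state$annotation$cell_id %in%
        unlist(lapply(state$counts, `[[`, "column_ids")), , drop = FALSE]
    manifest$rows$qc <<- nrow(removed)
  })

  run_stage("normalize", "counts", function() {
    state$normalized <<- lapply(state$counts, normalize_cells)
    manifest$rows$normalize <<- sum(vapply(state$normalized, ncol,
                                           integer(1)))
  })

  run_stage("deg", "normalized", function() {
    p <- cfg$params$deg
    em <- combine_samples(state$normalized)
    groups <- p$groups
    if (is.null(groups)) {
      # default contrast: first annotated cell type vs the rest
      ct <- state$annotation$cell_type[match(em$column_ids,
                                             state$annotation$cell_id)]
      groups <- factor(ifelse(ct == sort(unique(ct))[1], "g1", "g2"),
                       levels = c("g1", "g2"))
    }
    res <- differential_expression(
      em, groups,
      lfc_threshold = p$lfc_threshold %||% 1.0,
      alpha = p$alpha %||% 0.05)
    write_tsv_report(res, file.path(cfg$output_dir, "deg.tsv"))
    manifest$rows$deg <<- sum(res$status != "not_significant")
  })

  run_stage("coexpr", "normalized", function() {
    p <- cfg$params$coexpr
    em <- combine_samples(state$normalized)
    pick <- pick_soft_threshold(em,
                                candidate_powers = p$candidate_powers %||% 1:20,
                                r2_target = p$r2_target %||% 0.8)
    beta <- p$beta %||% pick$beta
    model <- build_adjacency_tom(em, beta)
    model <- detect_modules(model, cut_height = p$cut_height %||% 0.8,
                            min_size = p$min_size %||% 5L)
    write_tsv_report(pick$table,
                     file.path(cfg$output_dir, "soft_threshold.tsv"))
    write_tsv_report(data.frame(gene = names(model$modules),
                                module = unname(model$modules)),
                     file.path(cfg$output_dir, "modules.tsv"))
    if (any(model$modules != "grey")) {
      model <- module_eigengenes(model)
      eg <- data.frame(sample = rownames(model$eigengenes),
                       model$eigengenes, check.names = FALSE)
      write_tsv_report(eg, file.path(cfg$output_dir, "eigengenes.tsv"))
    }
    state$coexpr <<- model
    manifest$rows$coexpr <<- sum(model$modules != "grey")
  })

  run_stage("graph", character(0), function() {
    if (is.null(cfg$paths$ppi)) stop("graph stage needs paths$ppi")
    p <- cfg$params$graph
    g <- read_ppi_edges(cfg$paths$ppi,
                        min_confidence = p$min_confidence %||% 0.4)
    hubs <- rank_hubs(g, method = p$hub_method %||% "degree",
                      top_k = min(p$top_k %||% 10L, igraph::vcount(g)))
    clusters <- mcode_cluster(g, do.call(mcode_params,
                                         p$mcode %||% list()))
    write_tsv_report(hubs, file.path(cfg$output_dir, "hubs.tsv"))
    ctab <- do.call(rbind, lapply(seq_along(clusters), function(i) {
      cl <- clusters[[i]]
      data.frame(cluster = i, score = cl$score, n_nodes = cl$n_nodes,
                 n_edges = cl$n_edges,
                 nodes = paste(cl$nodes, collapse = ","),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(ctab)) {
      ctab <- data.frame(cluster = integer(), score = numeric(),
                         n_nodes = integer(), n_edges = integer(),
                         nodes = character())
    }
    write_tsv_report(ctab, file.path(cfg$output_dir, "mcode_clusters.tsv"))
    manifest$rows$graph <<- nrow(ctab)
  })

  run_stage("commscore", c("counts", "pairs"), function() {
    p <- cfg$params$commscore
    if (is.null(state$normalized)) {
      state$normalized <<- lapply(state$counts, normalize_cells)
    }
    res <- score_and_test_interactions(state$normalized, state$annotation,
                                       state$pairs,
                                       senders = p$senders,
                                       receivers = p$receivers)
    summ <- res$summary
    if (!is.null(state$phenotype)) {
      assoc <- phenotype_association(res$records, state$phenotype)
      me_all <- mean_expression_by_type(combine_samples(state$normalized),
                                        state$annotation)
      assoc <- decompose_association(assoc, me_all, state$phenotype,
                                     quadrant_bound = p$quadrant_bound %||% 0.5,
                                     alpha = p$alpha %||% 0.05)
      akey <- paste(assoc$ligand, assoc$receptor, assoc$sender,
                    assoc$receiver)
      skey <- paste(summ$ligand, summ$receptor, summ$sender, summ$receiver)
      summ <- cbind(summ, assoc[match(skey, akey),
                                c("rho_score", "p_assoc", "q_assoc",
                                  "rho_receptor", "rho_ligand",
                                  "quadrant_class")])
    }
    write_tsv_report(res$records,
                     file.path(cfg$output_dir, "interaction_records.tsv"))
    write_tsv_report(summ,
                     file.path(cfg$output_dir, "interaction_summary.tsv"))
    manifest$rows$commscore <<- nrow(res$records)
  })

  manifest_path <- file.path(cfg$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_pipeline_config <- function(config) {
  stopifnot(is.list(config))
  known <- c("simulate", "qc", "normalize", "deg", "coexpr", "graph",
             "commscore")
  stages <- config$stages
  if (is.null(stages) || !length(stages)) stop("config$stages is required")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (is.null(config$output_dir)) stop("config$output_dir is required")
  stochastic <- "simulate" %in% stages
  if (stochastic && is.null(config$seed)) {
    stop("config$seed is required when stochastic stages are enabled")
  }
  for (p in unlist(config$paths)) {
    if (!file.exists(p)) stop("configured input does not exist: ", p)
  }
  if (!"simulate" %in% stages) {
    needs_matrix <- any(c("qc", "normalize", "deg", "coexpr",
                          "commscore") %in% stages)
    if (needs_matrix && is.null(config$paths$matrix)) {
      stop("paths$matrix is required when simulate is disabled")
    }
  }
  if ("commscore" %in% stages && is.null(config$paths$pairs)) {
    stop("commscore stage needs paths$pairs")
  }
  list(stages = stages, output_dir = config$output_dir,
       seed = as.integer(config$seed %||% 1L),
       paths = config$paths %||% list(),
       params = utils::modifyList(
         list(simulate = list(), qc = list(), deg = list(), coexpr = list(),
              graph = list(), commscore = list()),
         config$params %||% list()))
}

# Split a combined matrix into per-sample matrices using the annotation.
split_by_sample <- function(em, annotation) {
  ann <- validate_annotation(annotation)
  idx <- match(em$column_ids, ann$cell_id)
  if (anyNA(idx)) stop("unannotated column(s) in matrix")
  samples <- unique(ann$sample_id[idx])
  out <- lapply(samples, function(s) {
    subset_matrix(em, columns = em$column_ids[ann$sample_id[idx] == s])
  })
  names(out) <- samples
  out
}
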