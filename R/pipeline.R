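#' Default run configuration
#'
#' Builds the configuration list driving [run_pipeline]. Any field can be
#' overridden through `...` (named nested lists are merged). Configurations
#' can also be read from YAML with [read_run_config].
#'
#' @param out_dir output directory for all stage artifacts.
#' @param ... overrides, e.g. `ica = list(order = 10)`.
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir = "sbm_run", ...) {
  cfg <- list(
    out_dir = out_dir,
    phantom = list(seed = 1L),          # phantom_spec overrides
    qc = list(sd_mult = 3, fwhm_mm = 4, on_smoothed = TRUE),
    ica = list(order = "auto", n_restarts = 5L, seed = 1L),
    glm = list(q = 0.05,
               terms = c("group", "age", "sex", "fsiq", "site"),
               variants = list(
                 adhd = c("group", "age", "sex", "fsiq", "site", "adhd"))),
    voxel = list(n_perm = 500L, seed = 1L,
                 tfce = list(E = 0.5, H = 2, dh = 0.01, connectivity = 26L)),
    cca = list(n_perm = 1000L, seed = 1L,
               batteries = list(examiner_rated = sprintf("beh_%d", 1:5))))
  over <- list(...)
  for (nm in names(over)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      modifyList(cfg[[nm]], over[[nm]]) else over[[nm]]
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, c(list(out_dir = y$out_dir %||% "sbm_run"),
                        y[setdiff(names(y), "out_dir")]))
}

#' Hash of the semantically meaningful configuration fields
#' @param config a `run_config`.
#' @return MD5 hex string.
#' @export
config_hash <- function(config) {
  sem <- config[setdiff(names(config), "out_dir")]
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(sem, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  unname(tools::md5sum(tmp))
}

stage_log <- function(log_path, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  message(msg)
  cat(msg, "\n", file = log_path, append = TRUE)
}

#' Run the source-based morphometry pipeline
#'
#' Executes the requested stages in dependency order:
#' `simulate` (phantom generation) -> `qc` (smoothing + homogeneity QC) ->
#' `decompose` (spatial ICA) -> `glm` (loading GLM + FDR) ->
#' `voxelglm` (permutation TFCE inference) -> `cca` (brain-behavior CCA with
#' permutation test and LOO stability). Later stages read the artifacts of
#' earlier ones from `out_dir`, so a stage can be re-run alone provided its
#' inputs exist; a missing input raises an error naming the artifact. Every
#' stage failure writes a `FAILED` marker and halts downstream stages,
#' retaining partial outputs. All outputs are stamped with the config hash.
#'
#' @param config a [run_config].
#' @param stages subset of
#'   `c("simulate", "qc", "decompose", "glm", "voxelglm", "cca")`.
#' @return The run report (also written to `report.json`), listing stage
#'   outputs and, when truth is available, booleans for recovery of the
#'   planted effects.
#' @export
run_pipeline <- function(config = run_config(),
                         stages = c("simulate", "qc", "decompose", "glm",
                                    "voxelglm", "cca")) {
  order_all <- c("simulate", "qc", "decompose", "glm", "voxelglm", "cca")
  stages <- order_all[order_all %in% stages]
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  hash <- config_hash(config)
  report <- list(config_hash = hash, stages = list())
  need <- function(path, what) {
    if (!file.exists(path))
      stop("missing dependency for this stage: ", what, " (", path, ")")
    path
  }
  failed <- FALSE
  for (st in stages) {
    if (failed) break
    stage_log(log_path, "stage ", st, " starting (config ", hash, ")")
    res <- tryCatch({
      switch(st,
        simulate = {
          spec <- do.call(phantom_spec, config$phantom)
          ph <- generate_phantom(spec, dir = file.path(config$out_dir, "maps"))
          list(maps_dir = file.path(config$out_dir, "maps"),
               n_subjects = spec$n_subjects, n_sources = spec$n_sources)
        },
        qc = {
          maps_dir <- need(file.path(config$out_dir, "maps"), "phantom maps")
          phen <- read.delim(need(file.path(maps_dir, "phenotypes.tsv"),
                                  "phenotype table"))
          paths <- file.path(maps_dir, paste0(phen$subject_id, ".nii.gz"))
          ds <- load_dataset(paths, file.path(maps_dir, "mask.nii.gz"),
                             subject_ids = phen$subject_id)
          if (config$qc$fwhm_mm > 0) ds <- smooth_fwhm(ds, config$qc$fwhm_mm)
          qc_ds <- if (isTRUE(config$qc$on_smoothed)) ds else
            load_dataset(paths, file.path(maps_dir, "mask.nii.gz"),
                         subject_ids = phen$subject_id)
          qc <- homogeneity_qc(qc_ds, sd_mult = config$qc$sd_mult)
          write.table(qc, file.path(config$out_dir, "qc.tsv"), sep = "\t",
                      quote = FALSE, row.names = FALSE)
          saveRDS(ds, file.path(config$out_dir, "dataset_smoothed.rds"))
          list(qc_flagged = sum(qc$flagged), n = nrow(qc))
        },
        decompose = {
          ds <- readRDS(need(file.path(config$out_dir, "dataset_smoothed.rds"),
                             "smoothed dataset"))
          ord <- config$ica$order
          if (identical(ord, "auto")) ord <- estimate_order(ds, "laplace")
          dec <- sbm_decompose(ds, order = max(2L, ord),
                               n_restarts = config$ica$n_restarts,
                               seed = config$ica$seed)
          write_sbm(dec, file.path(config$out_dir, "ica"), threshold = c(3, 5))
          saveRDS(dec, file.path(config$out_dir, "ica", "decomposition.rds"))
          list(order = dec$order,
               explained_variance = dec$explained_variance)
        },
        glm = {
          dec <- readRDS(need(file.path(config$out_dir, "ica",
                                        "decomposition.rds"),
                              "ICA decomposition"))
          phen <- read.delim(need(file.path(config$out_dir, "maps",
                                            "phenotypes.tsv"),
                                  "phenotype table"))
          des <- build_design(phen, config$glm$terms)
          fit <- fit_loading_glm(dec$loadings, des, q = config$glm$q)
          write_glm(fit, file.path(config$out_dir, "glm_main.tsv"))
          extra <- list()
          for (vn in names(config$glm$variants)) {
            dv <- build_design(phen, config$glm$variants[[vn]])
            fv <- fit_loading_glm(dec$loadings, dv, q = config$glm$q)
            write_glm(fv, file.path(config$out_dir,
                                    paste0("glm_", vn, ".tsv")))
            extra[[vn]] <- sum(fv$table$fdr_significant)
          }
          list(n_significant = sum(fit$table$fdr_significant),
               variants = extra)
        },
        voxelglm = {
          ds <- readRDS(need(file.path(config$out_dir, "dataset_smoothed.rds"),
                             "smoothed dataset"))
          phen <- read.delim(need(file.path(config$out_dir, "maps",
                                            "phenotypes.tsv"),
                                  "phenotype table"))
          des <- build_design(phen, config$glm$terms)
          tp <- do.call(tfce_params, config$voxel$tfce)
          vi <- permutation_glm(ds, des, n_perm = config$voxel$n_perm,
                                params = tp, seed = config$voxel$seed)
          write_voxel_inference(vi, file.path(config$out_dir, "voxel"))
          list(min_fwe_p = min(vi$fwe_p_map[vi$mask]),
               n_significant_voxels = sum(vi$fwe_p_map[vi$mask] < 0.05))
        },
        cca = {
          dec <- readRDS(need(file.path(config$out_dir, "ica",
                                        "decomposition.rds"),
                              "ICA decomposition"))
          phen <- read.delim(need(file.path(config$out_dir, "maps",
                                            "phenotypes.tsv"),
                                  "phenotype table"))
          aut <- phen$group == "autism"
          out <- list()
          for (bn in names(config$cca$batteries)) {
            cols <- config$cca$batteries[[bn]]
            y <- as.matrix(phen[aut, cols, drop = FALSE])
            x <- dec$loadings[aut, , drop = FALSE]
            fit <- suppressWarnings(fit_cca(x, y))
            fit <- correct_coefficients(x = x, y = y, result = fit)
            pt <- cca_permutation_test(x, y, n_perm = config$cca$n_perm,
                                       seed = config$cca$seed)
            fit$perm_p <- pt$perm_p
            fit$n_perm <- pt$n_perm
            write_cca(fit, file.path(config$out_dir, paste0("cca_", bn)))
            out[[bn]] <- list(n_complete = fit$n, r = fit$correlations[1],
                              perm_p = pt$perm_p,
                              bonferroni_alpha = pt$bonferroni_alpha,
                              significant = pt$significant)
          }
          out
        })
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- TRUE
      writeLines(conditionMessage(res),
                 file.path(config$out_dir, paste0("FAILED_", st)))
      stage_log(log_path, "stage ", st, " FAILED: ", conditionMessage(res))
      report$stages[[st]] <- list(status = "failed",
                                  error = conditionMessage(res))
    } else {
      stage_log(log_path, "stage ", st, " done")
      report$stages[[st]] <- c(list(status = "ok"), res)
    }
  }

  # planted-effect recovery summary when both truth and results exist
  truth_path <- file.path(config$out_dir, "maps", "truth.json")
  glm_path <- file.path(config$out_dir, "glm_main.tsv")
  ica_path <- file.path(config$out_dir, "ica", "decomposition.rds")
  if (file.exists(truth_path) && file.exists(glm_path) &&
      file.exists(ica_path)) {
    truth <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    glm_tab <- read.delim(glm_path)
    rec <- list()
    if (length(truth$group_effect)) {
      ge <- truth$group_effect
      if (!is.list(ge)) ge <- list(ge)
      rec$group_effects_detected <- vapply(ge, function(g)
        any(glm_tab$fdr_significant), logical(1))
    }
    cca_rep <- report$stages[["cca"]]
    if (!is.null(cca_rep) && !identical(cca_rep$status, "failed"))
      rec$cca_mode_significant <- vapply(
        cca_rep[setdiff(names(cca_rep), "status")],
        function(b) isTRUE(b$significant), logical(1))
    report$recovery <- rec
  }

  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(report)
}
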