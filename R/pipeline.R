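#' Run the full analysis pipeline on a simulated trial
#'
#' Orchestrates simulation, descriptive statistics, relationship-matrix
#' construction, model fitting across the requested model families, model
#' comparison, heritability estimation and (optionally) cross-validated
#' predictive ability, writing CSV/JSON artifacts and a run manifest to the
#' output directory.
#'
#' @param config list (or path to a YAML file) with entries:
#'   `simulation` (arguments to [sim_config()]), `models` (character vector
#'   among `ABLUP-OP`, `ABLUP-FS-A`, `ABLUP-FS-AD`, `GBLUP-A`, `GBLUP-AD`,
#'   `GBLUP-ADI`, `GBLUP-ADIE`), `cv` (list: `k`, `replicates`,
#'   `negligible_threshold`, `rkhs_h`, `gibbs` passed to [gibbs_config()],
#'   or `NULL` to skip), `out` (output directory), `seed`.
#' @return the run manifest (list), invisibly written as `manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out %||% "larchgp_run"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  models <- config$models %||% c("ABLUP-OP", "GBLUP-A", "GBLUP-ADIE")
  manifest <- list(seed = seed, models = models, artifacts = character(0),
                   started = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  stage <- "validate"
  known <- c("ABLUP-OP", "ABLUP-FS-A", "ABLUP-FS-AD", "GBLUP-A", "GBLUP-AD",
             "GBLUP-ADI", "GBLUP-ADIE")
  result <- NULL
  if (!all(models %in% known)) {
    manifest$status <- "failed"
    manifest$failed_stage <- stage
    manifest$error <- paste("unknown model name:",
                            paste(setdiff(models, known), collapse = ", "))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    return(invisible(manifest))
  }
  stage <- "simulate"
  result <- tryCatch({
    sim_args <- config$simulation %||% list()
    sim_args$seed <- seed
    cfg <- do.call(sim_config, sim_args)
    dat <- simulate_dataset(cfg)
    manifest$config_hash <- digest_config(cfg)

    stage <- "descriptives"
    desc <- describe_traits(dat$phenotypes, "y")
    write_artifact(desc, file.path(out_dir, "descriptives.csv"), manifest)

    stage <- "kinship"
    gen <- impute_random(filter_snps(dat$genotypes), seed = draw_seed(seed, 11L))
    mats <- genomic_matrices(gen, pedigree = dat$pedigree)
    names(mats) <- c("a", "d", "i", "e")[match(names(mats), c("A", "D", "I", "AA"))]
    pedA_op <- pedigree_additive(dat$pedigree, use_fs = FALSE)
    pedA_fs <- pedigree_additive(dat$pedigree, use_fs = TRUE)
    pedD_fs <- pedigree_dominance(dat$pedigree, use_fs = TRUE, A = pedA_fs)

    stage <- "fits"
    model_terms <- list(
      "ABLUP-OP" = list(include = "a", mats = list(a = pedA_op)),
      "ABLUP-FS-A" = list(include = "a", mats = list(a = pedA_fs)),
      "ABLUP-FS-AD" = list(include = c("a", "d"), mats = list(a = pedA_fs, d = pedD_fs)),
      "GBLUP-A" = list(include = "a", mats = mats["a"]),
      "GBLUP-AD" = list(include = c("a", "d"), mats = mats[c("a", "d")]),
      "GBLUP-ADI" = list(include = c("a", "d", "i"), mats = mats[c("a", "d", "i")]),
      "GBLUP-ADIE" = list(include = c("a", "d", "i", "e"), mats = mats))
    fits <- list()
    for (mname in models) {
      mt <- model_terms[[mname]]
      if (is.null(mt)) stop("unknown model name: ", mname)
      spec <- build_model(dat$phenotypes, "y", mt$mats, include = mt$include)
      fits[[mname]] <- fit_model(spec)
    }
    comp <- compare_models(fits)
    write_artifact(comp, file.path(out_dir, "model_comparison.csv"), manifest)

    stage <- "heritability"
    herit <- do.call(rbind, lapply(names(fits), function(m) {
      h <- heritability(fits[[m]])
      data.frame(model = m, h2 = h$h2, se_h2 = h$se_h2, H2 = h$H2,
                 se_H2 = h$se_H2)
    }))
    write_artifact(herit, file.path(out_dir, "heritability.csv"), manifest)
    props <- do.call(rbind, lapply(names(fits), function(m) {
      pr <- heritability(fits[[m]])$proportions
      data.frame(model = m, component = names(pr), proportion = as.numeric(pr))
    }))
    write_artifact(props, file.path(out_dir, "variance_proportions.csv"), manifest)

    cv_summary <- NULL
    if (!is.null(config$cv)) {
      stage <- "cross-validation"
      cvc <- config$cv
      folds <- make_folds(dat$phenotypes$id, k = cvc$k %||% 10L,
                          replicates = cvc$replicates %||% 10L,
                          seed = draw_seed(seed, 21L))
      full <- fits[[length(fits)]]
      optimal <- select_optimal_terms(full, cvc$negligible_threshold %||% 0.05)
      cv_a <- run_cv(dat$phenotypes, "y", folds, method = "gblup",
                     matrices = mats, include = "a", label = "GBLUP-A")
      cv_g <- run_cv(dat$phenotypes, "y", folds, method = "gblup",
                     matrices = mats, include = optimal, label = "GS-GBLUP")
      kerns <- kernel_set(gen, components = optimal,
                          h = cvc$rkhs_h %||% c(0.25, 1, 5),
                          pedigree = dat$pedigree)
      gcfg <- do.call(gibbs_config, c(cvc$gibbs %||% list(),
                                      list(seed = draw_seed(seed, 22L))))
      cv_r <- run_cv(dat$phenotypes, "y", folds, method = "rkhs",
                     kernels = kerns, include = optimal, gibbs = gcfg,
                     label = "GS-RKHS")
      cv_summary <- rbind(summary(cv_a), summary(cv_g), summary(cv_r))
      write_artifact(cv_summary, file.path(out_dir, "predictive_ability.csv"), manifest)
      cmp <- list(gs_gblup_vs_a = compare_pa(cv_g, cv_a),
                  gs_rkhs_vs_a = compare_pa(cv_r, cv_a))
      jsonlite::write_json(cmp, file.path(out_dir, "pa_comparison.json"),
                           auto_unbox = TRUE, digits = NA)
      manifest$artifacts <- c(manifest$artifacts, "pa_comparison.json")
    }
    manifest$status <- "complete"
    manifest
  }, error = function(e) {
    manifest$status <- "failed"
    manifest$failed_stage <- stage
    manifest$error <- conditionMessage(e)
    manifest
  })
  jsonlite::write_json(result, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(result)
}

write_artifact <- function(x, path, manifest) {
  utils::write.csv(x, path, row.names = FALSE)
  # record in the caller's manifest copy
  m <- get("manifest", envir = parent.frame())
  m$artifacts <- c(m$artifacts, basename(path))
  assign("manifest", m, envir = parent.frame())
  invisible(path)
}

digest_config <- function(cfg) {
  # stable content hash without external dependencies
  txt <- paste(utils::capture.output(utils::str(cfg, digits.d = 12)), collapse = "\n")
  sum(utf8ToInt(txt) * seq_along(utf8ToInt(txt))) %% 2147483647
}
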