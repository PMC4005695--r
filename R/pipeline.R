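# One-call orchestration: sequence filters -> feature table -> PLS +
# backward selection -> group contributions -> noise analysis, with all
# numeric outputs written to a directory and a run manifest recording
# seeds and configuration. Rerunning with the same configuration
# reproduces all outputs bit-identically.

#' Run the full analysis pipeline
#'
#' The configuration is a named list (or path to a YAML file readable by
#' `yaml::read_yaml`) with exactly one of:
#' * `simulate`: list(`n`, `seed`, ...) passed to [simulate_bundle()];
#' * `inputs`: list(`genome`, `format`, optional `gff`, `expression`
#'   (TSV with gene_id, mrna_level, protein_mean, protein_variance),
#'   optional `pwm`).
#' Further fields: `k` (folds, 10), `seed` (fold seed), `tol` (0.002),
#' `window` (noise window, 51), `protected` (never-removed predictors),
#' `out_dir` (if given, all tables are written there).
#'
#' @param config Named list or YAML path.
#' @return List of class `pipeline_result`: `features`, `selection`,
#'   `contributions`, `shares`, `efficiency`, `noise`, `report`,
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config)
    # YAML 1.1 reads a bare `n:` key as a boolean; map it back
    if (!is.null(config$simulate) &&
        "FALSE" %in% names(config$simulate)) {
      names(config$simulate)[names(config$simulate) == "FALSE"] <- "n"
    }
  }
  has_sim <- !is.null(config$simulate)
  has_inp <- !is.null(config$inputs)
  if (has_sim == has_inp) {
    stop("config must contain exactly one of 'simulate' or 'inputs'",
         call. = FALSE)
  }
  k <- config$k %||% 10L
  seed <- config$seed %||% 20140206L
  tol <- config$tol %||% 0.002
  window <- config$window %||% 51L

  if (has_sim) {
    bundle <- do.call(simulate_bundle, config$simulate)
    ft <- bundle$features
    expression <- merge(bundle$expression,
                        bundle$noise[, c("gene_id", "variance")],
                        by = "gene_id")
    names(expression)[names(expression) == "variance"] <- "protein_variance"
  } else {
    inp <- config$inputs
    for (f in c("genome", "expression")) {
      if (is.null(inp[[f]]) || !file.exists(inp[[f]])) {
        stop("validation error: missing input file for '", f, "': ",
             inp[[f]] %||% "<unset>", call. = FALSE)
      }
    }
    if (!is.null(inp$pwm) && !file.exists(inp$pwm)) {
      stop("validation error: PWM file not found: ", inp$pwm, call. = FALSE)
    }
    genome <- load_annotated_genome(inp$genome,
                                    format = inp$format %||% "genbank",
                                    gff_path = inp$gff)
    regions <- extract_regions_table(genome)
    screened <- screen_aberrant_genes(regions)
    expression <- utils::read.delim(inp$expression,
                                    stringsAsFactors = FALSE)
    expression <- expression[expression$gene_id %in%
                               screened$valid$gene_id, , drop = FALSE]
    flt <- flag_expression_outliers(expression)
    expression <- flt$kept
    pw <- if (is.null(inp$pwm)) default_sd_pwm() else read_pwm(inp$pwm)
    ft <- assemble_feature_table(
      screened$valid[screened$valid$gene_id %in% expression$gene_id, ],
      expression, pwm = pw)
  }

  y <- log10(expression$protein_mean[match(ft$gene_ids,
                                           expression$gene_id)])
  sel <- backward_eliminate(ft, y, k = k, seed = seed, tol = tol,
                            protected = config$protected %||% character())

  std <- standardize(ft$X[, sel$surviving, drop = FALSE], y)
  contrib <- group_contribution(sel$final_model, std$Xz, ft$group_of)
  shares <- variance_shares(sel$final_model, std$Xz, std$yz, ft$group_of)
  # groups with no surviving predictor contribute 0
  for (g in c("mRNA", "TIR", "CDS")) {
    if (is.null(contrib[[g]])) contrib[[g]] <- 0
  }
  eff <- efficiency_estimates(contrib)

  noise_tab <- NULL
  if (!is.null(expression$protein_variance)) {
    w_eff <- min(window, nrow(expression))
    if (w_eff %% 2L == 0L) w_eff <- w_eff - 1L
    noise_tab <- noise_differential(
      data.frame(gene_id = expression$gene_id,
                 mean = expression$protein_mean,
                 variance = expression$protein_variance,
                 stringsAsFactors = FALSE),
      window = w_eff)
    noise_tab$nd_group <- quartile_noise_groups(noise_tab)
  }
  report <- correlation_report(ft, y)

  manifest <- list(
    package_version = as.character(utils::packageVersion("seq2abundance")),
    k = k, seed = seed, tol = tol, window = window,
    n_genes = length(ft$gene_ids),
    n_predictors = ncol(ft$X),
    n_surviving = length(sel$surviving),
    cv_r2 = sel$final_cv_r2,
    imputed = ft$imputed,
    config = config[setdiff(names(config), "out_dir")])

  res <- structure(list(features = ft, selection = sel,
                        contributions = contrib, shares = shares,
                        efficiency = eff, noise = noise_tab,
                        report = report, manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(res, config$out_dir)
  res
}

#' @noRd
write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, name) {
    utils::write.table(x, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_feature_table(res$features, file.path(dir, "feature_table.tsv"))
  tsv(res$selection$trajectory, "selection_trajectory.tsv")
  tsv(res$contributions, "contributions.tsv")
  tsv(data.frame(group = names(res$shares$share),
                 share = unname(res$shares$share),
                 raw = unname(res$shares$raw)), "variance_shares.tsv")
  if (!is.null(res$noise)) tsv(res$noise, "noise_table.tsv")
  tsv(res$report, "correlation_report.tsv")
  write_model_json(res$selection$final_model, res$selection$final_std,
                   file.path(dir, "model.json"),
                   extra = list(surviving = res$selection$surviving,
                                seed = res$selection$seed))
  jsonlite::write_json(res$manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
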