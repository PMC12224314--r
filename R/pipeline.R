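# End-to-end pipeline: simulate/read -> detect -> impute/transform ->
# screen -> LDA -> associate -> CCA -> diversity -> report bundle, behind a
# JSON run config and a small CLI. Every stage output is a pure function of
# (inputs, config, seed); the bundle contains no timestamps so a repeated
# run is byte-identical.

#' Build a validated run configuration
#'
#' All statistical thresholds default to the values the analysis reports:
#' Kruskal-Wallis retention p < 0.05 for proteins and p < 0.01 for
#' microbes, `|r| > 0.7` for "highly correlated" edges, 0.8 for the
#' "strong" tier, 0.5 for the 2h-to-24h microbe correlations, and top-3
#' signed correlation lists.
#'
#' @param simulate `NULL`, or a list of [synthetic_config()] arguments: the
#'   pipeline then generates its own inputs.
#' @param inputs `NULL`, or a list of paths: `protein`, `protein_design`,
#'   `asv_2h`, `asv_2h_design`, `asv_24h`, `asv_24h_design`, and optionally
#'   `annotation`.
#' @param kw_protein,kw_microbe strict KW retention thresholds.
#' @param corr_high,corr_strong,corr_cross_time correlation tiers.
#' @param top_k size of the signed top-correlation lists.
#' @param skewness_scale `"raw"` or `"log10"` for the imputation objective.
#' @param alpha_bracket `"floor"` or `"round"` for the offset-log alpha.
#' @param protein_scale `"log10"` (default) or `"raw"`: scale of protein
#'   levels entering association and CCA.
#' @param lda_lambda,cca_lambda optional fixed shrinkage/ridge values
#'   (`NULL` = automatic).
#' @param mi compute mutual information in association tables.
#' @param grouping2 named list of two label sets defining the secondary
#'   (e.g. natural vs artificial substrate) grouping; `NULL` disables the
#'   grouped re-run.
#' @param seed integer seed for every source of randomness.
#' @param outdir output directory for the report bundle.
#' @return a validated `run_config` list.
#' @export
run_config <- function(simulate = NULL, inputs = NULL,
                       kw_protein = 0.05, kw_microbe = 0.01,
                       corr_high = 0.7, corr_strong = 0.8,
                       corr_cross_time = 0.5, top_k = 3L,
                       skewness_scale = "raw", alpha_bracket = "floor",
                       protein_scale = "log10",
                       lda_lambda = NULL, cca_lambda = NULL, mi = TRUE,
                       grouping2 = list(natural = c("dentine", "enamel"),
                                        artificial = "titanium"),
                       seed = 1L, outdir = "pellicca_run") {
  cfg <- list(simulate = simulate, inputs = inputs,
              thresholds = list(kw_protein = kw_protein, kw_microbe = kw_microbe,
                                corr_high = corr_high, corr_strong = corr_strong,
                                corr_cross_time = corr_cross_time,
                                top_k = as.integer(top_k)),
              transform = list(skewness_scale = skewness_scale,
                               alpha_bracket = alpha_bracket,
                               protein_scale = protein_scale,
                               lda_lambda = lda_lambda, cca_lambda = cca_lambda),
              mi = isTRUE(mi), grouping2 = grouping2,
              seed = as.integer(seed), outdir = outdir)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  th <- cfg$thresholds
  for (nm in c("kw_protein", "kw_microbe")) {
    v <- th[[nm]]
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v >= 1)
      stopf("threshold %s must lie in (0, 1), got %s", nm, format(th[[nm]]))
  }
  for (nm in c("corr_high", "corr_strong", "corr_cross_time")) {
    v <- th[[nm]]
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v > 1)
      stopf("threshold %s must lie in (0, 1], got %s", nm, format(th[[nm]]))
  }
  if (!is_count(th$top_k)) stopf("top_k must be a positive integer")
  if (!cfg$transform$skewness_scale %in% c("raw", "log10"))
    stopf("skewness_scale must be 'raw' or 'log10'")
  if (!cfg$transform$alpha_bracket %in% c("floor", "round"))
    stopf("alpha_bracket must be 'floor' or 'round'")
  if (!cfg$transform$protein_scale %in% c("raw", "log10"))
    stopf("protein_scale must be 'raw' or 'log10'")
  if (is.null(cfg$simulate) && is.null(cfg$inputs))
    stopf("config needs either a 'simulate' block or an 'inputs' block")
  invisible(cfg)
}

#' Read a run configuration from JSON
#' @param path JSON file matching the [run_config()] schema.
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  for (nm in c("simulate", "inputs", "seed", "outdir", "mi", "grouping2"))
    if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  if (!is.null(raw$thresholds)) args <- c(args, raw$thresholds)
  if (!is.null(raw$transform)) args <- c(args, raw$transform)
  if (!is.null(args$simulate)) args$simulate <- as.list(args$simulate)
  if (!is.null(args$inputs)) args$inputs <- as.list(args$inputs)
  if (!is.null(args$grouping2)) args$grouping2 <- lapply(args$grouping2, unlist)
  do.call(run_config, args)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  basename(path)
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       na = "null")
  basename(path)
}

lda_to_list <- function(model) {
  list(features = model$features, levels = model$levels,
       lambda = model$lambda, eigenvalues = unname(model$eigenvalues),
       proportion = unname(model$proportion),
       coef = apply(model$coef, 2L, identity, simplify = FALSE),
       std_coef = apply(model$std_coef, 2L, identity, simplify = FALSE),
       centroids = apply(model$centroids, 1L, identity, simplify = FALSE))
}

#' Simulate a fixture directory of pipeline inputs
#'
#' Writes the protein and ASV feature TSVs, their design sidecars, a sparse
#' random annotation map, and the full ground truth as JSON.
#'
#' @param config a [synthetic_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the tables, truths and file paths.
#' @export
simulate_fixture <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prot <- simulate_proteome(config)
  mic <- simulate_microbiome(config, prot$truth)
  ann <- simulate_annotation(feature_ids(prot$table), seed = config$seed + 2L)
  p <- function(f) file.path(dir, f)
  write_feature_table(prot$table, p("proteins.tsv"), p("proteins_design.tsv"))
  write_feature_table(mic$table_2h, p("asv_2h.tsv"), p("asv_2h_design.tsv"))
  write_feature_table(mic$table_24h, p("asv_24h.tsv"), p("asv_24h_design.tsv"))
  write_annotation_map(ann, p("annotation.tsv"))
  truth <- list(proteome = prot$truth[c("discriminant_proteins", "dropped_proteins",
                                        "detection_limit")],
                protein_effects = prot$truth$protein_effects,
                microbiome = mic$truth[c("discriminant_asvs")],
                couplings = mic$truth$couplings)
  write_json_out(truth, p("ground_truth.json"))
  invisible(list(protein = prot, microbiome = mic, annotation = ann,
                 dir = dir))
}

#' Run the full analysis pipeline
#'
#' Stages run in order: input acquisition (simulation or TSV reading),
#' detection summary, skewness-minimizing imputation, offset-log transform,
#' per-feature Kruskal-Wallis screening (proteins, 2h and 24h microbes,
#' molecular functions, biological processes), LDA with biplot coordinates
#' and heatmap orders (three-substrate and secondary two-group runs),
#' substrate-matched association (protein x 2h, protein x 24h, 2h x 24h)
#' with thresholded edges and top-k signed lists, CCA with
#' interset/intraset coordinates, diversity outputs, and a manifest. A
#' stage failure aborts with the stage name; a `FAILED` marker is left next
#' to any partial outputs.
#'
#' @param config a [run_config()].
#' @param upto last stage to run, one of `"detection"`, `"imputation"`,
#'   `"transform"`, `"diversity"`, `"screen"`, `"lda"`, `"association"`,
#'   `"cca"`, `"all"` (default); earlier stages in the order above always
#'   run, later ones are skipped (the manifest is always written).
#' @return invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config, upto = "all") {
  stopifnot(inherits(config, "run_config"))
  stage_order <- c("inputs", "detection", "imputation", "transform",
                   "diversity", "screen", "lda", "association", "cca", "all")
  upto <- match.arg(upto, stage_order[-1L])
  limit <- match(upto, stage_order)
  want <- function(nm) match(nm, stage_order) <= limit
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  th <- config$thresholds
  tr <- config$transform
  files <- character()
  log_lines <- character()
  state <- new.env(parent = emptyenv())

  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e) {
      writeLines(c(paste("stage:", name), paste("error:", conditionMessage(e))),
                 file.path(outdir, "FAILED"))
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  # -- inputs ---------------------------------------------------------------
  stage("inputs", {
    if (!is.null(config$simulate)) {
      sim_args <- config$simulate
      if (is.null(sim_args$seed)) sim_args$seed <- config$seed
      scfg <- do.call(synthetic_config, sim_args)
      fix <- simulate_fixture(scfg, file.path(outdir, "inputs"))
      state$protein <- fix$protein$table
      state$asv_2h <- fix$microbiome$table_2h
      state$asv_24h <- fix$microbiome$table_24h
      state$annotation <- fix$annotation
      state$truth <- list(proteome = fix$protein$truth,
                          microbiome = fix$microbiome$truth)
      note("inputs: simulated %d proteins x %d experiments, %d ASVs x 2 timepoints (seed %d)",
           nrow(state$protein$values), ncol(state$protein$values),
           nrow(state$asv_2h$values), scfg$seed)
    } else {
      inp <- config$inputs
      state$protein <- read_feature_table(inp$protein, inp$protein_design, "protein")
      state$asv_2h <- read_feature_table(inp$asv_2h, inp$asv_2h_design, "asv")
      state$asv_24h <- read_feature_table(inp$asv_24h, inp$asv_24h_design, "asv")
      state$annotation <- if (!is.null(inp$annotation)) read_annotation_map(inp$annotation)
                          else annotation_map()
      note("inputs: read %d proteins, %d + %d ASVs",
           nrow(state$protein$values), nrow(state$asv_2h$values),
           nrow(state$asv_24h$values))
    }
  })

  # -- detection ------------------------------------------------------------
  if (want("detection")) stage("detection", {
    state$detection <- summarize_detection(state$protein)
    files <- c(files,
               write_json_out(unclass(state$detection), file.path(outdir, "detection_summary.json")))
    write_detection_summary(state$detection, tsv_path = file.path(outdir, "detection_summary.tsv"))
    files <- c(files, "detection_summary.tsv")
    note("detection: %d proteins in union, %d shared by all substrates",
         state$detection$union_count,
         state$detection$shared[[paste(state$detection$substrates, collapse = "+")]])
  })

  # -- imputation + transforms ---------------------------------------------
  if (want("imputation")) stage("imputation", {
    state$imputation <- fit_imputation_constant(state$protein, scale = tr$skewness_scale)
    state$protein_complete <- if (state$imputation$applicable)
      apply_imputation(state$protein, state$imputation$c) else state$protein
    files <- c(files, write_json_out(unclass(state$imputation),
                                     file.path(outdir, "imputation.json")))
    note("imputation: %d cells imputed at c = %s",
         state$imputation$n_imputed,
         if (state$imputation$applicable) format(state$imputation$c, digits = 6) else "n/a")
  })

  if (want("transform")) stage("transform", {
    pooled <- cbind(state$asv_2h$values, state$asv_24h$values)
    state$offset <- offset_alpha(pooled, bracket = tr$alpha_bracket)
    state$mic_2h <- offset_log(state$asv_2h, state$offset)
    state$mic_24h <- offset_log(state$asv_24h, state$offset)
    pv <- table_values(state$protein_complete)
    state$prot_assoc <- feature_matrix(if (tr$protein_scale == "log10") log10(pv) else pv,
                                       state$protein_complete$design)
    files <- c(files, write_json_out(unclass(state$offset),
                                     file.path(outdir, "offset_spec.json")))
    note("transform: alpha = %g (min nonzero %g), protein scale %s",
         state$offset$alpha, state$offset$min_nonzero, tr$protein_scale)
  })

  # -- screening ------------------------------------------------------------
  if (want("screen")) stage("screen", {
    groups <- state$protein$design$substrate
    state$screen_protein <- screen_features(state$prot_assoc, threshold = th$kw_protein)
    state$screen_2h <- screen_features(state$mic_2h, threshold = th$kw_microbe)
    state$screen_24h <- screen_features(state$mic_24h, threshold = th$kw_microbe)
    state$functions <- aggregate_by_annotation(state$protein_complete, state$annotation,
                                               "molecular_function")
    state$processes <- aggregate_by_annotation(state$protein_complete, state$annotation,
                                               "biological_process")
    state$screen_functions <- if (nrow(state$functions$values) > 0L)
      screen_features(state$functions, threshold = th$kw_protein) else NULL
    state$screen_processes <- if (nrow(state$processes$values) > 0L)
      screen_features(state$processes, threshold = th$kw_protein) else NULL
    for (nm in c("protein", "2h", "24h", "functions", "processes")) {
      sc <- switch(nm, protein = state$screen_protein, "2h" = state$screen_2h,
                   "24h" = state$screen_24h, functions = state$screen_functions,
                   processes = state$screen_processes)
      if (!is.null(sc))
        files <- c(files, write_tsv(sc$results, file.path(outdir, sprintf("kw_%s.tsv", nm))))
    }
    note("screen: proteins %d -> %d (p < %g); microbes 2h %d -> %d, 24h %d -> %d (p < %g)",
         nrow(state$prot_assoc$values), length(state$screen_protein$retained), th$kw_protein,
         nrow(state$mic_2h$values), length(state$screen_2h$retained),
         nrow(state$mic_24h$values), length(state$screen_24h$retained), th$kw_microbe)
  })

  # -- LDA ------------------------------------------------------------------
  if (want("lda")) stage("lda", {
    fit_block <- function(tab, retained, groups, tag) {
      if (length(retained) < 1L) {
        note("lda[%s]: no retained features, skipped", tag)
        return(NULL)
      }
      vals <- table_values(tab)[retained, , drop = FALSE]
      model <- fit_lda(vals, groups, lambda = tr$lda_lambda)
      bc <- biplot_coordinates(model)
      ord <- if (length(retained) >= 2L) hclust_complete_order(vals) else NULL
      files <<- c(files,
                  write_json_out(lda_to_list(model), file.path(outdir, sprintf("lda_%s.json", tag))),
                  write_tsv(bc$cases, file.path(outdir, sprintf("biplot_cases_%s.tsv", tag))),
                  write_tsv(bc$centroids, file.path(outdir, sprintf("biplot_centroids_%s.tsv", tag))),
                  write_tsv(bc$features, file.path(outdir, sprintf("biplot_features_%s.tsv", tag))))
      if (!is.null(ord)) {
        files <<- c(files, write_tsv(
          data.frame(position = seq_along(ord$row_order),
                     feature = retained[ord$row_order]),
          file.path(outdir, sprintf("heatmap_order_%s.tsv", tag))))
      }
      note("lda[%s]: %d features, %d axes, lambda = %g", tag,
           length(retained), ncol(model$scores), model$lambda)
      model
    }
    subs <- state$protein$design$substrate
    state$lda_protein <- fit_block(state$prot_assoc, state$screen_protein$retained, subs, "protein")
    state$lda_2h <- fit_block(state$mic_2h, state$screen_2h$retained,
                              state$mic_2h$design$substrate, "2h")
    state$lda_24h <- fit_block(state$mic_24h, state$screen_24h$retained,
                               state$mic_24h$design$substrate, "24h")
    if (!is.null(state$screen_functions))
      state$lda_functions <- fit_block(state$functions, state$screen_functions$retained,
                                       subs, "functions")
    if (!is.null(state$screen_processes))
      state$lda_processes <- fit_block(state$processes, state$screen_processes$retained,
                                       subs, "processes")
    # secondary grouping (e.g. natural vs artificial substrates)
    if (!is.null(config$grouping2)) {
      g2 <- config$grouping2
      map <- stats::setNames(rep(names(g2), lengths(g2)), unlist(g2))
      if (all(subs %in% names(map))) {
        groups2 <- unname(map[subs])
        sc2 <- screen_features(state$prot_assoc, groups2, threshold = th$kw_protein)
        files <- c(files, write_tsv(sc2$results, file.path(outdir, "kw_protein_group2.tsv")))
        state$screen_protein_group2 <- sc2
        state$lda_protein_group2 <- fit_block(state$prot_assoc, sc2$retained, groups2,
                                              "protein_group2")
      } else note("lda[group2]: substrates not covered by grouping2, skipped")
    }
  })

  # -- association ----------------------------------------------------------
  if (want("association")) stage("association", {
    assoc_block <- function(xtab, ytab, xf, yf, tag, tau, topk = TRUE) {
      res <- associate_features(xtab, ytab, x_features = xf, y_features = yf,
                                mi = config$mi, tau = tau)
      edges <- threshold_associations(res, tau = tau, strong = th$corr_strong)
      files <<- c(files,
                  write_tsv(res, file.path(outdir, sprintf("association_%s.tsv", tag))),
                  write_tsv(edges, file.path(outdir, sprintf("chord_edges_%s.tsv", tag))))
      write_json_out(edges, file.path(outdir, sprintf("chord_edges_%s.json", tag)))
      files <<- c(files, sprintf("chord_edges_%s.json", tag))
      if (topk) {
        tk <- suppressWarnings(top_k_signed(res, k = th$top_k))
        tag_dir <- function(dir, d) {
          d$direction <- rep(dir, nrow(d))
          d[, c("direction", setdiff(names(d), "direction")), drop = FALSE]
        }
        files <<- c(files,
                    write_tsv(rbind(tag_dir("negative", tk$negative),
                                    tag_dir("positive", tk$positive)),
                              file.path(outdir, sprintf("top%d_%s.tsv", th$top_k, tag))))
      }
      note("association[%s]: %d pairs, %d edges with |r| > %g", tag,
           nrow(res), nrow(edges), tau)
      list(results = res, edges = edges)
    }
    state$assoc_2h <- assoc_block(state$prot_assoc, state$mic_2h,
                                  state$screen_protein$retained, state$screen_2h$retained,
                                  "protein_2h", th$corr_high)
    state$assoc_24h <- assoc_block(state$prot_assoc, state$mic_24h,
                                   state$screen_protein$retained, state$screen_24h$retained,
                                   "protein_24h", th$corr_high)
    state$assoc_cross <- assoc_block(state$mic_2h, state$mic_24h,
                                     state$screen_2h$retained, state$screen_24h$retained,
                                     "2h_24h", th$corr_cross_time, topk = FALSE)
  })

  # -- CCA ------------------------------------------------------------------
  if (want("cca")) stage("cca", {
    cca_block <- function(xtab, ytab, xf, yf, tag) {
      if (length(xf) < 1L || length(yf) < 1L) {
        note("cca[%s]: empty block, skipped", tag)
        return(NULL)
      }
      idx <- pair_index(table_design(xtab), table_design(ytab))
      X <- t(table_values(xtab)[xf, idx$i, drop = FALSE])
      Y <- t(table_values(ytab)[yf, idx$j, drop = FALSE])
      model <- fit_cca(X, Y, lambda_x = tr$cca_lambda, lambda_y = tr$cca_lambda)
      sc <- structure_correlations(model, X, Y)
      files <<- c(files,
                  write_json_out(list(cor = unname(model$cor),
                                      lambda_x = model$lambda_x, lambda_y = model$lambda_y,
                                      x_features = rownames(model$xcoef),
                                      y_features = rownames(model$ycoef),
                                      xcoef = apply(model$xcoef, 2L, identity, simplify = FALSE),
                                      ycoef = apply(model$ycoef, 2L, identity, simplify = FALSE)),
                                 file.path(outdir, sprintf("cca_%s.json", tag))),
                  write_tsv(sc$biplot, file.path(outdir, sprintf("cca_biplot_%s.tsv", tag))))
      note("cca[%s]: rho_1 = %.3f over %d x %d features", tag, model$cor[1L],
           length(xf), length(yf))
      list(model = model, structure = sc)
    }
    state$cca_2h <- cca_block(state$prot_assoc, state$mic_2h,
                              state$screen_protein$retained, state$screen_2h$retained, "2h")
    state$cca_24h <- cca_block(state$prot_assoc, state$mic_24h,
                               state$screen_protein$retained, state$screen_24h$retained, "24h")
  })

  # -- diversity ------------------------------------------------------------
  if (want("diversity")) stage("diversity", {
    for (tp in c("2h", "24h")) {
      tab <- if (tp == "2h") state$asv_2h else state$asv_24h
      props <- total_sum_scale(tab)
      sh <- apply(tab$values, 2L, shannon)
      files <- c(files, write_tsv(
        data.frame(experiment_id = names(sh), substrate = tab$design$substrate,
                   shannon = unname(sh)),
        file.path(outdir, sprintf("shannon_%s.tsv", tp))))
      D <- bray_curtis_matrix(props)
      files <- c(files, write_tsv(
        data.frame(experiment_id = rownames(D), as.data.frame(D)),
        file.path(outdir, sprintf("bray_curtis_%s.tsv", tp))))
      ord <- pcoa(D, k = 2L)
      files <- c(files, write_tsv(
        data.frame(experiment_id = rownames(ord$coordinates),
                   substrate = tab$design$substrate, ord$coordinates),
        file.path(outdir, sprintf("pcoa_%s.tsv", tp))))
      subs <- unique(tab$design$substrate)
      if (length(subs) >= 2L) {
        cmb <- utils::combn(subs, 2L)
        diffs <- lapply(seq_len(ncol(cmb)), function(ci)
          log2_median_proportion(props, cmb[1L, ci], cmb[2L, ci]))
        df <- data.frame(taxon = rownames(props$values),
                         taxonomy = if (!is.null(props$taxonomy))
                           unname(props$taxonomy) else NA_character_)
        for (ci in seq_len(ncol(cmb)))
          df[[paste0("log2_", cmb[1L, ci], "_vs_", cmb[2L, ci])]] <- unname(diffs[[ci]])
        files <- c(files, write_tsv(df, file.path(outdir, sprintf("heat_tree_%s.tsv", tp))))
      }
    }
    note("diversity: shannon, bray-curtis, pcoa and heat-tree tables written")
  })

  # -- manifest -------------------------------------------------------------
  stage("manifest", {
    manifest <- list(package = "pellicca",
                     version = as.character(utils::packageVersion("pellicca")),
                     seed = config$seed,
                     config = unclass(config),
                     log = log_lines,
                     files = sort(unique(files)))
    write_json_out(manifest, file.path(outdir, "manifest.json"))
    if (file.exists(file.path(outdir, "FAILED"))) file.remove(file.path(outdir, "FAILED"))
  })

  invisible(as.list(state))
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `impute`, `screen`, `lda`, `associate`, `cca`,
#' `diversity`, `run-all`. Options: `--config <json>`, `--seed <int>`,
#' `--outdir <dir>`, `--threads <n>` (accepted for interface stability;
#' results are independent of thread count). Stage subcommands run the
#' pipeline up to and including their stage.
#'
#' @param args character vector (default: the process command line).
#' @return exit status 0 invisibly on success.
#' @export
pipeline_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1L)
    stopf("usage: pellicca <simulate|impute|screen|lda|associate|cca|diversity|run-all> [--config F] [--seed N] [--outdir D]")
  cmd <- args[1L]
  opts <- list(config = NULL, seed = NULL, outdir = NULL, threads = NULL)
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opts)) stopf("unknown option: %s", args[i])
    if (i + 1L > length(args)) stopf("option --%s needs a value", key)
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  cfg <- if (!is.null(opts$config)) read_run_config(opts$config)
         else run_config(simulate = list())
  if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
  if (!is.null(opts$outdir)) cfg$outdir <- opts$outdir
  validate_run_config(cfg)

  if (cmd == "simulate") {
    sim_args <- if (is.null(cfg$simulate)) list() else cfg$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
    simulate_fixture(do.call(synthetic_config, sim_args), cfg$outdir)
  } else if (cmd %in% c("impute", "screen", "lda", "associate", "cca",
                        "diversity", "run-all")) {
    run_pipeline(cfg)
  } else {
    stopf("unknown subcommand: %s", cmd)
  }
  invisible(0L)
}
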