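#' Pipeline configuration
#'
#' Orchestrates the full concordance workflow on synthetic or file-based
#' input: ML branch-length comparison with the proportionality LRT,
#' calibration building under the chosen strategies, Bayesian dating per
#' strategy and data subset, and a concordance report. Budgets are
#' deliberately configurable so the whole grid runs at desk scale.
#'
#' @param synthetic a [sim_config()] (or `NULL` when file inputs are
#'   given).
#' @param tree_file,mol_file,morph_file,calibration_file input paths
#'   (Newick, FASTA, NEXUS, TSV) used when `synthetic` is `NULL`.
#' @param strategies subset of `c("Cr", "C1", "C2")`.
#' @param subsets subset of `c("mol", "morph", "combined")`.
#' @param clock clock linkage for the combined subset.
#' @param mcmc an [mcmc_config()] shared by the dating runs.
#' @param calib_t_L,calib_t_M fossil minimum and prior-mean ages for
#'   synthetic calibrations, as fractions of the true node age.
#' @param calib_max_nodes at most this many internal calibration nodes
#'   (chosen among nodes with >= 3 descendant tips, largest first).
#' @param lrt_tolerance convergence tolerance for the ML fits.
#' @param run_lrt,run_bf toggle the ML/LRT stage and the stepping-stone
#'   clock comparison stage.
#' @param ss_steps,ss_cfg stepping-stone budget when `run_bf`.
#' @param outdir output directory.
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = sim_config(),
                            tree_file = NULL, mol_file = NULL,
                            morph_file = NULL, calibration_file = NULL,
                            strategies = c("Cr", "C1", "C2"),
                            subsets = c("mol", "morph"),
                            clock = "unlinked",
                            mcmc = mcmc_config(runs = 2, iterations = 20000,
                                               interval = 20),
                            calib_t_L = 0.9, calib_t_M = 1.15,
                            calib_max_nodes = 7,
                            lrt_tolerance = 1e-4,
                            run_lrt = TRUE, run_bf = FALSE,
                            ss_steps = 10,
                            ss_cfg = mcmc_config(runs = 1, iterations = 2000,
                                                 interval = 10, burnin = 0.25),
                            outdir = tempfile("pipeline"), seed = 1) {
  stopifnot(length(strategies) >= 1,
            all(strategies %in% c("Cr", "C1", "C2")),
            all(subsets %in% c("mol", "morph", "combined")))
  structure(as.list(environment()), class = "pipeline_config")
}

#' Validate pipeline inputs
#'
#' Checks taxon-set agreement between matrices and tree, calibration
#' nesting, and alphabet sanity; distinguishes warnings (e.g. invariant
#' characters under variable-only ascertainment, which are uninformative)
#' from fatal errors (e.g. a taxon missing from a matrix).
#'
#' @param phy tree (`phylo`); `cm_list` named list of `char_matrix`;
#'   `calibration_table` optional data.frame; `mk` optional [mk_model()]
#'   to check ascertainment against.
#' @param cm_list named list of `char_matrix` objects.
#' @param calibration_table optional calibration data.frame.
#' @param mk optional [mk_model()].
#' @return list with `ok`, `errors`, `warnings`.
#' @export
validate_inputs <- function(phy, cm_list, calibration_table = NULL, mk = NULL) {
  errors <- character(0)
  warnings <- character(0)
  for (nm in names(cm_list)) {
    cm <- cm_list[[nm]]
    missing_taxa <- setdiff(phy$tip.label, rownames(cm$x))
    extra_taxa <- setdiff(rownames(cm$x), phy$tip.label)
    if (length(missing_taxa))
      errors <- c(errors, sprintf("matrix '%s' lacks tree tip(s): %s", nm,
                                  paste(missing_taxa, collapse = ", ")))
    if (length(extra_taxa))
      errors <- c(errors, sprintf("matrix '%s' has taxa not in tree: %s", nm,
                                  paste(extra_taxa, collapse = ", ")))
    if (cm$type == "standard") {
      kc <- state_counts(cm)
      if (!is.null(mk) && identical(mk$ascertainment, "variable_only") && any(kc <= 1))
        warnings <- c(warnings, sprintf(
          "matrix '%s': %d invariant character(s) under variable-only ascertainment (will be uninformative)",
          nm, sum(kc <= 1)))
    }
  }
  if (!is.null(calibration_table)) {
    nall <- length(phy$tip.label) + phy$Nnode
    nd <- suppressWarnings(as.integer(calibration_table$node))
    bad <- which(is.na(nd) | nd < 1 | nd > nall)
    if (length(bad))
      errors <- c(errors, sprintf("calibration on non-existent node: %s",
                                  paste(calibration_table$node[bad], collapse = ", ")))
  }
  list(ok = length(errors) == 0, errors = errors, warnings = warnings)
}

# Calibration table for a synthetic truth: root plus up to `max_nodes`
# internal nodes with >= 3 descendant tips, fossil minimum and prior mean
# as fractions of the true age (in Ma).
synthetic_calibration_table <- function(tt, t_L_frac = 0.9, t_M_frac = 1.15,
                                        max_nodes = 7, time_unit = 100) {
  phy <- tt$phy
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  cls <- classify_node_depth(phy)
  cand <- cls$node[cls$node != root & cls$n_tips >= 3]
  cand <- cand[order(-tt$ages[cand])]
  cand <- utils::head(cand, max_nodes - 1)
  nodes <- c(root, cand)
  data.frame(node = nodes,
             t_L = t_L_frac * tt$ages[nodes] * time_unit,
             t_M = t_M_frac * tt$ages[nodes] * time_unit,
             root = nodes == root)
}

stage_hash <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(obj, f)
  unname(tools::md5sum(f))
}

# Run `fun` unless a cached result with the same content hash exists.
run_stage <- function(outdir, name, hash, fun) {
  dir.create(file.path(outdir, "stages"), recursive = TRUE, showWarnings = FALSE)
  f <- file.path(outdir, "stages", paste0(name, ".rds"))
  if (file.exists(f)) {
    cached <- readRDS(f)
    if (identical(cached$hash, hash)) {
      message("stage '", name, "': reusing cached result")
      return(cached$value)
    }
  }
  message("stage '", name, "': running")
  value <- fun()
  saveRDS(list(hash = hash, value = value), f)
  value
}

#' Run the full concordance pipeline
#'
#' Stages: data (synthetic simulation or file loading), ML fits + LRT,
#' calibration building, dating per strategy x subset, concordance
#' report, and optionally the stepping-stone clock comparison. Completed
#' stages are skipped on rerun when their configuration hash is
#' unchanged. Reports are written under `config$outdir`:
#' `lrt.json`, `calibrations_<S>.json`, `dating_<S>_<subset>.tsv`,
#' `concordance_<S>.json`, `width_summary.tsv`, and `bf.json`.
#'
#' @param config a [pipeline_config()].
#' @return invisible list with all stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- list(config = config)

  data_hash <- stage_hash(list(config$synthetic, config$tree_file,
                               config$mol_file, config$morph_file,
                               config$seed))
  out$data <- run_stage(config$outdir, "data", data_hash, function() {
    if (!is.null(config$synthetic)) {
      sc <- config$synthetic
      sc$seed <- config$seed
      simulate_dataset(sc)
    } else {
      phy <- parse_tree(paste(readLines(config$tree_file), collapse = ""),
                        require_binary = TRUE)
      cm_mol <- parse_character_matrix(config$mol_file, "fasta")
      cm_morph <- parse_character_matrix(config$morph_file, "nexus")
      val <- validate_inputs(phy, list(mol = cm_mol, morph = cm_morph))
      if (!val$ok) stop(paste(val$errors, collapse = "; "))
      list(time_tree = NULL, phy = phy, cm_mol = cm_mol, cm_morph = cm_morph)
    }
  })
  ds <- out$data
  phy <- if (!is.null(ds$time_tree)) ds$time_tree$phy else ds$phy

  if (config$run_lrt) {
    h <- stage_hash(list(data_hash, config$lrt_tolerance))
    out$lrt <- run_stage(config$outdir, "mlfit", h, function() {
      mk <- mk_model(alpha = 1, ascertainment = "variable_only")
      gtr <- gtr_model(alpha = 1)
      pt <- proportionality_test(ds$cm_mol, ds$cm_morph, phy, gtr, mk,
                                 tolerance = config$lrt_tolerance)
      fl <- pt$fit_linked
      fu <- pt$fit_unlinked
      lrt <- pt$lrt
      jsonlite::write_json(
        list(l_linked = lrt$l_linked, l_unlinked = lrt$l_unlinked,
             statistic = lrt$statistic, df = lrt$df, p_value = lrt$p_value,
             c_morph = fl$c_b),
        file.path(config$outdir, "lrt.json"), auto_unbox = TRUE, digits = NA)
      list(fit_linked = fl, fit_unlinked = fu, lrt = lrt)
    })
  }

  cal_table <- if (!is.null(config$calibration_file)) {
    read_calibration_table(config$calibration_file)
  } else {
    if (is.null(ds$time_tree)) stop("calibration_file required for file input")
    synthetic_calibration_table(ds$time_tree, config$calib_t_L,
                                config$calib_t_M, config$calib_max_nodes)
  }
  out$calibrations <- lapply(config$strategies, function(s) {
    cs <- build_strategy(cal_table, s, phy = phy)
    write_calibration_set(cs, file.path(config$outdir,
                                        paste0("calibrations_", s, ".json")))
    cs
  })
  names(out$calibrations) <- config$strategies

  part_for <- function(subset) {
    switch(subset,
      mol = list(list(cm = ds$cm_mol, model = gtr_model(alpha = 1))),
      morph = list(list(cm = ds$cm_morph,
                        model = mk_model(alpha = 1, ascertainment = "variable_only"))),
      combined = list(list(cm = ds$cm_mol, model = gtr_model(alpha = 1)),
                      list(cm = ds$cm_morph,
                           model = mk_model(alpha = 1, ascertainment = "variable_only"))))
  }
  out$dating <- list()
  for (s in config$strategies) {
    for (subset in config$subsets) {
      key <- paste(s, subset, sep = "_")
      h <- stage_hash(list(data_hash, cal_table, s, subset, config$clock,
                           config$mcmc, config$seed))
      out$dating[[key]] <- run_stage(config$outdir, paste0("dating_", key), h, function() {
        cfg <- config$mcmc
        cfg$seed <- derive_seeds(config$seed, 100)[match(key, outer(config$strategies, config$subsets, paste, sep = "_"))]
        res <- run_mcmc(phy, part_for(subset), out$calibrations[[s]],
                        clock = if (subset == "combined") config$clock else "linked",
                        cfg = cfg)
        utils::write.table(res$summary,
                           file.path(config$outdir, paste0("dating_", key, ".tsv")),
                           sep = "\t", row.names = FALSE, quote = FALSE)
        res
      })
    }
  }

  # concordance + width summary over whatever subsets were run
  widths <- list()
  for (s in config$strategies) {
    for (subset in config$subsets) {
      res <- out$dating[[paste(s, subset, sep = "_")]]
      widths[[length(widths) + 1]] <- data.frame(
        strategy = s, subset = subset,
        mean_rel_hpd_width_pct = mean_relative_hpd_width(res$summary))
    }
    if (all(c("mol", "morph") %in% config$subsets)) {
      rep_s <- concordance_report(out$dating[[paste0(s, "_mol")]]$summary,
                                  out$dating[[paste0(s, "_morph")]]$summary,
                                  exclude_root = identical(s, "Cr"),
                                  root_node = length(phy$tip.label) + 1L)
      out$concordance[[s]] <- rep_s
      jsonlite::write_json(
        list(strategy = s, slope = rep_s$regression$slope,
             r = rep_s$regression$r, r_squared = rep_s$regression$r_squared,
             coverage_morph_in_mol_pct = rep_s$coverage_y_in_x_pct,
             mean_rel_width_mol = rep_s$mean_rel_width_x,
             mean_rel_width_morph = rep_s$mean_rel_width_y),
        file.path(config$outdir, paste0("concordance_", s, ".json")),
        auto_unbox = TRUE, digits = NA)
      utils::write.table(rep_s$scatter,
                         file.path(config$outdir, paste0("scatter_", s, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  out$width_summary <- do.call(rbind, widths)
  utils::write.table(out$width_summary,
                     file.path(config$outdir, "width_summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  if (config$run_bf) {
    h <- stage_hash(list(data_hash, cal_table, config$ss_steps, config$ss_cfg,
                         config$seed))
    out$bf <- run_stage(config$outdir, "bf", h, function() {
      cmp <- linked_vs_unlinked_clock_compare(
        phy, part_for("combined"), out$calibrations[[config$strategies[1]]],
        K = config$ss_steps, step_cfg = config$ss_cfg,
        post_cfg = config$mcmc)
      jsonlite::write_json(
        list(bf = cmp$bf, log_marginal_linked = cmp$ss_linked$log_marginal,
             log_marginal_unlinked = cmp$ss_unlinked$log_marginal),
        file.path(config$outdir, "bf.json"), auto_unbox = TRUE, digits = NA)
      cmp
    })
  }
  invisible(out)
}
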