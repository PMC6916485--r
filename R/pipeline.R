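# End-to-end orchestration: load or synthesize the tables, run every
# analysis stage, and write one delimited output per summary table plus a
# run manifest with checksums.

#' Pipeline run configuration
#'
#' All thresholds default to the analysis' stated values: FDR 0.10 for
#' flagging, VIP cutoff 0.8 for model reduction, per-allele-copy counting for
#' homozygotes, 5000 simulation draws.
#'
#' @param out_dir output directory (created if needed).
#' @param cohort_path,biochem_path CSV inputs; when `NULL` a synthetic cohort
#'   is generated from `synth_params`.
#' @param synth_params a [generator_params] (default uses `seed`).
#' @param fdr false-discovery threshold in (0, 1).
#' @param vip_cutoff VIP retention cutoff in (0, 1].
#' @param copy_policy passed to [explode_alleles()].
#' @param n_draws Monte Carlo draws per simulation.
#' @param seed master seed for every stochastic stage.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, cohort_path = NULL, biochem_path = NULL,
                       synth_params = NULL, fdr = 0.10, vip_cutoff = 0.8,
                       copy_policy = "per_allele_copy", n_draws = 5000,
                       seed = 1) {
  stopifnot(fdr > 0, fdr < 1, vip_cutoff > 0, vip_cutoff <= 1, n_draws >= 1)
  if (is.null(synth_params)) synth_params <- generator_params(seed = seed)
  structure(list(out_dir = out_dir, cohort_path = cohort_path,
                 biochem_path = biochem_path, synth_params = synth_params,
                 fdr = fdr, vip_cutoff = vip_cutoff,
                 copy_policy = copy_policy, n_draws = n_draws, seed = seed),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognized keys mirror the [run_config()] arguments (scalar fields only;
#' `synth_params` may override `n_patients` and `seed`).
#'
#' @param path YAML file.
#' @param out_dir output directory override.
#' @return a `run_config`.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  cfg <- yaml::read_yaml(path)
  if (is.null(out_dir)) out_dir <- cfg$out_dir
  seed <- if (is.null(cfg$seed)) 1 else cfg$seed
  sp <- NULL
  if (!is.null(cfg$synth_params)) {
    sp <- do.call(generator_params,
                  utils::modifyList(list(seed = seed), cfg$synth_params))
  }
  run_config(out_dir,
             cohort_path = cfg$cohort_path, biochem_path = cfg$biochem_path,
             synth_params = sp,
             fdr = if (is.null(cfg$fdr)) 0.10 else cfg$fdr,
             vip_cutoff = if (is.null(cfg$vip_cutoff)) 0.8 else cfg$vip_cutoff,
             copy_policy = if (is.null(cfg$copy_policy)) "per_allele_copy"
             else cfg$copy_policy,
             n_draws = if (is.null(cfg$n_draws)) 5000 else cfg$n_draws,
             seed = seed)
}

.stage <- function(name, log, code) {
  tryCatch(force(code),
           error = function(e) stop("stage '", name, "': ",
                                    conditionMessage(e), call. = FALSE))
}

#' Run the full genotype-phenotype pipeline
#'
#' Stages, in order: load (or synthesize) the cohort and biochemistry tables;
#' distribution tests of the clinical variables; contingency analysis of the
#' categorical phenotypes; association screens of AOO and SARA against
#' patient variables; correlation screen and Ward clustering of the
#' biochemical variables; PLS models (SARA on clinical variables; AOO and
#' SARA jointly on the four biochemical inputs) reduced by VIP; Monte Carlo
#' desirability simulation of the biochemical models (baseline + optimized).
#' Every output table is written to `out_dir`, and a `manifest.json` records
#' the configuration hash, seed, per-stage row counts, flagged results and a
#' checksum for every output. A rerun with the same configuration is
#' byte-identical. Any stage error aborts the run naming the stage; outputs
#' of completed stages are retained.
#'
#' @param config a [run_config()].
#' @return the manifest, invisibly (a list).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  log <- list(stages = list())
  note <- function(stage, rows, flagged = NA) {
    log$stages[[stage]] <<- list(rows = rows, flagged = flagged)
  }

  cfg_path <- out("config.yaml")
  yaml::write_yaml(list(
    cohort_path = config$cohort_path, biochem_path = config$biochem_path,
    synthetic = is.null(config$cohort_path),
    n_patients = config$synth_params$n_patients,
    fdr = config$fdr, vip_cutoff = config$vip_cutoff,
    copy_policy = config$copy_policy, n_draws = config$n_draws,
    seed = config$seed), cfg_path)

  dat <- .stage("load", log, {
    if (!is.null(config$cohort_path)) {
      list(cohort = load_cohort(config$cohort_path),
           biochem = load_biochem(config$biochem_path))
    } else {
      generate_cohort(config$synth_params)[c("cohort", "biochem")]
    }
  })
  cohort <- dat$cohort; biochem <- dat$biochem
  note("load", nrow(cohort))

  dist_tab <- .stage("distributions", log, {
    vars <- c("hypogonadism", "tr", "ancestry", "cd", "aoo", "sara",
              "homozygous", "sex")
    do.call(rbind, lapply(vars, function(v) {
      x <- cohort[[v]]
      if (is.logical(x)) x <- ifelse(x, "Y", "N")
      r <- test_distribution(x, name = v)
      r
    }))
  })
  write_screen(dist_tab, out("table1_distributions.csv"))
  note("distributions", nrow(dist_tab))

  cont_tab <- .stage("contingency", log, {
    pairs <- utils::combn(c("hypogonadism", "tr", "cd"), 2, simplify = FALSE)
    res <- do.call(rbind, lapply(pairs, function(pr) {
      d <- cohort[!is.na(cohort[[pr[1]]]) & !is.na(cohort[[pr[2]]]), ]
      fisher_exact(table(d[[pr[1]]], d[[pr[2]]]), pr[1], pr[2])
    }))
    res$q <- bh_adjust(res$p)
    res$flagged <- res$q < config$fdr
    res
  })
  write_screen(cont_tab, out("table2_contingency.csv"))
  note("contingency", nrow(cont_tab), sum(cont_tab$flagged))

  screens <- .stage("screens", log, {
    cohort2 <- cohort
    cohort2$homozygous <- ifelse(cohort2$homozygous, "Y", "N")
    rbind(
      screen(cohort2, "aoo",
             c("sex", "ancestry", "homozygous", "sara", "cd", "tr"),
             fdr = config$fdr),
      screen(cohort2, "sara",
             c("sex", "ancestry", "homozygous", "aoo", "cd", "tr"),
             fdr = config$fdr))
  })
  write_screen(screens, out("tableS2_screen.csv"))
  note("screens", nrow(screens), sum(screens$flagged))

  bio_vars <- c("kd", "bmax", "pct_hsp70_ub", "pct_chain", "tm", "pct_e")
  mutants <- biochem[biochem$mutation != "WT", ]
  corr <- .stage("correlations", log, {
    correlation_screen(mutants, bio_vars, fdr = config$fdr)
  })
  corr_long(corr, out("fig3_correlations.csv"))
  dendro <- .stage("clustering", log, ward_cluster(mutants, bio_vars))
  write_newick(dendro, out("fig3_dendrogram.nwk"))
  note("correlations", length(bio_vars),
       sum(corr$flagged[upper.tri(corr$flagged)]))

  pls_clin <- .stage("pls_clinical", log, {
    cohort2 <- cohort
    cohort2$homozygous <- ifelse(cohort2$homozygous, "Y", "N")
    cohort2 <- cohort2[!is.na(cohort2$aoo), ]
    reduce_and_refit(cohort2,
                     c("cd", "ancestry", "tr", "homozygous", "aoo", "sex"),
                     "sara", cutoff = config$vip_cutoff)
  })
  utils::write.csv(cbind(vip_table(pls_clin$initial),
                         retained = vip_table(pls_clin$initial)$var %in%
                           pls_clin$retained),
                   out("fig2_pls.csv"), row.names = FALSE)
  note("pls_clinical", length(pls_clin$retained))

  pls_bio <- .stage("pls_biochem", log, {
    alleles <- explode_alleles(cohort, copy_policy = config$copy_policy)
    merged <- merge_biochem(alleles, biochem)
    merged <- merged[!is.na(merged$aoo), ]
    reduce_and_refit(merged, c("pct_hsp70_ub", "pct_chain", "kd", "bmax"),
                     c("aoo", "sara"), cutoff = config$vip_cutoff)
  })
  for (r in names(pls_bio$equations)) {
    write_equation(pls_bio$equations[[r]], out(paste0("equation_", r, ".yaml")))
  }

  sim <- .stage("simulation", log, {
    resp_sd <- c(aoo = stats::sd(cohort$aoo[!is.na(cohort$aoo)]),
                 sara = stats::sd(cohort$sara))
    spec <- simulation_spec(
      equations = pls_bio$equations[c("aoo", "sara")],
      goals = c(aoo = "maximize", sara = "minimize"),
      target_offsets = resp_sd,
      n_draws = config$n_draws, seed = config$seed)
    opt <- optimize_settings(spec, budget = config$n_draws)
    list(spec = spec, opt = opt)
  })
  sim_tab <- do.call(rbind, lapply(
    list(c("baseline", "baseline"), c("optimized", "opt")),
    function(row) {
      res <- if (row[2] == "baseline") sim$opt$baseline else sim$opt$result
      cbind(data.frame(scenario = row[1]),
            as.data.frame(t(res$settings)),
            data.frame(aoo = res$mean[["aoo"]], sara = res$mean[["sara"]],
                       D = res$D))
    }))
  utils::write.csv(sim_tab, out("table3_simulation.csv"), row.names = FALSE)
  note("simulation", nrow(sim_tab))

  grid <- .stage("grid", log, {
    # preferred axes, restricted to the inputs the reduced model kept
    axes <- intersect(c("kd", "bmax", "pct_hsp70_ub", "pct_chain"),
                      sim$spec$inputs)
    if (length(axes) < 2) {
      profile_grid(sim$spec, sim$spec$inputs[1], sim$spec$inputs[1], n = 15)
    } else {
      profile_grid(sim$spec, axes[1], axes[2],
                   by_var = if (length(axes) >= 3) axes[3] else NULL, n = 15)
    }
  })
  utils::write.csv(grid, out("fig6_grid.csv"), row.names = FALSE)
  note("grid", nrow(grid))

  outputs <- list.files(config$out_dir, full.names = TRUE)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_path)),
    seed = config$seed,
    stages = log$stages,
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(f) unname(tools::md5sum(f)))
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
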