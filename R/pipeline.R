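#' Pipeline configuration
#'
#' Either a `simulation` block (a [demographic_model()] plus sampling
#' options) or a set of `input` paths (VCF + popmap, optional recombination
#' map and annotation TSV) must be present. Stage toggles select which
#' analyses run; each stage writes one TSV with a commented `#key=value`
#' header into `out_dir`. A `manifest.json` recording versions, seeds,
#' parameters and input checksums makes the run re-executable.
#'
#' @param out_dir output directory (created if needed).
#' @param seed global seed; per-stage seeds are derived from it.
#' @param simulation list with `model` (a `demographic_model` or
#'   `"default_wolf"`), `samples_per_pop`, `missing_rate`.
#' @param input list with `vcf`, `popmap`, and optionally `recomb_map`,
#'   `annotations`.
#' @param stages named logical list over
#'   `dstat, topoweights, roh, diversity, load, sfsfit`.
#' @param filter optional [filter_spec()] applied before analysis.
#' @param options named list of per-stage parameter overrides (see
#'   [run_pipeline()]).
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, simulation = NULL,
                            input = NULL, stages = NULL, filter = NULL,
                            options = list()) {
  if (is.null(simulation) == is.null(input))
    stopf("config error at 'simulation'/'input': exactly one must be given")
  if (!is.null(input))
    for (k in c("vcf", "popmap"))
      if (is.null(input[[k]])) stopf("config error at 'input.%s': required", k)
  all_stages <- c("dstat", "topoweights", "roh", "diversity", "load", "sfsfit")
  st <- setNames(rep(TRUE, length(all_stages)), all_stages)
  if (!is.null(stages)) {
    bad <- setdiff(names(stages), all_stages)
    if (length(bad)) stopf("config error at 'stages.%s': unknown stage", bad[1])
    st[all_stages] <- FALSE
    st[names(stages)] <- vapply(stages, isTRUE, logical(1))
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulation = simulation, input = input, stages = st,
                 filter = filter, options = options),
            class = "pipeline_config")
}

#' Demo configuration: simulated three-lineage cohort, all stages
#'
#' A desk-scale end-to-end run on a cohort simulated under
#' [default_wolf_model()], with every stage enabled at small budgets.
#'
#' @param out_dir output directory.
#' @param seed global seed.
#' @return A [pipeline_config()].
#' @export
demo_config <- function(out_dir, seed = 1L) {
  pipeline_config(
    out_dir = out_dir, seed = seed,
    simulation = list(model = "default_wolf",
                      samples_per_pop = c(Indian = 4, Tibetan = 2,
                                          Holarctic = 4, SWAsia = 6,
                                          Outgroup1 = 2, Outgroup2 = 2)),
    options = list(
      dstat = list(quartet = c("Holarctic", "SWAsia", "Indian", "Outgroup1")),
      topoweights = list(groups = c("Indian", "SWAsia", "Holarctic",
                                    "Outgroup1"), max_per_group = 2,
                         max_windows = 400),
      load = list(outgroups = c("Outgroup1", "Outgroup2")),
      sfsfit = list(pops = c("Indian", "SWAsia", "Holarctic"),
                    subsample = c(2, 3, 3), models = c("A", "B"),
                    n_loci = 2000, grid_points = 3, refine_iter = 0)))
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; keys mirror [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulation) && identical(y$simulation$model, "default_wolf"))
    y$simulation$samples_per_pop <- unlist(y$simulation$samples_per_pop)
  pipeline_config(out_dir = y$out_dir %||% ".", seed = y$seed %||% 1L,
                  simulation = y$simulation, input = y$input,
                  stages = y$stages,
                  options = y$options %||% list())
}

write_stage_tsv <- function(df, path, header) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("#%s=%s", names(header), unlist(header)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order: obtain the cohort
#' (simulate or load), apply the optional site filter, then run D
#' statistics, topology weighting, ROH detection, diversity, genetic load
#' and SFS model fitting. Each stage writes `<stage>.tsv` into the output
#' directory; failures of one stage are recorded in the manifest without
#' aborting the others. Identical config + seed reproduce all outputs
#' byte for byte.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the per-stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  logcon <- file(log_path, "w")
  on.exit(close(logcon))
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    writeLines(msg, logcon)
    message(msg)
  }
  manifest <- list(package = "lupuspg",
                   version = as.character(packageVersion("lupuspg")),
                   seed = config$seed, stages = list())
  results <- list()

  # --- inputs --------------------------------------------------------------
  annotations <- NULL; map <- NULL
  if (!is.null(config$simulation)) {
    sim <- config$simulation
    model <- sim$model
    if (identical(model, "default_wolf")) model <- default_wolf_model()
    say("simulating cohort (seed %d)", config$seed)
    simres <- simulate_cohort(model,
                              samples_per_pop = sim$samples_per_pop %||% 4L,
                              seed = derive_seed(config$seed, 1L),
                              missing_rate = sim$missing_rate %||% 0)
    cohort <- simres$cohort; popmap <- simres$popmap
    annotations <- assign_impact_annotations(cohort,
                                             seed = derive_seed(config$seed, 2L))
    map <- recomb_map(chrom = unique(cohort$chrom),
                      start = 0, end = model$sequence_length,
                      rate = genome_rate_cM_Mb(model))
    manifest$simulation <- list(seed = derive_seed(config$seed, 1L),
                                samples_per_pop = as.list(simres$truth$samples_per_pop))
  } else {
    say("loading inputs")
    rd <- read_vcf_cohort(config$input$vcf, config$input$popmap)
    cohort <- rd$cohort; popmap <- rd$popmap
    if (!is.null(config$input$recomb_map))
      map <- read_recomb_map(config$input$recomb_map)
    if (!is.null(config$input$annotations))
      annotations <- read_annotations(config$input$annotations)
    manifest$input_checksums <- as.list(tools::md5sum(unlist(config$input)))
  }
  if (!is.null(config$filter)) {
    cohort <- filter_sites(cohort, config$filter)
    manifest$filter_log <- as.list(attr(cohort, "filter_log"))
  }
  genome_len <- length(unique(cohort$chrom)) *
    (max(cohort$pos) + 1)  # equal-length chromosome convention
  opt <- config$options

  run_stage <- function(name, fun) {
    if (!config$stages[[name]]) return()
    say("stage %s", name)
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e) e)
    wall <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    if (inherits(res, "error")) {
      say("stage %s FAILED after %.1f s: %s", name, wall,
          conditionMessage(res))
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res))
    } else {
      # wall time goes to the log only, so outputs stay reproducible
      say("stage %s done in %.1f s", name, wall)
      manifest$stages[[name]] <<- list(status = "ok")
      results[[name]] <<- res
    }
  }

  run_stage("dstat", function() {
    o <- opt$dstat %||% list()
    q <- o$quartet %||% stopf("config error at 'options.dstat.quartet'")
    qs <- quartet_spec(q[1], q[2], q[3], q[4])
    d <- d_test(cohort, popmap, qs, block_bp = o$block_bp %||% 5e6)
    write_stage_tsv(data.frame(P1 = q[1], P2 = q[2], P3 = q[3], P4 = q[4],
                               D = d$D, SE = d$se, Z = d$Z, nABBA = d$abba,
                               nBABA = d$baba, n_blocks = d$n_blocks,
                               n_sites = d$n_sites),
                    file.path(config$out_dir, "dstat.tsv"),
                    list(stage = "dstat", seed = config$seed))
    d
  })

  run_stage("topoweights", function() {
    o <- opt$topoweights %||% list()
    g <- o$groups %||% stopf("config error at 'options.topoweights.groups'")
    tw <- window_topology_weights(cohort, popmap, g, map,
                                  window_snps = o$window_snps %||% 100L,
                                  max_per_group = o$max_per_group %||% Inf,
                                  max_windows = o$max_windows %||% Inf)
    strat <- stratify_weights(tw$weights, tw$windows)
    wdf <- cbind(tw$windows[, c("chrom", "start", "end", "mean_rate")],
                 as.data.frame(round(tw$weights, 6)))
    names(wdf)[-(1:4)] <- paste0("topo", seq_len(ncol(tw$weights)))
    write_stage_tsv(wdf, file.path(config$out_dir, "topoweights.tsv"),
                    list(stage = "topoweights", seed = config$seed,
                         groups = paste(g, collapse = ",")))
    sm <- data.frame(stratum = rownames(strat$means),
                     n_windows = as.integer(strat$counts),
                     round(strat$means, 6))
    write_stage_tsv(sm, file.path(config$out_dir, "topoweights_strata.tsv"),
                    list(stage = "topoweights_strata", seed = config$seed))
    writeLines(vapply(tw$trees, ape::write.tree, character(1)),
               file.path(config$out_dir, "window_trees.nwk"))
    list(weights = tw, strata = strat)
  })

  run_stage("roh", function() {
    o <- opt$roh %||% list()
    params <- o$params %||% hmm_params()
    ingroup <- popmap$sample[popmap$role == "ingroup"]
    segs <- lapply(ingroup, function(s) {
      sg <- detect_roh(cohort, s, params, map)
      if (nrow(sg)) cbind(sample = s, sg) else NULL
    })
    segdf <- do.call(rbind, segs) %||%
      data.frame(sample = character(), chrom = character(), start = integer(),
                 end = integer(), length = integer(), n_sites = integer(),
                 quality = numeric())
    write_stage_tsv(segdf, file.path(config$out_dir, "roh.tsv"),
                    list(stage = "roh", seed = config$seed,
                         min_length = params$min_length,
                         min_quality = params$min_quality))
    profs <- lapply(setNames(ingroup, ingroup), function(s)
      bin_roh(segdf[segdf$sample == s, , drop = FALSE], genome_len))
    pdf <- do.call(rbind, lapply(names(profs), function(s) {
      p <- profs[[s]]
      data.frame(sample = s, t(p$counts), total_mb = sum(p$total_mb),
                 F_ROH = p$F_ROH, stringsAsFactors = FALSE)
    }))
    write_stage_tsv(pdf, file.path(config$out_dir, "roh_profiles.tsv"),
                    list(stage = "roh_profiles", seed = config$seed,
                         genome_length = genome_len))
    list(segments = segdf, profiles = profs)
  })

  run_stage("diversity", function() {
    rep <- diversity_report(cohort, popmap)
    write_stage_tsv(rep, file.path(config$out_dir, "diversity.tsv"),
                    list(stage = "diversity", seed = config$seed))
    rep
  })

  run_stage("load", function() {
    o <- opt$load %||% list()
    og <- o$outgroups %||% stopf("config error at 'options.load.outgroups'")
    if (is.null(annotations)) stopf("load stage needs annotations")
    pol <- polarize_sites(cohort, og[1], og[2], annotations, popmap,
                          seed = derive_seed(config$seed, 3L))
    lt <- load_table(pol, units = o$units %||% "alleles")
    write_stage_tsv(lt, file.path(config$out_dir, "load.tsv"),
                    list(stage = "load", seed = config$seed,
                         outgroups = paste(og, collapse = ",")))
    list(polarized = pol, table = lt,
         comparison = compare_populations(lt, popmap))
  })

  run_stage("sfsfit", function() {
    o <- opt$sfsfit %||% list()
    pops <- o$pops %||% stopf("config error at 'options.sfsfit.pops'")
    sub <- o$subsample %||% c(3, 6, 9)
    obs <- build_folded_3dsfs(cohort, popmap, pops,
                              block_bp = o$block_bp %||% 2e6,
                              subsample = sub,
                              seed = derive_seed(config$seed, 4L))
    sc <- search_config(grid_points = o$grid_points %||% 4L,
                        refine_iter = o$refine_iter %||% 40L)
    fits <- lapply(o$models %||% c("A", "B", "C"), function(mm)
      fit_model(obs, sfs_model_spec(mm, subsample = sub),
                n_loci = o$n_loci %||% 5000L, search = sc,
                seed = derive_seed(config$seed, 5L)))
    cmp <- compare_models(fits)
    write_stage_tsv(as.data.frame(cmp),
                    file.path(config$out_dir, "sfsfit.tsv"),
                    list(stage = "sfsfit", seed = config$seed,
                         pops = paste(pops, collapse = ",")))
    list(observed = obs, fits = fits, comparison = cmp)
  })

  manifest$config <- serialize_config(config)
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  say("pipeline complete: %d stage(s) run", length(manifest$stages))
  invisible(list(results = results, manifest = manifest))
}

# model -> its mean recombination rate in cM/Mb
genome_rate_cM_Mb <- function(model) model$recombination_rate * 1e8

serialize_config <- function(config) {
  cf <- unclass(config)
  cf$out_dir <- NULL  # the manifest's own directory; kept out so reruns
                      # into different directories compare identical
  if (!is.null(cf$simulation) && inherits(cf$simulation$model, "demographic_model"))
    cf$simulation$model <- unclass(cf$simulation$model)
  if (!is.null(cf$filter)) cf$filter <- unclass(cf$filter)
  cf$stages <- as.list(cf$stages)
  cf
}
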