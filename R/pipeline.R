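pipeline_stages <- c("simulate_data", "filter", "metrics", "load", "ne",
                     "report", "simulate")

default_run_config <- function() {
  list(seed = 1,
       output_dir = "erosionscope_run",
       log_level = "info",
       stages = pipeline_stages,
       simulate_data = list(n_sites = 600, low_quality_fraction = 0.05),
       filter = list(max_missing = 0.2, depth_pct = c(2.5, 97.5),
                     thin_bp = NULL),
       metrics = list(window_bp = 50000, roh_min_snps = 20,
                      roh_min_len_bp = 50000),
       load = list(divergence_generations = 5000),
       ne = list(n = 5, reps = 20, maf_cutoff = 0.05),
       report = list(n = 5, reps = 100, test_on = "replicates"),
       simulate = list(K = c(20, 10), years = 200, reps = 5,
                       n_genes = 150, burnin_gens = 150, ancestral_K = 60))
}

#' Parse and validate a pipeline configuration
#'
#' Reads a YAML run configuration, fills defaults, and rejects unknown
#' keys (naming the offending key path) and stages whose inputs no prior
#' stage produces. Stage order is fixed: simulate_data, filter, metrics,
#' load, ne, report, simulate; a run may list any downstream-closed
#' subset starting from `simulate_data`.
#'
#' @param path YAML file, or a list already in config shape.
#' @return validated config list of class `run_config`.
#' @export
parse_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  defaults <- default_run_config()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (k in intersect(names(cfg), pipeline_stages)) {
    bad <- setdiff(names(cfg[[k]]), names(defaults[[k]]))
    if (length(bad))
      stop("unknown configuration key(s): ",
           paste(paste0(k, ".", bad), collapse = ", "))
  }
  out <- modifyList(defaults, cfg)
  if (!is.numeric(out$seed) || length(out$seed) != 1)
    stop("seed must be a single number")
  out$stages <- match.arg(out$stages, pipeline_stages, several.ok = TRUE)
  deps <- list(filter = "simulate_data", metrics = "filter",
               load = "filter", ne = "filter",
               report = c("metrics", "load", "ne"))
  for (st in out$stages) {
    need <- deps[[st]]
    miss <- setdiff(need, out$stages)
    if (length(miss))
      stop("stage '", st, "' requires stage(s) not in the run: ",
           paste(miss, collapse = ", "))
  }
  class(out) <- "run_config"
  out
}

log_msg <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf("[erosionscope %s] %s", format(Sys.time(), "%H:%M:%S"),
                  paste0(...)))
}

#' Run the end-to-end synthetic pipeline
#'
#' Executes the configured stages in order on a synthetic cohort:
#' data generation, site filtering, diversity and ROH metrics, load
#' annotation, LD-Ne resampling, the temporal erosion report, and the
#' forward simulation. Each stage writes its outputs under the run
#' directory and records seed, wall time and output checksums in a JSON
#' manifest. A re-run skips stages whose outputs already exist unless
#' `force = TRUE`; per-stage seeds derive from the global seed via
#' [derive_seed()], so forced re-runs reproduce identical outputs.
#'
#' @param config a `run_config` from [parse_config()] (or a list/path
#'   accepted by it).
#' @param force re-run stages whose outputs exist (default `FALSE`).
#' @return list with `manifest` (also written as `manifest.json`) and
#'   `results` (in-memory stage outputs).
#' @export
run_pipeline <- function(config, force = FALSE) {
  cfg <- if (inherits(config, "run_config")) config else
    parse_config(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(cfg$output_dir, "manifest.json")
  manifest <- list(seed = cfg$seed, stages = list())
  results <- list()
  state <- new.env()

  run_stage <- function(name, outputs, fun, reload = NULL) {
    if (!(name %in% cfg$stages)) return(invisible())
    paths <- file.path(cfg$output_dir, outputs)
    if (!force && length(paths) && all(file.exists(paths))) {
      log_msg(cfg, "stage ", name, ": outputs exist, skipped")
      manifest$stages[[name]] <<- list(status = "skipped",
                                       outputs = as.list(
                                         tools::md5sum(paths)))
      if (!is.null(reload)) reload(paths)  # rebuild in-memory state only
      return(invisible())
    }
    t0 <- proc.time()[["elapsed"]]
    res <- fun(derive_seed(cfg$seed, name), paths)
    manifest$stages[[name]] <<- list(
      status = "completed", seed = derive_seed(cfg$seed, name),
      wall_time_s = round(proc.time()[["elapsed"]] - t0, 3),
      outputs = as.list(tools::md5sum(paths[file.exists(paths)])))
    results[[name]] <<- res
    log_msg(cfg, "stage ", name, " completed")
  }

  run_stage("simulate_data", c("cohort.vcf.gz", "metadata.tsv",
                               "truth.json"),
            function(seed, paths) {
    sd_cfg <- cfg$simulate_data
    cc <- cohort_config(n_sites = sd_cfg$n_sites,
                        low_quality_fraction = sd_cfg$low_quality_fraction)
    state$cohort <- generate_cohort(cc, seed = seed, dir = cfg$output_dir)
    state$cohort
  }, reload = function(paths) {
    truth <- jsonlite::read_json(paths[3], simplifyVector = TRUE)
    state$cohort <- list(gm = read_genotypes(paths[1]),
                         meta = read.delim(paths[2]),
                         truth = truth)
  })
  run_stage("filter", "filtered.vcf.gz", function(seed, paths) {
    gm <- apply_hard_filters(state$cohort$gm)
    gm <- filter_missingness_depth(gm, cfg$filter$max_missing,
                                   cfg$filter$depth_pct[1],
                                   cfg$filter$depth_pct[2])
    if (!is.null(cfg$filter$thin_bp))
      gm <- thin_one_per_window(gm, cfg$filter$thin_bp)
    write_genotypes(gm, paths[1])
    state$gm <- gm
    gm
  }, reload = function(paths) state$gm <- read_genotypes(paths[1]))
  run_stage("metrics", "metrics.tsv", function(seed, paths) {
    gm <- state$gm; meta <- state$cohort$meta
    pis <- vapply(gm$sample_ids, function(s)
      pi_of_samples(gm, s, cfg$metrics$window_bp), 0)
    froh <- froh_all_samples(gm, min_snps = cfg$metrics$roh_min_snps,
                             min_len_bp = cfg$metrics$roh_min_len_bp)
    metrics <- rbind(
      data.frame(sample_id = gm$sample_ids, metric = "pi",
                 value = unname(pis)),
      data.frame(sample_id = froh$sample_id, metric = "froh",
                 value = froh$froh_gt100kb))
    write.table(metrics, paths[1], sep = "\t", quote = FALSE,
                row.names = FALSE)
    state$metrics <- metrics
    metrics
  }, reload = function(paths) state$metrics <- read.delim(paths[1]))
  run_stage("load", "load.tsv", function(seed, paths) {
    og <- generate_outgroup(state$cohort,
                            cfg$load$divergence_generations, seed = seed)
    pol <- polarize(state$gm, og)
    ## truth-backed classes: the generator records per-site categories
    tr <- state$cohort$truth$site
    key <- paste(state$gm$sites$chrom, state$gm$sites$pos)
    tr <- tr[match(key, paste(tr$chrom, tr$pos)), ]
    cat_map <- c(LOF = "LOF", missense = "deleterious_missense",
                 synonymous = "synonymous", neutral = "excluded")
    ann <- data.frame(chrom = state$gm$sites$chrom,
                      pos = state$gm$sites$pos,
                      ancestral = pol$ancestral, derived = pol$derived,
                      category = unname(cat_map[tr$class]),
                      stringsAsFactors = FALSE)
    ann$category[ann$ancestral == "unpolarized"] <- "excluded"
    loads <- cohort_load(state$gm, ann,
                         categories = c("LOF", "deleterious_missense",
                                        "synonymous"))
    write.table(loads, paths[1], sep = "\t", quote = FALSE,
                row.names = FALSE)
    state$loads <- loads
    loads
  }, reload = function(paths) state$loads <- read.delim(paths[1]))
  run_stage("ne", "ne.tsv", function(seed, paths) {
    meta <- state$cohort$meta
    rows <- list()
    for (pop in unique(meta$population))
      for (per in unique(meta$period)) {
        avail <- sum(meta$population == pop & meta$period == per)
        if (avail < cfg$ne$n) next
        rows[[length(rows) + 1L]] <-
          resample_ne(state$gm, meta, pop, per, n = cfg$ne$n,
                      reps = cfg$ne$reps, seed = derive_seed(seed, per),
                      maf_cutoff = cfg$ne$maf_cutoff)
      }
    ne <- do.call(rbind, rows)
    write.table(ne, paths[1], sep = "\t", quote = FALSE,
                row.names = FALSE)
    state$ne <- ne
    ne
  }, reload = function(paths) state$ne <- read.delim(paths[1]))
  run_stage("report", c("report_summary.tsv", "report_comparisons.tsv"),
            function(seed, paths) {
    lm <- state$loads[state$loads$category == "LOF", ]
    metrics <- rbind(state$metrics,
                     data.frame(sample_id = lm$sample_id,
                                metric = "load_LOF",
                                value = lm$load_ratio))
    metrics <- metrics[!is.na(metrics$value), ]
    rep_obj <- build_report(metrics, state$cohort$meta,
                            n = cfg$report$n, reps = cfg$report$reps,
                            seed = seed, test_on = cfg$report$test_on)
    write.table(rep_obj$summary, paths[1], sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(rep_obj$comparisons, paths[2], sep = "\t", quote = FALSE,
                row.names = FALSE)
    state$report <- rep_obj
    rep_obj
  })
  run_stage("simulate", "scenarios.tsv", function(seed, paths) {
    sc <- cfg$simulate
    scfg <- sim_config(ancestral_K = sc$ancestral_K * 100,
                       burnin_gens = sc$burnin_gens * 100, lambda = 100,
                       n_genes = sc$n_genes)
    pop <- burn_in(scfg, seed = seed)
    res <- run_scenarios(pop, sc$K, years = sc$years, reps = sc$reps,
                         seed = derive_seed(seed, "scenarios"))
    write.table(res$aggregate, paths[1], sep = "\t", quote = FALSE,
                row.names = FALSE)
    res
  })

  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  list(manifest = manifest, results = results)
}
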