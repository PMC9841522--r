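# Full triage orchestration from one configuration: ingest -> stage-1 filter
# -> pharmacophore pose filter -> consensus pool -> stage-2 filter ->
# diversity clustering + selection -> metrics. Every stage writes a plain
# CSV report so any stage can be re-run standalone; a JSON manifest records
# versions, seeds and the per-stage funnel counts.

#' Assemble and validate a pipeline run configuration
#'
#' @param deck path to the SMILES/CSV deck (columns `id`, `smiles`)
#' @param ranked_lists character vector of ranked-list CSV paths
#'   (columns `engine`, `id`, `score`)
#' @param directions per-list score directions (`"higher"`/`"lower"`)
#' @param poses optional SDF of docked poses; when NULL the pharmacophore
#'   stage is skipped
#' @param model optional pharmacophore model JSON (required with `poses`)
#' @param alerts optional alert-set CSV (default: built-in set)
#' @param descriptors optional CSV with columns `id`, `logd`, `psa`
#'   overriding the built-in stage-2 descriptor estimates
#' @param labels optional CSV with columns `id`, `active` for hit-rate
#'   reporting
#' @param out_dir output directory for reports and the manifest
#' @param n consensus top-N per engine
#' @param k,target,top_m clustering and selection sizes
#' @param radius,nbits fingerprint parameters
#' @param seed integer seed (clustering tie-breaks)
#' @param stage2_combine `"and"` or `"or"` for the stage-2 removal rule
#' @return object of class `run_config`
#' @export
run_config <- function(deck, ranked_lists, directions, out_dir,
                       poses = NULL, model = NULL, alerts = NULL,
                       descriptors = NULL, labels = NULL,
                       n = 1000, k = 960, target = 960, top_m = 50,
                       radius = 4, nbits = 2048, seed = 17,
                       stage2_combine = "and") {
  for (p in c(deck, ranked_lists, poses, model, alerts, descriptors, labels))
    if (!is.null(p) && !file.exists(p)) stop("missing input file: ", p)
  if (!is.null(poses) && is.null(model))
    stop("poses given without a pharmacophore model")
  if (length(directions) != length(ranked_lists))
    stop("one direction per ranked list required")
  stopifnot(n >= 1, k >= 1, target >= 1, top_m >= 0, radius %in% 0:5)
  structure(list(deck = deck, ranked_lists = ranked_lists,
                 directions = directions, poses = poses, model = model,
                 alerts = alerts, descriptors = descriptors, labels = labels,
                 out_dir = out_dir, n = as.integer(n), k = as.integer(k),
                 target = as.integer(target), top_m = as.integer(top_m),
                 radius = radius, nbits = as.integer(nbits),
                 seed = as.integer(seed), stage2_combine = stage2_combine),
            class = "run_config")
}

#' Load a run configuration from a YAML or JSON file
#' @param path config file; keys as in [run_config()]; relative paths are
#'   resolved against the config file's directory
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(normalizePath(path))
  fix <- function(p) if (is.null(p)) NULL else
    ifelse(startsWith(p, "/"), p, file.path(base, p))
  for (key in c("deck", "ranked_lists", "poses", "model", "alerts",
                "descriptors", "labels"))
    cfg[[key]] <- fix(cfg[[key]])
  cfg$out_dir <- cfg$out_dir %||% file.path(base, "triage_out")
  do.call(run_config, cfg)
}

stage_log <- function(manifest, name, n_in, n_out, t0, quiet) {
  dt <- round(as.numeric(Sys.time()) - t0, 2)
  if (!quiet)
    message(sprintf("[%s] in=%d passed=%d removed=%d (%.2fs)",
                    name, n_in, n_out, n_in - n_out, dt))
  manifest$stages[[name]] <- list(input = n_in, passed = n_out,
                                  removed = n_in - n_out, seconds = dt)
  manifest
}

#' Run the full triage pipeline
#'
#' Stages run in workflow order; each writes `<stage>.csv` under
#' `config$out_dir` and contributes a funnel count line to the manifest
#' (`manifest.json`). Any stage error aborts with the stage name while
#' preserving the outputs already written.
#'
#' @param config a `run_config`
#' @param quiet suppress per-stage log lines
#' @return the manifest, invisibly (list with `stages`, `params`,
#'   `versions`, `started`, `finished`)
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    params = config[c("n", "k", "target", "top_m", "radius", "nbits",
                      "seed", "stage2_combine")],
    versions = list(
      package = as.character(utils::packageVersion("screentriage")),
      r = R.version.string),
    stages = list())
  stage <- "ingest"
  result <- tryCatch({
    t0 <- as.numeric(Sys.time())
    deck <- read_smiles_table(config$deck)
    n_rows <- nrow(deck) + nrow(attr(deck, "skipped"))
    manifest <- stage_log(manifest, "ingest", n_rows, nrow(deck), t0, quiet)

    stage <- "stage1_filter"
    t0 <- as.numeric(Sys.time())
    alerts <- if (is.null(config$alerts)) list(default_alert_set()) else
      list(read_alert_set(config$alerts))
    v1 <- stage1_filter(deck, alerts = alerts)
    write_report(v1, file.path(config$out_dir, "stage1_filter.csv"))
    deck1 <- apply_verdicts(deck, v1)
    manifest <- stage_log(manifest, "stage1_filter", nrow(deck),
                          nrow(deck1), t0, quiet)

    pharm_pass <- deck1$id
    if (!is.null(config$poses)) {
      stage <- "pharmacophore"
      t0 <- as.numeric(Sys.time())
      model <- read_pharmacophore(config$model)
      pr <- read_pose_sdf(config$poses)
      keep <- vapply(pr$poses, function(p)
        p$compound_id %in% deck1$id, logical(1))
      scr <- screen_poses(pr$poses[keep], model)
      write_report(scr$results,
                   file.path(config$out_dir, "pharmacophore.csv"))
      pharm_pass <- intersect(deck1$id, scr$pass_ids)
      manifest <- stage_log(manifest, "pharmacophore", nrow(deck1),
                            length(pharm_pass), t0, quiet)
    }

    stage <- "consensus_pool"
    t0 <- as.numeric(Sys.time())
    lists <- mapply(read_ranked_list, config$ranked_lists,
                    config$directions, SIMPLIFY = FALSE)
    lists <- lapply(lists, function(rl) {
      keep <- rl$id %in% pharm_pass
      ranked_list(attr(rl, "engine"), rl$id[keep], rl$score[keep],
                  attr(rl, "direction"))
    })
    pool <- pool_ranked_lists(lists, config$n)
    write_report(as.data.frame(pool),
                 file.path(config$out_dir, "consensus_pool.csv"))
    manifest <- stage_log(manifest, "consensus_pool", length(pharm_pass),
                          nrow(pool), t0, quiet)

    stage <- "stage2_filter"
    t0 <- as.numeric(Sys.time())
    pool_deck <- deck_subset(deck, pool$id)
    desc <- if (!is.null(config$descriptors)) {
      ext <- utils::read.csv(config$descriptors, stringsAsFactors = FALSE)
      m <- match(pool$id, ext$id)
      if (anyNA(m)) stop("descriptor table misses pool compounds")
      data.frame(id = pool$id, logd = ext$logd[m], psa = ext$psa[m])
    } else compute_descriptors(pool_deck)
    v2 <- stage2_filter(desc, combine = config$stage2_combine)
    write_report(v2, file.path(config$out_dir, "stage2_filter.csv"))
    survivor_ids <- global_rank(pool)
    survivor_ids <- survivor_ids[survivor_ids %in%
                                   v2$compound_id[v2$passed]]
    manifest <- stage_log(manifest, "stage2_filter", nrow(pool),
                          length(survivor_ids), t0, quiet)

    stage <- "cluster_select"
    t0 <- as.numeric(Sys.time())
    sdeck <- deck_subset(deck, survivor_ids)
    fps <- fingerprint_deck(sdeck, radius = config$radius,
                            nbits = config$nbits)
    cl <- kmedoids(tanimoto_distance_matrix(fps), config$k,
                   seed = config$seed)
    sel <- select_purchase_set(cl, survivor_ids, target = config$target,
                               top_m = config$top_m)
    write_report(as.data.frame(sel),
                 file.path(config$out_dir, "selection.csv"))
    manifest <- stage_log(manifest, "cluster_select", length(survivor_ids),
                          length(sel$chosen), t0, quiet)

    if (!is.null(config$labels)) {
      stage <- "metrics"
      t0 <- as.numeric(Sys.time())
      lab <- utils::read.csv(config$labels, stringsAsFactors = FALSE)
      hits <- sum(lab$active[match(sel$chosen, lab$id)], na.rm = TRUE)
      hr <- hit_rate(hits, length(sel$chosen))
      write_report(data.frame(metric = c("n_selected", "n_hits",
                                         "hit_rate_pct"),
                              value = c(length(sel$chosen), hits, hr)),
                   file.path(config$out_dir, "metrics.csv"))
      manifest$metrics <- list(n_hits = hits, hit_rate_pct = hr)
      manifest <- stage_log(manifest, "metrics", length(sel$chosen),
                            length(sel$chosen), t0, quiet)
    }
    manifest
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  result$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(result, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(result)
}

#' Per-stage funnel counts from a manifest
#' @param manifest list returned by [run_pipeline()]
#' @return named integer vector of `passed` counts per stage
#' @export
funnel_counts <- function(manifest) {
  vapply(manifest$stages, function(s) as.integer(s$passed), integer(1))
}
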