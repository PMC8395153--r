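#' Run the end-to-end analysis pipeline
#'
#' Orchestrates the stages on one configuration: synthesize (or load) a
#' cohort, discover the network's attractors, align the cohort to the
#' catalogued states, embed the dissimilarities into 2-D, and optionally
#' search for a treatment course. Every artifact is written under
#' `out_dir` and recorded, with the seed and configuration snapshot, in a
#' JSON run manifest; re-running with the same configuration and seed
#' reproduces the stochastic outputs.
#'
#' @param config list with elements `seed` (integer), `cohort` (arguments
#'   for [cohort_spec()], or an existing [cohort_table]), and optionally
#'   `attractors = list(n_starts =, max_steps =)`,
#'   `optimize` (arguments for [ga_config()]; `start` names the ill start
#'   state, default `"SS5"`). Stages `attractors`, `align`, `embed` run by
#'   default; `optimize` only if configured.
#' @param out_dir output directory (created if missing).
#' @return The manifest (invisibly), as written to `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(is.list(config), !is.null(config$seed))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  net <- gwi_network()
  catalogue <- gwi_states()
  outputs <- character()
  emit <- function(obj, name, writer) {
    path <- file.path(out_dir, name)
    writer(obj, path)
    outputs <<- c(outputs, path)
    path
  }

  # stage: cohort
  cohort <- if (inherits(config$cohort, "ternet_cohort")) config$cohort
  else gen_cohort(do.call(cohort_spec, as.list(config$cohort)), catalogue)
  emit(cbind(group = cohort$group, as.data.frame(cohort$values)),
       "cohort.tsv",
       function(d, p) utils::write.table(d, p, sep = "\t", quote = FALSE,
                                         row.names = FALSE))

  # stage: attractors
  acfg <- config$attractors
  att <- find_attractors(net,
                         n_starts = acfg$n_starts %||% 10000,
                         max_steps = acfg$max_steps %||% 1000)
  emit(cbind(as.data.frame(att$fixed_points), basin_count = att$counts),
       "attractors.tsv",
       function(d, p) utils::write.table(d, p, sep = "\t", quote = FALSE,
                                         row.names = FALSE))

  # stage: align
  rho <- control_correlation(cohort)
  al <- align_cohort(cohort, catalogue, rho = rho)
  merged <- merge_indistinguishable_states(
    catalogue, unname(cohort$map[colnames(cohort$values)]))
  dstates <- state_dissim_matrix(merged, cohort$map, rho, merge = FALSE)
  emit(as.data.frame(dstates), "state_dissimilarity.tsv",
       function(d, p) utils::write.table(d, p, sep = "\t", quote = FALSE,
                                         col.names = NA))

  # stage: embed (anchors + the condition point)
  k <- ncol(dstates)
  dfull <- rbind(cbind(dstates, condition = al$dissimilarity[colnames(dstates)]),
                 condition = c(al$dissimilarity[colnames(dstates)], 0))
  layout <- mds_embed(dfull, anchors = colnames(dstates))
  emit(data.frame(point = rownames(layout$points), layout$points,
                  is_anchor = rownames(layout$points) %in% layout$anchors),
       "layout.tsv",
       function(d, p) utils::write.table(d, p, sep = "\t", quote = FALSE,
                                         row.names = FALSE))

  # stage: optimize (optional)
  ga_summary <- NULL
  if (!is.null(config$optimize)) {
    oc <- config$optimize
    start_name <- oc$start %||% "SS5"
    oc$start <- NULL
    if (is.null(oc$allowed_targets)) oc$allowed_targets <- gwi_allowed_targets()
    cfg <- do.call(ga_config, oc)
    run <- multi_run_best(net, setNames(catalogue[, start_name],
                                        rownames(catalogue)), cfg)
    ga_summary <- list(start = start_name,
                       best_pct_hhm = run$best_fitness,
                       best_course = as.data.frame(run$best_course),
                       trace = run$trace)
    emit(ga_summary, "best_course.json",
         function(d, p) jsonlite::write_json(d, p, auto_unbox = TRUE,
                                             digits = NA))
  }

  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = config[setdiff(names(config), "cohort")],
    alignment = list(best = al$best,
                     dissimilarity = as.list(al$dissimilarity)),
    stress = attr(layout, "stress"),
    outputs = basename(outputs),
    checksums = vapply(outputs, function(p)
      as.character(tools::md5sum(p)), ""))
  names(manifest$checksums) <- basename(outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
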