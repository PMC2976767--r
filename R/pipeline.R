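#' Pipeline configuration
#'
#' Collects everything one run needs: inputs (FASTA per marker, taxonomy,
#' backbone — as paths or in-memory objects), the marker combination, the
#' search settings, an output directory and the master seed. Any field can
#' also come from a flat YAML file via [pipeline_config_from_yaml()], with
#' function arguments overriding file values.
#'
#' @param fastas Named list/vector of FASTA paths keyed by marker, or `NULL`
#'   when `records` is given.
#' @param records Optional tibble of sequence records (all markers).
#' @param taxonomy Path to a taxonomy TSV or a `community_taxonomy`.
#' @param backbone Path to a Newick backbone or a `phylo`.
#' @param markers Marker combination to analyse.
#' @param flags Optional per-sample recovery flags (path to CSV or tibble)
#'   for the recovery table.
#' @param search A [search_config()]; its seed is overridden by `seed`.
#' @param spacer_rank Rank used to partition the spacer alignment.
#' @param identify Run leave-one-out identification on the representatives.
#' @param out_dir Output directory (`NULL` for no files).
#' @param seed Master seed for the run.
#' @param quiet Suppress progress messages.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(fastas = NULL, records = NULL, taxonomy,
                            backbone, markers = MARKERS, flags = NULL,
                            search = search_config(),
                            spacer_rank = "family", identify = FALSE,
                            out_dir = NULL, seed = 1L, quiet = FALSE) {
  markers <- match.arg(markers, MARKERS, several.ok = TRUE)
  if (is.null(fastas) && is.null(records)) {
    stop("either fastas or records must be supplied", call. = FALSE)
  }
  structure(list(fastas = fastas, records = records, taxonomy = taxonomy,
                 backbone = backbone, markers = markers, flags = flags,
                 search = search, spacer_rank = spacer_rank,
                 identify = isTRUE(identify), out_dir = out_dir,
                 seed = as.integer(seed), quiet = isTRUE(quiet)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a flat YAML file
#'
#' @param path YAML file with keys matching [pipeline_config()] arguments
#'   (`fastas` as a marker-keyed map; `search` as a nested map).
#' @param ... Overrides, passed to [pipeline_config()]; they win over file
#'   values.
#' @return A `pipeline_config` list.
#' @export
pipeline_config_from_yaml <- function(path, ...) {
  y <- yaml::read_yaml(path)
  overrides <- list(...)
  if (!is.null(y$search)) y$search <- do.call(search_config, y$search)
  args <- utils::modifyList(y, overrides)
  do.call(pipeline_config, args)
}

run_stage <- function(name, quiet, expr) {
  if (!quiet) message("[", name, "] ...")
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  if (!quiet) {
    message("[", name, "] done in ",
            sprintf("%.1fs", proc.time()[["elapsed"]] - t0))
  }
  out
}

#' Run the full community-phylogeny pipeline
#'
#' Align each requested marker with its locus-appropriate strategy,
#' assemble the supermatrix, build the ordinal constraint, search under the
#' constraint with the parsimony ratchet, build the majority-rule
#' consensus, and compute the evaluation metrics. When `out_dir` is set,
#' writes the consensus (Newick), the matrix (NEXUS), all metric tables
#' (CSV), and a manifest recording seed and parameters for exact re-runs.
#'
#' @param config A [pipeline_config()].
#' @return A `barcomm_run` list with the supermatrix, constraint, tree set,
#'   consensus and metric tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  q <- config$quiet

  taxonomy <- run_stage("taxonomy", q, {
    if (inherits(config$taxonomy, "community_taxonomy")) config$taxonomy
    else read_taxonomy(config$taxonomy)
  })
  backbone <- run_stage("backbone", q, {
    if (inherits(config$backbone, "phylo")) validate_backbone(config$backbone)
    else read_backbone(config$backbone)
  })
  records <- run_stage("import", q, {
    if (!is.null(config$records)) {
      config$records[config$records$marker %in% config$markers, , drop = FALSE]
    } else {
      dplyr::bind_rows(lapply(intersect(config$markers, names(config$fastas)),
                              function(m) read_fasta(config$fastas[[m]], m)))
    }
  })

  blocks <- run_stage("align", q, {
    out <- list()
    for (m in config$markers) {
      rec <- choose_species_representative(
        records[records$marker == m, , drop = FALSE])
      if (nrow(rec) == 0L) next
      if (m == "rbcLa") {
        out <- c(out, list(align_coding_global(rec)))
      } else if (m == "matK") {
        out <- c(out, list(align_backtranslate(rec)))
      } else {
        out <- c(out, align_partitioned(rec, taxonomy,
                                        rank = config$spacer_rank))
      }
    }
    out
  })

  sm <- run_stage("supermatrix", q, assemble_supermatrix(blocks, taxonomy))
  constraint <- run_stage("constraint", q,
                          build_constraint(backbone, taxonomy, sm$species))
  search <- config$search
  search$seed <- config$seed
  ts <- run_stage("search", q, ratchet_search(sm, constraint, search))
  consensus <- run_stage("consensus", q, majority_consensus(ts))

  metrics <- run_stage("metrics", q, {
    mono <- dplyr::bind_rows(lapply(c("genus", "family", "order"),
                                    function(rk)
                                      monophyly_report(consensus, taxonomy, rk)))
    mis <- misplaced_orders(consensus, backbone, taxonomy,
                            seed = config$seed)
    list(
      resolution = resolution_fraction(consensus),
      support = support_bins(consensus),
      monophyly = mono,
      misplaced = mis,
      missing = missing_fraction(sm)
    )
  })

  identification <- NULL
  recovery <- NULL
  if (config$identify) {
    identification <- run_stage("identify", q,
                                loo_identify(records, taxonomy))
  }
  if (!is.null(config$flags)) {
    recovery <- run_stage("recovery", q, {
      flags <- if (is.character(config$flags)) {
        fl <- utils::read.csv(config$flags, stringsAsFactors = FALSE)
        fl$success <- as.logical(fl$success)
        fl
      } else config$flags
      s2s <- dplyr::distinct(records[c("sample_id", "species_code")])
      names(s2s) <- c("sample_id", "species")
      extra <- setdiff(flags$sample_id, s2s$sample_id)
      if (length(extra)) {
        # flags may cover samples whose sequences were all dropped; map
        # them by the sample-id = species convention used by the simulator
        s2s <- dplyr::bind_rows(s2s, tibble::tibble(sample_id = extra,
                                                    species = extra))
      }
      recovery_table(tibble::as_tibble(flags), s2s, taxonomy)
    })
  }

  run <- structure(
    list(supermatrix = sm, constraint = constraint, tree_set = ts,
         consensus = consensus, metrics = metrics,
         identification = identification, recovery = recovery,
         taxonomy = taxonomy, config = config),
    class = "barcomm_run")

  if (!is.null(config$out_dir)) {
    run_stage("write", q, write_run(run, config$out_dir))
  }
  run
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  ape::write.tree(run$consensus, p("consensus.nwk"))
  write_tree_set(run$tree_set, p("mp_trees.nwk"))
  write_supermatrix(run$supermatrix, p("matrix.nex"), "nexus")
  ape::write.tree(run$constraint, p("constraint.nwk"))
  utils::write.csv(run$metrics$support, p("support_bins.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(run$metrics$monophyly, p("monophyly.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(
    tibble::tibble(order = run$metrics$misplaced$misplaced),
    p("misplaced_orders.csv"), row.names = FALSE, quote = FALSE)
  summary_df <- tibble::tibble(
    metric = c("resolution_pct", "missing_fraction", "mp_score", "n_mp_trees",
               "n_misplaced_orders"),
    value = c(run$metrics$resolution, run$metrics$missing,
              run$tree_set$score, length(run$tree_set$trees),
              run$metrics$misplaced$n_misplaced))
  utils::write.csv(summary_df, p("summary.csv"), row.names = FALSE,
                   quote = FALSE)
  if (!is.null(run$identification)) {
    utils::write.csv(tibble::as_tibble(run$identification),
                     p("identification.csv"), row.names = FALSE, quote = FALSE)
  }
  if (!is.null(run$recovery)) {
    utils::write.csv(tibble::as_tibble(run$recovery), p("recovery.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  manifest <- list(
    package = "barcomm",
    version = as.character(utils::packageVersion("barcomm")),
    seed = run$config$seed,
    markers = run$config$markers,
    search = unclass(run$config$search),
    spacer_rank = run$config$spacer_rank,
    n_species = length(run$supermatrix$species),
    n_characters = ncol(run$supermatrix$matrix),
    mp_score = run$tree_set$score,
    outputs = c("consensus.nwk", "mp_trees.nwk", "matrix.nex",
                "constraint.nwk", "support_bins.csv", "monophyly.csv",
                "misplaced_orders.csv", "summary.csv")
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.barcomm_run <- function(x, ...) {
  cat("<barcomm_run>\n")
  cat("  species:    ", length(x$supermatrix$species), "\n")
  cat("  characters: ", ncol(x$supermatrix$matrix),
      sprintf(" (%.1f%% missing)", 100 * x$metrics$missing), "\n")
  cat("  MP score:   ", x$tree_set$score, " (",
      length(x$tree_set$trees), " trees)\n", sep = "")
  cat("  resolution: ", sprintf("%.1f%%", x$metrics$resolution), "\n")
  cat("  misplaced orders: ", x$metrics$misplaced$n_misplaced, "\n")
  invisible(x)
}

#' One-row summary of a pipeline run
#'
#' @param x A `barcomm_run`.
#' @param ... Unused.
#' @return Tibble with the headline statistics of the run.
#' @export
glance.barcomm_run <- function(x, ...) {
  tibble::tibble(
    n_species = length(x$supermatrix$species),
    n_characters = ncol(x$supermatrix$matrix),
    missing_fraction = x$metrics$missing,
    mp_score = x$tree_set$score,
    n_mp_trees = length(x$tree_set$trees),
    resolution_pct = x$metrics$resolution,
    support_ge85_pct = x$metrics$support$ge85,
    n_misplaced_orders = x$metrics$misplaced$n_misplaced
  )
}
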