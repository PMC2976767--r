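#' Hierarchical sequence-recovery table
#'
#' Tabulates sequencing success per marker and marker union at the sample,
#' species, genus, family, and order levels. A sample succeeds for a union
#' column if any constituent marker succeeded for it; a species succeeds iff
#' any of its samples does, and higher ranks succeed iff any child does.
#' Totals at species level and above come from the full taxonomy, so taxa
#' with no sequenced samples count as failures.
#'
#' @param flags Tibble with columns `sample_id`, `marker`, `success`
#'   (logical). Missing (sample, marker) combinations count as failures.
#' @param sample_to_species Tibble with columns `sample_id`, `species`.
#' @param taxonomy A `community_taxonomy`.
#' @param combos Named list of marker combinations to add as union columns;
#'   defaults to the conventional pairings plus all markers present.
#' @return A `recovery_table` tibble: `level`, `column`, `successes`,
#'   `total`, `pct` (1 decimal).
#' @export
recovery_table <- function(flags, sample_to_species, taxonomy,
                           combos = NULL) {
  need <- c("sample_id", "marker", "success")
  if (!all(need %in% names(flags))) {
    stop("flags must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  unmapped <- setdiff(flags$sample_id, sample_to_species$sample_id)
  if (length(unmapped)) {
    stop("samples not mapped to a species: ",
         paste(unique(unmapped), collapse = ", "), call. = FALSE)
  }
  bad_sp <- setdiff(sample_to_species$species, taxonomy$species)
  if (length(bad_sp)) {
    stop("mapped species not in taxonomy: ",
         paste(unique(bad_sp), collapse = ", "), call. = FALSE)
  }
  markers <- intersect(MARKERS, unique(flags$marker))
  if (is.null(combos)) {
    combos <- list()
    if (all(c("rbcLa", "trnH-psbA") %in% markers)) {
      combos[["rbcLa+trnH-psbA"]] <- c("rbcLa", "trnH-psbA")
    }
    if (all(c("rbcLa", "matK") %in% markers)) {
      combos[["rbcLa+matK"]] <- c("rbcLa", "matK")
    }
    if (length(markers) > 1L) combos[["all"]] <- markers
  }

  # per-sample success in wide form; absent flags are failures
  wide <- flags |>
    dplyr::group_by(.data$sample_id, .data$marker) |>
    dplyr::summarise(success = any(.data$success), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "marker", values_from = "success",
                       values_fill = FALSE)
  for (m in markers) if (!m %in% names(wide)) wide[[m]] <- FALSE
  for (cn in names(combos)) {
    wide[[cn]] <- Reduce(`|`, lapply(combos[[cn]], function(m) wide[[m]]))
  }
  columns <- c(markers, names(combos))

  ranks <- c("species", "genus", "family", "order")
  joined <- wide |>
    dplyr::left_join(sample_to_species, by = "sample_id") |>
    dplyr::left_join(taxonomy, by = "species")

  totals <- c(sample = nrow(wide),
              species = length(unique(taxonomy$species)),
              genus = length(unique(taxonomy$genus)),
              family = length(unique(taxonomy$family)),
              order = length(unique(taxonomy$order)))

  rows <- list()
  for (col in columns) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      level = "sample", column = col,
      successes = sum(joined[[col]]), total = unname(totals["sample"]))
    for (rk in ranks) {
      succ <- joined |>
        dplyr::group_by(dplyr::across(dplyr::all_of(rk))) |>
        dplyr::summarise(ok = any(.data[[col]]), .groups = "drop")
      rows[[length(rows) + 1L]] <- tibble::tibble(
        level = rk, column = col,
        successes = sum(succ$ok), total = unname(totals[rk]))
    }
  }
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(pct = round(100 * .data$successes / .data$total, 1))
  out$level <- factor(out$level, levels = c("sample", ranks))
  out <- dplyr::arrange(out, .data$level, match(.data$column, columns))
  out$level <- as.character(out$level)
  class(out) <- c("recovery_table", class(out))
  out
}

#' Build a recovery table directly from published success counts
#'
#' Convenience constructor for tabulated recovery counts (e.g. transcribing
#' a published recovery table): computes the percentage column and returns
#' the same object [recovery_table()] produces.
#'
#' @param counts Data frame with columns `level`, `column`, `successes`,
#'   `total`.
#' @return A `recovery_table` tibble.
#' @export
recovery_table_from_counts <- function(counts) {
  need <- c("level", "column", "successes", "total")
  if (!all(need %in% names(counts))) {
    stop("counts must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(counts)[need] |>
    dplyr::mutate(pct = round(100 * .data$successes / .data$total, 1))
  class(out) <- c("recovery_table", class(out))
  out
}

#' Leave-one-out barcode identification
#'
#' Each sequence is queried against all other sequences of the same marker;
#' the best matches are those with the highest global-alignment identity
#' computed over the shorter sequence. A query is correctly identified at a
#' rank iff all tied best hits belong to the query's taxon at that rank, so
#' a tie spanning two species counts as a species-level failure (but may
#' still be correct at genus level). Correct-identification (CI) frequency
#' is the fraction of correct queries.
#'
#' @param records Tibble of sequence records (may span markers; each marker
#'   is analysed separately and needs at least two sequences).
#' @param taxonomy A `community_taxonomy` covering all record species.
#' @param ranks Ranks to score.
#' @return An `identification_report` tibble: `marker`, `rank`, `n_queries`,
#'   `n_correct`, `ci`. Per-query outcomes are in the `"outcomes"`
#'   attribute.
#' @export
loo_identify <- function(records, taxonomy,
                         ranks = c("species", "genus", "family", "order")) {
  validate_records(records)
  ranks <- match.arg(ranks, several.ok = TRUE)
  missing <- setdiff(records$species_code, taxonomy$species)
  if (length(missing)) {
    stop("species not in taxonomy: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tax <- taxonomy
  tax$species_code <- tax$species
  outcomes <- list()
  for (m in unique(records$marker)) {
    rec <- records[records$marker == m, , drop = FALSE]
    if (nrow(rec) < 2L) {
      stop("need at least two sequences for marker ", m, call. = FALSE)
    }
    seqs <- Biostrings::DNAStringSet(gsub("[^ACGTRYSWKMBDHVN]", "N",
                                          rec$bases))
    for (q in seq_len(nrow(rec))) {
      others <- setdiff(seq_len(nrow(rec)), q)
      aln <- Biostrings::pairwiseAlignment(seqs[others], seqs[[q]],
                                           type = "global")
      ident <- Biostrings::pid(aln, type = "PID3")
      best <- others[ident >= max(ident) - 1e-9]
      outcomes[[length(outcomes) + 1L]] <- tibble::tibble(
        marker = m,
        query_sample = rec$sample_id[q],
        query_species = rec$species_code[q],
        hit_species = list(unique(rec$species_code[best]))
      )
    }
  }
  oc <- dplyr::bind_rows(outcomes)

  rank_of <- function(species, rk) {
    tax[[rk]][match(species, tax$species)]
  }
  rows <- list()
  for (m in unique(oc$marker)) {
    sub <- oc[oc$marker == m, , drop = FALSE]
    for (rk in ranks) {
      qtax <- rank_of(sub$query_species, rk)
      correct <- vapply(seq_len(nrow(sub)), function(i) {
        hits <- rank_of(sub$hit_species[[i]], rk)
        all(hits == qtax[i])
      }, logical(1))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        marker = m, rank = rk, n_queries = nrow(sub),
        n_correct = sum(correct), ci = mean(correct))
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "outcomes") <- oc
  class(out) <- c("identification_report", class(out))
  out
}

# round half away from zero to integer percent
round_half_up <- function(x) floor(x + 0.5)

#' Effective identification power: recovery times CI
#'
#' Multiplies the sequence-recovery proportion by the correct-identification
#' frequency for each (marker, rank) pair present in both tables and reports
#' the product as an integer percentage (half rounds up).
#'
#' @param recovery A `recovery_table` (levels matching the report's ranks).
#' @param report An `identification_report`.
#' @return Tibble: `marker`, `rank`, `recovery`, `ci`, `recovery_times_ci`
#'   (integer percent).
#' @export
recovery_times_ci <- function(recovery, report) {
  rec <- recovery |>
    dplyr::transmute(marker = .data$column, rank = .data$level,
                     recovery = .data$successes / .data$total)
  joined <- dplyr::inner_join(tibble::as_tibble(report), rec,
                              by = c("marker", "rank"))
  missing_keys <- dplyr::anti_join(tibble::as_tibble(report), rec,
                                   by = c("marker", "rank"))
  if (nrow(missing_keys)) {
    stop("no recovery entry for: ",
         paste(missing_keys$marker, missing_keys$rank, sep = "/",
               collapse = ", "), call. = FALSE)
  }
  joined |>
    dplyr::transmute(.data$marker, .data$rank, .data$recovery, .data$ci,
                     recovery_times_ci =
                       round_half_up(100 * .data$recovery * .data$ci))
}
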