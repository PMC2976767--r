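#' Read barcode sequences from a FASTA file
#'
#' Headers follow the convention `sampleID|speciesCode`; a species-level file
#' may omit the sample field, in which case the species code doubles as the
#' sample id. Sequences are uppercased and any alignment gap characters
#' (`-`, `.`) are stripped, so records always hold unaligned bases.
#'
#' @param path Path to a FASTA file.
#' @param marker Marker name, one of [barcode_markers()].
#' @return A tibble of records with columns `sample_id`, `species_code`,
#'   `marker`, `bases`.
#' @export
read_fasta <- function(path, marker) {
  marker <- match.arg(marker, MARKERS)
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*$", lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1L]) {
    stop("malformed FASTA at line ", line_no[1L],
         ": expected a '>' header before sequence data", call. = FALSE)
  }
  grp <- cumsum(is_hdr)
  headers <- sub("^>\\s*", "", lines[is_hdr])
  seqs <- vapply(split(lines[!is_hdr], grp[!is_hdr]), paste0,
                 character(1), collapse = "")
  seqs_full <- rep("", length(headers))
  seqs_full[as.integer(names(seqs))] <- seqs
  empty <- seqs_full == ""
  if (any(empty)) {
    stop("empty sequence for FASTA entr", if (sum(empty) > 1) "ies: " else "y: ",
         paste(headers[empty], collapse = ", "), call. = FALSE)
  }
  bases <- toupper(gsub("[-.]", "", gsub("\\s", "", seqs_full)))
  bad <- !grepl("^[ACGTURYSWKMBDHVN?]*$", bases)
  if (any(bad)) {
    first <- which(bad)[1L]
    stop("non-IUPAC characters in sequence for header '", headers[first], "'",
         call. = FALSE)
  }
  parts <- stringr::str_split_fixed(headers, stringr::fixed("|"), 2)
  has_sample <- parts[, 2] != ""
  tibble::tibble(
    sample_id = trimws(ifelse(has_sample, parts[, 1], parts[, 1])),
    species_code = trimws(ifelse(has_sample, parts[, 2], parts[, 1])),
    marker = marker,
    bases = unname(bases)
  )
}

#' Write barcode records to FASTA
#'
#' Inverse of [read_fasta()]: headers are `sampleID|speciesCode`, or the bare
#' species code when the sample id equals it.
#'
#' @param records Tibble of records as returned by [read_fasta()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  validate_records(records)
  hdr <- ifelse(records$sample_id == records$species_code,
                records$species_code,
                paste0(records$sample_id, "|", records$species_code))
  writeLines(paste0(">", hdr, "\n", records$bases), path)
  invisible(path)
}

validate_records <- function(records) {
  need <- c("sample_id", "species_code", "marker", "bases")
  if (!all(need %in% names(records))) {
    stop("records must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(!records$marker %in% MARKERS)) {
    stop("unknown marker(s): ",
         paste(unique(setdiff(records$marker, MARKERS)), collapse = ", "),
         call. = FALSE)
  }
  if (any(nchar(records$bases) == 0L)) stop("empty bases in records", call. = FALSE)
  invisible(records)
}

#' Pick one representative sequence per species and marker
#'
#' Selection is deterministic: the longest sequence wins, ties broken by the
#' lexicographically smallest sample id, so the result does not depend on
#' input order.
#'
#' @param records Tibble of records for a single marker.
#' @return Tibble with one row per species present at the marker.
#' @export
choose_species_representative <- function(records) {
  validate_records(records)
  if (length(unique(records$marker)) > 1L) {
    stop("records must share a single marker", call. = FALSE)
  }
  records |>
    dplyr::mutate(.len = nchar(.data$bases)) |>
    dplyr::arrange(.data$species_code, dplyr::desc(.data$.len), .data$sample_id) |>
    dplyr::distinct(.data$species_code, .keep_all = TRUE) |>
    dplyr::select(-".len")
}

#' Read and validate a community taxonomy table
#'
#' Expects a TSV with columns `species`, `genus`, `family`, `order`.
#' Species must be unique, every genus must belong to exactly one family and
#' every family to exactly one order; violations are input errors.
#'
#' @param path Path to the TSV file.
#' @return A `community_taxonomy` tibble.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("taxonomy file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE)
  as_community_taxonomy(tab)
}

#' Coerce a data frame to a validated community taxonomy
#'
#' @param x Data frame with columns `species`, `genus`, `family`, `order`.
#' @return A `community_taxonomy` tibble.
#' @export
as_community_taxonomy <- function(x) {
  need <- c("species", "genus", "family", "order")
  if (!all(need %in% names(x))) {
    stop("taxonomy must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tax <- tibble::as_tibble(x)[need]
  tax[] <- lapply(tax, as.character)
  if (any(is.na(tax)) || any(unlist(tax) == "")) {
    stop("taxonomy contains empty entries", call. = FALSE)
  }
  dup <- tax$species[duplicated(tax$species)]
  if (length(dup)) {
    stop("duplicate species in taxonomy: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  gf <- dplyr::distinct(tax, .data$genus, .data$family)
  badg <- gf$genus[duplicated(gf$genus)]
  if (length(badg)) {
    stop("genus assigned to more than one family: ",
         paste(unique(badg), collapse = ", "), call. = FALSE)
  }
  fo <- dplyr::distinct(tax, .data$family, .data$order)
  badf <- fo$family[duplicated(fo$family)]
  if (length(badf)) {
    stop("family assigned to more than one order: ",
         paste(unique(badf), collapse = ", "), call. = FALSE)
  }
  class(tax) <- c("community_taxonomy", class(tax))
  tax
}

#' Write a community taxonomy table to TSV
#'
#' @param taxonomy A `community_taxonomy` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  utils::write.table(as.data.frame(taxonomy)[c("species", "genus", "family", "order")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Count taxa at each rank of a taxonomy
#'
#' @param taxonomy A `community_taxonomy` tibble.
#' @return Named integer vector with counts of species, genera, families and
#'   orders.
#' @export
taxonomy_counts <- function(taxonomy) {
  c(species = length(unique(taxonomy$species)),
    genus = length(unique(taxonomy$genus)),
    family = length(unique(taxonomy$family)),
    order = length(unique(taxonomy$order)))
}

#' Read an ordinal backbone topology
#'
#' The backbone is a rooted Newick tree whose tips are order names. When a
#' taxonomy is supplied, every order in the community must be present in the
#' backbone.
#'
#' @param path Path to a Newick file.
#' @param taxonomy Optional `community_taxonomy` used to validate coverage.
#' @return An `ape::phylo` tree.
#' @export
read_backbone <- function(path, taxonomy = NULL) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick backbone: ", path, call. = FALSE)
  validate_backbone(tree, taxonomy)
}

validate_backbone <- function(tree, taxonomy = NULL) {
  if (any(duplicated(tree$tip.label))) {
    stop("backbone tip names are not unique", call. = FALSE)
  }
  if (!is.null(taxonomy)) {
    missing <- setdiff(unique(taxonomy$order), tree$tip.label)
    if (length(missing)) {
      stop("orders missing from backbone: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  tree
}
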