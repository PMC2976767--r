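#' Assemble locus alignments into a sparse supermatrix
#'
#' Concatenates alignment blocks column-wise over the union of their species.
#' Cells for species absent from a block are filled with `?`. Species whose
#' only data come from taxonomically partitioned spacer blocks are excluded
#' (a lone spacer fragment cannot place a species, mirroring the exclusion of
#' taxa sequenced for the spacer alone); every retained species therefore has
#' at least one global-block sequence.
#'
#' @param blocks List of `barcode_alignment` objects.
#' @param taxonomy Optional `community_taxonomy`; when given, all block taxa
#'   must appear in it.
#' @return A `supermatrix` object: character matrix (`species` x characters)
#'   plus a partitions tibble with 0-based half-open column intervals.
#' @export
assemble_supermatrix <- function(blocks, taxonomy = NULL) {
  if (length(blocks) == 0L) stop("no alignment blocks", call. = FALSE)
  for (b in blocks) {
    if (!inherits(b, "barcode_alignment")) {
      stop("blocks must be barcode_alignment objects", call. = FALSE)
    }
    if (any(duplicated(b$taxa))) {
      stop("duplicate species within one block: ",
           paste(unique(b$taxa[duplicated(b$taxa)]), collapse = ", "),
           call. = FALSE)
    }
  }
  if (!is.null(taxonomy)) {
    all_taxa <- unique(unlist(lapply(blocks, `[[`, "taxa")))
    missing <- setdiff(all_taxa, taxonomy$species)
    if (length(missing)) {
      stop("block species not in taxonomy: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }

  anchored <- unique(unlist(lapply(blocks, function(b)
    if (!b$partitioned) b$taxa else character(0))))
  everyone <- unique(unlist(lapply(blocks, `[[`, "taxa")))
  if (length(anchored) == 0L) {
    # spacer-only analysis: with no global block the exclusion rule would
    # empty the matrix, so everyone with data is kept
    anchored <- everyone
  }
  excluded <- setdiff(everyone, anchored)
  species <- sort(anchored)

  widths <- vapply(blocks, alignment_ncol, integer(1))
  labels <- vapply(blocks, function(b) {
    if (b$partition_label == "global") b$marker
    else paste0(b$marker, ":", b$partition_label)
  }, character(1))
  ends <- cumsum(widths)
  starts <- c(0L, head(ends, -1L))

  mat <- matrix("?", length(species), sum(widths),
                dimnames = list(species, NULL))
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    keep <- intersect(b$taxa, species)
    if (!length(keep)) next
    rows <- do.call(rbind, strsplit(b$seqs[keep], "", fixed = TRUE))
    mat[keep, (starts[i] + 1L):ends[i]] <- rows
  }

  structure(
    list(species = species,
         matrix = mat,
         partitions = tibble::tibble(label = labels, start = starts,
                                     end = ends),
         excluded_species = sort(excluded)),
    class = "supermatrix"
  )
}

#' @export
print.supermatrix <- function(x, ...) {
  cat("<supermatrix> ", length(x$species), " species x ", ncol(x$matrix),
      " characters, ", nrow(x$partitions), " partition(s); ",
      sprintf("%.1f%%", 100 * missing_fraction(x)), " missing\n", sep = "")
  invisible(x)
}

#' Fraction of missing cells in a supermatrix
#'
#' Both `?` (absent data) and `-` (alignment gap) count as missing, matching
#' their treatment in parsimony scoring where gaps are not coded as states.
#'
#' @param sm A `supermatrix`.
#' @return Proportion in `[0, 1]`.
#' @export
missing_fraction <- function(sm) {
  if (!inherits(sm, "supermatrix")) stop("not a supermatrix", call. = FALSE)
  mean(sm$matrix == "?" | sm$matrix == "-")
}

row_strings <- function(sm) {
  apply(sm$matrix, 1L, paste0, collapse = "")
}

#' Export a supermatrix
#'
#' Serialization is deterministic (byte-identical across runs). NEXUS files
#' carry the partitions as 1-based inclusive `charset` statements in a SETS
#' block; CSV holds one character per column; relaxed PHYLIP has no partition
#' information.
#'
#' @param sm A `supermatrix`.
#' @param path Output path.
#' @param format `"nexus"`, `"phylip"`, or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_supermatrix <- function(sm, path, format = c("nexus", "phylip", "csv")) {
  format <- match.arg(format)
  rows <- row_strings(sm)
  if (format == "nexus") {
    pad <- max(nchar(sm$species)) + 2L
    lines <- c(
      "#NEXUS",
      "BEGIN DATA;",
      sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(sm$species),
              ncol(sm$matrix)),
      "  FORMAT DATATYPE=DNA MISSING=? GAP=-;",
      "  MATRIX",
      sprintf("    %s%s", formatC(sm$species, width = -pad), rows),
      "  ;",
      "END;",
      "BEGIN SETS;",
      sprintf("  CHARSET %s = %d-%d;",
              gsub("[^A-Za-z0-9_.:+-]", "_", sm$partitions$label),
              sm$partitions$start + 1L, sm$partitions$end),
      "END;"
    )
    writeLines(lines, path)
  } else if (format == "phylip") {
    writeLines(c(sprintf("%d %d", length(sm$species), ncol(sm$matrix)),
                 paste(sm$species, rows)), path)
  } else {
    df <- as.data.frame(sm$matrix, stringsAsFactors = FALSE)
    names(df) <- paste0("c", seq_len(ncol(df)))
    utils::write.csv(cbind(species = sm$species, df), path, row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}

#' Read a supermatrix written by [write_supermatrix()]
#'
#' @param path Input path.
#' @param format `"nexus"`, `"phylip"`, or `"csv"`.
#' @return A `supermatrix`.
#' @export
read_supermatrix <- function(path, format = c("nexus", "phylip", "csv")) {
  format <- match.arg(format)
  if (format == "nexus") {
    lines <- readLines(path)
    mstart <- grep("^\\s*MATRIX\\s*$", lines)[1L]
    mend <- which(grepl("^\\s*;\\s*$", lines) & seq_along(lines) > mstart)[1L]
    body <- trimws(lines[(mstart + 1L):(mend - 1L)])
    body <- body[body != ""]
    parts <- stringr::str_split_fixed(body, "\\s+", 2)
    species <- parts[, 1]
    rows <- gsub("\\s", "", parts[, 2])
    cs <- grep("^\\s*CHARSET\\s", lines, value = TRUE)
    m <- stringr::str_match(cs, "CHARSET\\s+(\\S+)\\s*=\\s*(\\d+)-(\\d+)")
    partitions <- tibble::tibble(label = m[, 2],
                                 start = as.integer(m[, 3]) - 1L,
                                 end = as.integer(m[, 4]))
  } else if (format == "phylip") {
    lines <- readLines(path)
    parts <- stringr::str_split_fixed(trimws(lines[-1L]), "\\s+", 2)
    species <- parts[, 1]
    rows <- gsub("\\s", "", parts[, 2])
    partitions <- tibble::tibble(label = "all", start = 0L,
                                 end = nchar(rows[1L]))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
    species <- df$species
    rows <- apply(as.matrix(df[-1L]), 1L, paste0, collapse = "")
    partitions <- tibble::tibble(label = "all", start = 0L,
                                 end = nchar(rows[1L]))
  }
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  rownames(mat) <- species
  structure(list(species = species, matrix = mat, partitions = partitions,
                 excluded_species = character(0)),
            class = "supermatrix")
}
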