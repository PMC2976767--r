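#' Construct an alignment object
#'
#' An alignment is a set of equal-length IUPAC strings (with `-` gaps and `?`
#' missing cells) over unique taxa, tagged with its marker and a partition
#' label (`"global"` for whole-community blocks, or a taxon name for
#' taxonomically partitioned spacer blocks).
#'
#' @param marker Marker name.
#' @param partition_label Label for the block.
#' @param seqs Named character vector of equal-length aligned sequences.
#' @param partitioned Logical; `TRUE` for taxonomically partitioned spacer
#'   blocks (these do not count as evidence for supermatrix inclusion).
#' @return A `barcode_alignment` object.
#' @export
new_alignment <- function(marker, partition_label, seqs, partitioned = FALSE) {
  if (length(seqs) < 1L) stop("alignment needs at least one row", call. = FALSE)
  if (is.null(names(seqs)) || any(names(seqs) == "") ||
      any(duplicated(names(seqs)))) {
    stop("alignment rows must carry unique taxon names", call. = FALSE)
  }
  if (length(unique(nchar(seqs))) != 1L) {
    stop("alignment rows must be equal length", call. = FALSE)
  }
  structure(
    list(marker = marker, partition_label = partition_label,
         taxa = names(seqs), seqs = seqs, partitioned = isTRUE(partitioned)),
    class = "barcode_alignment"
  )
}

#' @export
print.barcode_alignment <- function(x, ...) {
  cat("<barcode_alignment> ", x$marker, " [", x$partition_label, "]: ",
      length(x$taxa), " taxa x ", nchar(x$seqs[[1]]), " columns\n", sep = "")
  invisible(x)
}

#' Number of columns in an alignment
#' @param aln A `barcode_alignment`.
#' @return Integer column count.
#' @export
alignment_ncol <- function(aln) nchar(aln$seqs[[1L]])

#' Recover the ungapped input sequence from an alignment row
#'
#' Drops gap (`-`) and missing-pad (`?`) characters.
#' @param aln A `barcode_alignment`.
#' @param taxon Taxon name.
#' @return The unaligned sequence string.
#' @export
ungapped_row <- function(aln, taxon) {
  gsub("[-?]", "", aln$seqs[[taxon]])
}

#' Write an alignment as aligned FASTA
#' @param aln A `barcode_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(aln, path) {
  writeLines(paste0(">", aln$taxa, "\n", aln$seqs[aln$taxa]), path)
  invisible(path)
}

## ---- progressive aligner ---------------------------------------------------

# k-mer Jaccard distance between raw sequences; guide for progressive merging
kmer_jaccard <- function(seqs, k = 8L) {
  sets <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n <= k) return(s)
    unique(substring(s, 1:(n - k + 1L), k:n))
  })
  n <- length(sets)
  d <- matrix(0, n, n)
  if (n > 1L) {
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      inter <- length(intersect(sets[[i]], sets[[j]]))
      uni <- length(union(sets[[i]], sets[[j]]))
      d[i, j] <- d[j, i] <- 1 - inter / uni
    }
  }
  dimnames(d) <- list(names(seqs), names(seqs))
  d
}

dna_alphabet <- c("A", "C", "G", "T")

# fractional base masses for one aligned string; ambiguity codes split their
# mass across the bases they denote, gaps and '?' carry no mass
dna_profile <- function(rows) {
  L <- nchar(rows[[1L]])
  prof <- matrix(0, 4L, L)
  for (r in rows) {
    ch <- strsplit(r, "", fixed = TRUE)[[1L]]
    mask <- IUPAC_MASK[ch]
    mask[is.na(mask) | ch %in% c("-", "?")] <- 0L
    for (b in 1:4) {
      hit <- bitwAnd(mask, bitwShiftL(1L, b - 1L)) > 0L
      nbits <- (bitwAnd(mask, 1L) > 0) + (bitwAnd(mask, 2L) > 0) +
        (bitwAnd(mask, 4L) > 0) + (bitwAnd(mask, 8L) > 0)
      prof[b, hit] <- prof[b, hit] + 1 / nbits[hit]
    }
  }
  prof / length(rows)
}

protein_alphabet <- c(LETTERS[!LETTERS %in% c("B", "J", "O", "U", "Z")], "*")

protein_profile <- function(rows) {
  L <- nchar(rows[[1L]])
  k <- length(protein_alphabet)
  prof <- matrix(0, k, L)
  idx <- stats::setNames(seq_len(k), protein_alphabet)
  for (r in rows) {
    ch <- strsplit(r, "", fixed = TRUE)[[1L]]
    pos <- idx[ch]
    ok <- !is.na(pos)
    for (q in which(ok)) prof[pos[q], q] <- prof[pos[q], q] + 1
  }
  prof / length(rows)
}

score_matrix <- function(type) {
  if (type == "dna") {
    s <- matrix(-1, 4, 4, dimnames = list(dna_alphabet, dna_alphabet))
    diag(s) <- 1
  } else {
    k <- length(protein_alphabet)
    s <- matrix(-1, k, k, dimnames = list(protein_alphabet, protein_alphabet))
    diag(s) <- 1
    s["X", ] <- 0  # translation wildcard aligns freely
    s[, "X"] <- 0
  }
  s
}

expand_rows <- function(rows, src) {
  # src: per output column, source column (0 = gap)
  vapply(rows, function(r) {
    ch <- strsplit(r, "", fixed = TRUE)[[1L]]
    out <- rep("-", length(src))
    out[src > 0L] <- ch[src[src > 0L]]
    paste0(out, collapse = "")
  }, character(1))
}

#' Progressive multiple alignment
#'
#' Pairwise Needleman-Wunsch profile alignments (match +1, mismatch -1, gap
#' open -2, gap extend -1) merged along a UPGMA guide tree built from 8-mer
#' Jaccard distances. Taxa are processed in name order so the result is
#' independent of input ordering.
#'
#' @param seqs Named character vector of unaligned sequences.
#' @param type `"dna"` or `"protein"`.
#' @param gap_open,gap_extend Positive gap penalty magnitudes.
#' @param k k-mer size for the guide-tree distance.
#' @return Named character vector of equal-length aligned sequences.
#' @export
progressive_align <- function(seqs, type = c("dna", "protein"),
                              gap_open = 2, gap_extend = 1, k = 8L) {
  type <- match.arg(type)
  if (length(seqs) == 0L) stop("no sequences to align", call. = FALSE)
  seqs <- seqs[order(names(seqs))]
  if (length(seqs) == 1L) return(seqs)
  S <- score_matrix(type)
  profile_of <- if (type == "dna") dna_profile else protein_profile

  d <- kmer_jaccard(seqs, k = k)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  clusters <- lapply(seq_along(seqs), function(i) seqs[i])

  merged <- vector("list", nrow(hc$merge))
  get_cluster <- function(id) if (id < 0) clusters[[-id]] else merged[[id]]
  for (m in seq_len(nrow(hc$merge))) {
    a <- get_cluster(hc$merge[m, 1L])
    b <- get_cluster(hc$merge[m, 2L])
    path <- nw_profile_cpp(profile_of(a), profile_of(b), S,
                           gap_open, gap_extend)
    merged[[m]] <- c(expand_rows(a, path[1L, ]), expand_rows(b, path[2L, ]))
  }
  out <- merged[[nrow(hc$merge)]]
  out[order(names(out))]
}

## ---- locus strategies ------------------------------------------------------

#' Globally align a coding locus (rbcLa-style)
#'
#' Coding barcode loci such as rbcLa lack indel variation, so a single global
#' progressive alignment over all species is appropriate; indel-free
#' equal-length inputs come back as a plain stack with zero gap columns.
#'
#' @param records Tibble of records, one per species, single marker.
#' @return A `barcode_alignment` labelled `"global"`.
#' @export
align_coding_global <- function(records) {
  validate_records(records)
  if (nrow(records) == 0L) stop("no records to align", call. = FALSE)
  if (any(duplicated(records$species_code))) {
    stop("expected one record per species; duplicates: ",
         paste(unique(records$species_code[duplicated(records$species_code)]),
               collapse = ", "), call. = FALSE)
  }
  seqs <- stats::setNames(records$bases, records$species_code)
  new_alignment(records$marker[1L], "global", progressive_align(seqs, "dna"))
}

count_internal_stops <- function(bases, offset) {
  n <- nchar(bases)
  usable <- n - offset
  ncod <- usable %/% 3L
  if (ncod < 1L) return(c(stops = 0L, codons = 0L))
  starts <- offset + 1L + 3L * (0:(ncod - 1L))
  codons <- substring(bases, starts, starts + 2L)
  internal <- codons[-length(codons)]  # terminal stop is legitimate
  c(stops = sum(internal %in% c("TAA", "TAG", "TGA")),
    codons = length(internal))
}

translate_codons <- function(codons, genetic_code) {
  aa <- unname(genetic_code[codons])
  aa[is.na(aa)] <- "X"  # codons containing N or other ambiguity
  aa
}

#' Align a coding locus by back-translation (matK-style)
#'
#' Each sequence is assigned the reading frame minimising internal stop
#' codons (ties to the lowest offset), translated, aligned at the protein
#' level, and the protein gaps are mapped back onto the nucleotides in codon
#' triples. Frame-offset flanks are padded with `?` so the output length is a
#' multiple of three. Sequences whose best frame still has more than 5%
#' internal stops are excluded; the exclusions are recorded in the
#' `"excluded"` attribute.
#'
#' @param records Tibble of records, one per species, single marker.
#' @param genetic_code Named codon-to-amino-acid vector; defaults to the
#'   standard code from `Biostrings::GENETIC_CODE`.
#' @return A `barcode_alignment` labelled `"global"`.
#' @export
align_backtranslate <- function(records, genetic_code = NULL) {
  validate_records(records)
  if (nrow(records) == 0L) stop("no records to align", call. = FALSE)
  if (any(duplicated(records$species_code))) {
    stop("expected one record per species", call. = FALSE)
  }
  if (is.null(genetic_code)) {
    gc0 <- Biostrings::GENETIC_CODE
    genetic_code <- stats::setNames(as.character(gc0), names(gc0))
  }

  frames <- lapply(records$bases, function(b) {
    stats <- vapply(0:2, function(o) count_internal_stops(b, o), numeric(2))
    frac <- ifelse(stats["codons", ] > 0, stats["stops", ] / stats["codons", ], 0)
    o <- which.min(stats["stops", ]) - 1L  # ties -> lowest offset
    list(offset = o, stop_frac = frac[o + 1L])
  })
  offsets <- vapply(frames, `[[`, numeric(1), "offset")
  stop_frac <- vapply(frames, `[[`, numeric(1), "stop_frac")

  bad <- stop_frac > 0.05
  excluded <- tibble::tibble(
    species_code = records$species_code[bad],
    reason = sprintf("best frame has %.1f%% internal stops", 100 * stop_frac[bad])
  )
  if (any(bad)) {
    message("excluding ", sum(bad), " sequence(s) with excess internal stops: ",
            paste(records$species_code[bad], collapse = ", "))
  }
  records <- records[!bad, , drop = FALSE]
  offsets <- offsets[!bad]
  if (nrow(records) == 0L) stop("all sequences excluded by frame check", call. = FALSE)

  pieces <- lapply(seq_len(nrow(records)), function(i) {
    b <- records$bases[i]
    o <- offsets[i]
    ncod <- (nchar(b) - o) %/% 3L
    starts <- o + 1L + 3L * (0:(ncod - 1L))
    codons <- substring(b, starts, starts + 2L)
    list(left = substr(b, 1L, o),
         codons = codons,
         right = substr(b, o + 3L * ncod + 1L, nchar(b)),
         aa = paste0(translate_codons(codons, genetic_code), collapse = ""))
  })
  names(pieces) <- records$species_code

  aa <- vapply(pieces, `[[`, character(1), "aa")
  aligned_aa <- progressive_align(aa, "protein")

  fw <- max(vapply(pieces, function(p) nchar(p$left), integer(1)))
  fw <- 3L * ceiling(fw / 3)
  rw <- max(vapply(pieces, function(p) nchar(p$right), integer(1)))
  rw <- 3L * ceiling(rw / 3)

  rows <- vapply(names(aligned_aa), function(sp) {
    p <- pieces[[sp]]
    aach <- strsplit(aligned_aa[[sp]], "", fixed = TRUE)[[1L]]
    body <- character(length(aach))
    ci <- 0L
    for (q in seq_along(aach)) {
      if (aach[q] == "-") body[q] <- "---"
      else { ci <- ci + 1L; body[q] <- p$codons[ci] }
    }
    left <- paste0(strrep("?", fw - nchar(p$left)), p$left)
    right <- paste0(p$right, strrep("?", rw - nchar(p$right)))
    paste0(left, paste0(body, collapse = ""), right)
  }, character(1))

  out <- new_alignment(records$marker[1L], "global", rows)
  attr(out, "excluded") <- excluded
  attr(out, "frame_offsets") <- stats::setNames(offsets, records$species_code)
  out
}

#' Align a spacer locus in taxonomic partitions (trnH-psbA-style)
#'
#' Records are grouped by the value of `rank` in the taxonomy and each group
#' is aligned independently. Groups containing exactly one species are
#' omitted: a lone spacer sequence carries no alignable signal at that rank
#' and is left out of the phylogenetic alignment.
#'
#' @param records Tibble of records, one per species, single marker.
#' @param taxonomy A `community_taxonomy`.
#' @param rank `"family"` or `"order"`.
#' @return List of `barcode_alignment` blocks (possibly empty), sorted by
#'   partition label.
#' @export
align_partitioned <- function(records, taxonomy, rank = c("family", "order")) {
  rank <- match.arg(rank)
  validate_records(records)
  missing <- setdiff(records$species_code, taxonomy$species)
  if (length(missing)) {
    stop("species not in taxonomy: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  joined <- dplyr::left_join(records,
                             dplyr::select(taxonomy, "species",
                                           group = dplyr::all_of(rank)),
                             by = c(species_code = "species"))
  groups <- split(joined, joined$group)
  groups <- groups[vapply(groups, function(g)
    length(unique(g$species_code)) >= 2L, logical(1))]
  out <- lapply(groups[order(names(groups))], function(g) {
    seqs <- stats::setNames(g$bases, g$species_code)
    new_alignment(g$marker[1L], g$group[1L], progressive_align(seqs, "dna"),
                  partitioned = TRUE)
  })
  unname(out)
}
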