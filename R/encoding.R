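#' Seven-group amino-acid classification
#'
#' The 20 standard amino acids partitioned into seven classes by the dipole
#' and volume of their side chains. Group codes run 0--6 and are the symbols
#' of the reduced alphabet used by all descriptors in this package.
#'
#' @format Named integer vector: names are one-letter residue codes, values
#'   are group codes in `0:6`.
#' @export
aa_groups <- c(
  A = 0L, G = 0L, V = 0L,
  C = 1L,
  F = 2L, I = 2L, L = 2L, P = 2L,
  M = 3L, S = 3L, T = 3L, Y = 3L,
  H = 4L, N = 4L, Q = 4L, W = 4L,
  K = 5L, R = 5L,
  D = 6L, E = 6L
)

#' Map one residue to its group code
#'
#' @param aa Single one-letter amino-acid code (case-insensitive).
#' @return Integer group code in `0:6`.
#' @examples
#' group_residue("V")  # 0
#' group_residue("C")  # 1
#' group_residue("E")  # 6
#' @export
group_residue <- function(aa) {
  stopifnot(is.character(aa), length(aa) == 1L, nchar(aa) == 1L)
  g <- aa_groups[toupper(aa)]
  if (is.na(g)) {
    stop("non-standard amino-acid letter '", aa, "'", call. = FALSE)
  }
  unname(g)
}

#' Reduce a protein sequence to the seven-group alphabet
#'
#' Every residue is replaced by its group code; the result has the same
#' length as the input. Non-standard letters (B, J, O, U, X, Z, gaps, ...)
#' are rejected with the offending character and its position.
#'
#' @param sequence Character scalar over the 20 standard one-letter codes
#'   (case-insensitive), or a `ProteinRecord` as returned by
#'   [protein_record()].
#' @return An `EncodedSequence`: integer vector of group codes in `0:6`,
#'   with attribute `id` when the input carried one.
#' @examples
#' enc <- encode_sequence("VCCPPVCVVCPPVCVPVPPCCV")
#' paste(enc, collapse = "")  # "0112201001220102022110"
#' @export
encode_sequence <- function(sequence) {
  id <- NULL
  if (inherits(sequence, "ProteinRecord")) {
    id <- sequence$id
    sequence <- sequence$sequence
  }
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) stop("empty sequence", call. = FALSE)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  codes <- unname(aa_groups[chars])
  if (anyNA(codes)) {
    bad <- which(is.na(codes))[1L]
    stop(
      "non-standard amino-acid letter '", chars[bad], "' at position ", bad,
      if (!is.null(id)) paste0(" in protein '", id, "'") else "",
      call. = FALSE
    )
  }
  structure(codes, class = "EncodedSequence", id = id)
}

#' Construct a protein record
#'
#' @param id Identifier string.
#' @param sequence Amino-acid sequence (upper-cased on construction).
#' @param localization Optional subcellular-localization label.
#' @return A `ProteinRecord` list with fields `id`, `sequence`,
#'   `localization`.
#' @export
protein_record <- function(id, sequence, localization = NA_character_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(sequence)
  rec <- structure(
    list(id = id, sequence = sequence,
         localization = as.character(localization)),
    class = "ProteinRecord"
  )
  encode_sequence(rec)  # validates residues, errors name the protein
  rec
}

#' Ten-region split of a sequence
#'
#' Splits the residue index range `[0, L)` into the ten regions used by the
#' local descriptors: the four quarters A--D, the two halves E--F, the
#' central 50\% (G), the first and final 75\% (H, I), and the central 75\%
#' (J). Boundaries are `floor(k*L/4)` for the quarters and `floor(L/8)`,
#' `floor(7*L/8)` for region J, so A--D and E--F each partition the
#' sequence exactly for any length.
#'
#' @param L Sequence length, must be at least 8 so every region is
#'   non-empty.
#' @return A `RegionScheme`: named list of length-2 integer vectors
#'   `c(start, end)`, 0-based half-open.
#' @examples
#' split_regions(22)$A  # c(0, 5)
#' @export
split_regions <- function(L) {
  stopifnot(is.numeric(L), length(L) == 1L)
  L <- as.integer(L)
  if (L < 8L) {
    stop("sequence length ", L, " is too short to split into 10 regions ",
         "(minimum 8)", call. = FALSE)
  }
  b <- as.integer(floor((0:4) * L / 4))
  e1 <- as.integer(floor(L / 8))
  e7 <- as.integer(floor(7 * L / 8))
  structure(list(
    A = c(b[1], b[2]), B = c(b[2], b[3]), C = c(b[3], b[4]), D = c(b[4], b[5]),
    E = c(b[1], b[3]), F = c(b[3], b[5]),
    G = c(b[2], b[4]),
    H = c(b[1], b[4]), I = c(b[2], b[5]),
    J = c(e1, e7)
  ), class = "RegionScheme")
}

#' Extract one region of an encoded sequence
#'
#' @param codes Integer vector of group codes.
#' @param region Length-2 vector `c(start, end)`, 0-based half-open.
#' @return The sub-vector of codes in the region.
#' @keywords internal
region_codes <- function(codes, region) {
  codes[(region[1] + 1L):region[2]]
}

#' Read a protein FASTA file
#'
#' Multi-record FASTA with wrapped lines; the record id is the first
#' whitespace-delimited token of the header.
#'
#' @param path FASTA file path.
#' @param localization Optional path to a two-column delimited file
#'   (protein id, localization label; tab- or whitespace-separated, no
#'   header) whose labels are attached to the matching records.
#' @return Named list of [protein_record()] objects.
#' @export
read_proteins <- function(path, localization = NULL) {
  aa <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate protein ids in ", path, call. = FALSE)
  }
  loc <- rep(NA_character_, length(ids))
  names(loc) <- ids
  if (!is.null(localization)) {
    tab <- utils::read.table(localization, header = FALSE,
                             col.names = c("id", "localization"),
                             colClasses = "character")
    hit <- intersect(tab$id, ids)
    loc[hit] <- tab$localization[match(hit, tab$id)]
  }
  recs <- mapply(protein_record, ids, as.character(aa), loc,
                 SIMPLIFY = FALSE)
  names(recs) <- ids
  recs
}

#' Write protein records to FASTA (and optionally a localization table)
#'
#' @param proteome Named list of [protein_record()] objects.
#' @param path Output FASTA path.
#' @param localization Optional path for a two-column id/localization table.
#' @return `path`, invisibly.
#' @export
write_proteins <- function(proteome, path, localization = NULL) {
  seqs <- Biostrings::AAStringSet(vapply(proteome, `[[`, character(1),
                                         "sequence"))
  names(seqs) <- vapply(proteome, `[[`, character(1), "id")
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  if (!is.null(localization)) {
    loc <- vapply(proteome, `[[`, character(1), "localization")
    utils::write.table(
      data.frame(id = names(seqs), localization = loc),
      localization, sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE
    )
  }
  invisible(path)
}

#' Read an interaction pair list
#'
#' Delimited text with three columns: first protein id, second protein id,
#' label in \{0, 1\}. A header row is detected and skipped.
#'
#' @param path Pair-list file path.
#' @return `data.frame` with columns `idA`, `idB`, `label`.
#' @export
read_pairs <- function(path) {
  first <- readLines(path, n = 1L)
  # a header row ends in a column name, a data row in a numeric label
  has_header <- !grepl("[-0-9.]+\\s*$", first)
  tab <- utils::read.table(path, header = has_header, sep = "",
                           col.names = c("idA", "idB", "label"),
                           colClasses = c("character", "character", "integer"))
  if (!all(tab$label %in% c(0L, 1L))) {
    bad <- which(!tab$label %in% c(0L, 1L))[1L]
    stop("pair list ", path, ": label not in {0,1} at data row ", bad,
         call. = FALSE)
  }
  tab
}

#' Write an interaction pair list
#'
#' @param pairs `data.frame` with columns `idA`, `idB`, `label`.
#' @param path Output path (tab-separated, no header).
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.table(pairs[, c("idA", "idB", "label")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
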