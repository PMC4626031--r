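#' Reference mitogenome
#'
#' A `reference_genome` holds the circular mitogenome that defines the "np"
#' coordinate system (1-based positions) against which all variants are
#' expressed. The coordinate system is that of the Bovine Reference Sequence
#' (BRS, GenBank V00654), 16,338 bp.
#'
#' @param sequence Nucleotide sequence: a single string, a character vector of
#'   single bases, or a [Biostrings::DNAString].
#' @param id Identifier, by convention `"V00654"` for the BRS coordinate
#'   system.
#' @return An object of class `reference_genome` with fields `id`, `sequence`
#'   (uppercase string), `bases` (character vector) and `length`.
#' @export
reference_genome <- function(sequence, id = "V00654") {
  if (inherits(sequence, "DNAString")) sequence <- as.character(sequence)
  if (length(sequence) > 1L) sequence <- paste(sequence, collapse = "")
  sequence <- toupper(sequence)
  bases <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  if (!all(bases %in% c("A", "C", "G", "T", "N"))) {
    stop("reference sequence may contain only A/C/G/T/N")
  }
  structure(
    list(id = id, sequence = sequence, bases = bases,
         length = length(bases)),
    class = "reference_genome"
  )
}

#' @export
print.reference_genome <- function(x, ...) {
  cat(sprintf("<reference_genome %s: %d bp circular>\n", x$id, x$length))
  invisible(x)
}

#' Load the packaged reference mitogenome
#'
#' Returns the reference that ships with the package: a *synthetic* 16,338 bp
#' stand-in for the Bovine Reference Sequence that preserves the V00654
#' coordinate system, a bovine-like base composition, and the homopolymer
#' tracts relevant to hypervariable-site filtering (the G run after np 364,
#' the C tract anchored at np 221 and the A tract anchored at np 1600). It is
#' not the GenBank V00654 sequence; analyses of real data should supply the
#' true BRS via `path`.
#'
#' @param path Optional path to a single-record FASTA to use as reference
#'   instead of the packaged synthetic one.
#' @return A [reference_genome()].
#' @export
load_reference <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "synthetic_bovine_reference.fasta",
                        package = "mitotaur", mustWork = TRUE)
  }
  seqs <- read_mitogenomes(path)
  if (length(seqs) != 1L) stop("reference FASTA must contain exactly one record")
  reference_genome(seqs[[1L]], id = sub("_synthetic$", "", names(seqs)[1L]))
}

#' Read mitogenome sequences from FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning a named
#' character vector of uppercase sequences, with FASTA descriptions trimmed to
#' the first whitespace-delimited word.
#'
#' @param path FASTA file (optionally multi-record).
#' @return Named character vector of sequences.
#' @export
read_mitogenomes <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write mitogenome sequences to FASTA
#'
#' @param sequences Named character vector of sequences.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_mitogenomes <- function(sequences, path) {
  ss <- Biostrings::DNAStringSet(unlist(sequences))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Genomic region on the reference
#'
#' @param name Region name.
#' @param start,end 1-based inclusive np bounds.
#' @return An object of class `region`.
#' @export
region <- function(name, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || start > end) {
    stop("invalid region bounds")
  }
  structure(list(name = name, start = start, end = end), class = "region")
}

#' The mitogenome coding region used for dating
#'
#' np 364-15791 on the BRS coordinate system: the interval over which the
#' molecular clock of the package is calibrated and to which maximum
#' likelihood dating is restricted.
#'
#' @return A [region()] spanning np 364 to np 15791.
#' @export
coding_region <- function() region("coding", 364L, 15791L)

#' @export
print.region <- function(x, ...) {
  cat(sprintf("<region %s: np %d-%d (%d sites)>\n",
              x$name, x$start, x$end, x$end - x$start + 1L))
  invisible(x)
}

#' Number of sites in a region
#' @param r A [region()].
#' @return Integer site count.
#' @export
region_length <- function(r) r$end - r$start + 1L
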