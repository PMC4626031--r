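# Variant representation relative to the reference mitogenome, in the notation
# used on cattle mtDNA phylogeny branches: a bare np is a transition, a trailing
# base a transversion to that base, "+X" an insertion after the np, "d" a
# deletion of the np, and a trailing "h" marks heteroplasmy.

TRANSITION_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")

# two-base IUPAC ambiguity codes (heteroplasmy encoding)
IUPAC2 <- list(
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
  W = c("A", "T"), K = c("G", "T"), M = c("A", "C")
)
IUPAC2_CODE <- c("AG" = "R", "CT" = "Y", "CG" = "S",
                 "AT" = "W", "GT" = "K", "AC" = "M")

iupac2_code <- function(a, b) {
  unname(IUPAC2_CODE[paste(sort(c(a, b)), collapse = "")])
}

#' Transition partner of a base
#'
#' The purine partner of a purine (A<->G) or the pyrimidine partner of a
#' pyrimidine (C<->T); the base a "bare-number" transition label implies.
#'
#' @param base Character vector of bases (A/C/G/T).
#' @return Character vector of partner bases.
#' @export
transition_partner <- function(base) unname(TRANSITION_PARTNER[toupper(base)])

kind_order <- c(transition = 1L, transversion = 2L, insertion = 3L, deletion = 4L)

empty_variant_table <- function() {
  data.frame(position = integer(), kind = character(), allele = character(),
             heteroplasmic = logical(), label = character(),
             stringsAsFactors = FALSE)
}

#' Parse variant labels
#'
#' Parses labels of the grammar `position[base][+bases|d][h]` into a variant
#' table. A bare number is a transition; a trailing base a transversion to
#' that base; `+X` an insertion of X after the position; `d` a deletion; an
#' `h` suffix flags heteroplasmy. A trailing `@` (back-mutation mark used in
#' tree annotation) is tolerated and stripped.
#'
#' @param labels Character vector of labels.
#' @param ref Optional [reference_genome()]. When supplied, positions are
#'   range-checked and a "transversion" to the reference base or to its
#'   transition partner is rejected as malformed.
#' @return A data.frame with columns `position`, `kind`, `allele` (derived or
#'   inserted bases; `NA` for transitions and deletions), `heteroplasmic`,
#'   and the canonical `label`.
#' @examples
#' parse_variant_label(c("16049", "15953G", "364+G", "100d", "8000h"))
#' @export
parse_variant_label <- function(labels, ref = NULL) {
  labels <- as.character(labels)
  m <- regmatches(labels, regexec(
    "^([0-9]+)(?:([ACGT])|\\+([ACGT]+)|(d))?(h)?@?$", labels))
  out <- lapply(seq_along(labels), function(i) {
    g <- m[[i]]
    if (length(g) == 0L) stop("malformed variant label: '", labels[i], "'")
    pos <- as.integer(g[2L])
    het <- g[6L] == "h"
    if (g[3L] != "") {
      kind <- "transversion"; allele <- g[3L]
    } else if (g[4L] != "") {
      kind <- "insertion"; allele <- g[4L]
    } else if (g[5L] == "d") {
      kind <- "deletion"; allele <- NA_character_
    } else {
      kind <- "transition"; allele <- NA_character_
    }
    if (!is.null(ref)) {
      if (pos < 1L || pos > ref$length) {
        stop("position ", pos, " outside reference (length ", ref$length, ")")
      }
      if (kind == "transversion") {
        rb <- ref$bases[pos]
        if (allele == rb) stop("label '", labels[i], "': allele equals the reference base")
        if (allele == transition_partner(rb)) {
          stop("label '", labels[i], "': base ", allele,
               " is the transition partner of reference ", rb,
               "; write the bare position for a transition")
        }
      }
    }
    data.frame(position = pos, kind = kind, allele = allele,
               heteroplasmic = het, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(list(empty_variant_table()[0L, 1:4]), out))
  out$label <- format_variant_label(out)
  out
}

#' Format variants as labels
#'
#' Inverse of [parse_variant_label()]: renders a variant table (or one row of
#' it) back into canonical labels.
#'
#' @param v Variant table as returned by [parse_variant_label()], or a
#'   [variant_profile()].
#' @return Character vector of labels.
#' @export
format_variant_label <- function(v) {
  if (inherits(v, "variant_profile")) v <- v$variants
  if (nrow(v) == 0L) return(character())
  suffix <- character(nrow(v))
  suffix[v$kind == "transversion"] <- v$allele[v$kind == "transversion"]
  suffix[v$kind == "insertion"] <- paste0("+", v$allele[v$kind == "insertion"])
  suffix[v$kind == "deletion"] <- "d"
  paste0(v$position, suffix, ifelse(v$heteroplasmic, "h", ""))
}

#' Variant profile of one mitogenome
#'
#' The ordered set of differences of a single mitogenome from the reference,
#' unique by (position, kind, allele) and sorted by position.
#'
#' @param sample_id Sample identifier.
#' @param variants Either a character vector of labels or a variant table as
#'   returned by [parse_variant_label()].
#' @param ref Optional [reference_genome()] passed to the label parser for
#'   validation.
#' @return An object of class `variant_profile` with fields `sample_id` and
#'   `variants`.
#' @export
variant_profile <- function(sample_id, variants = character(), ref = NULL) {
  if (is.character(variants)) variants <- parse_variant_label(variants, ref)
  v <- variants[, c("position", "kind", "allele", "heteroplasmic")]
  key <- paste(v$position, v$kind, v$allele)
  v <- v[!duplicated(key), , drop = FALSE]
  ord <- order(v$position, kind_order[v$kind], v$allele, na.last = TRUE)
  v <- v[ord, , drop = FALSE]
  rownames(v) <- NULL
  v$label <- format_variant_label(v)
  structure(list(sample_id = as.character(sample_id), variants = v),
            class = "variant_profile")
}

#' @export
print.variant_profile <- function(x, ...) {
  cat(sprintf("<variant_profile %s: %d variants>\n",
              x$sample_id, nrow(x$variants)))
  if (nrow(x$variants) > 0L) {
    cat(" ", paste(x$variants$label, collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
length.variant_profile <- function(x) nrow(x$variants)

#' Variant labels of a profile
#'
#' @param p A [variant_profile()].
#' @param normalize Drop the heteroplasmy suffix, so labels compare by
#'   (position, kind, allele)?
#' @return Character vector of labels.
#' @export
profile_labels <- function(p, normalize = FALSE) {
  if (normalize) norm_label(p$variants$label) else p$variants$label
}

# canonical (position, kind, allele) key: heteroplasmy and back-mutation
# marks stripped
norm_label <- function(labels) sub("@$", "", sub("h(@?)$", "\\1", labels))

#' Call variants of a mitogenome against the reference
#'
#' Compares an (aligned or alignable) mitogenome with the reference and emits
#' one variant per differing site. Two-base IUPAC ambiguity codes that combine
#' the reference base with one alternative are called as heteroplasmic
#' variants; `N` is treated as missing data (no call); three- and four-base
#' ambiguity codes are rejected. Indels are left-aligned before labelling, so
#' homopolymer-tract length variants normalize to the canonical anchor np
#' (e.g. an extra C anywhere in the tract at np 222-229 is labelled `221+C`).
#'
#' @param seq Sample sequence: same length as the reference (gap characters
#'   `-` allowed for deletions), or a different length, in which case a global
#'   pairwise alignment to the (np 1-linearized) reference is computed with
#'   [Biostrings::pairwiseAlignment()].
#' @param ref A [reference_genome()].
#' @param sample_id Sample identifier for the returned profile.
#' @param aligned_ref Optional gapped reference string of the same alignment
#'   length as `seq`, for callers that align externally (required to represent
#'   insertions in a pre-aligned input).
#' @return A [variant_profile()].
#' @export
call_variants <- function(seq, ref, sample_id = "sample", aligned_ref = NULL) {
  if (inherits(seq, "DNAString")) seq <- as.character(seq)
  seq <- toupper(seq)
  if (is.null(aligned_ref)) {
    if (nchar(seq) == ref$length) {
      aligned_ref <- ref$sequence
    } else {
      al <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(gsub("-", "", seq)),
        Biostrings::DNAString(ref$sequence), type = "global",
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
          match = 1, mismatch = -2, baseOnly = FALSE),
        gapOpening = 6, gapExtension = 2)
      seq <- as.character(Biostrings::alignedPattern(al))
      aligned_ref <- as.character(Biostrings::alignedSubject(al))
    }
  }
  if (nchar(seq) != nchar(aligned_ref)) {
    stop("sequence and aligned reference differ in length")
  }
  sc <- strsplit(seq, "", fixed = TRUE)[[1L]]
  rc <- strsplit(aligned_ref, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(sc), c("A", "C", "G", "T", "N", "-", names(IUPAC2)))
  if (length(bad) > 0L) {
    stop("non-nucleotide characters in sequence: ", paste(bad, collapse = ", "))
  }

  np <- cumsum(rc != "-")  # np coordinate of each alignment column
  rows <- list()
  add <- function(position, kind, allele, het) {
    rows[[length(rows) + 1L]] <<- data.frame(
      position = as.integer(position), kind = kind, allele = allele,
      heteroplasmic = het, stringsAsFactors = FALSE)
  }

  # substitutions (columns where both carry a base)
  both <- which(rc != "-" & sc != "-" & sc != "N" & sc != rc)
  for (i in both) {
    s <- sc[i]; r <- rc[i]
    if (s %in% names(IUPAC2)) {
      pair <- IUPAC2[[s]]
      if (!(r %in% pair)) {
        stop("ambiguity code ", s, " at np ", np[i],
             " does not include the reference base ", r)
      }
      alt <- setdiff(pair, r)
      kind <- if (alt == transition_partner(r)) "transition" else "transversion"
      add(np[i], kind, if (kind == "transversion") alt else NA_character_, TRUE)
    } else {
      kind <- if (s == transition_partner(r)) "transition" else "transversion"
      add(np[i], kind, if (kind == "transversion") s else NA_character_, FALSE)
    }
  }

  # deletions: runs of '-' in the sample, left-aligned, one label per np
  del <- rle(rc != "-" & sc == "-")
  pos <- cumsum(c(1L, del$lengths))
  for (j in which(del$values)) {
    cols <- pos[j]:(pos[j] + del$lengths[j] - 1L)
    a <- np[cols[1L]]; b <- np[cols[length(cols)]]
    while (a > 1L && ref$bases[a - 1L] == ref$bases[b]) { a <- a - 1L; b <- b - 1L }
    for (p in a:b) add(p, "deletion", NA_character_, FALSE)
  }

  # insertions: runs of '-' in the reference, anchored to the preceding np,
  # left-rotated across identical reference bases
  ins <- rle(rc == "-")
  pos <- cumsum(c(1L, ins$lengths))
  for (j in which(ins$values)) {
    cols <- pos[j]:(pos[j] + ins$lengths[j] - 1L)
    x <- sc[cols]
    x <- x[x != "-"]
    if (length(x) == 0L) next
    anchor <- if (cols[1L] == 1L) 0L else np[cols[1L] - 1L]
    norm <- left_align_insertion(anchor, x, ref)
    add(norm$anchor, "insertion", paste(norm$bases, collapse = ""), FALSE)
  }

  v <- do.call(rbind, c(list(empty_variant_table()[0L, 1:4]), rows))
  variant_profile(sample_id, cbind(v, label = format_variant_label(v)))
}

# shift an insertion leftwards while the reference base at the anchor equals
# the last inserted base (rotating the inserted string), yielding the
# canonical leftmost placement
left_align_insertion <- function(anchor, bases, ref) {
  n <- length(bases)
  while (anchor >= 1L && ref$bases[anchor] == bases[n]) {
    bases <- c(bases[n], bases[-n])
    anchor <- anchor - 1L
  }
  list(anchor = anchor, bases = bases)
}

#' Apply a variant profile to the reference
#'
#' Reconstructs the mitogenome sequence carrying a profile's variants:
#' transitions and transversions replace the reference base (heteroplasmic
#' ones as the two-base IUPAC code), deletions remove the position and
#' insertions add bases after their anchor np.
#'
#' @param ref A [reference_genome()].
#' @param p A [variant_profile()].
#' @return The sample sequence as a single string.
#' @export
apply_profile <- function(ref, p) {
  bases <- ref$bases
  v <- p$variants
  keep <- rep(TRUE, length(bases))
  ins <- rep("", length(bases) + 1L)  # ins[k+1] = bases inserted after np k
  for (i in seq_len(nrow(v))) {
    pos <- v$position[i]
    if (pos > ref$length) stop("variant position ", pos, " outside reference")
    switch(v$kind[i],
      transition = {
        derived <- transition_partner(ref$bases[pos])
        bases[pos] <- if (v$heteroplasmic[i]) {
          iupac2_code(ref$bases[pos], derived)
        } else derived
      },
      transversion = {
        bases[pos] <- if (v$heteroplasmic[i]) {
          iupac2_code(ref$bases[pos], v$allele[i])
        } else v$allele[i]
      },
      deletion = keep[pos] <- FALSE,
      insertion = ins[pos + 1L] <- paste0(ins[pos + 1L], v$allele[i])
    )
  }
  pieces <- character(2L * length(bases) + 1L)
  pieces[1L] <- ins[1L]
  pieces[2L * seq_along(bases)] <- ifelse(keep, bases, "")
  pieces[2L * seq_along(bases) + 1L] <- ins[-1L]
  paste(pieces, collapse = "")
}

#' Default hypervariable-site annotation
#'
#' The sites excluded from phylogeny construction: the hypervariable G
#' insertion anchored at np 364 and length variation of the homopolymer
#' tracts scored at np 221 (C tract) and np 1600 (A tract). Tracts are given
#' as np intervals into which a left-aligned indel of the tract base
#' normalizes.
#'
#' @return A list with elements `g_insertion` (np) and `tracts` (list of
#'   `c(start, end)` np intervals).
#' @export
hypervariable_sites <- function() {
  list(g_insertion = 364L, tracts = list(c(221L, 229L), c(1600L, 1606L)))
}

#' Remove hypervariable length variants from a profile
#'
#' Drops the G insertion at np 364 and any insertion or deletion whose
#' (left-aligned) position falls in the C tract scored at np 221 or the A
#' tract scored at np 1600. Point substitutions, including those inside the
#' tracts, are retained. Idempotent.
#'
#' @param p A [variant_profile()].
#' @param sites Hypervariable-site annotation as from [hypervariable_sites()].
#' @return The filtered [variant_profile()].
#' @export
filter_hypervariable <- function(p, sites = hypervariable_sites()) {
  v <- p$variants
  is_indel <- v$kind %in% c("insertion", "deletion")
  drop <- is_indel & v$position == sites$g_insertion & v$kind == "insertion" &
    grepl("^G+$", v$allele)
  for (tr in sites$tracts) {
    drop <- drop | (is_indel & v$position >= tr[1L] & v$position <= tr[2L])
  }
  variant_profile(p$sample_id, v[!drop, , drop = FALSE])
}

#' Restrict a profile to a genomic region
#'
#' Keeps variants with `start <= position <= end` (inclusive), optionally
#' dropping heteroplasmic variants, as done before coding-region dating.
#'
#' @param p A [variant_profile()].
#' @param r A [region()]; defaults to the coding region np 364-15791.
#' @param exclude_heteroplasmic Drop heteroplasmic variants?
#' @return The restricted [variant_profile()].
#' @export
restrict_region <- function(p, r = coding_region(),
                            exclude_heteroplasmic = FALSE) {
  v <- p$variants
  keep <- v$position >= r$start & v$position <= r$end
  if (exclude_heteroplasmic) keep <- keep & !v$heteroplasmic
  variant_profile(p$sample_id, v[keep, , drop = FALSE])
}

#' Read variant profiles from TSV
#'
#' Expects columns `sample_id` and `label`, one row per variant; samples with
#' no variants may appear as a row with an empty label.
#'
#' @param path TSV file path.
#' @param ref Optional [reference_genome()] for label validation.
#' @return Named list of [variant_profile()] objects, in order of first
#'   appearance.
#' @export
read_variant_tsv <- function(path, ref = NULL) {
  d <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("sample_id", "label") %in% names(d))) {
    stop("variant TSV must have columns sample_id and label")
  }
  ids <- unique(d$sample_id)
  out <- lapply(ids, function(id) {
    lab <- d$label[d$sample_id == id]
    variant_profile(id, lab[nzchar(lab)], ref = ref)
  })
  names(out) <- ids
  out
}

#' Write variant profiles to TSV
#'
#' @param profiles List of [variant_profile()] objects.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_variant_tsv <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    lab <- profile_labels(p)
    if (length(lab) == 0L) lab <- ""
    data.frame(sample_id = p$sample_id, label = lab, stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
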