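# Haplogroup classification from defining-mutation motifs. A haplogroup tree
# encodes the taurine mtDNA phylogeny (P, Q, T and subclades, plus a zebu I
# placeholder); each node carries its own defining variants and a node's full
# motif is the union of the defining variants along the path from the root.

#' Load a haplogroup configuration
#'
#' Reads a haplogroup tree from TSV (columns `name`, `parent`,
#' `defining_variants` as comma-separated labels, optional `verified`) or
#' YAML (a list of mappings with the same keys), validates it (unique names,
#' a single root, resolvable parents, no cycles, parseable labels) and
#' returns a `haplogroup_tree`.
#'
#' The packaged default transcribes the published taurine topology
#' (PQT > P/QT; Q > Q1/Q2; T > T1'2'3/T5; T1-T3 subclades; a zebu haplogroup
#' I placeholder). Only the Q-diagnostic C-to-G transversion at np 15953 is
#' anchored in the literature; the remaining defining motifs are synthetic
#' placeholders (column `verified`) and the file is intended to be edited
#' with curated motifs for real analyses. Classification behaviour is always
#' defined relative to the configuration in use.
#'
#' @param path Config file; `NULL` loads the packaged default.
#' @return An object of class `haplogroup_tree`: a list with `nodes`
#'   (data.frame `name`, `parent`, `verified`, `depth`) and `motifs` (named
#'   list of defining-variant label vectors, per node, own variants only).
#' @export
load_haplogroup_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "taurine_haplogroups.tsv",
                        package = "mitotaur", mustWork = TRUE)
  }
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("yaml", "yml")) {
    y <- yaml::read_yaml(path)
    if (length(y) == 0L) stop("empty haplogroup config")
    d <- data.frame(
      name = vapply(y, function(n) as.character(n$name), ""),
      parent = vapply(y, function(n) {
        p <- n$parent; if (is.null(p)) "" else as.character(p)
      }, ""),
      defining_variants = vapply(y, function(n) {
        v <- n$defining_variants
        if (is.null(v)) "" else paste(unlist(v), collapse = ",")
      }, ""),
      verified = vapply(y, function(n) {
        v <- n$verified; if (is.null(v)) "no" else as.character(v)
      }, ""),
      stringsAsFactors = FALSE)
  } else {
    d <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
    if (nrow(d) == 0L) stop("empty haplogroup config")
    if (!all(c("name", "parent", "defining_variants") %in% names(d))) {
      stop("haplogroup config needs columns name, parent, defining_variants")
    }
    if (is.null(d$verified)) d$verified <- "no"
    d[is.na(d)] <- ""
  }
  haplogroup_tree(d)
}

#' Construct a haplogroup tree from a node table
#'
#' @param nodes data.frame with columns `name`, `parent` (empty/`NA` for the
#'   root), `defining_variants` (comma-separated labels) and optionally
#'   `verified`.
#' @return A `haplogroup_tree`.
#' @export
haplogroup_tree <- function(nodes) {
  nodes$parent[is.na(nodes$parent)] <- ""
  if (anyDuplicated(nodes$name)) {
    stop("duplicate haplogroup names: ",
         paste(unique(nodes$name[duplicated(nodes$name)]), collapse = ", "))
  }
  root <- nodes$name[nodes$parent == ""]
  if (length(root) != 1L) stop("haplogroup tree must have exactly one root")
  known <- nodes$parent == "" | nodes$parent %in% nodes$name
  if (!all(known)) {
    stop("unresolved parent(s): ", paste(nodes$parent[!known], collapse = ", "))
  }
  # depth by walking to the root; a walk longer than the node count is a cycle
  parent_of <- setNames(nodes$parent, nodes$name)
  depth <- vapply(nodes$name, function(n) {
    d <- 0L
    while (parent_of[[n]] != "") {
      n <- parent_of[[n]]; d <- d + 1L
      if (d > nrow(nodes)) stop("cycle in haplogroup tree")
    }
    d
  }, 0L)
  motifs <- lapply(nodes$defining_variants, function(s) {
    labs <- trimws(strsplit(s, ",", fixed = TRUE)[[1L]])
    labs <- labs[nzchar(labs)]
    if (length(labs) == 0L) return(character())
    format_variant_label(parse_variant_label(labs))  # validates + canonicalizes
  })
  names(motifs) <- nodes$name
  if (is.null(nodes$verified)) nodes$verified <- "no"
  structure(
    list(nodes = data.frame(name = nodes$name, parent = nodes$parent,
                            verified = nodes$verified, depth = depth,
                            stringsAsFactors = FALSE),
         motifs = motifs, root = root),
    class = "haplogroup_tree")
}

#' @export
print.haplogroup_tree <- function(x, ...) {
  cat(sprintf("<haplogroup_tree: %d nodes, root '%s'>\n",
              nrow(x$nodes), x$root))
  invisible(x)
}

hg_path_to_root <- function(tree, h) {
  parent_of <- setNames(tree$nodes$parent, tree$nodes$name)
  path <- character()
  while (h != "") {
    path <- c(path, h)
    h <- parent_of[[h]]
  }
  rev(path)
}

#' Full founding motif of a haplogroup
#'
#' The union of the defining variants of a haplogroup and of all its
#' ancestors: the mutations every member of the clade is expected to carry,
#' as opposed to "non-founding" (post-founding) mutations.
#'
#' @param h Haplogroup name.
#' @param tree A `haplogroup_tree`.
#' @return Character vector of variant labels.
#' @export
founding_set <- function(h, tree) {
  if (!h %in% tree$nodes$name) stop("unknown haplogroup: ", h)
  unique(unlist(tree$motifs[hg_path_to_root(tree, h)], use.names = FALSE))
}

#' Classify a variant profile into a haplogroup
#'
#' Scores every node of the haplogroup tree against the profile as
#' `matched - lambda * mismatched` over the node's full motif, where
#' `matched` counts motif variants present in the profile and `mismatched`
#' counts motif variants absent from it (including back mutations that
#' restored the reference allele at a motif site, which by construction are
#' absent from the profile). The best-scoring node wins; ties break toward
#' the deepest node and then lexicographically. Heteroplasmy suffixes are
#' ignored for matching.
#'
#' @param p A [variant_profile()].
#' @param tree A `haplogroup_tree`.
#' @param lambda Mismatch penalty (default 1).
#' @return An object of class `classification_result`: list with
#'   `sample_id`, `haplogroup`, `matched`, `mismatched`, `score`.
#' @export
classify_profile <- function(p, tree, lambda = 1) {
  labs <- profile_labels(p, normalize = TRUE)
  sc <- lapply(tree$nodes$name, function(nm) {
    motif <- norm_label(founding_set(nm, tree))
    matched <- sum(motif %in% labs)
    mismatched <- length(motif) - matched
    c(matched = matched, mismatched = mismatched,
      score = matched - lambda * mismatched)
  })
  sc <- do.call(rbind, sc)
  ord <- order(-sc[, "score"], -tree$nodes$depth, tree$nodes$name)
  best <- ord[1L]
  structure(
    list(sample_id = p$sample_id, haplogroup = tree$nodes$name[best],
         matched = as.integer(sc[best, "matched"]),
         mismatched = as.integer(sc[best, "mismatched"]),
         score = unname(sc[best, "score"])),
    class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<%s -> %s (matched %d, mismatched %d, score %g)>\n",
              x$sample_id, x$haplogroup, x$matched, x$mismatched, x$score))
  invisible(x)
}

#' Classify a set of profiles
#'
#' @param profiles List of [variant_profile()] objects.
#' @param tree A `haplogroup_tree`.
#' @param lambda Mismatch penalty passed to [classify_profile()].
#' @return data.frame with columns `sample_id`, `haplogroup`, `matched`,
#'   `mismatched`, `score` (the classification report).
#' @export
classify_profiles <- function(profiles, tree, lambda = 1) {
  rows <- lapply(profiles, function(p) {
    r <- classify_profile(p, tree, lambda)
    data.frame(sample_id = r$sample_id, haplogroup = r$haplogroup,
               matched = r$matched, mismatched = r$mismatched,
               score = r$score, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
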