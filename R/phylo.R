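# Mutation-annotated trees: rooted trees whose branches carry mutation label
# lists. Each branch b contributes its length l_b (mutation count) and the
# number n_b of samples it subtends; these are the ingredients of the
# genealogy-based rho/sigma estimators.

#' Construct a mutation tree
#'
#' @param parent Integer vector: parent node id per node (`NA` for the single
#'   root). Node ids are `1:length(parent)`.
#' @param label Character vector of node labels (sample ids at tips,
#'   haplogroup or clade names at internal nodes).
#' @param mutations List of character vectors: the mutation labels on the
#'   branch leading to each node (empty for the root).
#' @return An object of class `mutation_tree` with fields `parent`, `label`,
#'   `mutations`, `is_tip` and `n_tips`.
#' @export
mutation_tree <- function(parent, label, mutations) {
  parent <- as.integer(parent)
  n <- length(parent)
  if (length(label) != n || length(mutations) != n) {
    stop("parent, label and mutations must have one entry per node")
  }
  if (sum(is.na(parent)) != 1L) stop("tree must have exactly one root")
  if (any(stats::na.omit(parent) < 1L | stats::na.omit(parent) > n)) {
    stop("parent ids out of range")
  }
  mutations <- lapply(mutations, function(m) unique(as.character(m)))
  is_tip <- !(seq_len(n) %in% parent)
  structure(list(parent = parent, label = as.character(label),
                 mutations = mutations, is_tip = is_tip,
                 n_tips = sum(is_tip)),
            class = "mutation_tree")
}

#' @export
print.mutation_tree <- function(x, ...) {
  cat(sprintf("<mutation_tree: %d nodes, %d tips, total length %d>\n",
              length(x$parent), x$n_tips, total_tree_length(x)))
  invisible(x)
}

tree_root <- function(t) which(is.na(t$parent))

tree_children <- function(t) {
  ch <- vector("list", length(t$parent))
  for (i in seq_along(t$parent)) {
    p <- t$parent[i]
    if (!is.na(p)) ch[[p]] <- c(ch[[p]], i)
  }
  ch
}

# number of tips subtended by each node (a tip subtends itself)
tips_below <- function(t) {
  ch <- tree_children(t)
  n <- length(t$parent)
  out <- integer(n)
  # process children before parents: order nodes by decreasing depth
  depth <- node_depths(t)
  for (i in order(depth, decreasing = TRUE)) {
    out[i] <- if (t$is_tip[i]) 1L else sum(out[ch[[i]]])
  }
  out
}

node_depths <- function(t) {
  d <- integer(length(t$parent))
  for (i in seq_along(t$parent)) {
    j <- i; k <- 0L
    while (!is.na(t$parent[j])) { j <- t$parent[j]; k <- k + 1L }
    d[i] <- k
  }
  d
}

#' Total mutation count of a tree
#'
#' Sum of branch mutation-list lengths over all branches: the
#' maximum-parsimony objective.
#'
#' @param t A [mutation_tree()].
#' @return Integer total length.
#' @export
total_tree_length <- function(t) {
  sum(vapply(t$mutations, length, 0L))
}

#' Branch table of a mutation tree
#'
#' @param t A [mutation_tree()].
#' @return data.frame with one row per node: `branch_id`, `parent_id`,
#'   `label`, `is_tip`, `n_b` (tips subtended), `l_b` (mutations on the
#'   branch) and `mutations` (comma-separated labels, with back mutations
#'   carrying their `@` suffix after [annotate_recurrence()]), plus a
#'   `recurrent` column listing the branch's recurrent mutations if the tree
#'   has been annotated.
#' @export
tree_branch_table <- function(t) {
  n_b <- tips_below(t)
  d <- data.frame(
    branch_id = seq_along(t$parent),
    parent_id = t$parent,
    label = t$label,
    is_tip = t$is_tip,
    n_b = n_b,
    l_b = vapply(t$mutations, length, 0L),
    mutations = vapply(t$mutations, paste, "", collapse = ","),
    stringsAsFactors = FALSE)
  if (!is.null(t$recurrent)) {
    d$recurrent <- vapply(t$mutations, function(m) {
      paste(m[norm_label(m) %in% t$recurrent], collapse = ",")
    }, "")
  }
  d
}

#' Write the branch table to TSV
#'
#' @param t A [mutation_tree()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_branch_table <- function(t, path) {
  write.table(tree_branch_table(t), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Build a backbone-constrained most-parsimonious mutation tree
#'
#' Places each classified profile under its haplogroup node on the haplogroup
#' backbone, then joins profiles of the same haplogroup that share
#' non-founding mutations under intermediate nodes whenever that strictly
#' reduces the total mutation count (greedy agglomeration on the
#' maximum-parsimony objective: the pair sharing the most non-founding
#' variants is merged first, ties broken by the smallest position in the
#' shared set, then by label). Profiles sharing nothing radiate in a star
#' from the haplogroup root. Input profiles should already be filtered with
#' [filter_hypervariable()]; heteroplasmy suffixes are ignored when comparing
#' mutations across samples.
#'
#' @param profiles List of [variant_profile()] objects.
#' @param backbone A `haplogroup_tree` (see [load_haplogroup_config()]).
#' @param assignments Optional classification report from
#'   [classify_profiles()]; computed if missing. Every profile must be
#'   assigned.
#' @return A [mutation_tree()] whose internal backbone nodes are haplogroup
#'   roots (branches carrying the haplogroup's own defining variants) and
#'   whose tips are the samples.
#' @export
build_tree <- function(profiles, backbone, assignments = NULL) {
  if (is.null(assignments)) assignments <- classify_profiles(profiles, backbone)
  ids <- vapply(profiles, function(p) p$sample_id, "")
  miss <- setdiff(ids, assignments$sample_id)
  if (length(miss) > 0L) {
    stop("unclassified profile(s): ", paste(miss, collapse = ", "))
  }
  hg_of <- setNames(assignments$haplogroup, assignments$sample_id)

  # backbone subtree: used haplogroups and their ancestors, root first
  used <- unique(hg_of[ids])
  keep <- unique(unlist(lapply(used, hg_path_to_root, tree = backbone)))
  keep <- keep[order(match(keep, backbone$nodes$name))]
  keep <- backbone$nodes$name[backbone$nodes$name %in% keep]  # config order
  ord <- order(backbone$nodes$depth[match(keep, backbone$nodes$name)])
  keep <- keep[ord]

  parent <- integer(); label <- character(); mutations <- list()
  add_node <- function(parent_id, lab, muts) {
    parent[length(parent) + 1L] <<- parent_id
    label[length(label) + 1L] <<- lab
    mutations[[length(mutations) + 1L]] <<- muts
    length(parent)
  }
  hg_node <- setNames(integer(length(keep)), keep)
  parent_of <- setNames(backbone$nodes$parent, backbone$nodes$name)
  for (h in keep) {
    p <- parent_of[[h]]
    pid <- if (p == "" || !p %in% names(hg_node)) NA_integer_ else hg_node[[p]]
    hg_node[[h]] <- add_node(pid, h, norm_label(backbone$motifs[[h]]))
  }

  flatten <- function(unit, parent_id) {
    id <- add_node(parent_id, unit$label, unit$branch)
    for (ch in unit$children) flatten(ch, id)
  }
  for (h in used) {
    members <- profiles[hg_of[ids] == h]
    founders <- norm_label(founding_set(h, backbone))
    units <- lapply(members, function(p) {
      list(label = p$sample_id,
           branch = setdiff(profile_labels(p, normalize = TRUE), founders),
           children = list(), tip = TRUE)
    })
    units <- agglomerate_units(units)
    for (u in units) flatten(u, hg_node[[h]])
  }
  mutation_tree(parent, label, mutations)
}

# greedy parsimony agglomeration: repeatedly extract the largest shared
# mutation set among current units onto a new internal node
agglomerate_units <- function(units) {
  repeat {
    k <- length(units)
    if (k < 2L) return(units)
    best <- NULL
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        sh <- intersect(units[[i]]$branch, units[[j]]$branch)
        if (length(sh) == 0L) next
        cand <- list(i = i, j = j, shared = sh)
        if (is.null(best) || better_merge(cand, best, units)) best <- cand
      }
    }
    if (is.null(best)) return(units)
    a <- units[[best$i]]; b <- units[[best$j]]
    a$branch <- setdiff(a$branch, best$shared)
    b$branch <- setdiff(b$branch, best$shared)
    children <- list()
    for (u in list(a, b)) {
      if (length(u$branch) == 0L && !u$tip) {
        children <- c(children, u$children)  # contract empty internal branch
      } else {
        children <- c(children, list(u))
      }
    }
    merged <- list(
      label = "",
      branch = best$shared, children = children, tip = FALSE)
    units <- c(units[-c(best$i, best$j)], list(merged))
  }
}

better_merge <- function(a, b, units) {
  if (length(a$shared) != length(b$shared)) {
    return(length(a$shared) > length(b$shared))
  }
  pa <- min(label_positions(a$shared)); pb <- min(label_positions(b$shared))
  if (pa != pb) return(pa < pb)
  ka <- paste(sort(c(units[[a$i]]$label, units[[a$j]]$label)), collapse = "|")
  kb <- paste(sort(c(units[[b$i]]$label, units[[b$j]]$label)), collapse = "|")
  ka < kb
}

label_positions <- function(labels) {
  as.integer(sub("^([0-9]+).*$", "\\1", labels))
}

#' Annotate recurrent and back mutations on a tree
#'
#' A mutation is flagged *recurrent* when the same (position, kind, allele)
#' occurs on two or more branches of the tree. A mutation is flagged a *back
#' mutation* (suffix `@`) when it restores the reference allele at a site
#' already mutated on an ancestral branch; from labels alone this is
#' decidable for transitions (which are self-inverse), so a transition whose
#' root-to-tip path carries an odd number of earlier transitions at the same
#' np receives the `@` suffix. Idempotent: existing `@` marks are stripped
#' before re-annotation.
#'
#' @param t A [mutation_tree()].
#' @return The tree with back mutations suffixed `@` in the branch mutation
#'   lists and a `recurrent` field holding the recurrent labels.
#' @export
annotate_recurrence <- function(t) {
  muts <- lapply(t$mutations, function(m) sub("@$", "", m))
  all_norm <- norm_label(unlist(muts, use.names = FALSE))
  tab <- table(all_norm)
  t$recurrent <- names(tab)[tab >= 2L]

  is_transition <- function(labels) grepl("^[0-9]+h?$", labels)
  ch <- tree_children(t)
  decorate <- function(node, trans_count) {
    m <- muts[[node]]
    if (length(m) > 0L) {
      pos <- label_positions(m)
      tr <- is_transition(m)
      back <- logical(length(m))
      for (i in seq_along(m)) {
        if (tr[i]) {
          prior <- trans_count[as.character(pos[i])]
          prior <- if (is.na(prior)) 0L else prior
          back[i] <- prior %% 2L == 1L
          trans_count[as.character(pos[i])] <- prior + 1L
        }
      }
      muts[[node]] <<- paste0(m, ifelse(back, "@", ""))
    }
    for (c_ in ch[[node]]) decorate(c_, trans_count)
  }
  counts0 <- integer(0)
  decorate(tree_root(t), counts0)
  t$mutations <- muts
  t
}

#' Shared non-founding mutations of two profiles
#'
#' The mutations two profiles have in common beyond the founding motif of
#' their haplogroup -- the signature of post-founding common ancestry (or of
#' recurrence). Heteroplasmy suffixes are ignored.
#'
#' @param a,b [variant_profile()] objects (or character label vectors).
#' @param founders Founding-motif labels, e.g. from [founding_set()].
#' @return Character vector of shared non-founding labels, sorted by
#'   position.
#' @export
shared_nonfounding <- function(a, b, founders = character()) {
  la <- if (inherits(a, "variant_profile")) profile_labels(a, normalize = TRUE) else norm_label(a)
  lb <- if (inherits(b, "variant_profile")) profile_labels(b, normalize = TRUE) else norm_label(b)
  out <- setdiff(intersect(la, lb), norm_label(founders))
  out[order(label_positions(out))]
}

#' Private mutations of a profile
#'
#' Mutations carried by `a` that are neither founding mutations nor present
#' in any of the other profiles.
#'
#' @param a A [variant_profile()] (or character label vector).
#' @param others List of comparison profiles (or label vectors).
#' @param founders Founding-motif labels.
#' @return Character vector of private labels, sorted by position.
#' @export
private_mutations <- function(a, others = list(), founders = character()) {
  la <- if (inherits(a, "variant_profile")) profile_labels(a, normalize = TRUE) else norm_label(a)
  lo <- unlist(lapply(others, function(o) {
    if (inherits(o, "variant_profile")) profile_labels(o, normalize = TRUE) else norm_label(o)
  }), use.names = FALSE)
  out <- setdiff(setdiff(la, norm_label(founders)), lo)
  out[order(label_positions(out))]
}

#' Write a mutation tree in newick format
#'
#' Branch lengths are mutation counts; the mutation labels travel in a
#' bracketed comment after each node (`[&mutations=a|b]`), which standard
#' newick readers skip.
#'
#' @param t A [mutation_tree()].
#' @param path Optional output file; when `NULL` the newick string is
#'   returned.
#' @param annotations Include the mutation-label comments?
#' @return The newick string (invisibly when `path` is given).
#' @export
write_tree_newick <- function(t, path = NULL, annotations = TRUE) {
  ch <- tree_children(t)
  esc <- function(x) gsub("[,;:()\\[\\]\\s]", "_", x, perl = TRUE)
  rec <- function(node) {
    core <- if (t$is_tip[node]) {
      esc(t$label[node])
    } else {
      paste0("(", paste(vapply(ch[[node]], rec, ""), collapse = ","), ")",
             esc(t$label[node]))
    }
    com <- if (annotations && length(t$mutations[[node]]) > 0L) {
      paste0("[&mutations=", paste(t$mutations[[node]], collapse = "|"), "]")
    } else ""
    paste0(core, com, ":", length(t$mutations[[node]]))
  }
  s <- paste0(rec(tree_root(t)), ";")
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}
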