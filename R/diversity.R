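# Haplotype diversity and related summaries. Haplotype identity is equality
# of (filtered) variant profiles over the whole molecule, control region
# included.

haplotype_keys <- function(profiles) {
  if (is.character(profiles)) return(profiles)
  vapply(profiles, function(p) {
    paste(profile_labels(p, normalize = TRUE), collapse = " ")
  }, "")
}

#' Haplotype (gene) diversity with its standard error
#'
#' Nei's unbiased gene diversity
#' \deqn{H = \frac{n}{n-1}\Big(1 - \sum_i p_i^2\Big)}
#' over haplotype class frequencies p_i, with sampling variance
#' \deqn{V = \frac{2}{n(n-1)}\Big\{2(n-2)\Big[\sum_i p_i^3 -
#'   \big(\sum_i p_i^2\big)^2\Big] + \sum_i p_i^2 -
#'   \big(\sum_i p_i^2\big)^2\Big\}}
#' and standard error sqrt(V). H equals 1 exactly when all n >= 2 haplotypes
#' are distinct.
#'
#' @param profiles List of [variant_profile()] objects, or a character vector
#'   of precomputed haplotype keys (one per sampled individual).
#' @return List with `H`, `se_H` and `n`. `se_H` is exact; report formatting
#'   conventionally rounds it to 3 decimals.
#' @export
haplotype_diversity <- function(profiles) {
  keys <- haplotype_keys(profiles)
  n <- length(keys)
  if (n < 2L) stop("haplotype diversity needs at least two samples")
  counts <- as.numeric(table(keys))
  p <- counts / n
  s2 <- sum(p^2)
  s3 <- sum(p^3)
  # count form keeps the all-distinct case exactly 1
  H <- (n^2 - sum(counts^2)) / (n * (n - 1))
  V <- 2 / (n * (n - 1)) * (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  list(H = H, se_H = sqrt(max(V, 0)), n = n)
}

#' Mean pairwise nucleotide differences
#'
#' The average, over all unordered pairs of profiles, of the number of
#' variants carried by exactly one of the pair (symmetric difference of the
#' variant sets, heteroplasmy suffixes ignored) -- the within-haplogroup M
#' statistic when applied to one haplogroup's (filtered) profiles.
#'
#' @param profiles List of >= 2 [variant_profile()] objects.
#' @return Mean pairwise difference (numeric scalar).
#' @export
mean_pairwise_diff <- function(profiles) {
  n <- length(profiles)
  if (n < 2L) stop("mean pairwise difference needs at least two profiles")
  labs <- lapply(profiles, profile_labels, normalize = TRUE)
  tot <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      tot <- tot + length(setdiff(labs[[i]], labs[[j]])) +
        length(setdiff(labs[[j]], labs[[i]]))
    }
  }
  tot / (n * (n - 1) / 2)
}

#' Haplogroup frequency summary
#'
#' @param assignments A classification report from [classify_profiles()], a
#'   character vector of haplogroup names (one per sample), or a named count
#'   vector.
#' @return data.frame with columns `haplogroup`, `n`, `freq` (exact percent;
#'   sums to 100) and `percent` (half-even rounded to 1 decimal for
#'   reporting), sorted by decreasing count then name.
#' @export
haplogroup_frequencies <- function(assignments) {
  counts <- if (is.data.frame(assignments)) {
    table(assignments$haplogroup)
  } else if (!is.null(names(assignments)) && is.numeric(assignments)) {
    assignments
  } else {
    table(as.character(assignments))
  }
  if (length(counts) == 0L || sum(counts) == 0) stop("no assignments")
  d <- data.frame(haplogroup = names(counts), n = as.integer(counts),
                  stringsAsFactors = FALSE)
  d$freq <- 100 * d$n / sum(d$n)
  d$percent <- round(d$freq, 1)
  d <- d[order(-d$n, d$haplogroup), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Diversity summary of a classified sample
#'
#' Combines haplotype diversity, haplogroup frequencies and the
#' within-haplogroup mean pairwise differences (M, computed for haplogroups
#' with >= 2 members) into one report.
#'
#' @param profiles List of [variant_profile()] objects (already filtered as
#'   desired; haplotype identity spans the whole molecule).
#' @param assignments Classification report from [classify_profiles()].
#' @return List with `n`, `H`, `se_H`, and `by_haplogroup` (data.frame
#'   `haplogroup`, `n`, `freq`, `percent`, `M`).
#' @export
diversity_summary <- function(profiles, assignments) {
  hd <- haplotype_diversity(profiles)
  fr <- haplogroup_frequencies(assignments)
  ids <- vapply(profiles, function(p) p$sample_id, "")
  hg_of <- setNames(assignments$haplogroup, assignments$sample_id)
  fr$M <- vapply(fr$haplogroup, function(h) {
    members <- profiles[hg_of[ids] == h]
    if (length(members) < 2L) return(NA_real_)
    mean_pairwise_diff(members)
  }, 0)
  list(n = hd$n, H = hd$H, se_H = hd$se_H, by_haplogroup = fr)
}
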