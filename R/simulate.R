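# Synthetic mitogenome datasets with the statistical structure of a
# population mitogenome survey: haplogroup founder motifs applied to the
# reference, star-like or coalescent within-haplogroup genealogies, and
# Poisson clock-rate mutations under HKY85 with discrete-gamma site rates.
# Every dataset carries a truth manifest so pipeline recovery can be checked.

#' Simulation configuration
#'
#' The defaults reproduce the composition of the Nile Delta survey that
#' motivates the package: 31 mitogenomes in four haplogroups (T1:18, T2:6,
#' T3:5, Q1:2), star-like within-haplogroup radiations at the published
#' rho-based clade depths, a coding-region clock of one mutation per 3,172
#' years, and a 5x hypermutable control region.
#'
#' @param seed Integer seed; fully determines the dataset.
#' @param haplogroup_mix Named integer vector: samples per haplogroup.
#' @param clade_age_ky Named numeric vector: true clade age (ky) per
#'   haplogroup in `haplogroup_mix`.
#' @param genealogy Within-clade genealogy: `"star"` (all tips attach to the
#'   clade root at the clade age), `"coalescent_constant"` (Kingman
#'   n-coalescent scaled so the expected root height equals the clade age) or
#'   `"coalescent_growth"` (coalescent under exponential growth, rescaled to
#'   the same expected root height).
#' @param clock A [clock_model()].
#' @param model An [hky85_model()] for mutation placement; `NULL` uses
#'   kappa = 20, alpha = 0.5, 32 categories and the reference's base
#'   composition.
#' @param control_region_rate_multiplier Per-site rate multiplier for sites
#'   outside the clock's coding region.
#' @param growth_rate Exponential growth rate (per ky) for the growth
#'   genealogy.
#' @param reference A [reference_genome()]; `NULL` loads the packaged one.
#' @param haplogroups A `haplogroup_tree` providing founder motifs; `NULL`
#'   loads the packaged config.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       haplogroup_mix = c(T1 = 18L, T2 = 6L, T3 = 5L, Q1 = 2L),
                       clade_age_ky = c(T1 = 15.57, T2 = 13.64,
                                        T3 = 12.53, Q1 = 19.29),
                       genealogy = c("star", "coalescent_constant",
                                     "coalescent_growth"),
                       clock = clock_model(),
                       model = NULL,
                       control_region_rate_multiplier = 5,
                       growth_rate = 0.5,
                       reference = NULL,
                       haplogroups = NULL) {
  genealogy <- match.arg(genealogy)
  if (is.null(reference)) reference <- load_reference()
  if (is.null(haplogroups)) haplogroups <- load_haplogroup_config()
  if (is.null(model)) {
    bf <- table(factor(reference$bases, levels = c("A", "C", "G", "T")))
    model <- hky85_model(kappa = 20, base_freqs = as.numeric(bf) / sum(bf),
                         alpha = 0.5, n_categories = 32L)
  }
  if (length(haplogroup_mix) == 0L || any(haplogroup_mix < 1L)) {
    stop("haplogroup_mix must give counts >= 1")
  }
  miss <- setdiff(names(haplogroup_mix), names(clade_age_ky))
  if (length(miss) > 0L) stop("no clade age for: ", paste(miss, collapse = ", "))
  if (any(clade_age_ky[names(haplogroup_mix)] <= 0)) {
    stop("clade ages must be positive")
  }
  unknown <- setdiff(names(haplogroup_mix), haplogroups$nodes$name)
  if (length(unknown) > 0L) {
    stop("haplogroup(s) not in config: ", paste(unknown, collapse = ", "))
  }
  if (control_region_rate_multiplier <= 0) {
    stop("control_region_rate_multiplier must be positive")
  }
  structure(list(seed = as.integer(seed),
                 haplogroup_mix = haplogroup_mix,
                 clade_age_ky = clade_age_ky,
                 genealogy = genealogy, clock = clock, model = model,
                 control_region_rate_multiplier = control_region_rate_multiplier,
                 growth_rate = growth_rate,
                 reference = reference, haplogroups = haplogroups),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config: seed %d, %d samples (%s), %s genealogy>\n",
              x$seed, sum(x$haplogroup_mix),
              paste(names(x$haplogroup_mix), x$haplogroup_mix,
                    sep = ":", collapse = " "),
              x$genealogy))
  invisible(x)
}

#' Simulate a within-clade genealogy
#'
#' Draws a rooted timed tree for one clade using the current RNG stream
#' (seed at the caller, or use [generate_dataset()] which seeds from the
#' config). Star mode attaches every tip to the root at the clade age;
#' coalescent modes draw standard n-coalescent waiting times (with an
#' exponential-growth time transform in growth mode), scaled so the expected
#' root height equals the clade age.
#'
#' @param cfg A [sim_config()].
#' @param clade Haplogroup name (must appear in `cfg$haplogroup_mix`).
#' @param n Number of tips; defaults to the clade's count in the mix.
#' @return A `timed_tree`: list with `parent` (NA at root), `label`,
#'   `age_ky` (node ages, tips at 0) and `is_tip`.
#' @export
simulate_genealogy <- function(cfg, clade, n = NULL) {
  if (!clade %in% names(cfg$clade_age_ky)) stop("unknown clade: ", clade)
  if (is.null(n)) n <- cfg$haplogroup_mix[[clade]]
  n <- as.integer(n)
  age <- cfg$clade_age_ky[[clade]]
  tip_labels <- sprintf("%s_%02d", clade, seq_len(n))

  if (cfg$genealogy == "star" || n == 1L) {
    tt <- list(parent = c(NA_integer_, rep(1L, n)),
               label = c(clade, tip_labels),
               age_ky = c(age, rep(0, n)),
               is_tip = c(FALSE, rep(TRUE, n)))
    return(structure(tt, class = "timed_tree"))
  }

  heights <- coalescent_heights(n)        # standard coalescent, N = 1
  if (cfg$genealogy == "coalescent_growth") {
    b <- cfg$growth_rate
    heights <- log1p(b * heights) / b
    expected <- expected_growth_height(n, b)
  } else {
    expected <- 2 * (1 - 1 / n)           # E[TMRCA], N = 1
  }
  heights <- heights * (age / expected)

  parent <- rep(NA_integer_, 2L * n - 1L)
  label <- c(tip_labels, rep("", n - 1L))
  age_ky <- c(rep(0, n), heights)
  active <- seq_len(n)
  for (k in seq_len(n - 1L)) {
    pair <- sample(active, 2L)
    new <- n + k
    parent[pair] <- new
    active <- c(setdiff(active, pair), new)
  }
  label[2L * n - 1L] <- clade
  structure(list(parent = parent, label = label, age_ky = age_ky,
                 is_tip = c(rep(TRUE, n), rep(FALSE, n - 1L))),
            class = "timed_tree")
}

# cumulative coalescence heights (ages of the n-1 internal nodes, oldest
# last) for a standard coalescent with N = 1
coalescent_heights <- function(n) {
  w <- rexp(n - 1L, rate = choose(n:2, 2))
  cumsum(w)
}

# expected root height of the growth-transformed coalescent, by Monte Carlo
# on an isolated RNG stream (memoised; constant for given n and rate)
growth_height_cache <- new.env(parent = emptyenv())
expected_growth_height <- function(n, b, reps = 4000L) {
  key <- sprintf("%d_%g", n, b)
  if (!is.null(growth_height_cache[[key]])) return(growth_height_cache[[key]])
  state <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(state)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", state, envir = globalenv())
  })
  set.seed(830L)
  h <- vapply(seq_len(reps), function(i) {
    x <- coalescent_heights(n)
    log1p(b * x[n - 1L]) / b
  }, 0)
  growth_height_cache[[key]] <- mean(h)
  mean(h)
}

#' Simulate mutations along a timed genealogy
#'
#' Applies the clade's founder motif to the reference at the root, then drops
#' mutations on each branch as a Poisson process with mean
#' `branch_years / years_per_mutation` over the coding region (control-region
#' sites mutate at the configured multiple of the per-site coding rate).
#' Sites are chosen proportionally to discrete-gamma site rates drawn once
#' per simulation; the substituting base is drawn from the HKY85 jump
#' probabilities given the current base. Recurrent and back mutations are
#' possible and left in place.
#'
#' @param tree A `timed_tree` from [simulate_genealogy()].
#' @param cfg A [sim_config()].
#' @param clade Haplogroup name whose founder motif seeds the root.
#' @return List with `sequences` (named character, tips), `tip_profiles`
#'   (named list of truth variant-label vectors, computed from the simulated
#'   states, not by sequence comparison), `branch_events` (list of
#'   data.frames `np`, `from`, `to` per node) and `branch_counts` (mutations
#'   per branch).
#' @export
simulate_mutations <- function(tree, cfg, clade) {
  ref <- cfg$reference
  L <- ref$length
  reg <- cfg$clock$region
  coding <- seq_len(L) >= reg$start & seq_len(L) <= reg$end
  ypm <- cfg$clock$years_per_mutation

  site_rate <- sample(discretize_gamma(cfg$model$alpha,
                                       cfg$model$n_categories),
                      L, replace = TRUE)

  # founder motif at the root (substitutions only)
  root_bases <- ref$bases
  motif <- parse_variant_label(founding_set(clade, cfg$haplogroups))
  for (i in seq_len(nrow(motif))) {
    pos <- motif$position[i]
    if (motif$kind[i] == "transition") {
      root_bases[pos] <- transition_partner(ref$bases[pos])
    } else if (motif$kind[i] == "transversion") {
      root_bases[pos] <- motif$allele[i]
    }
  }

  jump <- hky85_jump_weights(cfg$model)
  nnode <- length(tree$parent)
  ch <- vector("list", nnode)
  for (i in seq_len(nnode)) {
    p <- tree$parent[i]
    if (!is.na(p)) ch[[p]] <- c(ch[[p]], i)
  }
  root <- which(is.na(tree$parent))

  sequences <- list()
  tip_profiles <- list()
  branch_events <- vector("list", nnode)
  branch_counts <- integer(nnode)

  mult <- cfg$control_region_rate_multiplier
  n_coding <- sum(coding)
  n_control <- L - n_coding
  w_coding <- site_rate * coding
  w_control <- site_rate * !coding

  walk <- function(node, bases) {
    p <- tree$parent[node]
    if (!is.na(p)) {
      t_years <- (tree$age_ky[p] - tree$age_ky[node]) * 1000
      k_cod <- rpois(1L, t_years / ypm)
      k_ctl <- rpois(1L, t_years / ypm * mult * n_control / n_coding)
      np <- integer(0)
      if (k_cod > 0L) np <- c(np, sample.int(L, k_cod, replace = TRUE,
                                             prob = w_coding))
      if (k_ctl > 0L) np <- c(np, sample.int(L, k_ctl, replace = TRUE,
                                             prob = w_control))
      ev <- list()
      for (s in np) {
        from <- bases[s]
        to <- sample(c("A", "C", "G", "T"), 1L, prob = jump[from, ])
        bases[s] <- to
        ev[[length(ev) + 1L]] <- data.frame(np = s, from = from, to = to,
                                            stringsAsFactors = FALSE)
      }
      branch_events[[node]] <<- if (length(ev)) do.call(rbind, ev) else
        data.frame(np = integer(), from = character(), to = character(),
                   stringsAsFactors = FALSE)
      branch_counts[node] <<- length(np)
    }
    if (tree$is_tip[node]) {
      sequences[[tree$label[node]]] <<- paste(bases, collapse = "")
      tip_profiles[[tree$label[node]]] <<- state_labels(ref$bases, bases)
    } else {
      for (c_ in ch[[node]]) walk(c_, bases)
    }
  }
  walk(root, root_bases)

  list(sequences = unlist(sequences),
       tip_profiles = tip_profiles,
       branch_events = branch_events,
       branch_counts = branch_counts)
}

# HKY85 jump-chain weights: probability that a mutating base b substitutes to
# a, proportional to pi_a (times kappa for the transition partner)
hky85_jump_weights <- function(model) {
  bases <- c("A", "C", "G", "T")
  w <- matrix(rep(model$base_freqs, each = 4L), 4, 4,
              dimnames = list(bases, bases))
  for (b in bases) {
    w[b, transition_partner(b)] <- w[b, transition_partner(b)] * model$kappa
    w[b, b] <- 0
  }
  w / rowSums(w)
}

# reference-relative labels of a simulated state vector (substitutions only)
state_labels <- function(ref_bases, bases) {
  diff <- which(bases != ref_bases)
  if (length(diff) == 0L) return(character())
  vapply(diff, function(p) {
    if (bases[p] == transition_partner(ref_bases[p])) {
      as.character(p)
    } else {
      paste0(p, bases[p])
    }
  }, "")
}

#' Simulate one clade (genealogy plus sequences)
#'
#' Convenience wrapper drawing a genealogy and mutations for a single clade
#' from the current RNG stream.
#'
#' @param cfg A [sim_config()].
#' @param clade Haplogroup name.
#' @param n Optional tip count override.
#' @return List with `genealogy` (`timed_tree`) and the elements of
#'   [simulate_mutations()].
#' @export
simulate_clade <- function(cfg, clade, n = NULL) {
  g <- simulate_genealogy(cfg, clade, n)
  c(list(genealogy = g), simulate_mutations(g, cfg, clade))
}

#' Generate a full synthetic dataset with its truth manifest
#'
#' Seeds the RNG from the config and simulates every clade in the haplogroup
#' mix; output is byte-identical across runs with the same config. Variant
#' profiles are obtained by running [call_variants()] on the simulated
#' sequences, so the returned profiles exercise the same code path as real
#' data.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `sim_dataset`: list with `sequences` (named
#'   character vector), `profiles` (list of [variant_profile()]), `truth`
#'   (list: `samples` data.frame with `sample_id`/`haplogroup`/`clade_age_ky`,
#'   `branch_counts`, `tip_profiles`, `genealogies` as newick strings,
#'   `seed`) and `config`.
#' @export
generate_dataset <- function(cfg) {
  set.seed(cfg$seed)
  sequences <- character()
  profiles <- list()
  samples <- list()
  genealogies <- list()
  branch_counts <- list()
  tip_profiles <- list()
  for (clade in names(cfg$haplogroup_mix)) {
    sim <- simulate_clade(cfg, clade)
    sequences <- c(sequences, sim$sequences)
    genealogies[[clade]] <- write_timed_newick(sim$genealogy)
    branch_counts[[clade]] <- sim$branch_counts
    tip_profiles <- c(tip_profiles, sim$tip_profiles)
    samples[[clade]] <- data.frame(
      sample_id = names(sim$sequences), haplogroup = clade,
      clade_age_ky = cfg$clade_age_ky[[clade]], stringsAsFactors = FALSE)
  }
  profiles <- lapply(names(sequences), function(id) {
    call_variants(sequences[[id]], cfg$reference, sample_id = id)
  })
  names(profiles) <- names(sequences)
  truth <- list(samples = do.call(rbind, unname(samples)),
                branch_counts = branch_counts,
                tip_profiles = tip_profiles,
                genealogies = genealogies,
                seed = cfg$seed)
  structure(list(sequences = sequences, profiles = profiles, truth = truth,
                 config = cfg),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset: %d sequences, seed %d>\n",
              length(x$sequences), x$config$seed))
  invisible(x)
}

write_timed_newick <- function(tt) {
  ch <- vector("list", length(tt$parent))
  for (i in seq_along(tt$parent)) {
    p <- tt$parent[i]
    if (!is.na(p)) ch[[p]] <- c(ch[[p]], i)
  }
  rec <- function(node) {
    blen <- if (is.na(tt$parent[node])) 0 else
      tt$age_ky[tt$parent[node]] - tt$age_ky[node]
    core <- if (tt$is_tip[node]) {
      tt$label[node]
    } else {
      paste0("(", paste(vapply(ch[[node]], rec, ""), collapse = ","), ")",
             tt$label[node])
    }
    paste0(core, ":", format(blen, digits = 10))
  }
  paste0(rec(which(is.na(tt$parent))), ";")
}

#' Write a simulated dataset to disk
#'
#' Emits `sequences.fasta`, `variants.tsv` (the package's variant-TSV
#' dialect), `truth.json` and one `genealogy_<clade>.nwk` per clade.
#'
#' @param ds A `sim_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_mitogenomes(ds$sequences, file.path(dir, "sequences.fasta"))
  write_variant_tsv(ds$profiles, file.path(dir, "variants.tsv"))
  truth <- ds$truth
  jsonlite::write_json(
    list(samples = truth$samples,
         branch_counts = truth$branch_counts,
         tip_profiles = truth$tip_profiles,
         genealogies = truth$genealogies,
         seed = truth$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  for (clade in names(truth$genealogies)) {
    writeLines(truth$genealogies[[clade]],
               file.path(dir, paste0("genealogy_", clade, ".nwk")))
  }
  invisible(dir)
}

#' Date one haplogroup's profiles with the rho statistic
#'
#' The standard dating pipeline for a clade: hypervariable filtering,
#' restriction to the clock's coding region with heteroplasmies excluded,
#' backbone-constrained tree building, rho/sigma, and clock conversion.
#'
#' @param profiles List of [variant_profile()] objects, all belonging to
#'   `haplogroup`.
#' @param haplogroup Haplogroup name.
#' @param backbone A `haplogroup_tree`.
#' @param clock A [clock_model()].
#' @return List with `rho` (`rho_estimate`), `age` (`age_estimate`) and
#'   `tree` (the clade [mutation_tree()]).
#' @export
date_clade <- function(profiles, haplogroup, backbone,
                       clock = clock_model()) {
  prof <- lapply(profiles, function(p) {
    restrict_region(filter_hypervariable(p), clock$region,
                    exclude_heteroplasmic = TRUE)
  })
  ids <- vapply(prof, function(p) p$sample_id, "")
  assignments <- data.frame(sample_id = ids, haplogroup = haplogroup,
                            stringsAsFactors = FALSE)
  t <- build_tree(prof, backbone, assignments)
  r <- compute_rho(t, node = haplogroup)
  list(rho = r, age = to_age(r$rho, r$sigma, clock, "rho"), tree = t)
}
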