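# Independent oracles and fixture builders used across the test files.
# Everything here is deliberately brute-force / closed-form and shares no code
# with the package implementation paths it checks.

# --- random mutation trees --------------------------------------------------

# random rooted mutation tree: each non-root node attaches to a uniformly
# chosen earlier node and carries a Poisson number of unique mutation labels
random_mutation_tree <- function(n_tips, lambda = 2) {
  n_extra <- sample(0:(n_tips - 1L), 1L)      # internal nodes besides the root
  n_nodes <- 1L + n_extra + n_tips
  parent <- rep(NA_integer_, n_nodes)
  next_lab <- 0L
  muts <- vector("list", n_nodes)
  muts[[1L]] <- character()
  for (i in seq_len(n_nodes)[-1L]) {
    # tips (the last n_tips ids) may attach anywhere before them; internal
    # nodes attach to earlier internal nodes, keeping ids topologically sorted
    parent[i] <- sample.int(min(i - 1L, 1L + n_extra), 1L)
    k <- rpois(1L, lambda)
    muts[[i]] <- if (k > 0L) as.character(next_lab + seq_len(k)) else character()
    next_lab <- next_lab + k
  }
  is_internal <- seq_len(n_nodes) <= 1L + n_extra
  # force internal nodes without children to be tips by reindexing: simplest
  # is to accept them as tips
  label <- ifelse(is_internal, paste0("n", seq_len(n_nodes)),
                  paste0("t", seq_len(n_nodes)))
  mutation_tree(parent, label, muts)
}

# brute-force rho: mean over tips of the root-to-tip mutation count
brute_rho <- function(t) {
  tips <- which(t$is_tip)
  d <- vapply(tips, function(v) {
    tot <- 0L
    while (!is.na(t$parent[v])) {
      tot <- tot + length(t$mutations[[v]])
      v <- t$parent[v]
    }
    tot
  }, 0L)
  mean(d)
}

# brute-force sigma: sqrt(sum_b l_b n_b^2) / n with n_b counted by explicit
# root-to-tip path enumeration
brute_sigma <- function(t) {
  tips <- which(t$is_tip)
  n <- length(tips)
  onpath <- matrix(FALSE, length(t$parent), n)
  for (j in seq_along(tips)) {
    v <- tips[j]
    while (!is.na(t$parent[v])) {
      onpath[v, j] <- TRUE
      v <- t$parent[v]
    }
  }
  l <- vapply(t$mutations, length, 0L)
  sqrt(sum(l * rowSums(onpath)^2)) / n
}

# --- exhaustive parsimony ---------------------------------------------------

# all set partitions of a vector into >= 2 blocks
set_partitions <- function(x) {
  n <- length(x)
  if (n == 1L) return(list(list(x)))
  parts <- list()
  rest <- set_partitions_all(x[-1L])
  for (p in rest) {
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(x[1L], q[[i]])
      parts[[length(parts) + 1L]] <- q
    }
    parts[[length(parts) + 1L]] <- c(list(x[1L]), p)
  }
  Filter(function(p) length(p) >= 2L, parts)
}
set_partitions_all <- function(x) {
  if (length(x) == 1L) return(list(list(x)))
  parts <- list()
  for (p in set_partitions_all(x[-1L])) {
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(x[1L], q[[i]])
      parts[[length(parts) + 1L]] <- q
    }
    parts[[length(parts) + 1L]] <- c(list(x[1L]), p)
  }
  parts
}

# all rooted multifurcating topologies over the tips, as nested lists
all_topologies <- function(tips) {
  if (length(tips) == 1L) return(list(tips[[1L]]))
  out <- list()
  for (p in set_partitions(tips)) {
    subs <- lapply(p, all_topologies)
    idx <- rep(1L, length(subs))
    repeat {
      out[[length(out) + 1L]] <- lapply(seq_along(subs),
                                        function(i) subs[[i]][[idx[i]]])
      j <- length(idx)
      while (j >= 1L) {
        idx[j] <- idx[j] + 1L
        if (idx[j] <= length(subs[[j]])) break
        idx[j] <- 1L; j <- j - 1L
      }
      if (j < 1L) break
    }
  }
  out
}

# minimal parsimony changes for one binary character (tips carrying the
# mutation = 1) on a nested-list topology, root fixed ancestral (0):
# Sankoff over states {0, 1}, unit change cost
sankoff_binary <- function(topo, carriers) {
  cost <- function(node) {
    if (!is.list(node)) {
      if (node %in% carriers) return(c(Inf, 0)) else return(c(0, Inf))
    }
    kid_costs <- lapply(node, cost)
    vapply(1:2, function(s) {
      sum(vapply(kid_costs, function(kc) {
        min(kc[s], kc[3L - s] + 1)
      }, 0))
    }, 0)
  }
  c0 <- cost(topo)
  min(c0[1L], c0[2L] + 1)
}

# exhaustive minimum total parsimony length over all rooted topologies
exhaustive_min_length <- function(tip_sets) {
  tips <- names(tip_sets)
  all_muts <- unique(unlist(tip_sets))
  best <- Inf
  for (topo in all_topologies(as.list(tips))) {
    len <- sum(vapply(all_muts, function(m) {
      sankoff_binary(topo, tips[vapply(tip_sets, function(s) m %in% s, TRUE)])
    }, 0))
    best <- min(best, len)
  }
  best
}

# --- substitution-model oracles ---------------------------------------------

# HKY85 rate matrix built from first principles (A,C,G,T order), mean rate 1
oracle_hky_Q <- function(kappa, pi) {
  bases <- c("A", "C", "G", "T")
  names(pi) <- bases
  Q <- matrix(0, 4, 4, dimnames = list(bases, bases))
  for (i in bases) for (j in bases) {
    if (i == j) next
    ts <- (i == "A" && j == "G") || (i == "G" && j == "A") ||
      (i == "C" && j == "T") || (i == "T" && j == "C")
    Q[i, j] <- pi[j] * if (ts) kappa else 1
  }
  diag(Q) <- -rowSums(Q)
  Q / (-sum(pi * diag(Q)))
}

# matrix exponential by scaling and squaring on the Taylor series
oracle_expm <- function(A, squarings = 20L, terms = 24L) {
  A <- A / 2^squarings
  P <- diag(nrow(A))
  term <- diag(nrow(A))
  for (k in seq_len(terms)) {
    term <- term %*% A / k
    P <- P + term
  }
  for (s in seq_len(squarings)) P <- P %*% P
  P
}

# exhaustive-enumeration log-likelihood of an alignment on a rooted topology
# (nested list of tip names) under HKY + discrete gamma: sums over all
# internal-state assignments explicitly
oracle_enum_loglik <- function(seqs, topo, node_lengths, kappa, pi, alpha, k) {
  rates <- mitotaur::discretize_gamma(alpha, k)
  Q <- oracle_hky_Q(kappa, pi)
  base_idx <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  mats <- lapply(rates, function(r) {
    lapply(node_lengths, function(t) oracle_expm(Q * (t * r)))
  })
  # collect nodes in a fixed traversal; internal nodes enumerated
  flatten <- function(node, parent_id, acc) {
    id <- length(acc$kind) + 1L
    acc$kind <- c(acc$kind, if (is.list(node)) "internal" else "tip")
    acc$parent <- c(acc$parent, parent_id)
    acc$tip <- c(acc$tip, if (is.list(node)) NA_character_ else node)
    if (is.list(node)) for (ch in node) acc <- flatten(ch, id, acc)
    acc
  }
  acc <- flatten(topo, NA_integer_, list(kind = character(),
                                         parent = integer(),
                                         tip = character()))
  internals <- which(acc$kind == "internal")
  tipsv <- which(acc$kind == "tip")
  nsite <- nchar(seqs[[1L]])
  chars <- lapply(seqs, function(s) base_idx[strsplit(s, "")[[1L]]])
  ll <- 0
  for (site in seq_len(nsite)) {
    site_lik <- 0
    for (ri in seq_along(rates)) {
      P <- mats[[ri]]
      tot <- 0
      grid <- as.matrix(expand.grid(rep(list(1:4), length(internals))))
      for (g in seq_len(nrow(grid))) {
        states <- integer(length(acc$kind))
        states[internals] <- grid[g, ]
        for (v in tipsv) states[v] <- chars[[acc$tip[v]]][site]
        pr <- unname(pi[states[1L]])
        for (v in seq_along(acc$kind)[-1L]) {
          pr <- pr * P[[v]][states[acc$parent[v]], states[v]]
        }
        tot <- tot + pr
      }
      site_lik <- site_lik + tot / length(rates)
    }
    ll <- ll + log(site_lik)
  }
  unname(ll)
}

# --- misc -------------------------------------------------------------------

# trivial one-node backbone for trees built outside the taurine config
trivial_backbone <- function() {
  haplogroup_tree(data.frame(name = "anc", parent = "",
                             defining_variants = "",
                             stringsAsFactors = FALSE))
}

# a small reference + matching clock/haplogroups for cheap simulations
small_sim_config <- function(seed, n, age_ky, genealogy = "star",
                             ref_len = 2000L, motif = "150,250",
                             multiplier = 5, alpha = 0.5) {
  set.seed(991L)
  ref <- reference_genome(paste(
    sample(c("A", "C", "G", "T"), ref_len, TRUE,
           prob = c(.33, .26, .13, .28)), collapse = ""), id = "miniref")
  hg <- haplogroup_tree(data.frame(
    name = c("anc", "X"), parent = c("", "anc"),
    defining_variants = c("", motif), stringsAsFactors = FALSE))
  sim_config(seed = seed, haplogroup_mix = c(X = n),
             clade_age_ky = c(X = age_ky), genealogy = genealogy,
             clock = clock_model(3172, region("mini-coding", 100L,
                                              ref_len - 100L)),
             control_region_rate_multiplier = multiplier,
             model = hky85_model(kappa = 20, alpha = alpha),
             reference = ref, haplogroups = hg)
}
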