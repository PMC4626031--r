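# Coalescence dating. Two routes to a clade's mutational divergence:
#   * the rho statistic -- the average mutational distance of a clade's
#     haplotypes from the clade root -- with the heuristic genealogy-based
#     standard error sigma; and
#   * clock-constrained maximum likelihood under HKY85 with discrete-gamma
#     rate heterogeneity (Felsenstein pruning), whose "molecular divergence"
#     is the fitted per-site root height scaled to the coding region.
# Both are converted to years with a coding-region molecular clock.

#' Molecular clock
#'
#' The substitution-rate calibration used to convert mutational divergence
#' into years. The default is the bovine coding-region clock of one mutation
#' every 3,172 years over np 364-15791.
#'
#' @param years_per_mutation Years per expected mutation over `region`.
#' @param region The [region()] over which the clock is calibrated.
#' @return An object of class `clock_model`.
#' @export
clock_model <- function(years_per_mutation = 3172, region = coding_region()) {
  if (!is.numeric(years_per_mutation) || years_per_mutation <= 0) {
    stop("years_per_mutation must be positive")
  }
  structure(list(years_per_mutation = years_per_mutation, region = region),
            class = "clock_model")
}

#' Rho statistic of a clade with its heuristic standard error
#'
#' For a clade subtree whose branches b carry l_b mutations and subtend n_b
#' of the clade's n sampled haplotypes,
#' \deqn{\rho = \sum_b l_b n_b / n, \qquad
#'       \sigma = \sqrt{\sum_b l_b n_b^2} / n.}
#' rho equals the average mutational distance of the haplotypes from the
#' clade root; sigma is the genealogy-based heuristic standard error.
#' Mutation counting follows whatever filtering the caller applied when the
#' tree was built (for dating: coding region, heteroplasmies excluded).
#'
#' @param clade A [mutation_tree()].
#' @param node Root of the clade: a node label or id; defaults to the tree
#'   root.
#' @return An object of class `rho_estimate`: list with `rho`, `sigma`, `n`.
#' @export
compute_rho <- function(clade, node = NULL) {
  root <- if (is.null(node)) {
    tree_root(clade)
  } else if (is.character(node)) {
    w <- which(clade$label == node)
    if (length(w) == 0L) stop("no node labelled '", node, "'")
    w[1L]
  } else {
    as.integer(node)
  }
  # nodes strictly below the clade root
  below <- logical(length(clade$parent))
  for (i in seq_along(clade$parent)) {
    j <- i
    while (!is.na(clade$parent[j])) {
      if (clade$parent[j] == root) { below[i] <- TRUE; break }
      j <- clade$parent[j]
    }
  }
  nb_all <- tips_below(clade)
  n <- if (clade$is_tip[root]) 1L else nb_all[root]
  if (n < 1L || (!clade$is_tip[root] && !any(below))) stop("empty clade")
  l_b <- vapply(clade$mutations[below], length, 0L)
  n_b <- nb_all[below]
  rho <- sum(l_b * n_b) / n
  sigma <- sqrt(sum(l_b * n_b^2)) / n
  structure(list(rho = rho, sigma = sigma, n = n), class = "rho_estimate")
}

#' @export
print.rho_estimate <- function(x, ...) {
  cat(sprintf("<rho_estimate: rho = %.4g, sigma = %.4g, n = %d>\n",
              x$rho, x$sigma, x$n))
  invisible(x)
}

#' Convert mutational divergence to an age in ky
#'
#' Multiplies a mutational divergence (rho or ML molecular divergence, in
#' expected mutations over the clock's region) and its uncertainty by the
#' clock's years-per-mutation, reporting thousands of years.
#'
#' @param divergence Mutational divergence (>= 0).
#' @param uncertainty Its standard error (sigma or ML SE; >= 0).
#' @param clock A [clock_model()].
#' @param source `"rho"` or `"ml"`, recorded on the estimate.
#' @return An object of class `age_estimate`: list with `source`, `T_ky`,
#'   `dT_ky` and the input `divergence`/`uncertainty`. Values are exact;
#'   report formatting rounds to 2 decimals (see [age_table()]).
#' @export
to_age <- function(divergence, uncertainty = 0, clock = clock_model(),
                   source = c("rho", "ml")) {
  source <- match.arg(source)
  if (divergence < 0 || uncertainty < 0) {
    stop("divergence and uncertainty must be non-negative")
  }
  structure(list(source = source,
                 T_ky = divergence * clock$years_per_mutation / 1000,
                 dT_ky = uncertainty * clock$years_per_mutation / 1000,
                 divergence = divergence, uncertainty = uncertainty),
            class = "age_estimate")
}

#' @export
print.age_estimate <- function(x, ...) {
  cat(sprintf("<age_estimate (%s): T = %.2f ky, dT = %.2f ky>\n",
              x$source, round(x$T_ky, 2), round(x$dT_ky, 2)))
  invisible(x)
}

#' HKY85 substitution model with discrete-gamma rate heterogeneity
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param base_freqs Equilibrium base frequencies in A, C, G, T order
#'   (positive; normalized to sum to 1).
#' @param alpha Gamma shape for among-site rate variation (> 0).
#' @param n_categories Number of equal-probability discrete rate categories.
#' @return An object of class `hky85_model`.
#' @export
hky85_model <- function(kappa = 2, base_freqs = rep(0.25, 4), alpha = 1,
                        n_categories = 32L) {
  if (kappa <= 0 || alpha <= 0) stop("kappa and alpha must be positive")
  if (length(base_freqs) != 4L || any(base_freqs <= 0)) {
    stop("base_freqs must be 4 positive numbers (A, C, G, T)")
  }
  base_freqs <- base_freqs / sum(base_freqs)
  names(base_freqs) <- c("A", "C", "G", "T")
  n_categories <- as.integer(n_categories)
  if (n_categories < 1L) stop("n_categories must be >= 1")
  structure(list(kappa = kappa, base_freqs = base_freqs, alpha = alpha,
                 n_categories = n_categories),
            class = "hky85_model")
}

#' @export
print.hky85_model <- function(x, ...) {
  cat(sprintf(
    "<hky85_model: kappa = %.3g, pi = (%.3f %.3f %.3f %.3f), alpha = %.3g, %d rate categories>\n",
    x$kappa, x$base_freqs[1], x$base_freqs[2], x$base_freqs[3],
    x$base_freqs[4], x$alpha, x$n_categories))
  invisible(x)
}

# instantaneous rate matrix, scaled to one expected substitution per site
# per unit time at equilibrium (A, C, G, T order)
hky85_rate_matrix <- function(model) {
  pi <- model$base_freqs
  k <- model$kappa
  is_transition <- matrix(FALSE, 4, 4, dimnames = list(names(pi), names(pi)))
  is_transition["A", "G"] <- is_transition["G", "A"] <- TRUE
  is_transition["C", "T"] <- is_transition["T", "C"] <- TRUE
  Q <- matrix(rep(pi, each = 4), 4, 4, dimnames = dimnames(is_transition))
  Q[is_transition] <- Q[is_transition] * k
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q / mu
}

# eigen-decomposition of the (reversible) HKY generator via its symmetric
# similarity transform, for stable transition probabilities at any t
hky85_eigen <- function(model) {
  Q <- hky85_rate_matrix(model)
  pi <- model$base_freqs
  D <- sqrt(pi)
  S <- outer(D, 1 / D) * Q          # D Q D^-1, symmetric for reversible Q
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  list(values = e$values,
       right = (1 / D) * e$vectors,       # D^-1 U
       left = t(D * e$vectors))           # U^T D
}

#' HKY85 transition probability matrix
#'
#' P(t) = exp(Qt) for the HKY85 generator scaled to one expected substitution
#' per site per unit branch length. Rows (ancestral base) sum to one; t = 0
#' gives the identity; as t grows rows converge to the equilibrium base
#' frequencies; detailed balance pi_i P_ij(t) = pi_j P_ji(t) holds.
#'
#' @param model An [hky85_model()].
#' @param t Branch length in expected substitutions per site (>= 0).
#' @return 4x4 probability matrix in A, C, G, T order.
#' @export
hky85_transition_matrix <- function(model, t) {
  if (t < 0) stop("branch length must be non-negative")
  eig <- hky85_eigen(model)
  P <- eig$right %*% (exp(eig$values * t) * eig$left)
  dimnames(P) <- list(names(model$base_freqs), names(model$base_freqs))
  # clip tiny negative round-off
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Discrete-gamma rate categories
#'
#' Equal-probability discretization of a Gamma(alpha, alpha) distribution
#' (mean 1): category k's rate is the mean of the distribution between the
#' (k-1)/K and k/K quantiles, so the K rates average to 1.
#'
#' @param alpha Gamma shape (> 0).
#' @param k Number of categories (>= 1).
#' @return Numeric vector of k rates.
#' @export
discretize_gamma <- function(alpha, k = 32L) {
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be positive")
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k == 1L) return(1)
  q <- qgamma(seq(0, 1, length.out = k + 1L), shape = alpha, rate = alpha)
  rates <- k * diff(pgamma(q, shape = alpha + 1, rate = alpha))
  rates / mean(rates)  # analytically mean 1; guard floating-point drift
}

# --- pruning likelihood -----------------------------------------------------

BASE4 <- c(A = 1L, C = 2L, G = 3L, T = 4L)

# alignment (named character vector of equal-length sequences) -> integer
# matrix of site patterns (tips x patterns) plus weights; columns containing
# anything but A/C/G/T are dropped
compress_patterns <- function(seqs) {
  mat <- do.call(rbind, strsplit(toupper(unname(seqs)), "", fixed = TRUE))
  rownames(mat) <- names(seqs)
  ok <- colSums(matrix(mat %in% names(BASE4), nrow(mat))) == nrow(mat)
  mat <- mat[, ok, drop = FALSE]
  if (ncol(mat) == 0L) stop("no usable alignment columns (A/C/G/T only)")
  key <- apply(mat, 2L, paste, collapse = "")
  tab <- table(key)
  pats <- do.call(cbind, strsplit(names(tab), "", fixed = TRUE))
  m <- matrix(BASE4[pats], nrow = nrow(mat),
              dimnames = list(rownames(mat), NULL))
  list(patterns = m, weights = as.numeric(tab), n_sites = ncol(mat))
}

# postorder node sequence (children before parents)
postorder_nodes <- function(parent) {
  depth <- integer(length(parent))
  for (i in seq_along(parent)) {
    j <- i
    while (!is.na(parent[j])) { j <- parent[j]; depth[i] <- depth[i] + 1L }
  }
  order(depth, decreasing = TRUE)
}

# conditional likelihoods by Felsenstein pruning for one set of per-node
# branch lengths; returns per-pattern site likelihoods
prune_site_likelihoods <- function(patterns, topology, lengths, model,
                                   eig = hky85_eigen(model)) {
  parent <- topology$parent
  label <- topology$label
  n <- length(parent)
  npat <- ncol(patterns)
  tipmap <- match(label, rownames(patterns))
  partial <- vector("list", n)
  Pmat <- function(t) {
    P <- eig$right %*% (exp(eig$values * t) * eig$left)
    P[P < 0] <- 0
    P
  }
  for (v in postorder_nodes(parent)) {
    if (!is.na(tipmap[v]) && !(v %in% parent)) {
      L <- matrix(0, 4, npat)
      L[cbind(patterns[tipmap[v], ], seq_len(npat))] <- 1
    } else {
      kids <- which(!is.na(parent) & parent == v)
      L <- matrix(1, 4, npat)
      for (c_ in kids) {
        L <- L * (Pmat(lengths[c_]) %*% partial[[c_]])
      }
    }
    partial[[v]] <- L
  }
  root <- which(is.na(parent))
  as.numeric(model$base_freqs %*% partial[[root]])
}

#' Log-likelihood of an alignment by the pruning algorithm
#'
#' Felsenstein's pruning algorithm under HKY85 with discrete-gamma rate
#' mixing: per-site likelihoods are averaged over the model's
#' equal-probability rate categories, with every branch length multiplied by
#' the category rate.
#'
#' @param seqs Named character vector of equal-length aligned sequences
#'   (columns with non-ACGT characters are dropped).
#' @param topology List with `parent` (integer, `NA` at the single root) and
#'   `label` (tip labels matching `names(seqs)`); a [mutation_tree()] is also
#'   accepted.
#' @param lengths Per-node branch lengths (expected substitutions per site on
#'   the branch above each node; ignored at the root).
#' @param model An [hky85_model()].
#' @return Log-likelihood (numeric scalar).
#' @export
pruning_loglik <- function(seqs, topology, lengths, model = hky85_model()) {
  if (inherits(topology, "mutation_tree")) {
    topology <- list(parent = topology$parent, label = topology$label)
  }
  cp <- compress_patterns(seqs)
  eig <- hky85_eigen(model)
  rates <- discretize_gamma(model$alpha, model$n_categories)
  site <- matrix(0, length(rates), ncol(cp$patterns))
  for (k in seq_along(rates)) {
    site[k, ] <- prune_site_likelihoods(cp$patterns, topology,
                                        lengths * rates[k], model, eig)
  }
  sum(cp$weights * log(colMeans(site)))
}

# drop internal nodes with no sampled tips below and contract unary internal
# nodes, keeping a valid rooted topology over the given tips
simplify_topology <- function(parent, label, tips) {
  n <- length(parent)
  keep_tip <- label %in% tips & !(seq_len(n) %in% parent)
  has_tip <- keep_tip
  for (v in postorder_nodes(parent)) {
    p <- parent[v]
    if (!is.na(p) && has_tip[v]) has_tip[p] <- TRUE
  }
  parent[!has_tip] <- NA_integer_  # detach, will be dropped
  keep <- has_tip
  # contract unary internals (single surviving child, not a tip)
  repeat {
    kids <- table(factor(parent[keep & !is.na(parent)],
                         levels = as.character(seq_len(n))))
    unary <- which(keep & !keep_tip & kids[as.character(seq_len(n))] == 1L)
    unary <- unary[!is.na(unary)]
    root <- which(keep & is.na(parent))
    unary <- setdiff(unary, integer(0))
    if (length(unary) == 0L) break
    v <- unary[1L]
    child <- which(keep & !is.na(parent) & parent == v)
    if (is.na(parent[v])) {            # unary root: child becomes root
      parent[child] <- NA_integer_
    } else {
      parent[child] <- parent[v]
    }
    keep[v] <- FALSE
  }
  idx <- which(keep)
  remap <- match(seq_len(n), idx)
  list(parent = remap[parent[idx]], label = label[idx],
       is_tip = keep_tip[idx])
}

#' Clock-constrained maximum likelihood molecular divergence of a clade
#'
#' Fits, by maximum likelihood under HKY85 with discrete-gamma rates
#' (pruning algorithm), an ultrametric (clock-constrained: equal root-to-tip
#' height) rooted tree on the clade's aligned sequences, optimizing the root
#' height, the relative heights of internal nodes, and optionally kappa and
#' alpha. The reported molecular divergence is the fitted per-site root
#' height scaled by the clock region length (np 364-15791 by default), i.e.
#' the expected number of mutations from the clade root to a tip over the
#' region -- directly comparable to rho and convertible to years with
#' [to_age()]. The standard error comes from the curvature (observed
#' information) of the log-likelihood at the optimum.
#'
#' @param seqs Named character vector of >= 2 equal-length aligned sequences
#'   in full mitogenome coordinates (restricted internally to `region`), or
#'   an already-restricted alignment shorter than `region`.
#' @param topology Rooted topology for the clade: `NULL` for a star tree, a
#'   [mutation_tree()] (tips matched to `names(seqs)`; unrelated backbone
#'   nodes are pruned away), or a list with `parent` and `label`.
#' @param model An [hky85_model()]; `kappa` and `alpha` are used as starting
#'   values when optimized.
#' @param region The [region()] to restrict to and to scale divergence by.
#' @param base_freqs `"empirical"` (default) to estimate equilibrium
#'   frequencies from the alignment, or a numeric 4-vector.
#' @param optimize_kappa,optimize_alpha Optimize these, or hold them at the
#'   model's values?
#' @param clock Must be `TRUE`; the estimator is defined under the clock
#'   constraint.
#' @return An object of class `ml_divergence`: list with `divergence`, `se`,
#'   `height` (per-site), `height_se`, `kappa`, `alpha`, `logLik`,
#'   `convergence` (0 = converged), `n_sites`, `n_patterns`.
#' @export
ml_divergence <- function(seqs, topology = NULL, model = hky85_model(),
                          region = coding_region(),
                          base_freqs = "empirical",
                          optimize_kappa = TRUE, optimize_alpha = TRUE,
                          clock = TRUE) {
  if (!isTRUE(clock)) stop("only the clock-constrained estimator is provided")
  if (length(seqs) < 2L) stop("need at least two sequences")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  len <- unique(nchar(seqs))
  if (length(len) != 1L) stop("sequences must be aligned (equal length)")
  if (len >= region$end) {
    seqs <- vapply(seqs, substr, "", region$start, region$end)
  }
  cp <- compress_patterns(seqs)
  L_region <- region_length(region)

  if (identical(base_freqs, "empirical")) {
    # frequency of each base weighted by pattern multiplicity
    counts <- sapply(1:4, function(b) {
      sum(cp$weights * colSums(cp$patterns == b))
    })
    bf <- pmax(counts, 1) / sum(pmax(counts, 1))
  } else {
    bf <- base_freqs / sum(base_freqs)
  }
  model <- hky85_model(model$kappa, bf, model$alpha, model$n_categories)

  topo <- if (is.null(topology)) {
    list(parent = c(NA_integer_, rep(1L, length(seqs))),
         label = c("root", names(seqs)),
         is_tip = c(FALSE, rep(TRUE, length(seqs))))
  } else {
    if (inherits(topology, "mutation_tree")) {
      topology <- list(parent = topology$parent, label = topology$label)
    }
    missing_tips <- setdiff(names(seqs), topology$label)
    if (length(missing_tips) > 0L) {
      stop("topology lacks tips: ", paste(missing_tips, collapse = ", "))
    }
    simplify_topology(topology$parent, topology$label, names(seqs))
  }

  # identical sequences: the height MLE is 0 (boundary); report it directly
  if (ncol(cp$patterns) == sum(apply(cp$patterns, 2, function(x) {
        length(unique(x)) == 1L
      }))) {
    return(structure(list(divergence = 0, se = 0, height = 0, height_se = 0,
                          kappa = model$kappa, alpha = model$alpha,
                          logLik = pruning_loglik(seqs, topo,
                                                  rep(0, length(topo$parent)),
                                                  model),
                          convergence = 0L, n_sites = cp$n_sites,
                          n_patterns = ncol(cp$patterns)),
                     class = "ml_divergence"))
  }

  internal <- which(!topo$is_tip)
  root <- which(is.na(topo$parent))
  free_internal <- setdiff(internal, root)
  # preorder over internals so parent heights are set before children
  pre <- rev(postorder_nodes(topo$parent))
  free_internal <- free_internal[order(match(free_internal, pre))]

  eig_cache <- new.env()
  get_eig <- function(kappa) {
    key <- sprintf("%.12g", kappa)
    if (is.null(eig_cache[[key]])) {
      eig_cache[[key]] <- hky85_eigen(
        hky85_model(kappa, model$base_freqs, model$alpha, model$n_categories))
    }
    eig_cache[[key]]
  }

  unpack <- function(theta) {
    i <- 1L
    h_root <- exp(theta[i]); i <- i + 1L
    heights <- numeric(length(topo$parent))
    heights[root] <- h_root
    for (v in free_internal) {
      heights[v] <- heights[topo$parent[v]] * stats::plogis(theta[i])
      i <- i + 1L
    }
    kappa <- if (optimize_kappa) exp(theta[i]) else model$kappa
    if (optimize_kappa) i <- i + 1L
    alpha <- if (optimize_alpha) exp(theta[i]) else model$alpha
    list(heights = heights, kappa = kappa, alpha = alpha)
  }

  negll <- function(theta) {
    par <- unpack(theta)
    lengths <- ifelse(is.na(topo$parent), 0,
                      par$heights[topo$parent] - par$heights)
    lengths <- pmax(lengths, 0)
    m <- hky85_model(par$kappa, model$base_freqs, par$alpha,
                     model$n_categories)
    rates <- discretize_gamma(par$alpha, model$n_categories)
    site <- matrix(0, length(rates), ncol(cp$patterns))
    eig <- if (optimize_kappa) hky85_eigen(m) else get_eig(par$kappa)
    for (k in seq_along(rates)) {
      site[k, ] <- prune_site_likelihoods(cp$patterns, topo,
                                          lengths * rates[k], m, eig)
    }
    lik <- colMeans(site)
    if (any(lik <= 0)) return(1e10)
    -sum(cp$weights * log(lik))
  }

  # starting height: half the mean pairwise mismatch fraction
  pm <- 0
  npair <- 0L
  for (i in seq_len(nrow(cp$patterns) - 1L)) {
    for (j in (i + 1L):nrow(cp$patterns)) {
      pm <- pm + sum(cp$weights * (cp$patterns[i, ] != cp$patterns[j, ]))
      npair <- npair + 1L
    }
  }
  h0 <- max(pm / npair / cp$n_sites / 2, 1 / cp$n_sites)
  theta0 <- c(log(h0), rep(0, length(free_internal)))
  if (optimize_kappa) theta0 <- c(theta0, log(model$kappa))
  if (optimize_alpha) theta0 <- c(theta0, log(model$alpha))

  fit <- optim(theta0, negll, method = "L-BFGS-B",
               lower = c(log(1e-9), rep(-12, length(free_internal)),
                         if (optimize_kappa) log(1e-3),
                         if (optimize_alpha) log(5e-3)),
               upper = c(log(10), rep(12, length(free_internal)),
                         if (optimize_kappa) log(1e3),
                         if (optimize_alpha) log(50)),
               control = list(factr = 1e7, maxit = 500))
  if (fit$convergence != 0L) {
    warning("ML optimizer did not converge (code ", fit$convergence, "): ",
            fit$message)
  }
  par <- unpack(fit$par)
  h <- par$heights[root]

  height_se <- NA_real_
  H <- tryCatch(optimHess(fit$par, negll), error = function(e) NULL)
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V) && is.finite(V[1L, 1L]) && V[1L, 1L] > 0) {
      height_se <- h * sqrt(V[1L, 1L])  # delta method for h = exp(theta_1)
    }
  }
  structure(list(divergence = h * L_region,
                 se = height_se * L_region,
                 height = h, height_se = height_se,
                 kappa = par$kappa, alpha = par$alpha,
                 logLik = -fit$value, convergence = fit$convergence,
                 n_sites = cp$n_sites, n_patterns = ncol(cp$patterns)),
            class = "ml_divergence")
}

#' @export
print.ml_divergence <- function(x, ...) {
  cat(sprintf(
    "<ml_divergence: %.3f mutations (se %.3f); kappa = %.3g, alpha = %.3g, logLik = %.2f>\n",
    x$divergence, x$se, x$kappa, x$alpha, x$logLik))
  invisible(x)
}

#' Age table for a set of clades
#'
#' Assembles the standard divergence-and-age report: one row per clade with
#' the ML molecular divergence and its SE, the rho statistic and sigma, and
#' each converted to ky with the clock. Values are rounded half-even to two
#' decimals for reporting; pass the raw estimates if exact values are
#' needed downstream.
#'
#' @param clades Named list; each element a list with `n` (sample count) and
#'   either or both of `rho` (a `rho_estimate` or numeric `c(rho, sigma)`)
#'   and `ml` (an `ml_divergence` or numeric `c(divergence, se)`).
#' @param clock A [clock_model()].
#' @return data.frame with columns `haplogroup`, `N`, `ML`, `SE`, `T_ml`,
#'   `dT_ml`, `rho`, `sigma`, `T_rho`, `dT_rho`.
#' @export
age_table <- function(clades, clock = clock_model()) {
  cols <- c("haplogroup", "N", "ML", "SE", "T_ml", "dT_ml",
            "rho", "sigma", "T_rho", "dT_rho")
  if (length(clades) == 0L) {
    out <- as.data.frame(setNames(
      c(list(character(0)), rep(list(numeric(0)), 9L)), cols))
    return(out)
  }
  rows <- lapply(names(clades), function(nm) {
    cl <- clades[[nm]]
    ml <- cl$ml
    if (inherits(ml, "ml_divergence")) ml <- c(ml$divergence, ml$se)
    rho <- cl$rho
    if (inherits(rho, "rho_estimate")) rho <- c(rho$rho, rho$sigma)
    n <- if (is.null(cl$n)) NA_integer_ else cl$n
    r2 <- function(x) round(x, 2)
    if (is.null(ml)) ml <- c(NA_real_, NA_real_)
    if (is.null(rho)) rho <- c(NA_real_, NA_real_)
    aml <- if (all(is.finite(ml))) to_age(ml[1], ml[2], clock, "ml") else NULL
    arh <- if (all(is.finite(rho))) to_age(rho[1], rho[2], clock, "rho") else NULL
    data.frame(haplogroup = nm, N = n,
               ML = r2(ml[1]), SE = r2(ml[2]),
               T_ml = if (is.null(aml)) NA_real_ else r2(aml$T_ky),
               dT_ml = if (is.null(aml)) NA_real_ else r2(aml$dT_ky),
               rho = r2(rho[1]), sigma = r2(rho[2]),
               T_rho = if (is.null(arh)) NA_real_ else r2(arh$T_ky),
               dT_rho = if (is.null(arh)) NA_real_ else r2(arh$dT_ky),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
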