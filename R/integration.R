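## Transcript-guided condition-specific model extraction and comparison.

#' Prune a model to a condition using transcript abundances
#'
#' Transcript-guided extraction: per-reaction abundances are obtained by
#' propagating gene TPM through the GPRs (AND = min, OR = sum),
#' log-transformed (transcript abundance spans orders of magnitude, and a
#' linear rescaling would let a handful of highly expressed genes compress
#' the contrast between suppressed and ordinary pathways), rescaled to
#' \[0, 1\] over the assessed reactions, and converted to pruning costs
#' `cost = eps + (1 - eps) * (1 - scaled)` (eps = 0.01 keeps every carried
#' flux weakly penalized so unused reactions drop out); reactions without a
#' GPR get the median cost. A cost-weighted absolute-flux minimization LP is
#' solved subject to retaining at least `objective_fraction` of the FBA
#' optimum, and reactions with |flux| below 1e-9 are pruned. The pruned
#' model is feasible at the stated fraction by construction.
#'
#' @param model A [MetabolicModel-class] with an objective, feasible under
#'   its current constraints.
#' @param tpm Named numeric vector of transcript abundances (gene -> TPM).
#' @param objective_fraction Minimum retained fraction of the parent
#'   optimum (default 0.9).
#' @param condition Condition label for the report.
#' @return List with `model` (pruned) and `report`: condition,
#'   `kept_reactions`, `pruned_reactions`, `objective_retained_fraction`,
#'   and `correlation_p` (Spearman rank association between |flux| and
#'   reaction abundance over kept, assessed reactions).
#' @export
pruneToCondition <- function(model, tpm, objective_fraction = 0.9,
                             condition = "condition") {
  stopifnot(objective_fraction > 0, objective_fraction <= 1)
  parent <- fba(model)
  if (parent@status != "optimal") {
    stop("model is ", parent@status,
         "; cannot extract a condition model (try a lower fraction)")
  }
  abund <- vapply(model@gprs, reactionAbundance, numeric(1), tpm = tpm)
  assessed <- !is.na(abund)
  scaled <- rep(NA_real_, length(abund))
  if (any(assessed)) {
    la <- log1p(abund[assessed])
    rng <- range(la)
    scaled[assessed] <- if (diff(rng) > 0) {
      (la - rng[1]) / diff(rng)
    } else {
      rep(0.5, sum(assessed))
    }
  }
  eps <- 0.01
  cost <- eps + (1 - eps) * (1 - scaled)
  cost[!assessed] <- if (any(assessed)) stats::median(cost[assessed]) else 1

  obj <- objectiveVector(model)
  sol <- solveWeightedAbsFluxLP(
    cost = cost, S = model@stoichiometry,
    lb = model@reactions$lower_bound, ub = model@reactions$upper_bound,
    ineq = list(A = matrix(obj, 1),
                rhs = objective_fraction * parent@objective_value))
  if (sol$status != "optimal") {
    stop("extraction LP is ", sol$status,
         "; try a lower objective_fraction")
  }
  keep <- abs(sol$v) > 1e-9
  # never prune the objective or fixed-flux reactions
  keep <- keep | obj != 0 |
    model@reactions$lower_bound == model@reactions$upper_bound
  kept_ids <- model@reactions$id[keep]
  pruned_ids <- model@reactions$id[!keep]
  pruned <- subModel(model, kept_ids)

  child <- fba(pruned)
  retained <- child@objective_value / parent@objective_value

  kept_assessed <- keep & assessed
  correlation_p <- NA_real_
  if (sum(kept_assessed) >= 4) {
    ct <- suppressWarnings(stats::cor.test(
      abs(sol$v[kept_assessed]), abund[kept_assessed],
      method = "spearman", exact = FALSE))
    correlation_p <- ct$p.value
  }
  list(model = pruned,
       report = list(condition = condition,
                     kept_reactions = kept_ids,
                     pruned_reactions = pruned_ids,
                     objective_retained_fraction = retained,
                     objective_fraction = objective_fraction,
                     correlation_p = correlation_p))
}

#' Flux-sample a condition-specific model
#'
#' Delegates to [fluxSample()] with the objective-fraction constraint kept
#' active, so every sampled flux vector retains at least
#' `objective_fraction` of the condition model's optimum (the parsimonious
#' sampling regime).
#'
#' @param model A pruned condition [MetabolicModel-class].
#' @param n Number of samples (default 50).
#' @param seed Integer seed.
#' @param objective_fraction Minimum retained objective fraction
#'   (default 0.9).
#' @param thinning Chain thinning (default 100).
#' @param condition Condition label.
#' @return A [FluxSampleSet-class].
#' @export
sampleCondition <- function(model, n = 50, seed = 1,
                            objective_fraction = 0.9, thinning = 100,
                            condition = "condition") {
  parent <- fba(model)
  if (parent@status != "optimal") stop("condition model is ", parent@status)
  obj <- objectiveVector(model)
  fluxSample(model, n = n, seed = seed, thinning = thinning,
             ineq = list(A = matrix(obj, 1),
                         rhs = objective_fraction * parent@objective_value),
             condition = condition)
}

#' Reactions shared by all sample sets
#'
#' @param sample_sets List of at least two [FluxSampleSet-class] objects.
#' @return Lexicographically ordered intersection of their reaction ids
#'   (empty, with a warning, when disjoint).
#' @export
sharedReactions <- function(sample_sets) {
  stopifnot(length(sample_sets) >= 2)
  shared <- Reduce(intersect, lapply(sample_sets, function(s) s@reaction_ids))
  if (!length(shared)) warning("no reactions shared across conditions")
  sort(shared)
}

#' Bray-Curtis distances between flux samples
#'
#' Fluxes are transformed to nonnegative activity (|v|), restricted to the
#' reactions shared by all sets, and pairwise Bray-Curtis distances
#' `sum|x - y| / sum(x + y)` computed over all samples of all sets (via
#' vegan). An all-zero pair of profiles has distance 0 (logged as a note).
#'
#' @param sample_sets List of [FluxSampleSet-class] objects.
#' @param shared Optional precomputed shared reaction vector.
#' @return Symmetric distance matrix with sample labels
#'   `<condition>.<row>`; values in \[0, 1\].
#' @export
brayCurtisMatrix <- function(sample_sets, shared = NULL) {
  if (is.null(shared)) shared <- sharedReactions(sample_sets)
  if (!length(shared)) stop("no shared reactions to compare")
  act <- do.call(rbind, lapply(sample_sets, function(s) {
    m <- abs(s@samples[, shared, drop = FALSE])
    rownames(m) <- paste0(s@condition, ".", seq_len(nrow(m)))
    m
  }))
  # all-zero rows produce NaN in vegdist (with a warning); handled below
  d <- as.matrix(suppressWarnings(vegan::vegdist(act, method = "bray")))
  if (any(!is.finite(d))) {
    message("all-zero sample pairs present; their distance is set to 0")
    d[!is.finite(d)] <- 0
  }
  d
}

#' Two-dimensional NMDS ordination
#'
#' Non-metric multidimensional scaling (monotone-regression stress
#' minimization, via vegan's engine) to two dimensions with seeded random
#' restarts; the configuration with the lowest stress is returned.
#'
#' @param distances Symmetric distance matrix (>= 3 points).
#' @param seed Integer seed.
#' @param n_restarts Number of random restarts (default 4; the classical
#'   metric solution is always included as a start).
#' @return List with `coordinates` (n x 2 matrix) and `stress`.
#' @export
ordinate2d <- function(distances, seed = 1, n_restarts = 4) {
  distances <- as.matrix(distances)
  if (nrow(distances) < 3) stop("ordination needs at least 3 points")
  if (max(distances) < 1e-12) {
    # all points coincide; the trivial embedding is exact
    coords <- matrix(0, nrow(distances), 2,
                     dimnames = list(rownames(distances),
                                     c("NMDS1", "NMDS2")))
    return(list(coordinates = coords, stress = 0))
  }
  d <- stats::as.dist(distances)
  # classical metric solution as the anchored first start; when the
  # dissimilarities are heavily tied the rank-based fit has nothing to
  # improve and keeps this metric configuration
  init0 <- suppressWarnings(stats::cmdscale(d, k = 2))
  if (ncol(init0) < 2) {
    init0 <- cbind(init0, matrix(0, nrow(init0), 2 - ncol(init0)))
  }
  best <- withr::with_seed(seed, {
    fits <- c(list(vegan::monoMDS(d, y = init0, k = 2, model = "global")),
              lapply(seq_len(n_restarts), function(i) {
                init <- matrix(stats::rnorm(nrow(distances) * 2),
                               ncol = 2)
                vegan::monoMDS(d, y = init, k = 2, model = "global")
              }))
    fits[[which.min(vapply(fits, function(f) f$stress, numeric(1)))]]
  })
  coords <- best$points
  rownames(coords) <- rownames(distances)
  colnames(coords) <- c("NMDS1", "NMDS2")
  list(coordinates = coords, stress = best$stress)
}

#' Rank reactions that distinguish conditions
#'
#' Ensemble-of-randomized-trees (random forest) permutation importance for
#' classifying samples by condition from their |flux| profiles over the
#' shared reactions; deterministic given the seed. A model-free fallback
#' (`method = "smd"`) ranks by the maximum absolute standardized mean
#' difference between condition pairs and is expected to agree on the top
#' feature for a cleanly separated reaction. Optional label-permutation
#' null importances give a per-reaction 95th-percentile reference.
#'
#' @param sample_sets List of labeled [FluxSampleSet-class] objects
#'   (>= 2 distinct conditions, each with >= 5 samples).
#' @param seed Integer seed.
#' @param method `"forest"` (default) or `"smd"`.
#' @param num_trees Trees in the forest (default 500).
#' @param n_null Number of label permutations for the null importance
#'   reference (default 0 = skip).
#' @return List with `ranking` (`data.frame`: reaction, importance; sorted
#'   decreasing), `method`, `seed`, and (when `n_null > 0`) `null_q95`, the
#'   per-reaction 95th percentile of null importances, plus
#'   `null_max_q95`, the 95th percentile of the maximum null importance
#'   across reactions (the familywise reference: under identical
#'   distributions the top observed importance should not exceed it).
#' @export
rankDistinguishingReactions <- function(sample_sets, seed = 1,
                                        method = c("forest", "smd"),
                                        num_trees = 500, n_null = 0) {
  method <- match.arg(method)
  labels <- vapply(sample_sets, function(s) s@condition, character(1))
  if (length(unique(labels)) < 2) {
    stop("need at least two distinct condition labels")
  }
  if (any(vapply(sample_sets, function(s) nrow(s@samples), integer(1)) < 5)) {
    stop("each condition needs at least 5 samples")
  }
  shared <- sharedReactions(sample_sets)
  X <- do.call(rbind, lapply(sample_sets,
                             function(s) abs(s@samples[, shared, drop = FALSE])))
  y <- factor(rep(labels, vapply(sample_sets, function(s) nrow(s@samples),
                                 integer(1))))

  imp <- computeImportance(X, y, method, num_trees, seed)
  ranking <- data.frame(reaction = names(imp), importance = unname(imp))
  ranking <- ranking[order(-ranking$importance, ranking$reaction), ]
  rownames(ranking) <- NULL
  out <- list(ranking = ranking, method = method, seed = as.integer(seed))

  if (n_null > 0) {
    nulls <- withr::with_seed(seed + 1L, {
      vapply(seq_len(n_null), function(i) {
        computeImportance(X, sample(y), method, num_trees, seed + 1L + i)
      }, numeric(ncol(X)))
    })
    out$null_q95 <- apply(nulls, 1, stats::quantile, probs = 0.95,
                          names = FALSE)
    names(out$null_q95) <- colnames(X)
    out$null_max_q95 <- stats::quantile(apply(nulls, 2, max), probs = 0.95,
                                        names = FALSE)
  }
  out
}

computeImportance <- function(X, y, method, num_trees, seed) {
  if (method == "forest") {
    df <- data.frame(X, check.names = FALSE)
    fit <- ranger::ranger(x = df, y = y, num.trees = num_trees,
                          importance = "permutation", seed = seed,
                          num.threads = 1)
    imp <- fit$variable.importance
  } else {
    lv <- levels(y)
    pairs <- utils::combn(lv, 2, simplify = FALSE)
    imp <- apply(X, 2, function(col) {
      max(vapply(pairs, function(p) {
        a <- col[y == p[1]]
        b <- col[y == p[2]]
        s <- sqrt((stats::var(a) + stats::var(b)) / 2)
        if (s < 1e-12) {
          if (abs(mean(a) - mean(b)) < 1e-12) 0 else Inf
        } else {
          abs(mean(a) - mean(b)) / s
        }
      }, numeric(1)))
    })
  }
  imp[colnames(X)]
}
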