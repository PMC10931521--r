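# Shared fixtures and independent oracles, built in code.

# Linear chain: EX_A (uptake) -> T_A -> A->B -> B->ATP -> DM_atp
# (objective). Five reactions, two of them boundary (one exchange, one
# demand).
chainModel <- function(uptake_lb = -10) {
  metabolicModel(
    id = "chain",
    metabolites = data.frame(
      id = c("A_e", "A_c", "B_c", "atp_c"),
      compartment = c("e", "c", "c", "c")),
    reactions = data.frame(
      id = c("EX_A_e", "T_A", "R_AB", "R_BATP", "DM_atp"),
      lower_bound = c(uptake_lb, 0, 0, 0, 0),
      upper_bound = rep(1000, 5),
      gpr = c("", "g_t", "g_ab1 and g_ab2", "g_batp", "")),
    stoichiometry = list(
      EX_A_e = c(A_e = -1),
      T_A = c(A_e = -1, A_c = 1),
      R_AB = c(A_c = -1, B_c = 1),
      R_BATP = c(B_c = -1, atp_c = 1),
      DM_atp = c(atp_c = -1)),
    objective = c(DM_atp = 1),
    compartments = c(c = "cytosol", e = "extracellular"),
    extracellular = "e")
}

# Two parallel routes A -> B: direct (1 reaction) vs via intermediate
# (2 reactions). Used for parsimony tests.
parallelModel <- function() {
  metabolicModel(
    id = "parallel",
    metabolites = data.frame(
      id = c("A_e", "A_c", "X_c", "B_c"),
      compartment = c("e", "c", "c", "c")),
    reactions = data.frame(
      id = c("EX_A_e", "T_A", "R_direct", "R_via1", "R_via2", "DM_B"),
      lower_bound = c(-10, 0, 0, 0, 0, 0),
      upper_bound = rep(1000, 6),
      gpr = c("", "g_t", "g_d", "g_v1", "g_v2", "")),
    stoichiometry = list(
      EX_A_e = c(A_e = -1),
      T_A = c(A_e = -1, A_c = 1),
      R_direct = c(A_c = -1, B_c = 1),
      R_via1 = c(A_c = -1, X_c = 1),
      R_via2 = c(X_c = -1, B_c = 1),
      DM_B = c(B_c = -1)),
    objective = c(DM_B = 1),
    compartments = c(c = "cytosol", e = "extracellular"),
    extracellular = "e")
}

# --- independent GPR oracle ----------------------------------------------
# Recursively gathers child values and applies the stated selection rule
# directly: AND keeps the minimum-|.| candidate, OR the maximum-|.|
# candidate; ties resolve to the first positive candidate in child order,
# else the leftmost.
oracleReactionWeight <- function(expr, weights) {
  if (expr$kind == "gene") {
    v <- weights[expr$gene]
    return(if (is.na(v)) 0 else unname(v))
  }
  vals <- vapply(expr$children, oracleReactionWeight, numeric(1),
                 weights = weights)
  target <- if (expr$kind == "and") min(abs(vals)) else max(abs(vals))
  cand <- which(abs(vals) == target)
  pos <- cand[vals[cand] > 0]
  if (length(pos)) vals[pos[1]] else vals[cand[1]]
}

randomGPRTree <- function(genes, max_leaves = 6) {
  n_leaves <- sample(seq_len(max_leaves), 1)
  leaves <- sample(genes, n_leaves, replace = TRUE)
  build <- function(ids) {
    if (length(ids) == 1) return(gprLeaf(ids))
    split <- sample(seq_len(length(ids) - 1), 1)
    kind <- sample(c("and", "or"), 1)
    gprNode(kind, list(build(ids[seq_len(split)]),
                       build(ids[-seq_len(split)])))
  }
  build(leaves)
}

# --- independent Mann-Whitney oracle -------------------------------------
# Enumerates all group assignments and computes U by direct pairwise
# comparison counts (not rank sums).
oracleMannWhitney <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  uOf <- function(xs, ys) {
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- uOf(x, y)
  combs <- utils::combn(length(pooled), nx)
  u_null <- apply(combs, 2, function(idx) uOf(pooled[idx], pooled[-idx]))
  eps <- 1e-9
  p <- min(1, 2 * min(mean(u_null <= u_obs + eps),
                      mean(u_null >= u_obs - eps)))
  list(U = u_obs, p = p)
}

# --- pFBA oracle: exhaustive vertex enumeration of the optimal face ------
# Minimum of sum|v| over the polytope {S v = 0, lb <= v <= ub,
# obj'v = opt} is attained at a vertex of the polytope intersected with
# sign orthants, i.e. a point where enough reactions sit at lb, ub or 0.
oraclePfbaMinTotalFlux <- function(model, opt) {
  S <- as.matrix(stoichMatrix(model))
  obj <- rep(0, ncol(S))
  names(obj) <- reactionIds(model)
  obj[names(objectiveCoefficients(model))] <- objectiveCoefficients(model)
  A <- rbind(S, obj)
  b <- c(rep(0, nrow(S)), opt)
  n <- ncol(S)
  rk <- qr(A)$rank
  n_fix <- n - rk
  lb <- model@reactions$lower_bound
  ub <- model@reactions$upper_bound
  if (n_fix <= 0) stop("fully determined; nothing to enumerate")
  best <- Inf
  subsets <- utils::combn(n, n_fix, simplify = FALSE)
  for (sub in subsets) {
    vals_opts <- expand.grid(rep(list(1:3), n_fix))
    for (r in seq_len(nrow(vals_opts))) {
      fixed <- vapply(seq_len(n_fix), function(j) {
        switch(vals_opts[r, j], lb[sub[j]], ub[sub[j]], 0)
      }, numeric(1))
      free <- setdiff(seq_len(n), sub)
      rhs <- b - A[, sub, drop = FALSE] %*% fixed
      sol <- tryCatch(qr.solve(A[, free, drop = FALSE], rhs, tol = 1e-10),
                      error = function(e) NULL)
      if (is.null(sol)) next
      if (max(abs(A[, free, drop = FALSE] %*% sol - rhs)) > 1e-7) next
      v <- numeric(n)
      v[sub] <- fixed
      v[free] <- sol
      if (any(v < lb - 1e-7 | v > ub + 1e-7)) next
      best <- min(best, sum(abs(v)))
    }
  }
  best
}

# Small abundance matrix with engineered structure for metabolomics tests.
toyAbundance <- function() {
  counts <- matrix(
    NA_real_, 4, 9,
    dimnames = list(c("m_keep", "m_border", "m_drop", "m_flat"),
                    paste0(rep(c("blank", "trt", "ctl"), each = 3), 1:3)))
  counts["m_keep", ] <- c(100, 110, 90, 10, 12, 9, 95, 105, 100)
  counts["m_border", ] <- c(50, NA, NA, NA, 60, NA, NA, 55, NA)  # 5/9 missing
  counts["m_drop", ] <- c(80, NA, NA, NA, NA, NA, NA, NA, 70)    # 7/9 missing
  counts["m_flat", ] <- rep(42, 9)
  abundanceExperiment(counts, rep(c("blank", "trt", "ctl"), each = 3),
                      blank_group = "blank")
}

# Two labeled sample sets over shared reactions with one planted
# flux-divergent reaction; all other reactions share one distribution.
plantedSampleSets <- function(seed, n = 25, n_rxn = 20) {
  withr::with_seed(seed, {
    rids <- sprintf("R%02d", seq_len(n_rxn))
    base <- matrix(abs(rnorm(2 * n * n_rxn, 5, 1)), 2 * n, n_rxn,
                   dimnames = list(NULL, rids))
    a <- base[seq_len(n), ]
    b <- base[n + seq_len(n), ]
    divergent <- "R07"
    a[, divergent] <- runif(n, 0, 1)     # disjoint ranges
    b[, divergent] <- runif(n, 8, 10)
    list(a = new("FluxSampleSet", condition = "condA", reaction_ids = rids,
                 samples = a, seed = as.integer(seed)),
         b = new("FluxSampleSet", condition = "condB", reaction_ids = rids,
                 samples = b, seed = as.integer(seed)),
         divergent = divergent)
  })
}

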