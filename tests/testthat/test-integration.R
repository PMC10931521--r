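toy <- makeToyModel()

tailoredToy <- function() {
  cc <- conditionConstraints(
    consumed_metabolites = c("glc_e", "o2_e", "rib_e", "nh4_e", "fa_e",
                             "pyr_e", "ura_e", "glyc_e"),
    objective_reaction = "R_ATPM",
    maintenance = c(DM_rna = 1, DM_dna = 1))
  applyConditionConstraints(toy$model, cc)
}

test_that("transcript suppression prunes the suppressed ATP route", {
  tl <- tailoredToy()
  tpm <- simulateTPM(toy$model, toy$pathways,
                     suppressed = c(treated = "oxphos", control = "fao"),
                     seed = 12)
  pt <- pruneToCondition(tl, tpm$treated, condition = "treated")
  pc <- pruneToCondition(tl, tpm$control, condition = "control")
  expect_true(all(c("R_PDH", "R_OXPHOS") %in% pt$report$pruned_reactions))
  expect_true("R_FAO" %in% pt$report$kept_reactions)
  expect_true(all(c("R_FACS", "R_FAO") %in% pc$report$pruned_reactions))
  expect_true("R_OXPHOS" %in% pc$report$kept_reactions)
  # pruned models stay feasible and retain >= 90% of the parent optimum
  for (pr in list(pt, pc)) {
    expect_gte(pr$report$objective_retained_fraction, 0.9 - 1e-6)
    expect_equal(fba(pr$model)@status, "optimal")
    expect_setequal(c(pr$report$kept_reactions, pr$report$pruned_reactions),
                    reactionIds(tl))
  }
})

test_that("uniform transcript abundance reduces pruning to parsimony", {
  tl <- tailoredToy()
  genes <- modelGenes(tl)
  tpm_uniform <- setNames(rep(100, length(genes)), genes)
  pr <- pruneToCondition(tl, tpm_uniform, condition = "uniform")
  sol <- pfba(tl, 0.9)
  pfba_support <- reactionIds(tl)[abs(sol@fluxes) > 1e-9 |
                                    tidescope:::objectiveVector(tl) != 0 |
                                    tl@reactions$lower_bound ==
                                      tl@reactions$upper_bound]
  # equal costs: kept set carries the same total flux budget as pFBA
  expect_equal(sort(pr$report$kept_reactions), sort(pfba_support))
})

test_that("infeasible extraction fractions fail with guidance", {
  tl <- tailoredToy()
  tl2 <- setReactionBounds(tl, "R_ATPM", 200, 200)  # beyond capacity
  genes <- modelGenes(tl2)
  expect_error(pruneToCondition(tl2, setNames(rep(1, length(genes)), genes)),
               "infeasible|lower fraction")
})

test_that("condition sampling keeps the objective-fraction constraint", {
  tl <- tailoredToy()
  tpm <- simulateTPM(toy$model, toy$pathways, seed = 2)
  pr <- pruneToCondition(tl, tpm$treated, condition = "treated")
  opt <- fba(pr$model)@objective_value
  ss <- sampleCondition(pr$model, n = 50, seed = 4, condition = "treated")
  expect_equal(nrow(sampleMatrix(ss)), 50)
  obj_flux <- sampleMatrix(ss)[, "R_ATPM"]
  expect_true(all(obj_flux >= 0.9 * opt - 1e-6))
  # steady state on every row
  resid <- abs(as.matrix(stoichMatrix(pr$model)) %*% t(sampleMatrix(ss)))
  expect_lt(max(resid), 1e-6)
  # bitwise reproducibility
  ss2 <- sampleCondition(pr$model, n = 50, seed = 4, condition = "treated")
  expect_identical(sampleMatrix(ss), sampleMatrix(ss2))
})

test_that("shared reactions are the ordered intersection", {
  mk <- function(cond, rids) {
    new("FluxSampleSet", condition = cond, reaction_ids = rids,
        samples = matrix(0, 2, length(rids), dimnames = list(NULL, rids)),
        seed = 1L)
  }
  expect_identical(
    sharedReactions(list(mk("x", c("A", "B", "C")), mk("y", c("B", "C", "D")),
                         mk("z", c("C", "B")))),
    c("B", "C"))
  expect_identical(sharedReactions(list(mk("x", c("A", "B")),
                                        mk("y", c("A", "B")))),
                   c("A", "B"))
  expect_warning(out <- sharedReactions(list(mk("x", "A"), mk("y", "B"))),
                 "no reactions shared")
  expect_length(out, 0)
})

test_that("Bray-Curtis distances match the closed form", {
  rids <- c("R1", "R2")
  mk <- function(cond, m) new("FluxSampleSet", condition = cond,
                              reaction_ids = rids,
                              samples = matrix(m, ncol = 2,
                                               dimnames = list(NULL, rids)),
                              seed = 1L)
  sets <- list(mk("a", rbind(c(1, 2), c(1, 2))),
               mk("b", rbind(c(3, 0), c(-1, -2))))
  d <- brayCurtisMatrix(sets)
  expect_equal(dim(d), c(4, 4))
  expect_true(all(diag(d) == 0))
  expect_equal(d, t(d))
  expect_true(all(d >= 0 & d <= 1))
  # x = (1,2), y = (3,0): (|1-3| + |2-0|) / (4 + 2) = 2/3
  expect_equal(d["a.1", "b.1"], 2 / 3)
  # identical profiles at distance 0; |.| makes signs irrelevant
  expect_equal(d["a.1", "a.2"], 0)
  expect_equal(d["a.1", "b.2"], 0)
})

test_that("all-zero profile pairs get distance zero with a note", {
  rids <- c("R1", "R2")
  mk <- function(cond, m) new("FluxSampleSet", condition = cond,
                              reaction_ids = rids,
                              samples = matrix(m, ncol = 2,
                                               dimnames = list(NULL, rids)),
                              seed = 1L)
  sets <- list(mk("a", rbind(c(0, 0), c(0, 0))),
               mk("b", rbind(c(1, 1), c(1, 1))))
  expect_message(d <- brayCurtisMatrix(sets), "all-zero")
  expect_equal(d["a.1", "a.2"], 0)
})

test_that("NMDS ordination honors simple geometric structure", {
  # three equidistant points embed as an equilateral triangle
  d3 <- matrix(1, 3, 3) - diag(3)
  dimnames(d3) <- list(letters[1:3], letters[1:3])
  ord <- ordinate2d(d3, seed = 2)
  emb <- as.matrix(dist(ord$coordinates))
  expect_lt(diff(range(emb[upper.tri(emb)])) / mean(emb[upper.tri(emb)]),
            0.05)

  # duplicated points stay coincident
  d4 <- as.matrix(dist(rbind(c(0, 0), c(0, 0), c(3, 0), c(0, 4))))
  ord4 <- ordinate2d(d4, seed = 3)
  expect_lt(sqrt(sum((ord4$coordinates[1, ] - ord4$coordinates[2, ])^2)),
            1e-6 + 0.05 * max(abs(ord4$coordinates)))

  expect_error(ordinate2d(matrix(0, 2, 2)), "at least 3")
})

test_that("more NMDS restarts never increase the reported stress", {
  sets <- plantedSampleSets(5)
  d <- brayCurtisMatrix(list(sets$a, sets$b))
  s1 <- ordinate2d(d, seed = 9, n_restarts = 1)$stress
  s8 <- ordinate2d(d, seed = 9, n_restarts = 8)$stress
  expect_lte(s8, s1 + 1e-12)
})

test_that("a planted divergent reaction ranks first by forest importance", {
  sets <- plantedSampleSets(11)
  rk <- rankDistinguishingReactions(list(sets$a, sets$b), seed = 1)
  expect_equal(rk$ranking$reaction[1], sets$divergent)
  expect_true(all(diff(rk$ranking$importance) <= 0))
  # the model-free fallback agrees on the top feature
  rk_smd <- rankDistinguishingReactions(list(sets$a, sets$b), seed = 1,
                                        method = "smd")
  expect_equal(rk_smd$ranking$reaction[1], sets$divergent)
  # seeded reproducibility of the full ranking
  rk2 <- rankDistinguishingReactions(list(sets$a, sets$b), seed = 1)
  expect_identical(rk$ranking, rk2$ranking)
})

test_that("identical distributions yield no importance above the null", {
  withr::with_seed(77, {
    rids <- sprintf("R%02d", 1:10)
    X <- matrix(abs(rnorm(800, 5, 1)), 80, 10,
                dimnames = list(NULL, rids))
    a <- new("FluxSampleSet", condition = "a", reaction_ids = rids,
             samples = X[1:40, ], seed = 77L)
    b <- new("FluxSampleSet", condition = "b", reaction_ids = rids,
             samples = X[41:80, ], seed = 77L)
    rk <- rankDistinguishingReactions(list(a, b), seed = 3, n_null = 20)
    # familywise check: the top importance stays within the null of the
    # maximum importance across reactions
    expect_lte(max(rk$ranking$importance), rk$null_max_q95 + 1e-9)
  })
})

test_that("ranking rejects degenerate designs", {
  sets <- plantedSampleSets(2)
  expect_error(rankDistinguishingReactions(list(sets$a), seed = 1),
               "two distinct")
  small <- sets$a
  small@samples <- small@samples[1:3, , drop = FALSE]
  expect_error(rankDistinguishingReactions(list(small, sets$b), seed = 1),
               "at least 5")
})
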