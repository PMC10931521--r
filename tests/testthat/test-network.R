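test_that("model validity catches structural errors", {
  expect_error(metabolicModel(
    "bad",
    metabolites = data.frame(id = "A_c", compartment = "c"),
    reactions = data.frame(id = "R1", lower_bound = 0, upper_bound = 1),
    stoichiometry = list(R1 = c(B_c = 1)),
    compartments = c(c = "cytosol", e = "extra"), extracellular = "e"),
    "undeclared metabolites")
  expect_error(metabolicModel(
    "bad",
    metabolites = data.frame(id = "A_c", compartment = "c"),
    reactions = data.frame(id = "R1", lower_bound = 5, upper_bound = 1),
    stoichiometry = list(R1 = c(A_c = 1)),
    compartments = c(c = "cytosol", e = "extra"), extracellular = "e"),
    "lower_bound > upper_bound")
})

test_that("exchange detection requires a single extracellular metabolite", {
  m <- chainModel()
  ex <- isExchange(m)
  expect_identical(ex, c(EX_A_e = TRUE, T_A = FALSE, R_AB = FALSE,
                         R_BATP = FALSE, DM_atp = FALSE))
})

test_that("FBA of a bounded chain hits the uptake limit", {
  m <- chainModel(uptake_lb = -10)
  sol <- fba(m)
  expect_equal(sol@status, "optimal")
  expect_equal(sol@objective_value, 10)
  # no uptake, no flux
  sol0 <- fba(chainModel(uptake_lb = 0))
  expect_equal(sol0@objective_value, 0)
})

test_that("parallel routes reach the same optimum as a single route", {
  m <- parallelModel()
  sol <- fba(m)
  expect_equal(sol@objective_value, 10)
  # dropping either route keeps the optimum (the other suffices)
  expect_equal(fba(removeReactions(m, "R_direct"))@objective_value, 10)
  expect_equal(fba(removeReactions(m, c("R_via1", "R_via2")))@objective_value, 10)
})

test_that("FBA solutions satisfy steady state and bounds", {
  for (m in list(chainModel(), parallelModel(), makeToyModel()$model)) {
    sol <- fba(m)
    v <- sol@fluxes
    expect_lt(max(abs(as.vector(stoichMatrix(m) %*% v))), 1e-6)
    expect_true(all(v >= m@reactions$lower_bound - 1e-9))
    expect_true(all(v <= m@reactions$upper_bound + 1e-9))
  }
})

test_that("unbounded and infeasible problems are reported distinctly", {
  m <- chainModel()
  m_unb <- setReactionBounds(m, reactionIds(m),
                             lower_bound = c(-Inf, 0, 0, 0, 0),
                             upper_bound = rep(Inf, 5))
  expect_equal(fba(m_unb)@status, "unbounded")
  # force impossible flux: demand fixed above achievable uptake
  m_inf <- setReactionBounds(chainModel(-1), "DM_atp", 5, 5)
  expect_equal(fba(m_inf)@status, "infeasible")
  expect_error(fba(metabolicModel(
    "noobj",
    metabolites = data.frame(id = "A_c", compartment = "c"),
    reactions = data.frame(id = "R1", lower_bound = 0, upper_bound = 1),
    stoichiometry = list(R1 = c(A_c = 0.0001)),
    compartments = c(c = "c", e = "e"), extracellular = "e")),
    "empty objective")
})

test_that("relaxing a bound never decreases the FBA optimum", {
  m <- makeToyModel()$model
  base <- fba(m)@objective_value
  set.seed(11)
  for (i in 1:20) {
    rid <- sample(reactionIds(m), 1)
    idx <- match(rid, reactionIds(m))
    relaxed <- setReactionBounds(
      m, rid,
      lower_bound = m@reactions$lower_bound[idx] - runif(1, 0, 5),
      upper_bound = m@reactions$upper_bound[idx] + runif(1, 0, 5))
    expect_gte(fba(relaxed)@objective_value, base - 1e-6)
  }
})

test_that("pFBA routes flux through the shorter of two parallel paths", {
  m <- parallelModel()
  sol <- pfba(m)
  expect_equal(sol@objective_value, 10)
  expect_equal(unname(sol@fluxes["R_direct"]), 10)
  expect_equal(unname(sol@fluxes["R_via1"]), 0)
  expect_equal(unname(sol@fluxes["R_via2"]), 0)
})

test_that("pFBA at fraction 1 reproduces FBA fluxes on a unique-optimum chain", {
  m <- chainModel()
  expect_equal(pfba(m, 1.0)@fluxes, fba(m)@fluxes, tolerance = 1e-9)
})

test_that("pFBA at fraction 0.9 retains at least 90% of the optimum", {
  m <- makeToyModel()$model
  opt <- fba(m)@objective_value
  sol <- pfba(m, 0.9)
  expect_gte(sol@objective_value, 0.9 * opt - 1e-6)
  # and is strictly sparser than unconstrained parsimony would forbid
  expect_lte(sum(abs(sol@fluxes)), sum(abs(pfba(m, 1.0)@fluxes)) + 1e-6)
})

test_that("pFBA total flux matches exhaustive vertex enumeration on small nets", {
  m1 <- parallelModel()
  # capacity-limited direct route: the parsimonious optimum must split
  m2 <- setReactionBounds(parallelModel(), "R_direct", 0, 4)
  for (m in list(m1, m2)) {
    opt <- fba(m)@objective_value
    sol <- pfba(m, 1.0)
    want <- oraclePfbaMinTotalFlux(m, opt)
    expect_equal(sum(abs(sol@fluxes)), want, tolerance = 1e-6)
  }
  # the chain has a unique flux vector at optimum: closed form 5 x 10
  expect_equal(sum(abs(pfba(chainModel(), 1.0)@fluxes)), 50)
})

test_that("task feasibility and minimal cut behave as designed", {
  toy <- makeToyModel()
  m <- toy$model
  chk <- checkTask(m, toy$tasks$task_atp)
  expect_true(chk$feasible)
  expect_true(length(chk$active_reactions) > 0)
  expect_true(all(chk$active_reactions %in% reactionIds(m)))
  # glycolysis is the sole pyruvate/ATP entry point under task conditions
  expect_false(checkTask(removeReactions(m, "R_GLYC"),
                         toy$tasks$task_atp)$feasible)
  # ROS task dies without superoxide dismutase
  expect_false(checkTask(removeReactions(m, "R_SOD"),
                         toy$tasks$task_ros)$feasible)
  # unknown task metabolite errors
  bad <- metabolicTask("bad", inputs = list(unobtainium_e = c(0, 10)))
  expect_error(checkTask(m, bad), "unknown metabolite")
})

test_that("flux sampling is seeded, steady-state and bound-feasible", {
  m <- makeToyModel()$model
  s1 <- fluxSample(m, n = 20, seed = 99, thinning = 30)
  s2 <- fluxSample(m, n = 20, seed = 99, thinning = 30)
  expect_identical(sampleMatrix(s1), sampleMatrix(s2))
  X <- sampleMatrix(s1)
  expect_equal(nrow(X), 20)
  resid <- abs(as.matrix(stoichMatrix(m)) %*% t(X))
  expect_lt(max(resid), 1e-6)
  lb <- m@reactions$lower_bound
  ub <- m@reactions$upper_bound
  expect_true(all(t(X) >= lb - 1e-9))
  expect_true(all(t(X) <= ub + 1e-9))
  # the chain explores the polytope: free reactions vary
  expect_gt(max(apply(X, 2, var)), 0)
})

test_that("a fully determined network yields identical samples", {
  m <- chainModel()
  m <- setReactionBounds(m, "DM_atp", 10, 10)
  m <- setReactionBounds(m, "EX_A_e", -10, -10)
  s <- fluxSample(m, n = 5, seed = 3, thinning = 10)
  X <- sampleMatrix(s)
  expect_true(all(apply(X, 2, function(col) diff(range(col)) == 0)))
})

test_that("sampling an infeasible model errors before any draws", {
  m_inf <- setReactionBounds(chainModel(-1), "DM_atp", 5, 5)
  expect_error(fluxSample(m_inf, n = 5, seed = 1), "infeasible")
})
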