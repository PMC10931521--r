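toy <- makeToyModel()

test_that("reference mapping extracts the subnetwork with a complete ledger", {
  general <- toy$model
  reference <- c("EX_glc_e", "T_glc", "R_GLYC", "R_LDH", "T_lac",
                 "EX_lac_e", "EX_o2_e", "T_o2", "R_OXPHOS", "R_ATPM",
                 "EX_co2_e", "T_co2")
  extras <- c("R_FAO", "T_fa")
  res <- mapReferenceReactions(general, reference, extras)
  expect_setequal(reactionIds(res$model), c(reference, extras))
  expect_equal(nrow(res$model@reactions), 14)
  expect_equal(nrow(res$ledger), 14)
  expect_setequal(res$ledger$action[res$ledger$reaction_id %in% reference],
                  "mapped")
  expect_setequal(res$ledger$action[res$ledger$reaction_id %in% extras],
                  "added_species_specific")
  # no orphan metabolites survive
  expect_true(all(Matrix::rowSums(stoichMatrix(res$model) != 0) > 0))

  # the ledger reconstructs the structural diff exactly
  expect_setequal(res$ledger$reaction_id[res$ledger$action != "unmappable"],
                  reactionIds(res$model))

  # unmappable ids are reported, not dropped silently
  res2 <- mapReferenceReactions(general, c(reference, "R_ghost"))
  expect_true("R_ghost" %in%
                res2$ledger$reaction_id[res2$ledger$action == "unmappable"])
  expect_error(mapReferenceReactions(general, reference, "R_ghost"),
               "species-specific")
})

test_that("an empty extras set gives a pure subnetwork", {
  res <- mapReferenceReactions(toy$model, c("EX_glc_e", "T_glc", "R_GLYC"))
  expect_setequal(reactionIds(res$model), c("EX_glc_e", "T_glc", "R_GLYC"))
})

test_that("mapping chosen to keep the ATP task feasible does so", {
  keep <- checkTask(toy$model, toy$tasks$task_atp)$active_reactions
  # include the full glycolytic environment so the task has its substrate
  keep <- union(keep, c("EX_glc_e", "T_glc", "EX_lac_e", "T_lac",
                        "EX_co2_e", "T_co2", "EX_o2_e", "T_o2",
                        "EX_h2o_e", "T_h2o"))
  res <- mapReferenceReactions(toy$model, keep)
  expect_true(checkTask(res$model, toy$tasks$task_atp)$feasible)
})

test_that("exchanges are added for measured changed metabolites", {
  general <- toy$model
  # tissue model lacking the uracil exchange+transport and the glycerol
  # exchange (transporter present)
  tissue <- removeReactions(general, c("EX_ura_e", "T_ura", "EX_glyc_e"),
                            drop_orphans = FALSE)
  measured <- c("C00031",  # glucose: exchange already present
                "C00106",  # uracil: exchange + transport both missing
                "C00116",  # glycerol: only exchange missing
                "X999")    # not mappable to the model
  calls <- data.frame(
    metabolite = measured,
    class = c("consumed_only", "consumed_only", "produced_or_consumed",
              "consumed_only"))
  res <- addExchangesForMeasured(tissue, general, measured, calls)
  expect_equal(unname(res$counts),
               c(3, 3, 2))  # matched, with_exchange, added
  expect_true(all(c("EX_ura_e", "EX_glyc_e") %in% reactionIds(res$model)))
  # transport-chain completion co-added the uracil transporter
  expect_true("T_ura" %in% reactionIds(res$model))
  expect_true("added_transport" %in% res$ledger$action)
  # glucose exchange reported as already present
  expect_true("present" %in%
                res$ledger$action[res$ledger$reaction_id == "EX_glc_e"])

  # idempotence: a second application changes nothing
  res2 <- addExchangesForMeasured(res$model, general, measured, calls)
  expect_identical(sort(reactionIds(res2$model)),
                   sort(reactionIds(res$model)))
  expect_equal(unname(res2$counts["added"]), 0)
})

test_that("metabolites without significant calls trigger no additions", {
  tissue <- removeReactions(toy$model, "EX_ura_e", drop_orphans = FALSE)
  calls <- data.frame(metabolite = "C00106", class = "unchanged")
  res <- addExchangesForMeasured(tissue, toy$model, "C00106", calls)
  expect_equal(unname(res$counts["added"]), 0)
  expect_false("EX_ura_e" %in% reactionIds(res$model))
})

test_that("the condition constraint recipe is applied structurally", {
  m <- toy$model
  consumed <- c("glc_e", "o2_e", "rib_e", "nh4_e", "fa_e", "pyr_e",
                "ura_e", "glyc_e")
  cc <- conditionConstraints(
    consumed_metabolites = consumed,
    objective_reaction = "R_ATPM",
    maintenance = c(DM_rna = 1, DM_dna = 1))
  out <- applyConditionConstraints(m, cc)
  rx <- out@reactions

  # consumed exchanges opened to a lower bound of -10
  for (met in consumed) {
    ex <- paste0("EX_", met)
    expect_equal(rx$lower_bound[rx$id == ex], -10, label = ex)
  }
  # ATP-hydrolysis objective with upper bound 100
  expect_equal(rx$upper_bound[rx$id == "R_ATPM"], 100)
  expect_equal(objectiveCoefficients(out), c(R_ATPM = 1))
  # DNA and RNA demands fixed at 1 unit
  for (d in c("DM_rna", "DM_dna")) {
    expect_equal(rx$lower_bound[rx$id == d], 1, label = d)
    expect_equal(rx$upper_bound[rx$id == d], 1, label = d)
  }
  # all other internal reactions capped at 1e6
  internal <- setdiff(rx$id[!isExchange(out)],
                      c("R_ATPM", "DM_rna", "DM_dna"))
  expect_true(all(rx$upper_bound[rx$id %in% internal] == 1e6))
  expect_true(out@notes$feasible)
  expect_equal(fba(out)@status, "optimal")
})

test_that("an empty consumed set changes only objective and caps", {
  cc <- conditionConstraints(character(0), "R_ATPM",
                             maintenance = c(DM_rna = 1, DM_dna = 1))
  before <- toy$model@reactions
  out <- suppressWarnings(applyConditionConstraints(toy$model, cc))
  after <- out@reactions
  ex <- isExchange(toy$model)
  expect_equal(after$lower_bound[ex], before$lower_bound[ex])
})

test_that("infeasibility reports name the blocking maintenance demand", {
  # sever ribonucleotide reduction: the DNA demand becomes unreachable
  m <- removeReactions(toy$model, "R_RNR", drop_orphans = FALSE)
  cc <- conditionConstraints(
    consumed_metabolites = c("glc_e", "o2_e", "rib_e", "nh4_e", "ura_e"),
    objective_reaction = "R_ATPM",
    maintenance = c(DM_rna = 1, DM_dna = 1))
  expect_warning(out <- applyConditionConstraints(m, cc), "blocking")
  expect_false(out@notes$feasible)
  expect_equal(out@notes$infeasibility$blocking_demands, "DM_dna")

  expect_error(applyConditionConstraints(
    toy$model, conditionConstraints(character(0), "R_ghost",
                                    maintenance = c(DM_rna = 1))),
    "missing reactions")
})

test_that("constraint recipes validate their invariants", {
  expect_error(conditionConstraints(character(0), "R_ATPM",
                                    maintenance = c(DM_rna = 1),
                                    uptake_bound = 5),
               "uptake_bound")
  expect_error(conditionConstraints(character(0), "R_ATPM",
                                    maintenance = c(DM_rna = Inf)),
               "finite")
})
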