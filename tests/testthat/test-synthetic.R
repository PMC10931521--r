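test_that("the toy model satisfies its construction contract", {
  toy <- makeToyModel()
  m <- toy$model
  expect_gte(nrow(m@reactions), 30)
  expect_lte(nrow(m@reactions), 80)
  expect_gte(sum(isExchange(m)), 10)
  # exchanged metabolites carry KEGG-style compound ids
  ex_mets <- m@metabolites[m@metabolites$compartment == "e", ]
  expect_true(all(grepl("^C\\d{5}$", ex_mets$kegg_id)))
  # every internal non-demand reaction has a GPR
  demand <- grepl("^DM_", m@reactions$id)
  internal <- !isExchange(m) & !demand
  expect_true(all(nzchar(m@reactions$gpr[internal])))
  # the model contains both complexes and isozymes
  kinds <- unlist(lapply(m@gprs, function(g) {
    if (is.null(g) || g$kind == "gene") NULL else g$kind
  }))
  expect_true(all(c("and", "or") %in% kinds))
  # all catalogued tasks are feasible
  for (t in toy$tasks) {
    expect_true(checkTask(m, t)$feasible, label = t@id)
  }
  # two alternative oxidative ATP routes, each individually sufficient
  for (dropped in list(c("R_PDH", "R_OXPHOS"), c("R_FACS", "R_FAO"))) {
    reduced <- removeReactions(m, dropped, drop_orphans = FALSE)
    expect_gte(fba(reduced)@objective_value, 90)
  }
})

test_that("removing a pathway's key reaction cuts its task", {
  toy <- makeToyModel()
  cuts <- c(task_atp = "R_GLYC", task_ntp = "R_RNAS", task_dna = "R_RNR",
            task_lipid = "R_LIPS", task_ros = "R_SOD")
  for (tid in names(cuts)) {
    reduced <- removeReactions(toy$model, cuts[[tid]], drop_orphans = FALSE)
    expect_false(checkTask(reduced, toy$tasks[[tid]])$feasible,
                 label = paste(tid, "without", cuts[[tid]]))
  }
})

test_that("toy model construction is deterministic", {
  t1 <- makeToyModel(seed = 1)
  t2 <- makeToyModel(seed = 1)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  writeModel(t1$model, p1)
  writeModel(t2$model, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("fewer product pathways give a smaller but valid model", {
  toy2 <- makeToyModel(n_pathways = 2)
  expect_lt(nrow(toy2$model@reactions), nrow(makeToyModel()$model@reactions))
  expect_setequal(names(toy2$tasks), c("task_atp", "task_ntp"))
  for (t in toy2$tasks) expect_true(checkTask(toy2$model, t)$feasible)
  expect_error(makeToyModel(n_pathways = 1))
})

test_that("simulated DE tables respect the planted distributions", {
  toy <- makeToyModel()
  de <- simulateDE(toy$model, toy$tasks, planted = c(task_ntp = "increased"),
                   effect = 2, background_deg_rate = 0.05, seed = 3)
  planted <- attr(de, "planted_genes")
  expect_gt(length(planted), 3)
  pl <- de[de$gene %in% planted, ]
  # planted genes are strongly significant with lfc near +2
  expect_true(all(pl$fdr < 0.01))
  expect_gt(mean(pl$lfc), 1.5)
  # background obeys its DEG rate roughly (49 genes, 5% rate)
  bg <- de[!de$gene %in% planted, ]
  expect_lte(sum(bg$fdr < 0.01), ceiling(0.3 * nrow(bg)))
  # determinism and dependence on the seed
  expect_identical(simulateDE(toy$model, toy$tasks,
                              planted = c(task_ntp = "increased"),
                              seed = 3)$lfc, de$lfc)
  expect_false(identical(simulateDE(toy$model, toy$tasks,
                                    planted = c(task_ntp = "increased"),
                                    seed = 4)$lfc, de$lfc))
  expect_error(simulateDE(toy$model, toy$tasks,
                          planted = c(task_ntp = "increased"), effect = 0),
               "nonzero")
  # no planting and no background leaves nothing significant
  de0 <- simulateDE(toy$model, toy$tasks, background_deg_rate = 0, seed = 1)
  expect_true(all(de0$fdr >= 0.2))
})

test_that("simulated abundance matrices carry their planted truth", {
  sim <- simulateAbundances(seed = 6)
  a <- SummarizedExperiment::assay(sim$abundances)
  groups <- sampleGroups(sim$abundances)
  expect_equal(sum(groups == "blank"), 3)
  expect_equal(dim(a), c(24, 9))   # 22 + 2 engineered high-missing rows
  # planted consumed metabolite sits far below blank in its groups
  blank_mean <- mean(a["C00031", groups == "blank"], na.rm = TRUE)
  trt_mean <- mean(a["C00031", groups == "treated"], na.rm = TRUE)
  expect_lt(trt_mean, 0.3 * blank_mean)
  # produced metabolite sits far above blank
  expect_gt(mean(a["C00186", groups == "control"], na.rm = TRUE),
            2 * mean(a["C00186", groups == "blank"], na.rm = TRUE))
  # engineered rows exceed the 60% missingness cutoff; others do not
  frac <- rowMeans(is.na(a))
  expect_true(all(frac[sim$truth$high_missing] > 0.6))
  expect_true(all(frac[setdiff(rownames(a), sim$truth$high_missing)] <= 0.6))
  # zero missingness leaves the filter nothing to remove
  sim0 <- simulateAbundances(seed = 6, missing_rate = 0, n_high_missing = 0)
  filtered <- suppressMessages(filterMissing(sim0$abundances))
  expect_equal(nrow(filtered), nrow(sim0$abundances))
  # determinism
  expect_identical(SummarizedExperiment::assay(simulateAbundances(seed = 6)$abundances), a)
})

test_that("simulated TPM suppresses the planted pathway 20-fold", {
  toy <- makeToyModel()
  tpm <- simulateTPM(toy$model, toy$pathways,
                     suppressed = c(treated = "oxphos", control = "fao"),
                     seed = 8)
  oxp_genes <- unique(unlist(lapply(toy$model@gprs[toy$pathways$oxphos],
                                    gprGenes)))
  ratio <- tpm$treated[oxp_genes] / tpm$control[oxp_genes]
  expect_true(all(abs(ratio - 0.05) < 1e-12))
  other <- setdiff(modelGenes(toy$model),
                   unique(unlist(lapply(
                     toy$model@gprs[unlist(toy$pathways[c("oxphos", "fao")])],
                     gprGenes))))
  expect_identical(tpm$treated[other], tpm$control[other])
  expect_true(all(unlist(tpm) >= 0))
  expect_error(simulateTPM(toy$model, toy$pathways,
                           suppressed = c(x = "unknown")), "unknown pathways")
  expect_identical(simulateTPM(toy$model, toy$pathways, seed = 8),
                   simulateTPM(toy$model, toy$pathways, seed = 8))
})

test_that("generated bundles are complete and byte-reproducible", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  b1 <- generateBundle(file.path(d1, "bundle"), seed = 5)
  b2 <- generateBundle(file.path(d2, "bundle"), seed = 5)
  files <- c("model.json", "model.xml", "tasks.yaml", "de_treated.tsv",
             "de_control.tsv", "abundances.tsv", "samples.tsv",
             "tpm_treated.tsv", "tpm_control.tsv", "truth.json")
  for (f in files) {
    expect_true(file.exists(file.path(d1, "bundle", f)), label = f)
    expect_identical(readLines(file.path(d1, "bundle", f)),
                     readLines(file.path(d2, "bundle", f)), label = f)
  }
  # the bundle is sufficient to rebuild every pipeline input
  back <- readBundle(file.path(d1, "bundle"))
  expect_equal(sort(reactionIds(back$model)), sort(reactionIds(b1$model)))
  expect_setequal(names(back$tasks), names(b1$tasks))
  expect_equal(back$de$treated$lfc, b1$de$treated$lfc, tolerance = 1e-12)
  expect_equal(unname(back$tpm$control), unname(b1$tpm$control),
               tolerance = 1e-12)
  expect_equal(back$truth$seed, 5)
})

test_that("task catalogues round trip through YAML", {
  toy <- makeToyModel()
  path <- withr::local_tempfile(fileext = ".yaml")
  writeTaskCatalogue(toy$tasks, path)
  back <- readTaskCatalogue(path)
  expect_setequal(names(back), names(toy$tasks))
  for (tid in names(toy$tasks)) {
    expect_equal(back[[tid]]@inputs, toy$tasks[[tid]]@inputs, label = tid)
    expect_equal(back[[tid]]@outputs, toy$tasks[[tid]]@outputs, label = tid)
    expect_equal(back[[tid]]@bounds, toy$tasks[[tid]]@bounds, label = tid)
  }
})
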