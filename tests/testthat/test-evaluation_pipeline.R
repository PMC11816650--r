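# End-to-end evaluation: composition, tie conventions, determinism,
# report serialization, and cross-dataset aggregation.

make_eval_inputs <- function(seed = 6, effectSize = 4) {
  sim <- simulateDataset(fast_sim_config(seed = seed,
                                         effectSize = effectSize))
  asg <- list(sim$truth$labels,
              perturbLabels(sim$truth$labels, 0.5, seed = seed + 100),
              perturbLabels(sim$truth$labels, 1, seed = seed + 200))
  list(sim = sim, asg = asg)
}

test_that("evaluation degrades monotonically with label perturbation", {
  inp <- make_eval_inputs(seed = 6)
  rep <- suppressMessages(evaluateMethods(inp$sim$dataset, inp$sim$clinical,
                                          inp$asg))
  a <- awaValues(rep)
  expect_gt(a[["truth"]], a[["perturbed_0.5"]])
  expect_gt(a[["perturbed_0.5"]], a[["perturbed_1"]])
  expect_identical(awaRanking(rep)[1], "truth")
  expect_identical(rownames(rawMetrics(rep)),
                   c("truth", "perturbed_0.5", "perturbed_1"))
})

test_that("identical assignments tie at the neutral score 5", {
  inp <- make_eval_inputs(seed = 9)
  twin <- ClusterAssignment(clusterLabels(inp$asg[[1]]),
                            methodName = "twin", k = 3)
  rep <- suppressMessages(evaluateMethods(inp$sim$dataset, inp$sim$clinical,
                                          list(inp$asg[[1]], twin)))
  expect_true(all(metricScores(rep) == 5))
  expect_equal(unname(awaValues(rep)), c(5, 5))
  expect_equal(rawMetrics(rep)["truth", ], rawMetrics(rep)["twin", ],
               tolerance = 1e-12)
})

test_that("a single method is rejected: normalization needs >= 2", {
  inp <- make_eval_inputs(seed = 3)
  expect_error(evaluateMethods(inp$sim$dataset, inp$sim$clinical,
                               list(inp$asg[[1]])), ">= 2 methods")
})

test_that("removing a method renormalizes scores but not raw metrics", {
  inp <- make_eval_inputs(seed = 13)
  rep3 <- suppressMessages(evaluateMethods(inp$sim$dataset,
                                           inp$sim$clinical, inp$asg))
  rep2 <- suppressMessages(evaluateMethods(inp$sim$dataset,
                                           inp$sim$clinical, inp$asg[1:2]))
  shared <- rownames(rawMetrics(rep2))
  expect_equal(rawMetrics(rep3)[shared, ], rawMetrics(rep2)[shared, ],
               tolerance = 1e-12)
})

test_that("reports are deterministic and round-trip through JSON", {
  inp <- make_eval_inputs(seed = 5)
  r1 <- suppressMessages(evaluateMethods(inp$sim$dataset, inp$sim$clinical,
                                         inp$asg,
                                         sweepWeights = list(c(0.3, 0.7))))
  r2 <- suppressMessages(evaluateMethods(inp$sim$dataset, inp$sim$clinical,
                                         inp$asg,
                                         sweepWeights = list(c(0.3, 0.7))))
  f1 <- tempfile(fileext = ".json")
  f2 <- tempfile(fileext = ".json")
  writeReport(r1, f1)
  writeReport(r2, f2)
  expect_identical(readLines(f1), readLines(f2))

  back <- readReport(f1)
  expect_equal(unlist(back$awa), awaValues(r1), tolerance = 1e-12)
  expect_identical(unlist(back$ranking), awaRanking(r1))
  expect_equal(unlist(back$raw$truth),
               rawMetrics(r1)["truth", ], tolerance = 1e-12)

  tsv <- tempfile(fileext = ".tsv")
  writeScoreBoard(r1, tsv)
  board <- utils::read.delim(tsv)
  expect_identical(board$method,
                   rownames(rawMetrics(r1)))
  expect_identical(ncol(board), 15L)
})

test_that("compareReports averages AWA across datasets symmetrically", {
  reps <- lapply(c(5, 6), function(s) {
    inp <- make_eval_inputs(seed = s)
    suppressMessages(evaluateMethods(inp$sim$dataset, inp$sim$clinical,
                                     inp$asg))
  })
  tab <- compareReports(reps)
  expect_identical(tab$method[1], "truth")
  m <- tab$method
  manual <- rowMeans(cbind(awaValues(reps[[1]])[m], awaValues(reps[[2]])[m]))
  expect_equal(tab$meanAWA, unname(manual), tolerance = 1e-12)

  # permuting the dataset order changes nothing
  tab_rev <- compareReports(rev(reps))
  expect_equal(tab$meanAWA, tab_rev$meanAWA, tolerance = 1e-12)
  expect_identical(tab$method, tab_rev$method)

  # single report: averages are that report's AWA
  tab1 <- compareReports(reps[1])
  expect_equal(stats::setNames(tab1$meanAWA, tab1$method),
               awaValues(reps[[1]])[tab1$method], tolerance = 1e-12)

  # method-name mismatch is rejected, listing the offending names
  bad <- reps
  renamed <- ClusterAssignment(
    clusterLabels(make_eval_inputs(seed = 7)$asg[[1]]),
    methodName = "other", k = 3)
  inp <- make_eval_inputs(seed = 7)
  bad[[2]] <- suppressMessages(evaluateMethods(
    inp$sim$dataset, inp$sim$clinical,
    list(renamed, inp$asg[[2]], inp$asg[[3]])))
  expect_error(compareReports(bad), "disagree on method names.*truth")
})

test_that("YAML-configured runs execute from files on disk", {
  inp <- make_eval_inputs(seed = 14)
  dir <- tempfile()
  dir.create(dir)
  omics_paths <- list()
  for (kind in names(omicsLayers(inp$sim$dataset))) {
    p <- file.path(dir, paste0(kind, ".tsv"))
    writeOmicsMatrix(omicsLayers(inp$sim$dataset)[[kind]], p)
    omics_paths[[length(omics_paths) + 1]] <- list(path = p, kind = kind)
  }
  clin_path <- file.path(dir, "clinical.tsv")
  writeClinicalTable(inp$sim$clinical, clin_path)
  asg_paths <- vapply(inp$asg, function(a) {
    p <- file.path(dir, paste0(methodName(a), ".tsv"))
    writeClusterAssignment(a, p)
    p
  }, character(1))
  cfg_path <- file.path(dir, "run.yaml")
  yaml::write_yaml(list(name = "sim_run", omics = omics_paths,
                        clinical = clin_path,
                        assignments = as.list(unname(asg_paths)),
                        w1 = 0.5, w2 = 0.5), cfg_path)
  cfg <- readEvalConfig(cfg_path)
  ds <- OmicsDataset(lapply(cfg$omics, function(o)
    readOmicsMatrix(o$path, o$kind)), name = cfg$name)
  cl <- readClinicalTable(cfg$clinical)
  asg <- lapply(cfg$assignments, readClusterAssignment)
  rep_disk <- suppressMessages(evaluateMethods(ds, cl, asg,
                                               w1 = cfg$w1, w2 = cfg$w2))
  rep_mem <- suppressMessages(evaluateMethods(inp$sim$dataset,
                                              inp$sim$clinical, inp$asg))
  expect_equal(rawMetrics(rep_disk), rawMetrics(rep_mem), tolerance = 1e-9)
})
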