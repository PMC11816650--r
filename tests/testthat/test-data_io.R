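# Reading, writing, validation and alignment of the three input artifacts.

test_that("omics TSV reading preserves shape, order and missingness", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tf1\tf2\tf3",
               "s1\t1\tNA\t3",
               "s2\t4\t5\t6"), tsv)
  m <- readOmicsMatrix(tsv, "mrna")
  expect_identical(dim(omicsValues(m)), c(2L, 3L))
  expect_identical(sampleIds(m), c("s1", "s2"))
  expect_identical(featureIds(m), c("f1", "f2", "f3"))
  expect_true(is.na(omicsValues(m)["s1", "f2"]))
  expect_identical(omicsValues(m)["s2", ], c(f1 = 4, f2 = 5, f3 = 6))
})

test_that("omics reading rejects malformed input with informative errors", {
  dup <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tf1", "s1\t1", "s1\t2"), dup)
  expect_error(readOmicsMatrix(dup, "mrna"), "duplicate sample id: s1")

  nonnum <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tf1\tf2", "s1\t1\tok", "s2\t2\t3"), nonnum)
  expect_error(readOmicsMatrix(nonnum, "mrna"), "non-numeric cell 'ok'")

  beta <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tcg1\tcg2", "s1\t0.5\t1.2", "s2\t0.2\t0.9"), beta)
  expect_error(readOmicsMatrix(beta, "methylation"), "cg2")
})

test_that("write/read round trips are exact for all three artifacts", {
  set.seed(11)
  v <- matrix(rnorm(12), 3, 4,
              dimnames = list(paste0("s", 1:3), paste0("f", 1:4)))
  v[2, 3] <- NA
  m <- OmicsMatrix(v, "copy_number")
  f <- tempfile(fileext = ".tsv")
  writeOmicsMatrix(m, f)
  m2 <- readOmicsMatrix(f, "copy_number")
  expect_identical(omicsValues(m2), omicsValues(m))

  cl <- make_clinical(time = c(10.25, 0, 333.125), event = c(1L, 0L, 1L),
                      covariates = data.frame(
                        gender = c("male", NA, "female"),
                        age_at_diagnosis = c(61.5, 70, NA)))
  fc <- tempfile(fileext = ".tsv")
  writeClinicalTable(cl, fc)
  cl2 <- readClinicalTable(fc, covariateKinds(cl))
  expect_identical(survivalTime(cl2), survivalTime(cl))
  expect_identical(survivalEvent(cl2), survivalEvent(cl))
  expect_identical(covariates(cl2), covariates(cl))

  a <- make_assignment(c(1, 2, 1), method = "demo")
  fa <- tempfile(fileext = ".tsv")
  writeClusterAssignment(a, fa)
  a2 <- readClusterAssignment(fa, methodName = "demo")
  expect_identical(clusterLabels(a2), clusterLabels(a))
  expect_identical(clusterK(a2), clusterK(a))
})

test_that("clinical reading applies the six-covariate schema", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c(paste("sample_id", "os_time", "os_event", "gender",
                     "age_at_diagnosis", "pathologic_t", "pathologic_m",
                     "pathologic_n", "pathologic_stage", sep = "\t"),
               "s1\t100\t1\tmale\t60\tT1\tM0\tN0\tStageI",
               "s2\t200\t0\tfemale\t70\tT2\tM0\tN1\tStageII",
               "s3\t\t1\tmale\tNA\tT1\tM1\tN0\tStageIII"), tsv)
  cl <- readClinicalTable(tsv)
  expect_identical(ncol(covariates(cl)), 6L)
  expect_true(is.na(survivalTime(cl)[["s3"]]))
  expect_true(is.numeric(covariates(cl)$age_at_diagnosis))
  expect_true(is.character(covariates(cl)$pathologic_t))
})

test_that("clinical reading warns on absent/unknown columns and rejects bad rows", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c(paste("sample_id", "os_time", "os_event", "gender",
                     "age_at_diagnosis", "pathologic_t", "pathologic_m",
                     "pathologic_n", "extra_col", sep = "\t"),
               "s1\t100\t1\tmale\t60\tT1\tM0\tN0\tx",
               "s2\t200\t0\tfemale\t70\tT2\tM0\tN1\ty"), tsv)
  expect_warning(expect_warning(cl <- readClinicalTable(tsv),
                                "pathologic_stage"), "extra_col")
  expect_identical(ncol(covariates(cl)), 5L)

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tos_time\tos_event", "s1\t10\t1", "s2\t20\t2"), bad)
  expect_error(readClinicalTable(bad), "os_event = 2.*s2")

  neg <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tos_time\tos_event", "s1\t-5\t1"), neg)
  expect_error(readClinicalTable(neg), "negative os_time.*s1")
})

test_that("alignAndValidate intersects, reports drops, and is idempotent", {
  v <- matrix(1:8, 4, 2, dimnames = list(paste0("s", 1:4), c("f1", "f2")))
  ds <- OmicsDataset(list(OmicsMatrix(v, "mrna")))
  cl <- make_clinical(time = c(1, 2, 3, 4, 5), event = c(1L, 0L, 1L, 0L, 1L),
                      ids = paste0("s", 1:5))
  a <- make_assignment(c(1, 1, 2, 2), ids = paste0("s", 1:4))

  out <- suppressMessages(alignAndValidate(ds, cl, list(a)))
  expect_identical(sampleIds(out$dataset), paste0("s", 1:4))
  expect_identical(out$dropped$clinical, "s5")
  expect_identical(sampleIds(out$clinical), paste0("s", 1:4))

  out2 <- suppressMessages(
    alignAndValidate(out$dataset, out$clinical, out$assignments))
  expect_identical(omicsValues(omicsLayers(out2$dataset)[[1]]),
                   omicsValues(omicsLayers(out$dataset)[[1]]))
  expect_identical(clusterLabels(out2$assignments[[1]]),
                   clusterLabels(out$assignments[[1]]))
})

test_that("alignment failures are rejected with the offending name", {
  v <- matrix(1:4, 2, 2, dimnames = list(c("s1", "s2"), c("f1", "f2")))
  ds <- OmicsDataset(list(OmicsMatrix(v, "mrna")))
  cl_disjoint <- make_clinical(time = c(1, 2), event = c(1L, 0L),
                               ids = c("x1", "x2"))
  a <- make_assignment(c(1, 2), ids = c("s1", "s2"))
  expect_error(alignAndValidate(ds, cl_disjoint, list(a)), "empty")

  # cluster 2 of "half" lives entirely outside the omics sample set
  cl <- make_clinical(time = c(1, 2), event = c(1L, 0L))
  a_half <- make_assignment(c(1, 1, 2, 2), ids = c("s1", "s2", "t3", "t4"),
                            method = "half")
  expect_error(suppressMessages(alignAndValidate(ds, cl, list(a_half))),
               "cluster 2 of method 'half'")
})

test_that("domain invariants are enforced at construction", {
  v <- matrix(c(0.2, 0.8), 1, 2, dimnames = list("s1", c("c1", "c2")))
  expect_error(OmicsMatrix(rbind(v, v), "methylation"), "duplicate sample")
  expect_error(make_assignment(c(1, 1, 3), k = 3), "cluster 2.*empty")
  expect_error(make_clinical(time = c(-1, 2), event = c(1L, 0L)),
               "negative survival time")
  expect_error(make_clinical(time = c(1, 2), event = c(1L, 5L)), "event")
})
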