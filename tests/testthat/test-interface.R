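test_that("pattern and RDM files round-trip losslessly", {
  tmp <- withr::local_tempdir()
  ps <- random_pattern_set(5, 7, seed = 701)
  pfile <- file.path(tmp, "patterns.csv")
  write_patterns(ps, pfile)
  ps2 <- read_patterns(pfile)
  expect_equal(ps2$data, ps$data, tolerance = 1e-15)
  expect_identical(ps2$labels, ps$labels)

  r <- random_rdm(6, 702, measure = "correlation")
  sq <- file.path(tmp, "rdm_square.csv")
  vec <- file.path(tmp, "rdm_vec.csv")
  write_rdm(r, sq, form = "square")
  write_rdm(r, vec, form = "vector")
  r_sq <- read_rdm(sq, measure = "correlation")
  r_vec <- read_rdm(vec)
  # the two dialects load to equal objects
  expect_equal(r_sq$d, r$d, tolerance = 1e-15)
  expect_equal(r_vec$d, r$d, tolerance = 1e-15)
  expect_identical(r_vec$measure, "correlation")
  expect_identical(r_sq$labels, r$labels)

  coll <- random_collection(4, 5, seed = 703)
  cfile <- file.path(tmp, "collection.csv")
  write_rdm_collection(coll, cfile)
  coll2 <- read_rdm_collection(cfile)
  expect_equal(lapply(coll2$rdms, `[[`, "d"), lapply(coll$rdms, `[[`, "d"),
               tolerance = 1e-15)
  expect_identical(coll2$roles, coll$roles)

  expect_error(read_patterns(file.path(tmp, "nope.csv")), "not found")
})

test_that("volume JSON round-trips and validates shapes", {
  tmp <- withr::local_tempdir()
  set.seed(711)
  vol <- volume(array(rnorm(3 * 4 * 2 * 5), c(3, 4, 2, 5)),
                array(c(TRUE, FALSE), c(3, 4, 2)),
                voxel_size_mm = c(2, 2, 3))
  vfile <- file.path(tmp, "vol.json")
  write_volume(vol, vfile)
  v2 <- read_volume(vfile)
  expect_equal(v2$data, vol$data, tolerance = 1e-15)
  expect_identical(v2$mask, vol$mask)
  expect_equal(v2$voxel_size_mm, vol$voxel_size_mm)
  # corrupted shape rejected with both lengths reported
  obj <- jsonlite::read_json(vfile, simplifyVector = TRUE)
  obj$mask <- obj$mask[-1]
  jsonlite::write_json(obj, vfile, digits = NA, auto_unbox = FALSE)
  expect_error(read_volume(vfile), "mask length")
})

test_that("the CLI runs an end-to-end simulate -> infer analysis", {
  tmp <- withr::local_tempdir()
  prefix <- file.path(tmp, "demo")
  status <- suppressMessages(rsa_cli(c(
    "simulate", "fig4", "--seed", "1", "--out", prefix,
    "--conditions", "20", "--channels", "24", "--subjects", "12")))
  expect_identical(status, 0L)
  expect_true(file.exists(paste0(prefix, "_subjects.csv")))
  expect_true(file.exists(paste0(prefix, "_subjects.csv.json")))

  out <- file.path(tmp, "result.json")
  status <- suppressMessages(rsa_cli(c(
    "infer", "--subjects", paste0(prefix, "_subjects.csv"),
    "--candidates", paste0(prefix, "_candidates.csv"),
    "--method", "spearman", "--mc", "fdr", "--alpha", "0.05",
    "--seed", "1", "--out", out)))
  expect_identical(status, 0L)
  res <- jsonlite::read_json(out, simplifyVector = TRUE)
  expect_setequal(res$candidate_names,
                  c("true_model", "categorical_faces",
                    "categorical_animacy", "unrelated_control",
                    "other_brain"))
  expect_true(all(res$relatedness_p >= 0 & res$relatedness_p <= 1))
  expect_true(file.exists(paste0(out, ".provenance.json")))

  # reruns are byte-identical
  out2 <- file.path(tmp, "result2.json")
  suppressMessages(rsa_cli(c(
    "infer", "--subjects", paste0(prefix, "_subjects.csv"),
    "--candidates", paste0(prefix, "_candidates.csv"),
    "--method", "spearman", "--mc", "fdr", "--alpha", "0.05",
    "--seed", "1", "--out", out2)))
  expect_identical(readLines(out), readLines(out2))
})

test_that("CLI subcommands cover the remaining operations", {
  tmp <- withr::local_tempdir()
  ps <- random_pattern_set(6, 8, seed = 721)
  pfile <- file.path(tmp, "p.csv")
  write_patterns(ps, pfile)
  rfile <- file.path(tmp, "r.csv")
  expect_identical(suppressMessages(rsa_cli(c(
    "compute-rdm", "--patterns", pfile, "--measure", "euclidean",
    "--out", rfile))), 0L)
  expect_equal(read_rdm(rfile)$d, compute_rdm(ps, "euclidean")$d,
               tolerance = 1e-12)

  r2file <- file.path(tmp, "r2.csv")
  write_rdm(random_rdm(6, 722), r2file)
  out <- utils::capture.output(
    status <- suppressMessages(rsa_cli(c("compare", "--method", "tau-a",
                                         rfile, r2file))))
  expect_identical(status, 0L)
  expect_false(is.na(as.numeric(out[1])))

  coll <- random_collection(5, 6, seed = 723)
  cfile <- file.path(tmp, "subs.csv")
  write_rdm_collection(coll, cfile)
  cjson <- file.path(tmp, "ceiling.json")
  expect_identical(suppressMessages(rsa_cli(c(
    "ceiling", "--subjects", cfile, "--method", "spearman",
    "--out", cjson))), 0L)
  cj <- jsonlite::read_json(cjson, simplifyVector = TRUE)
  expect_lte(cj$lower, cj$upper)
  expect_identical(cj$n_subjects, 5L)

  mfile <- file.path(tmp, "coords.csv")
  expect_identical(suppressMessages(rsa_cli(c("mds", rfile, "--out",
                                              mfile))), 0L)
  expect_equal(nrow(utils::read.csv(mfile)), 6L)

  tfile <- file.path(tmp, "tree.json")
  nwk <- file.path(tmp, "tree.nwk")
  expect_identical(suppressMessages(rsa_cli(c(
    "cluster", rfile, "--linkage", "average", "--out", tfile,
    "--newick", nwk))), 0L)
  tj <- jsonlite::read_json(tfile, simplifyVector = TRUE)
  expect_equal(nrow(tj$merge), 5L)
  if (file.exists(nwk))
    expect_match(readLines(nwk)[1], "^\\(")
})

test_that("CLI reports usage and runtime errors with proper statuses", {
  expect_identical(suppressMessages(rsa_cli(character())), 2L)
  expect_identical(suppressMessages(rsa_cli(c("frobnicate"))), 2L)
  # unknown flag -> usage error
  expect_identical(suppressMessages(rsa_cli(c("mds", "x.csv", "--bogus",
                                              "1", "--out", "y.csv"))), 2L)
  # missing input file -> runtime error naming the path
  msgs <- character()
  status <- withCallingHandlers(
    rsa_cli(c("mds", "/nonexistent/rdm.csv", "--out", "o.csv")),
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    })
  expect_identical(status, 1L)
  expect_true(any(grepl("/nonexistent/rdm.csv", msgs)))
})
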