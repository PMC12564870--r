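test_that("aseg and aparc stats dialects parse and round-trip", {
  lines <- c("# some header", "# more header",
             "# ColHeaders Index SegId NVoxels Volume_mm3 StructName",
             "1 4 10 100.0 Left-A", "2 5 10 200.0 Left-B",
             "3 6 10 300.0 Left-C")
  v <- parse_stats_file(lines, "aseg")
  expect_equal(v, c("Left-A" = 100, "Left-B" = 200, "Left-C" = 300))

  expect_warning(empty <- parse_stats_file(c("# only", "# comments"), "aseg"),
                 "no data rows")
  expect_length(empty, 0)

  ap <- c("# ColHeaders StructName NumVert SurfArea GrayVol",
          "insula 10 20 7000.5")
  expect_equal(parse_stats_file(ap, "aparc", hemisphere = "rh"),
               c("ctx-rh-insula" = 7000.5))

  # writer -> parser is bit-identical on a full 95-structure vector
  set.seed(11)
  tax <- dkt_taxonomy()
  vols <- stats::setNames(round(stats::runif(95, 100, 50000), 3),
                          tax$region_name)
  for (dia in c("aseg", "aparc")) {
    tf <- withr::local_tempfile(fileext = ".stats")
    write_stats_file(vols, tf, dialect = dia)
    back <- parse_stats_file(tf, dia)
    if (dia == "aparc") names(back) <- sub("^ctx-lh-", "", names(back))
    expect_identical(unname(back), unname(vols))
  }
})

test_that("stats parsing reports malformed input instead of guessing", {
  bad <- c("# ColHeaders Index SegId NVoxels Volume_mm3 StructName",
           "1 4 10 100.0 Left-A", "garbage-row")
  expect_warning(v <- parse_stats_file(bad, "aseg"), "unparseable")
  expect_length(v, 1)
  dup <- c("# ColHeaders Index SegId NVoxels Volume_mm3 StructName",
           "1 4 10 100.0 Left-A", "2 5 10 150.0 Left-A")
  expect_error(parse_stats_file(dup, "aseg"), "duplicated")
  nocol <- c("# ColHeaders Index SegId NVoxels StructName",
             "1 4 10 Left-A")
  expect_error(parse_stats_file(nocol, "aseg"), "Volume_mm3")
})

test_that("delimited tables load, validate, and round-trip", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,cohort,age,sex,Left-A,Right-A",
               "s1,K,25,M,100.5,101.5", "s2,K,67,female,90,91"), tf)
  vm <- load_volume_table(tf)
  expect_s3_class(vm, "volume_matrix")
  expect_equal(dim(vm), c(2L, 2L))
  expect_equal(vm$data$sex, c("M", "F"))

  noage <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,cohort,sex,Left-A", "s1,K,M,100"), noage)
  expect_error(load_volume_table(noage), "age")

  badsex <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,cohort,age,sex,Left-A", "s1,K,25,X,100"), badsex)
  expect_error(load_volume_table(badsex), "sex code")

  badnum <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,cohort,age,sex,Left-A",
               "s1,K,25,M,abc"), badnum)
  expect_error(load_volume_table(badnum), "s1")

  # generator output -> write -> load is the identity
  vm2 <- generate_volumes(synthetic_spec(
    regions = c("Hippocampus", "Thalamus")), seed = 5)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_volume_table(vm2, out)
  back <- load_volume_table(out, provenance = "synthetic")
  expect_identical(back$data, vm2$data)
})

test_that("bilateral combination sums pairs, passes midline, conserves mass", {
  vb <- combine_bilateral(tiny_lateralized())
  expect_equal(region_values(vb, "Hippocampus"), c(8768, 8300))
  expect_equal(region_values(vb, "Brain Stem"), c(20063.7, 21000))
  expect_equal(dim(vb), c(2L, 3L))

  # conservation oracle on a random 10-subject matrix over the full roster
  set.seed(42)
  tax <- dkt_taxonomy()
  df <- data.frame(subject_id = sprintf("s%02d", 1:10), cohort = "A",
                   age = sample(21:90, 10), sex = sample(c("M", "F"), 10,
                                                         TRUE))
  for (r in tax$region_name) df[[r]] <- stats::runif(10, 100, 40000)
  vm <- volume_matrix(df)
  vb <- combine_bilateral(vm)
  expect_equal(length(vb$regions), 50)
  tot_in <- rowSums(as.data.frame(vm)[tax$region_name])
  tot_out <- rowSums(as.data.frame(vb)[vb$regions])
  expect_equal(tot_out, tot_in, tolerance = 1e-12)
})

test_that("a missing hemisphere flags the region, not the subject", {
  vm <- tiny_lateralized()
  vm$data[["Right-Thalamus"]] <- NULL
  vm$regions <- setdiff(vm$regions, "Right-Thalamus")
  expect_warning(vb <- combine_bilateral(vm), "Thalamus")
  expect_true(all(is.na(region_values(vb, "Thalamus"))))
  expect_equal(region_values(vb, "Hippocampus"), c(8768, 8300))
})

test_that("volume matrix validation rejects malformed input", {
  df <- data.frame(subject_id = c("a", "a"), cohort = "K", age = c(30, 40),
                   sex = "M", R1 = c(1, 2))
  expect_error(volume_matrix(df), "duplicated subject_id")
  df2 <- data.frame(subject_id = c("a", "b"), cohort = "K",
                    age = c(30, 150), sex = "M", R1 = c(1, 2))
  expect_error(volume_matrix(df2), "age")
  df3 <- data.frame(subject_id = "a", cohort = "K", age = 30, sex = "M",
                    R1 = -5)
  expect_error(volume_matrix(df3), "negative volume")
})
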