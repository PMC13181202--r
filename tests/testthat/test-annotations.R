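test_that("consensus labelling follows the mean-grade rule around 3", {
  expect_identical(assign_label(c(4, 5, 4)), "malignant")   # grade 4.33
  expect_identical(assign_label(c(3, 3, 3)), "excluded")    # uncertain
  expect_identical(assign_label(c(1, 2, 2)), "benign")      # grade 1.67
  expect_identical(assign_label(c(2, 3, 4), aggregate = "median"), "excluded")
  expect_error(assign_label(c(2, 6)), "1..5")
  expect_error(assign_label(integer()), "nonempty")
})

test_that("labelling is permutation-invariant in the ratings list", {
  set.seed(11)
  for (i in 1:25) {
    r <- sample(1:5, sample(1:6, 1), replace = TRUE)
    expect_identical(assign_label(r), assign_label(r[sample.int(length(r))]))
  }
})

test_that("annotation parsing preserves counts and applies the reader filter", {
  df <- data.frame(seriesuid = sprintf("uid%d", 1:10),
                   coordX = seq(10, 100, 10), coordY = 0, coordZ = 0,
                   diameter_mm = 5,
                   ratings = c(rep("1;2;2", 5), rep("4;4;5", 5)))
  ann <- parse_annotations(df)
  expect_equal(nrow(ann), 10L)
  expect_true(all(ann$reader_count == 3L))

  # 2-reader sidecar entry is dropped by the >=3 consensus filter
  csvdir <- withr::local_tempdir()
  writeLines(c("seriesuid,coordX,coordY,coordZ,diameter_mm",
               "uid1,-24.0,12.5,-100.3,6.1"),
             file.path(csvdir, "ann.csv"))
  side <- data.frame(seriesuid = "uid1", coordX = -24, coordY = 12.5,
                     coordZ = -100.3, rating = c(4, 4))
  expect_equal(nrow(parse_annotations(file.path(csvdir, "ann.csv"),
                                      ratings = side)), 0L)
  kept <- parse_annotations(file.path(csvdir, "ann.csv"), ratings = side,
                            min_readers = 2L)
  expect_equal(kept$reader_count, 2L)
  expect_identical(kept$ratings[[1]], c(4L, 4L))

  # without any rating source the filter does not apply
  expect_equal(nrow(parse_annotations(df[, 1:5])), 10L)
  expect_error(parse_annotations(df[, 2:5]), "seriesuid")
  bad <- df; bad$coordX[3] <- "oops"
  expect_error(parse_annotations(bad), "malformed")
})

test_that("duplicate-entry merging matches a brute-force transitive-closure oracle", {
  same_nodule <- function(df, i, j) {
    df$seriesuid[i] == df$seriesuid[j] &&
      sqrt(sum((unlist(df[i, c("coordX", "coordY", "coordZ")]) -
                unlist(df[j, c("coordX", "coordY", "coordZ")]))^2)) <
        max(df$diameter_mm[i], df$diameter_mm[j]) / 2
  }
  oracle_clusters <- function(df) {
    n <- nrow(df)
    adj <- diag(TRUE, n)
    for (i in seq_len(n)) for (j in seq_len(n))
      if (i != j && same_nodule(df, i, j)) adj[i, j] <- TRUE
    reach <- adj
    for (k in seq_len(n)) reach <- reach | (reach %*% reach) > 0  # closure
    unique(apply(reach, 1, function(r) paste(which(r), collapse = ",")))
  }
  set.seed(21)
  for (rep in 1:8) {
    n <- sample(5:20, 1)
    df <- data.frame(seriesuid = sample(c("a", "b"), n, replace = TRUE),
                     coordX = runif(n, 0, 30), coordY = runif(n, 0, 30),
                     coordZ = runif(n, 0, 30),
                     diameter_mm = runif(n, 3, 12),
                     ratings = "3;4;5")
    merged <- parse_annotations(df, merge = TRUE)
    expect_equal(nrow(merged), length(oracle_clusters(df)))
  }
})

test_that("LIDC-style XML reading sessions parse into per-reader rows", {
  xml <- paste0(
    '<LidcReadMessage><ResponseHeader>',
    '<SeriesInstanceUid>1.2.3</SeriesInstanceUid></ResponseHeader>',
    paste0(vapply(1:3, function(r) paste0(
      '<readingSession><unblindedReadNodule>',
      '<characteristics><malignancy>', 3 + r %% 2, '</malignancy></characteristics>',
      '<roi><imageZposition>-100.5</imageZposition>',
      '<edgeMap><xCoord>50</xCoord><yCoord>60</yCoord></edgeMap>',
      '<edgeMap><xCoord>54</xCoord><yCoord>60</yCoord></edgeMap>',
      '</roi></unblindedReadNodule></readingSession>'), character(1)),
      collapse = ""),
    '</LidcReadMessage>')
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(xml, f)
  rows <- parse_lidc_xml(f)
  expect_equal(nrow(rows), 3L)
  expect_equal(rows$seriesuid, rep("1.2.3", 3))
  expect_equal(rows$coordX, rep(52, 3))
  expect_equal(rows$coordZ, rep(-100.5, 3))
  # assemble into one consensus annotation
  rows$ratings <- as.character(rows$rating)
  ann <- parse_annotations(rows[, c("seriesuid", "coordX", "coordY", "coordZ",
                                    "diameter_mm", "ratings")])
  expect_equal(nrow(ann), 1L)
  expect_equal(ann$reader_count, 3L)
})
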