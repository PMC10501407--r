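test_that("activity transform maps IC50 to the pAct scale and inverts", {
  expect_equal(transformActivity(1), 9)
  expect_equal(transformActivity(10), 8)
  expect_equal(transformActivity(0.18), 9.744727494896694, tolerance = 1e-12)
  # strictly decreasing in ic50
  ic <- sort(10^runif(50, -3, 3))
  expect_true(all(diff(transformActivity(ic)) < 0))
  # inverse identity over the assay-relevant range
  expect_equal(inverseTransformActivity(transformActivity(ic)), ic,
               tolerance = 1e-9)
  # literal audit variant is increasing
  expect_equal(transformActivity(10, formula = "literal"), 10)
  # errors name the compound
  expect_error(transformActivity(c(1, -2), id = c("ok", "bad")), "bad")
  expect_error(transformActivity(NaN), "finite")
})

test_that("the packaged assay fixture loads with the expected structure", {
  cs <- table1CompoundSet()
  expect_s4_class(cs, "CompoundSet")
  expect_length(cs, 34)
  ic <- ic50(cs)
  expect_identical(names(which.min(ic)), "21E")
  expect_identical(names(which.max(ic)), "13m")
  expect_equal(unname(range(activities(cs))),
               c(8.97061622231479, 9.744727494896694), tolerance = 1e-12)
})

test_that("compound tables reject malformed input and round-trip cleanly", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines("", tmp)
  expect_error(readCompoundTable(tmp), "empty")
  writeLines(c("id,ic50_uM", "a,1", "a,2"), tmp)
  expect_error(readCompoundTable(tmp), "duplicate")
  writeLines(c("id,conc", "a,1"), tmp)
  expect_error(readCompoundTable(tmp), "ic50")
  writeLines(c("id,ic50_uM", "a,1", "b,oops"), tmp)
  expect_error(readCompoundTable(tmp), "b")
  cs <- table1CompoundSet()
  writeCompoundTable(cs, tmp)
  back <- readCompoundTable(tmp)
  expect_equal(as.data.frame(back)[c("id", "ic50", "activity")],
               as.data.frame(cs)[c("id", "ic50", "activity")])
})

test_that("seeded splits honor the ratio arithmetic and are reproducible", {
  cs <- table1CompoundSet()
  for (s in c(1, 7, 1234)) {
    sp <- splitDataset(cs, c(1, 3), seed = s)
    expect_length(sp$train, 26)
    expect_length(sp$heldOut, 8)
    expect_setequal(c(compoundIds(sp$train), compoundIds(sp$heldOut)),
                    compoundIds(cs))
    expect_length(intersect(compoundIds(sp$train), compoundIds(sp$heldOut)), 0)
    expect_true(all(roles(sp$train) == "train"))
    expect_true(all(roles(sp$heldOut) == "test"))
  }
  small <- cs[1:4]
  sp <- splitDataset(small, c(1, 3), seed = 2)
  expect_length(sp$train, 3)
  expect_length(sp$heldOut, 1)
  a <- splitDataset(cs, c(1, 3), seed = 11)
  b <- splitDataset(cs, c(1, 3), seed = 11)
  expect_identical(compoundIds(a$heldOut), compoundIds(b$heldOut))
  # 1:4 validation split stamps the validation role
  v <- splitDataset(cs, c(1, 4), seed = 3, heldOutRole = "validation")
  expect_length(v$heldOut, round(34 / 5))
  expect_true(all(roles(v$heldOut) == "validation"))
  expect_error(splitDataset(cs[1:2], 0.1), "empty")
})

test_that("descriptor tables read/write with explicit missing-value handling", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  m <- matrix(rnorm(12), 3, 4,
              dimnames = list(c("a", "b", "c"), paste0("d", 1:4)))
  writeDescriptorTable(descriptorTable(m), tmp)
  back <- readDescriptorTable(tmp)
  expect_equal(descriptorMatrix(back), m, tolerance = 1e-12)
  writeLines(c("id,d1,d2", "a,1,2", "b,,3", "c,4,5"), tmp)
  expect_error(readDescriptorTable(tmp), "d1")
  expect_message(dropCol <- readDescriptorTable(tmp, na_action = "drop_columns"),
                 "d1")
  expect_identical(descriptorNames(dropCol), "d2")
  expect_message(dropRow <- readDescriptorTable(tmp, na_action = "drop_rows"),
                 "b")
  expect_identical(compoundIds(dropRow), c("a", "c"))
})

test_that("the descriptor registry carries the six published descriptors", {
  reg <- descriptorRegistry()
  expect_setequal(reg$name, c("NFA", "MRCH", "MECN", "TEIZP", "ZXS", "MCIHN"))
  expect_equal(reg$coefficient[reg$name == "MECN"], 5.6298)
})
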