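test_that("slice stacks read in ascending filename order with inferred depth", {
  dir <- withr::local_tempdir()
  # three 4x4 slices written out of order, constant values matching suffix
  for (v in c(2, 0, 1))
    png::writePNG(matrix(v / 255, 4, 4), file.path(dir, sprintf("s%03d.png", v)))
  vol <- read_slice_stack(dir, 3)
  expect_s3_class(vol, "voxel_volume")
  expect_identical(dim(vol$data), c(3L, 4L, 4L))
  expect_equal(vol$data[1, 1, 1], 0)
  expect_equal(vol$data[2, 1, 1], 1)
  expect_equal(vol$data[3, 1, 1], 2)
  expect_identical(vol$bit_depth, 8L)

  dir2 <- withr::local_tempdir()
  for (i in 1:3) png::writePNG(matrix(0, 4, 4), file.path(dir2, sprintf("a%02d.png", i)))
  z <- read_slice_stack(dir2, 3)
  expect_true(all(z$data == 0))

  # a 16-bit slice with the full-scale value
  dir3 <- withr::local_tempdir()
  m <- matrix(0, 4, 4); m[2, 3] <- 1
  tiff::writeTIFF(m, file.path(dir3, "s000.tif"), bits.per.sample = 16)
  v16 <- read_slice_stack(dir3, 3)
  expect_identical(v16$bit_depth, 16L)
  expect_equal(max(v16$data), 65535)
})

test_that("malformed stacks are rejected with specific errors", {
  dir <- withr::local_tempdir()
  png::writePNG(matrix(0, 4, 4), file.path(dir, "s000.png"))
  png::writePNG(matrix(0, 5, 4), file.path(dir, "s001.png"))
  expect_error(read_slice_stack(dir, 3), "dimension mismatch")

  dir2 <- withr::local_tempdir()
  expect_error(read_slice_stack(dir2, 3), "no readable")

  dir3 <- withr::local_tempdir()
  png::writePNG(array(0.5, c(4, 4, 3)), file.path(dir3, "rgb000.png"))
  expect_error(read_slice_stack(dir3, 3), "multi-channel")
})

test_that("8-bit BMP slices round-trip through the reader", {
  dir <- withr::local_tempdir()
  set.seed(42)
  m <- matrix(sample(0:255, 7 * 5, replace = TRUE), 7, 5)
  grainscan:::write_bmp_gray(m, file.path(dir, "s000.bmp"))
  vol <- read_slice_stack(dir, 3)
  expect_identical(dim(vol$data), c(1L, 7L, 5L))
  expect_equal(matrix(vol$data[1, , ], 7, 5), m)
})

test_that("label volumes round-trip losslessly through the slice writer", {
  dir <- withr::local_tempdir()
  lv1 <- label_volume(array(TISSUE_LABELS[["HULL"]], c(1, 1, 1)), 3)
  write_label_volume(lv1, file.path(dir, "a"))
  back1 <- read_label_volume(file.path(dir, "a"))
  expect_identical(back1$labels, lv1$labels)
  expect_equal(back1$voxel_size_um, 3)

  set.seed(7)
  arr <- array(sample(TISSUE_LABELS, 125, replace = TRUE), c(5, 5, 5))
  lv2 <- label_volume(arr, 2.5)
  write_label_volume(lv2, file.path(dir, "b"))
  back2 <- read_label_volume(file.path(dir, "b"))
  expect_identical(back2$labels, lv2$labels)
  expect_equal(back2$voxel_size_um, 2.5)
})

test_that("checked CSV readers validate schema, domains and ordering", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene_id,chrom,pos_mb,log2fc,pvalue",
               "g1,2,25.18,1.5,0.01", "g2,2,28.33,-2.0,0.04"), f)
  deg <- read_deg_table(f)
  expect_equal(nrow(deg), 2)
  expect_identical(deg$direction, c("up", "down"))

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene_id,chrom,pos_mb,log2fc", "g1,2,25.18,1.5"), f2)
  expect_error(read_deg_table(f2), "missing required column.*pvalue")

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene_id,chrom,pos_mb,log2fc,pvalue",
               "g1,2,25.18,oops,0.01"), f3)
  expect_error(read_deg_table(f3), "row error.*log2fc.*row\\(s\\) 1")

  g <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("line_id,m1,m2", "L1,A,B", "L2,H,A"), g)
  expect_error(read_genotype_matrix(g), "row 2.*'m1'.*'H'")

  m <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("chrom,marker,cM,Mb",
               "1,a,0,0", "1,b,10,4", "1,c,5,6"), m)
  expect_error(read_genetic_map(m), "ordering error.*cM")
})
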