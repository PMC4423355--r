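test_that("batch ids format and parse as species_stain_date", {
  b <- batch_id("ma", "gt", "260911")
  expect_identical(format(b), "ma_gt_260911")
  p <- parse_batch_id("ma_gt_260911")
  expect_identical(p$species, "ma")
  expect_identical(p$stain, "gt")
  expect_identical(p$date, "260911")
  expect_error(parse_batch_id("ma_gt"), "species_stain_date")
  expect_error(batch_id("ma", "gt", "26091"), "\\d|date|grepl")
})

test_that("layout paths reproduce the documented worked example", {
  expect_identical(layout_paths("ma_gt_260911", "001", "_ch00"),
                   "ish/megaselia/ma_gt_260911/proc/001_ch00.png")
  expect_identical(layout_paths("ma_gt_260911", "001", "_prof.dat"),
                   "ish/megaselia/ma_gt_260911/proc/001_prof.dat")
  expect_identical(layout_paths("ma_Kr_010213", "017", "_embmsk", rnai = TRUE),
                   "RNAi/megaselia/ma_Kr_010213/proc/017_embmsk.png")
  expect_error(layout_paths("ma_gt_260911", "001", "_foo"), "unknown suffix")
})

test_that("layout paths parse back to their components", {
  for (sfx in c("_ch00", "_dic_ch00", "_nuc_ch00", "_memb_ch00", "_embmsk",
                "_band", "_stband", "_prof.dat")) {
    p <- layout_paths("ma_hb_120412", "042", sfx)
    parsed <- parse_layout_path(p)
    expect_identical(format(parsed$batch), "ma_hb_120412")
    expect_identical(parsed$embryo_id, "042")
    expect_identical(parsed$suffix, sfx)
    expect_false(parsed$rnai)
  }
  expect_true(parse_layout_path(
    layout_paths("ma_kni_010101", "003", "_ch00", rnai = TRUE))$rnai)
})

tc_fixture <- function() {
  data.frame(embryo = c("ma_gt_260911/proc/001", "ma_gt_260911/proc/002"),
             timeclass = c("C14_T4", "C13"),
             spline_height = c(24L, 26L),
             spline_x1 = c(11, 12), spline_x2 = c(161, 162.5),
             spline_x3 = c(311, 313), spline_x4 = c(461, 463.5),
             spline_x5 = c(611, 614),
             spline_y1 = c(130.5, 131), spline_y2 = c(131, 132),
             spline_y3 = c(131, 132), spline_y4 = c(131, 132),
             spline_y5 = c(130.5, 131),
             check.names = FALSE, stringsAsFactors = FALSE)
}

bd_fixture <- function() {
  data.frame(embryo = rep("ma_gt_260911/proc/001", 2),
             boundary_id = c(2L, 5L), facing = c("posterior", "anterior"),
             gene = "gt", channel = "purple",
             boundary_x1 = c(133, 245.5), boundary_x2 = c(151, 263),
             boundary_x3 = c(169, 281.25),
             boundary_y1 = c(60, 225), boundary_y2 = c(142.5, 142.5),
             boundary_y3 = c(225, 60),
             check.names = FALSE, stringsAsFactors = FALSE)
}

int_fixture <- function() {
  data.frame(gene = c("gt", "gt"), timeclass = c("C14_T1", "C14_T2"),
             boundary_id = c(2L, 2L), mean = c(24.81, 25.3),
             median = c(24.9, 25.25), standard_deviation = c(1.02, 0.98),
             MAD = c(0.8, 0.75), n = c(12L, 9L), stringsAsFactors = FALSE)
}

test_that("timeclasses_bands round-trips byte-identically", {
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_timeclasses_bands(tc_fixture(), p1)
  back <- read_timeclasses_bands(p1)
  write_timeclasses_bands(back, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("timeclasses_bands validation names the offending line", {
  rows <- tc_fixture()
  rows$timeclass[2] <- "C14_T9"
  p <- withr::local_tempfile(fileext = ".csv")
  write_timeclasses_bands(rows, p)
  expect_error(read_timeclasses_bands(p), "line 3.*C14_T9")
  rows2 <- tc_fixture()
  rows2$spline_x3[1] <- 5 # breaks strict x ordering
  write_timeclasses_bands(rows2, p)
  expect_error(read_timeclasses_bands(p), "line 2.*increasing")
})

test_that("header-only files read as empty tables", {
  p <- withr::local_tempfile(fileext = ".csv")
  write_timeclasses_bands(tc_fixture()[0, ], p)
  expect_identical(nrow(read_timeclasses_bands(p)), 0L)
})

test_that("boundary_data round-trips and rejects bad categorical values", {
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_boundary_data(bd_fixture(), p1)
  back <- read_boundary_data(p1)
  write_boundary_data(back, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))

  bad <- bd_fixture(); bad$facing[1] <- "dorsal"
  write_boundary_data(bad, p1)
  expect_error(read_boundary_data(p1), "invalid facing 'dorsal'")
  bad2 <- bd_fixture(); bad2$channel[2] <- "green"
  write_boundary_data(bad2, p1)
  expect_error(read_boundary_data(p1), "invalid channel")
  bad3 <- bd_fixture(); bad3$boundary_x2[1] <- bad3$boundary_x1[1] - 1
  write_boundary_data(bad3, p1)
  expect_error(read_boundary_data(p1), "strictly increasing")
})

test_that("the integrated table uses the printed headers and round-trips", {
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_integrated(int_fixture(), p1)
  header <- readLines(p1, n = 1)
  expect_identical(header,
                   "gene,timeclass,boundary id,mean,median,standard deviation,MAD")
  back <- read_integrated(p1)
  expect_identical(names(back)[3], "boundary_id")
  write_integrated(back, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  # optional n column
  write_integrated(int_fixture(), p1, include_n = TRUE)
  expect_match(readLines(p1, n = 1), ",n$")
  expect_identical(read_integrated(p1)$n, c(12L, 9L))
})

test_that("writers are deterministic: same rows, same bytes", {
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_boundary_data(bd_fixture(), p1)
  write_boundary_data(bd_fixture(), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("validate_tree reports completeness per embryo", {
  tmp <- withr::local_tempdir()
  man <- generate_batch(list(n_embryos = 2, gene = "gt", stage = "C10",
                             boundaries = single_domain_boundaries()),
                        tmp, seed = 6)
  qc <- validate_tree(tmp)
  expect_identical(nrow(qc), 2L)
  expect_true(all(qc$complete))
  # remove one image -> flagged incomplete
  unlink(file.path(tmp, layout_paths(man$batch_id[1], "002", "_nuc_ch00")))
  qc2 <- validate_tree(tmp)
  expect_false(qc2$complete[qc2$embryo_id == "002"])
  expect_match(qc2$missing[qc2$embryo_id == "002"], "_nuc_ch00")
})
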