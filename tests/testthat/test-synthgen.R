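test_that("zero stain renders a uniform embryo interior", {
  b <- single_domain_boundaries()
  b$plateau_intensity <- 0
  ge <- small_embryo(boundaries = b, noise_sd = 0)
  bf <- ge$record$images[["_ch00"]]
  geom <- ge$truth$geometry
  cm <- stain_color_model("NBT_BCIP")
  # sample a horizontal transect through the ellipse centre, well inside
  cy <- round(geom$center_xy[2])
  cx <- round(geom$center_xy[1])
  xs <- (cx - 100):(cx + 100)
  for (k in 1:3)
    expect_true(all(bf[cy, xs, k] == cm$background_rgb[k]))
})

test_that("nuclear image carries exactly 2^(cycle-1) nuclei for C10", {
  ge <- small_embryo(stage = "C10")
  expect_identical(ge$truth$n_nuclei, 512)
  m <- compute_mask(ge$record$images[["_dic_ch00"]])
  n <- count_nuclei(ge$record$images[["_nuc_ch00"]], m)
  expect_identical(n, 512L)
})

test_that("same seed and arguments give bit-identical rasters", {
  g1 <- small_embryo(seed = 99, noise_sd = 5)
  g2 <- small_embryo(seed = 99, noise_sd = 5)
  for (sfx in names(g1$record$images))
    expect_identical(g1$record$images[[sfx]], g2$record$images[[sfx]])
  g3 <- small_embryo(seed = 100, noise_sd = 5)
  expect_false(identical(g1$record$images[["_ch00"]],
                         g3$record$images[["_ch00"]]))
})

test_that("rasters share dimensions and stay in 8-bit range", {
  ge <- small_embryo(noise_sd = 12, stage = "C14_T2")
  d <- dim(ge$record$images[["_ch00"]])
  for (img in ge$record$images) {
    expect_identical(dim(img), d)
    expect_true(all(img >= 0 & img <= 255))
    expect_true(all(img == round(img)))
  }
})

test_that("overlapping boundary ramps are rejected", {
  b <- single_domain_boundaries(p1 = 40, p2 = 44, width = 6)
  expect_error(domain_spec("gt", b), "overlap")
  expect_error(
    domain_spec("gt", data.frame(boundary_id = 1:2,
                                 facing = c("anterior", "anterior"),
                                 position_pct_el = c(30, 60),
                                 width_pct_el = 6, plateau_intensity = 1)),
    "alternate")
  expect_error(
    domain_spec("gt", data.frame(boundary_id = 1:2,
                                 facing = c("anterior", "posterior"),
                                 position_pct_el = c(60, 30),
                                 width_pct_el = 6, plateau_intensity = 1)),
    "increasing")
})

test_that("unmixing a noise-free embryo recovers boundary positions to 0.5 %EL", {
  truth <- c(25, 45, 62, 80)
  ge <- full_embryo(boundaries = gt_like_boundaries(truth), noise_sd = 0)
  q <- quantify_to_fits(ge)
  # half-maximum crossings of the unmixed intensity profile
  prof <- q$profile
  lo <- min(prof$intensity); hi <- max(prof$intensity)
  half <- (lo + hi) / 2
  crossing <- which(diff(sign(prof$intensity - half)) != 0)
  pos <- sort(prof$pct_el[crossing])
  pos <- pos[pos > 5 & pos < 95] # interior crossings, away from pole mixing
  expect_length(pos, 4L)
  expect_true(all(abs(pos - truth) <= 0.5))
})

test_that("generate_batch writes the suffix scheme and a lossless manifest", {
  tmp <- withr::local_tempdir()
  spec <- list(n_embryos = 3, gene = "gt", stain = "NBT_BCIP",
               stage = "C10", noise_sd = 0,
               boundaries = single_domain_boundaries())
  man <- generate_batch(spec, tmp, seed = 5)
  proc <- file.path(tmp, "ish", "megaselia", man$batch_id[1], "proc")
  for (id in c("001", "002", "003"))
    for (sfx in c("_ch00", "_dic_ch00", "_nuc_ch00", "_memb_ch00"))
      expect_true(file.exists(file.path(proc, paste0(id, sfx, ".png"))))
  # manifest round-trips boundaries losslessly
  man2 <- read.csv(file.path(proc, "manifest.csv"), stringsAsFactors = FALSE,
                   colClasses = c(embryo_id = "character"))
  expect_identical(man2$embryo_id, c("001", "002", "003"))
  b <- unpack_boundaries(man2$boundaries[1])
  expect_identical(b$position_pct_el, c(35, 60))
  expect_identical(b$facing, c("anterior", "posterior"))

  # refusal on non-empty dir, determinism with the same seed
  expect_error(generate_batch(spec, tmp, seed = 5), "not empty")
  tmp2 <- withr::local_tempdir()
  man3 <- generate_batch(spec, tmp2, seed = 5)
  expect_identical(man, man3)
  expect_error(generate_batch(list(n_embryos = 0), tmp2), "at least one")
})
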