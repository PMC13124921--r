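ref_corner_mask <- function(dims = c(4, 4, 4), n = 2) {
  m <- array(FALSE, dim = dims)
  m[seq_len(n), 1, 1] <- TRUE
  binary_mask(m)
}

test_that("compute_suvr normalizes by the reference mean", {
  v <- vol3(rep(2, 64))
  suvr <- compute_suvr(v, all_mask())
  expect_equal(unique(as.vector(suvr$data)), 1)
  expect_identical(suvr$kind, "suvr")

  # reference {1.5, 2.5} -> mean 2.0; target 3.0 -> 1.5
  v2 <- vol3(rep(1, 64))
  v2$data[1, 1, 1] <- 1.5; v2$data[2, 1, 1] <- 2.5; v2$data[3, 1, 1] <- 3.0
  suvr2 <- compute_suvr(v2, ref_corner_mask())
  expect_equal(suvr2$data[3, 1, 1], 1.5)
  expect_equal(mean(suvr2$data[ref_corner_mask()$data]), 1, tolerance = 1e-9)
})

test_that("SUVR is invariant to global rescaling of SUV", {
  set.seed(31)
  v <- vol3(runif(64, 0.5, 3))
  ref <- ref_corner_mask(n = 4)
  s1 <- compute_suvr(v, ref)
  for (c in c(0.2, 7.5)) {
    vc <- vol3(v$data * c)
    expect_equal(compute_suvr(vc, ref)$data, s1$data, tolerance = 1e-12)
  }
})

test_that("compute_suvr rejects empty or non-positive references", {
  v <- vol3(rep(1, 64))
  expect_error(compute_suvr(v, binary_mask(array(FALSE, c(4, 4, 4)))),
               "empty")
  vneg <- vol3(rep(-1, 64))
  expect_error(compute_suvr(vneg, all_mask()), "positive")
})

test_that("regional_suvr equals brute-force accumulation and names missing regions", {
  set.seed(32)
  scheme <- region_scheme(
    list(ref = 1L, a = 2L, b = c(3L, 4L)),
    reference_regions = "ref", composite_regions = c("a", "b"))
  lab <- vol3(sample(0:4, 64, replace = TRUE), kind = "label")
  suvr <- vol3(runif(64, 0.8, 2), kind = "suvr")
  tab <- regional_suvr(suvr, lab, scheme)
  for (nm in c("ref", "a", "b")) {
    sel <- lab$data %in% scheme$label_to_name[[nm]]
    expect_equal(tab$rsuvr[tab$region == nm], mean(suvr$data[sel]))
    expect_equal(tab$voxel_count[tab$region == nm], sum(sel))
  }
  lab2 <- vol3(rep(c(0, 1, 2), length.out = 64), kind = "label")  # no 3/4
  expect_error(regional_suvr(suvr, lab2, scheme), "'b'")
})

test_that("com_suvr averages composite regions (and bounds hold)", {
  scheme <- region_scheme(
    as.list(setNames(1:6, c("ref", "f", "pc", "pre", "par", "lt"))),
    "ref", c("f", "pc", "pre", "par", "lt"))
  tab <- data.frame(region = c("ref", "f", "pc", "pre", "par", "lt"),
                    rsuvr = c(1.0, 1.1, 1.2, 1.3, 1.4, 1.5),
                    voxel_count = c(10, 10, 20, 30, 40, 50))
  expect_equal(com_suvr(tab, scheme), 1.3)
  expect_equal(com_suvr(tab, scheme, weighted = TRUE),
               sum(tab$rsuvr[-1] * tab$voxel_count[-1]) /
                 sum(tab$voxel_count[-1]))
  cs <- com_suvr(tab, scheme)
  expect_gte(cs, min(tab$rsuvr[-1])); expect_lte(cs, max(tab$rsuvr[-1]))
  expect_error(com_suvr(tab[tab$region != "f", ], scheme), "missing.*f")
})

test_that("uniform SUVR volume gives ComSUVR 1 through the whole chain", {
  lab <- vol3(rep(1:6, length.out = 64), kind = "label")
  suv <- vol3(rep(4.2, 64))
  scheme <- default_region_scheme()
  suvr <- compute_suvr(suv, make_label_mask(lab, 1L))
  tab <- regional_suvr(suvr, lab, scheme)
  expect_equal(com_suvr(tab, scheme), 1)
})

test_that("region scheme round-trips through JSON and validates", {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(
    list(labels = list(cerebellum = 1, frontal = c(2, 12), parietal = 3),
         reference = "cerebellum", composite = c("frontal", "parietal")),
    path, auto_unbox = TRUE)
  sc <- read_region_scheme(path)
  expect_identical(sc$label_to_name$frontal, c(2L, 12L))
  expect_identical(sc$reference_regions, "cerebellum")
  unlink(path)
  expect_error(region_scheme(list(a = 1L), "a", "a"), "disjoint")
  expect_error(region_scheme(list(a = 1L), "a", "zz"), "without labels")
})
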