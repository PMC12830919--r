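test_that("region masks tile the image exactly once across geometries", {
  for (size in c(64L, 101L, 128L, 256L)) {
    lay <- make_region_layout(c(size, size), 3 / size)
    stack <- Reduce(`+`, lapply(lay$masks, function(m) m * 1L)) + lay$faz * 1L
    expect_true(all(stack == 1L), label = sprintf("partition at %d px", size))
  }
})

test_that("annulus membership matches an independent per-pixel radial scan", {
  size <- 128L
  px <- 0.0234
  lay <- make_region_layout(c(size, size), px)
  annulus <- Reduce(`|`, lay$masks[paste0("S", 1:12)])
  count <- 0L
  for (r in seq_len(size)) for (c in seq_len(size)) {
    d <- px * sqrt((c - 0.5 - size / 2)^2 + (r - 0.5 - size / 2)^2)
    if (d > 0.5 && d <= 1.45) count <- count + 1L
  }
  expect_identical(sum(annulus), count)
})

test_that("sector areas are near-equal 30-degree arcs", {
  lay <- make_region_layout(c(128L, 128L), 0.0234)
  counts <- vapply(paste0("S", 1:12), function(s) sum(lay$masks[[s]]),
                   integer(1))
  expect_lte(max(counts) / min(counts), 1.02)
})

test_that("quadrants split the perifovea at the fovea center axes", {
  lay <- make_region_layout(c(96L, 96L), 3 / 96)
  # Q1 is the top-right corner: all its pixels right of / above the center
  q1 <- which(lay$masks$Q1, arr.ind = TRUE)
  expect_true(all(q1[, "col"] - 0.5 >= 48))
  expect_true(all(q1[, "row"] - 0.5 < 48))
  corners <- rbind(c(1, 96), c(1, 1), c(96, 1), c(96, 96))
  for (i in 1:4)
    expect_true(lay$masks[[paste0("Q", i)]][corners[i, 1], corners[i, 2]])
})

test_that("layout geometry preconditions are enforced", {
  expect_error(make_region_layout(c(64, 64), 3 / 64, inner_radius_mm = 1.5,
                                  outer_radius_mm = 1.45), "inner")
  expect_error(make_region_layout(c(64, 64), 0.01), "half-diagonal")
})

test_that("vessel density is the exact vessel-pixel ratio", {
  b <- matrix(FALSE, 20, 20)
  mask <- matrix(FALSE, 20, 20)
  mask[1:10, 1:20] <- TRUE                     # 200 px region
  b[1:10, 1:20][sample(200, 37)] <- TRUE       # 37 vessel px inside
  expect_equal(vessel_density(b, mask), 18.5)
  expect_equal(vessel_density(mask & TRUE, mask), 100)
  expect_equal(vessel_density(b & FALSE, mask), 0)
  expect_error(vessel_density(b, matrix(FALSE, 20, 20)), "empty mask")
  expect_error(vessel_density(b, matrix(FALSE, 5, 5)), "shape")
})

test_that("zone VD is the mask-size-weighted mean of its region VDs", {
  set.seed(4)
  lay <- make_region_layout(c(96L, 96L), 3 / 96)
  b <- matrix(runif(96 * 96) < 0.3, 96, 96)
  sn <- paste0("S", 1:12)
  per_region <- vapply(sn, function(s) vessel_density(b, lay$masks[[s]]),
                       numeric(1))
  sizes <- vapply(sn, function(s) sum(lay$masks[[s]]), integer(1))
  whole <- vessel_density(b, Reduce(`|`, lay$masks[sn]))
  expect_equal(whole, sum(per_region * sizes) / sum(sizes), tolerance = 1e-10)
})

test_that("extract_features: lengths, ordering and error propagation", {
  set.seed(8)
  cfg <- test_cohort_config(n_patients = 2)
  coh <- generate_cohort(cfg)
  lay <- make_region_layout(coh[[1]]$images$SVP)
  fv <- extract_features(coh[[1]], lay)
  expect_named(fv, as.vector(outer(c("SVP", "ICP", "DCP"),
                                   c("parafoveal", "perifoveal"),
                                   paste, sep = ".")), ignore.order = TRUE)
  expect_length(fv$SVP.parafoveal$values, 12L)
  expect_length(fv$SVP.perifoveal$values, 4L)
  expect_named(fv$DCP.parafoveal$values, paste0("S", 1:12))
  expect_true(all(unlist(lapply(fv, `[[`, "values")) >= 0))
  expect_true(all(unlist(lapply(fv, `[[`, "values")) <= 100))

  # an all-background image cannot be binarized; the error surfaces
  flat <- coh[[1]]
  flat$images$SVP <- angiogram(matrix(0.2, 96, 96), 3 / 96)
  expect_error(extract_features(flat, lay, plexuses = "SVP"), "degenerate")
  expect_error(extract_features(coh[[1]], lay, plexuses = "NOPE"), "no image")
})

test_that("perifoveal dropout lowers every quadrant VD in a paired render", {
  geom <- test_geom(96)
  lay <- make_region_layout(c(96L, 96L), 3 / 96)
  vd_quads <- function(img) {
    b <- binarize_map(frangi_vesselness(img))
    vapply(paste0("Q", 1:4), function(q) vessel_density(b, lay$masks[[q]]),
           numeric(1))
  }
  for (s in c(2, 5, 9)) {
    set.seed(s)
    clean <- render_vessel_network(geom, "ICP", c(para = 0, peri = 0))
    set.seed(s)
    dropped <- render_vessel_network(geom, "ICP", c(para = 0, peri = 0.5))
    expect_true(all(vd_quads(dropped) < vd_quads(clean)),
                label = sprintf("seed %d", s))
  }
})
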