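test_that("empty cell range yields a background-only image", {
  spec <- cohort_spec("HEALTHY", 1,
    cells_per_image_range = c(0L, 0L),
    smudge_rate = 0, image_size = c(96L, 64L)
  )
  sm <- generate_smear(spec, "P1", seed = 1)
  expect_equal(dim(sm$image), c(64, 96, 3))
  expect_equal(nrow(sm$annotations), 0L)
  # background stays near the nominal stain-free colour everywhere
  expect_lt(max(abs(sm$image[, , 1] - 0.94)), 0.1)
})

test_that("a fixed seed reproduces images and annotations bit for bit", {
  spec <- cohort_spec("APL", 1,
    cells_per_image_range = c(8L, 12L),
    image_size = c(160L, 120L)
  )
  a <- generate_smear(spec, "P1", seed = 77)
  b <- generate_smear(spec, "P1", seed = 77)
  expect_identical(a$image, b$image)
  expect_identical(a$annotations, b$annotations)
  c <- generate_smear(spec, "P1", seed = 78)
  expect_false(identical(a$image, c$image))
})

test_that("invalid specifications are rejected", {
  expect_error(
    cohort_spec("APL", 1, image_size = c(0L, 10L)),
    class = "aplsmear_invalid_spec"
  )
  expect_error(
    cohort_spec("APL", 1, composition_dist = list(
      mean = c(
        myeloblast = 0.5, promyelocyte = 0.4,
        auer_promyelocyte = 0.2, other = 0.1
      ),
      concentration = 8
    )),
    class = "aplsmear_invalid_spec"
  )
  expect_error(
    cell_type_spec("myeloblast", c(5, 10), 1, 0.5,
      auer_rod_count_range = c(1L, 2L)
    ),
    class = "aplsmear_invalid_spec"
  )
  expect_error(
    cohort_spec("APL", 1, overlap_prob = 1.5),
    class = "aplsmear_invalid_spec"
  )
})

# 50 seeded images x 30 cells at an effectively fixed composition: the
# promyelocyte-family total is a Binomial(1500, 0.63) draw; check it against
# the exact 99% binomial interval (expected count 18.9 per image).
test_that("promyelocyte-family counts follow the binomial composition", {
  spec <- cohort_spec("APL", 1,
    cells_per_image_range = c(30L, 30L),
    composition_dist = list(
      mean = c(
        myeloblast = 0.07, promyelocyte = 0.48,
        auer_promyelocyte = 0.15, other = 0.30
      ),
      concentration = 1e9
    ),
    smudge_rate = 0, image_size = c(320L, 240L)
  )
  counts <- vapply(1:50, function(i) {
    ann <- generate_smear(spec, "P1", seed = 9000 + i)$annotations
    sum(ann$is_promyelocyte)
  }, numeric(1))
  total <- sum(counts)
  lo <- qbinom(0.005, 50 * 30, 0.63)
  hi <- qbinom(0.995, 50 * 30, 0.63)
  expect_gte(total, lo)
  expect_lte(total, hi)
  .fx$comp_counts <- counts # reused below
  .fx$comp_spec <- spec
})

test_that("empirical type fractions match the composition within 3 SE", {
  spec <- .fx$comp_spec
  anns <- lapply(51:70, function(i) {
    generate_smear(spec, "P1", seed = 9000 + i)$annotations
  })
  ann <- do.call(rbind, anns)
  n <- nrow(ann) + 50 * 30
  expect_gte(n, 2000)
  promy <- sum(ann$is_promyelocyte) + sum(.fx$comp_counts)
  p <- 0.63
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(promy / n - p), 3 * se)
})

test_that("border cells keep at least 70% of their area on canvas", {
  spec <- cohort_spec("APL", 1,
    cells_per_image_range = c(40L, 40L),
    image_size = c(256L, 192L), smudge_rate = 0
  )
  ann <- generate_smear(spec, "P1", seed = 5)$annotations
  pad <- 60
  for (i in seq_len(nrow(ann))) {
    m <- aplsmear:::ellipse_mask(
      192 + 2 * pad, 256 + 2 * pad,
      ann$cx[i] + pad, ann$cy[i] + pad, ann$rx[i], ann$ry[i], ann$theta[i]
    )
    total <- sum(m)
    inside <- sum(m[(pad + 1):(pad + 192), (pad + 1):(pad + 256)])
    expect_gte(inside / total, 0.70)
  }
})

test_that("Auer rods are conserved and confined to promyelocytes", {
  sm <- fx_smears()
  ann <- sm$annotations
  expect_true(any(ann$has_auer_rod))
  expect_identical(ann$has_auer_rod, ann$n_auer_rods >= 1L)
  expect_true(all(ann$is_promyelocyte[ann$has_auer_rod]))
  # ground-truth types mutually exclusive
  expect_false(any(ann$is_myeloblast & ann$is_promyelocyte))
})

test_that("cohort manifests have the prescribed geometry", {
  dir <- withr::local_tempdir()
  tiny <- function(d, n) {
    cohort_spec(d, n,
      images_per_patient = 1L,
      cells_per_image_range = c(2L, 3L), image_size = c(96L, 72L),
      smudge_rate = 0
    )
  }
  man <- generate_cohort(
    list(tiny("APL", 2), tiny("AML", 2), tiny("HEALTHY", 2)),
    dir, seed = 3
  )
  expect_equal(nrow(man), 6L)
  expect_equal(length(unique(man$patient_id)), 6L)
  expect_equal(unname(table(man$diagnosis)), rep(2L, 3), ignore_attr = TRUE)
  expect_true(all(file.exists(man$image_path)))
  expect_true(all(file.exists(man$annotation_path)))
  expect_true(file.exists(file.path(dir, "manifest.csv")))

  empty <- generate_cohort(list(tiny("APL", 0)), withr::local_tempdir())
  expect_equal(nrow(empty), 0L)

  expect_error(
    generate_cohort(list(tiny("APL", 1), tiny("APL", 1)), dir),
    class = "aplsmear_invalid_spec"
  )
})
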