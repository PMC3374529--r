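test_that("voxelization recovers analytic volumes and the skin shell invariant", {
  # 20 mm cube at 1 mm spacing: exactly 8000 tissue voxels
  g <- voxelize(cube_mesh(20), 1, layer_thicknesses(skin = 1, fat_gland = 2,
                                                    muscle = 2))
  expect_equal(sum(g$labels != 0), 8000)
  # sphere r = 10 at 0.5 mm: volume within 2%
  sp <- sphere_mesh(10, 40)
  gs <- voxelize(sp, 0.5, layer_thicknesses(skin = 1, fat_gland = 2, muscle = 2))
  expect_lt(abs(sum(gs$labels != 0) * 0.5^3 / (4 / 3 * pi * 1000) - 1), 0.02)
  # every tissue voxel with an OUTSIDE 6-neighbour is SKIN
  lab <- gs$labels
  lv <- tissue_levels()
  d <- dim(lab)
  shift <- function(a, off) {
    out <- array(0L, dim(a))
    src <- dst <- lapply(dim(a), seq_len)
    for (ax in 1:3) {
      if (off[ax] == 1) { src[[ax]] <- seq_len(d[ax] - 1); dst[[ax]] <- 2:d[ax] }
      if (off[ax] == -1) { src[[ax]] <- 2:d[ax]; dst[[ax]] <- seq_len(d[ax] - 1) }
    }
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    out
  }
  for (off in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
    sh <- shift(lab, off)
    expect_false(any(lab != 0 & lab != lv["SKIN"] & sh == 0))
  }
  # layer ordering inside-out: core deeper than muscle, muscle deeper than
  # fat, fat deeper than skin (by distance to surface)
  centre_lab <- lab[ceiling(d[1] / 2), ceiling(d[2] / 2), ceiling(d[3] / 2)]
  expect_equal(unname(centre_lab), unname(lv[["BONE_CORE"]]))
  # spacing coarser than the thinnest layer is rejected
  expect_error(voxelize(sp, 2, layer_thicknesses(skin = 1, fat_gland = 2,
                                                 muscle = 2)),
               "smallest layer thickness")
})

test_that("voxel grids round-trip through the NRRD text container", {
  g <- voxelize(cube_mesh(12), 2, layer_thicknesses(skin = 2, fat_gland = 3,
                                                    muscle = 3))
  path <- tempfile(fileext = ".nrrd")
  write_voxel_grid(g, path)
  back <- read_voxel_grid(path)
  expect_identical(back$labels, g$labels)
  expect_equal(back$origin, g$origin)
  expect_equal(back$spacing, g$spacing)
})

test_that("catalogue loading validates and filtering matches a predicate oracle", {
  path <- system.file("extdata", "implants_synthetic.csv", package = "mammoplan")
  cat_tbl <- read_implant_catalogue(path)
  expect_s3_class(cat_tbl, "implant_catalogue")
  expect_gte(nrow(cat_tbl), 10)
  # all-encompassing ranges return everything, in order
  all_out <- filter_catalogue(cat_tbl, diameter = c(0, 1000),
                              projection = c(0, 1000), volume = c(0, 1e5))
  expect_identical(all_out$id, cat_tbl$id)
  # disjoint volume range returns nothing
  expect_equal(nrow(filter_catalogue(cat_tbl, volume = c(5000, 6000))), 0)
  # brute-force triple-predicate scan on random ranges
  set.seed(99)
  for (i in 1:25) {
    dr <- sort(runif(2, 90, 130))
    pr <- sort(runif(2, 25, 60))
    vr <- sort(runif(2, 100, 400))
    got <- filter_catalogue(cat_tbl, dr, pr, vr)$id
    want <- cat_tbl$id[cat_tbl$base_diameter_mm >= dr[1] & cat_tbl$base_diameter_mm <= dr[2] &
                       cat_tbl$projection_mm >= pr[1] & cat_tbl$projection_mm <= pr[2] &
                       cat_tbl$volume_cc >= vr[1] & cat_tbl$volume_cc <= vr[2]]
    expect_identical(got, want)
  }
  expect_error(filter_catalogue(cat_tbl[0, ]), "empty")
  expect_error(filter_catalogue(cat_tbl, diameter = c(10, 5)), "min <= max")
})

test_that("implant voxelization matches the half-ellipsoid closed form and rescales to nominal volume", {
  # d = 100, projection = 40: (2/3) pi 50^2 40 = 209.4 cc
  analytic <- 2 / 3 * pi * 50^2 * 40 / 1000
  iv <- implant_voxels(list(id = "X", shape = "round", base_diameter_mm = 100,
                            projection_mm = 40, volume_cc = analytic),
                       spacing = 2)
  expect_lt(abs(iv$volume_cc / analytic - 1), 0.02)
  # nominal 200 cc honoured within 2% by uniform rescaling
  iv2 <- implant_voxels(list(id = "X", shape = "round", base_diameter_mm = 100,
                             projection_mm = 40, volume_cc = 200), spacing = 2)
  expect_lt(abs(iv2$volume_cc / 200 - 1), 0.02)
  # anatomical shape narrows the transverse axis
  iv3 <- implant_voxels(list(id = "X", shape = "anatomical",
                             base_diameter_mm = 100, projection_mm = 40,
                             volume_cc = 150), spacing = 2)
  expect_lt(iv3$axes[2], iv3$axes[1])
  # flat face posterior: no voxel below z = 0
  expect_gte(min(iv$voxels[, 3]), 0)
  expect_error(implant_voxels(list(id = "X", shape = "round",
                                   base_diameter_mm = 100, projection_mm = 0,
                                   volume_cc = 100), spacing = 2),
               "projection")
  expect_error(implant_voxels(list(id = "X", shape = "round",
                                   base_diameter_mm = 100, projection_mm = 40,
                                   volume_cc = 100), spacing = 20),
               "projection/3")
})

test_that("pocket creation places the implant at the planned interface", {
  pk <- fixture("pocket_case", build_pocket_case)
  lab <- pk$pocket$labels
  lv <- tissue_levels()
  expect_gt(sum(lab == lv["IMPLANT"]), 0)
  # implant centroid within one voxel of the requested frontal centre
  iv <- which(lab == lv["IMPLANT"], arr.ind = TRUE)
  ctr <- sweep((iv - 0.5) * pk$pocket$spacing, 2, pk$pocket$origin, "+")
  left <- ctr[ctr[, 1] > 0, ]
  expect_lt(abs(mean(left[, 1]) - 60), pk$pocket$spacing)
  expect_lt(abs(mean(left[, 2]) - (-126)), pk$pocket$spacing)
  # subglandular adjacency census: anterior neighbours fat/gland, posterior
  # neighbours muscle, each for >= 90% of the implant's z-facing boundary
  d <- dim(lab)
  ant <- 0; ant_fat <- 0; post <- 0; post_mus <- 0
  for (r in seq_len(nrow(iv))) {
    i <- iv[r, 1]; j <- iv[r, 2]; k <- iv[r, 3]
    if (k < d[3] && lab[i, j, k + 1] != lv["IMPLANT"]) {
      ant <- ant + 1
      if (lab[i, j, k + 1] == lv["FAT_GLAND"]) ant_fat <- ant_fat + 1
    }
    if (k > 1 && lab[i, j, k - 1] != lv["IMPLANT"]) {
      post <- post + 1
      if (lab[i, j, k - 1] == lv["MUSCLE"]) post_mus <- post_mus + 1
    }
  }
  expect_gte(ant_fat / ant, 0.9)
  expect_gte(post_mus / post, 0.9)
  # displaced tissue is preserved, not deleted: the overlying columns shift
  # anteriorly, so the tissue voxel count is unchanged
  pre <- attr(pk$pocket, "pre_pocket")
  expect_equal(sum(lab != lv["OUTSIDE"] & lab != lv["IMPLANT"]),
               sum(pre != lv["OUTSIDE"]))
  # plan centre outside the torso errors
  bad <- placement_plan(left = list(implant_id = "S64", center = c(500, -126),
                                    placement = "SUBGLANDULAR"))
  expect_error(create_pocket(pk$grid, bad, list(left = pk$imp)),
               "outside the torso")
})

test_that("plans validate their placement enumeration and round-trip as JSON", {
  expect_error(placement_plan(left = list(implant_id = "A", center = c(0, 0),
                                          placement = "UNDER")),
               "SUBGLANDULAR, SUBMUSCULAR or DUAL_PLANE")
  plan <- bilateral_plan("A200")
  path <- tempfile(fileext = ".json")
  write_plan(plan, path)
  back <- read_plan(path)
  expect_equal(back$left$center, plan$left$center)
  expect_equal(back$right$placement, plan$right$placement)
})
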