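# Shared small-phantom simulation: built once, reused by several blocks.
small_sim <- function(id = "A200", elasticity = "tight") {
  fixture(paste0("sim_", id, "_", elasticity), function() {
    spec <- small_phantom_spec()
    mesh <- build_torso_mesh(phantom_template(spec), 4)
    simulate_augmentation(mesh, bilateral_plan(id, cx = 60, cy = -126),
                          test_catalogue(),
                          elasticity = elasticity_class(elasticity),
                          config = sim_config(max_iterations = 500,
                                              tolerance = 0.05))
  })
}

test_that("the particle system mirrors the voxel grid", {
  pk <- fixture("pocket_case", build_pocket_case)
  tem <- build_tem(pk$pocket)
  lv <- tissue_levels()
  expect_equal(nrow(tem$pos), sum(pk$pocket$labels != lv["OUTSIDE"]))
  # 6-neighbour rest lengths equal the spacing, diagonals spacing * sqrt(2)
  expect_setequal(round(unique(tem$edge_len0), 9),
                  round(c(4, 4 * sqrt(2)), 9))
  # bone core fixed, implant anchored and near-rigid
  expect_true(all(tem$invmass[tem$labels == lv["BONE_CORE"]] == 0))
  expect_true(all(tem$anchor_k[tem$labels == lv["IMPLANT"]] > 0))
  imp_edges <- tem$labels[tem$edges[, 1] + 1] == lv["IMPLANT"] &
               tem$labels[tem$edges[, 2] + 1] == lv["IMPLANT"]
  skin_edges <- tem$labels[tem$edges[, 1] + 1] == lv["SKIN"] &
                tem$labels[tem$edges[, 2] + 1] == lv["SKIN"]
  expect_gt(min(tem$edge_k[imp_edges]), 50 * max(tem$edge_k[skin_edges]))
})

test_that("looser skin classes have strictly smaller skin stiffness", {
  pk <- fixture("pocket_case", build_pocket_case)
  lv <- tissue_levels()
  ks <- vapply(c("loose", "moderate", "tight", "very_tight"), function(el) {
    tem <- build_tem(pk$pocket, elasticity_class(el))
    skin_edges <- tem$labels[tem$edges[, 1] + 1] == lv["SKIN"] &
                  tem$labels[tem$edges[, 2] + 1] == lv["SKIN"]
    mean(tem$edge_k[skin_edges])
  }, 0)
  expect_true(all(diff(ks) > 0))
  expect_error(elasticity_class("loose", multipliers = c(loose = 1, moderate = 0.5,
                                                         tight = 1, very_tight = 2)),
               "increase strictly")
})

test_that("an implant-free rest state is a fixed point of the solver", {
  spec <- small_phantom_spec()
  mesh <- build_torso_mesh(phantom_template(spec), 4)
  g <- voxelize(mesh, 4)
  tem <- build_tem(g)
  sv <- solve_tem(tem, sim_config(max_iterations = 50, tolerance = 0.02))
  expect_true(sv$info$converged)
  expect_equal(max(abs(sv$pos - tem$pos)), 0)
})

test_that("converged solves conserve tissue volume and are deterministic", {
  res <- small_sim("S64")
  expect_true(res$info$converged)
  base <- build_tem(res$grid)
  v0 <- tem_total_volume(base)
  v1 <- tem_total_volume(res$state)
  expect_lt(abs(v1 / v0 - 1), 0.05)
  res2 <- small_sim_rerun <- {
    spec <- small_phantom_spec()
    mesh <- build_torso_mesh(phantom_template(spec), 4)
    simulate_augmentation(mesh, bilateral_plan("S64", cx = 60, cy = -126),
                          test_catalogue(),
                          config = sim_config(max_iterations = 500,
                                              tolerance = 0.05))
  }
  expect_identical(res$postop$vertices, res2$postop$vertices)
  expect_identical(res$state$pos, res2$state$pos)
})

test_that("volume gain tracks the implant volume and grows with implant size", {
  r200 <- small_sim("S64")
  expect_lt(abs(r200$volume_gain_cc / r200$implant_volume_cc - 1), 0.1)
  r150 <- small_sim("S45")
  r250 <- small_sim("S87")
  # postoperative anterior projection is monotone in implant volume
  apex <- function(r) max(r$postop$vertices[, 3])
  expect_gt(apex(r250), apex(r200))
  expect_gt(apex(r200), apex(r150))
})

test_that("loose skin yields at least the anterior displacement of very tight skin", {
  # compare the bulge top (95th percentile of anterior skin particle height):
  # tighter skin flattens the transition zone of the bulge
  lv <- tissue_levels()
  bulge_top <- function(r) {
    sk <- r$state$labels == lv["SKIN"] & r$state$pos[, 3] > 0
    unname(quantile(r$state$pos[sk, 3], 0.95))
  }
  expect_gte(bulge_top(small_sim("S64", "loose")),
             bulge_top(small_sim("S64", "very_tight")))
})

test_that("symmetric phantom and identical bilateral plan give a mirror-symmetric result", {
  res <- small_sim("S64")
  expect_lt(mirror_deviation(res$postop), 0.5)
})

test_that("extracted surfaces are watertight and metrically faithful", {
  # undeformed voxelized sphere: area within 5% of 4 pi r^2
  sp <- sphere_mesh(10, 40)
  g <- voxelize(sp, 0.5, layer_thicknesses(skin = 1, fat_gland = 2, muscle = 2))
  tem <- build_tem(g)
  surf <- extract_skin_surface(tem)
  expect_true(all(edge_share_counts(surf) == 2))
  expect_lt(abs(mesh_area(surf) / (4 * pi * 100) - 1), 0.05)
  # mesh -> voxelize -> extract round trip: two-sided deviation <= 2 spacing
  d1 <- max(point_surface_distance(surf$vertices, sp))
  d2 <- max(point_surface_distance(sp$vertices, surf))
  expect_lt(max(d1, d2), 2 * 0.5)
  # postoperative surface is watertight too
  res <- small_sim("S64")
  expect_true(all(edge_share_counts(res$postop) == 2))
})

test_that("dual-plane placement softens the muscle over the implant's upper pole", {
  pk <- fixture("pocket_case", build_pocket_case)
  spec <- small_phantom_spec()
  mesh <- build_torso_mesh(phantom_template(spec), 4)
  cat_tbl <- test_catalogue()
  imp <- implant_voxels(cat_tbl[cat_tbl$id == "S64", ], spacing = 4)
  grid <- voxelize(mesh, 4, pad = imp$axes[3] + 12)
  plan_dp <- bilateral_plan("S64", cx = 60, cy = -126, placement = "DUAL_PLANE")
  pocket <- create_pocket(grid, plan_dp, list(left = imp, right = imp))
  tem_sg <- build_tem(pk$pocket)
  tem_dp <- build_tem(pocket)
  lv <- tissue_levels()
  mus_sg <- tem_sg$edge_k[tem_sg$labels[tem_sg$edges[, 1] + 1] == lv["MUSCLE"]]
  mus_dp <- tem_dp$edge_k[tem_dp$labels[tem_dp$edges[, 1] + 1] == lv["MUSCLE"]]
  expect_lt(mean(mus_dp), mean(mus_sg))
})
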