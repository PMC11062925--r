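test_that("terminal allocation is proportional, exact, and guarded", {
  expect_equal(unname(allocate_terminals(c(a = 1, b = 1), 10)), c(5L, 5L))
  expect_equal(unname(allocate_terminals(c(a = 3, b = 1), 8)), c(6L, 2L))
  for (seed in 1:5) {
    set.seed(seed)
    v <- stats::runif(7, 0.1, 10)
    names(v) <- letters[1:7]
    n <- sample(7:600, 1)
    cnt <- allocate_terminals(v, n)
    expect_identical(sum(cnt), as.integer(n))
    expect_true(all(cnt >= 1L))
  }
  expect_error(allocate_terminals(c(a = 1, b = 1, c = 1), 2), "at least")
})

test_that("grown trees have binary topology and Murray radii for all seeds", {
  set.seed(99)
  pts <- matrix(stats::runif(300, -1, 1), ncol = 3)
  for (seed in 1:10) {
    n <- 6L
    tr <- grow_tree(pts, c(0, 0, 2), root_radius = 0.1, root_flow = 1,
                    n_terminals = n, config = cco_config(seed = seed,
                                                         min_terminal_radius = 1e-6),
                    territory_volume = 8)
    expect_equal(length(tr$outlet_ids), n)
    expect_equal(nrow(tr$segments), 2L * n - 1L)
    expect_true(validate_tree(tr))
    # Murray relation r_p^3 = r_1^3 + r_2^3 at every bifurcation (uncapped)
    seg <- tr$segments
    kids <- tree_children(tr)
    for (id in seg$id) {
      ch <- kids[[as.character(id)]]
      if (length(ch) != 2) next
      rp <- seg$radius[match(id, seg$id)]
      rc <- seg$radius[match(ch, seg$id)]
      expect_equal(rp^3, sum(rc^3), tolerance = 1e-9)
    }
  }
})

test_that("single-terminal trees and symmetric splits match closed forms", {
  pts <- matrix(c(0, 0, 0), 1, 3)
  tr <- grow_tree(pts, c(0, 0, 1), 0.05, 1, 1, cco_config(seed = 1))
  expect_equal(nrow(tr$segments), 1)
  expect_equal(tr$segments$radius, 0.05)

  # two equal-flow daughters: r_child/r_parent = 2^(-1/3)
  set.seed(1)
  pts2 <- matrix(stats::runif(60, -1, 1), ncol = 3)
  tr2 <- grow_tree(pts2, c(0, 0, 3), 0.1, 1, 2,
                   cco_config(seed = 2, min_terminal_radius = 1e-6),
                   territory_volume = 8)
  seg <- tr2$segments
  root_r <- seg$radius[match(tr2$root, seg$id)]
  child_r <- seg$radius[seg$id != tr2$root]
  expect_equal(child_r / root_r, rep(2^(-1 / 3), 2), tolerance = 1e-12)
})

test_that("optimized connections never cost more than the naive midpoint", {
  set.seed(7)
  pts <- matrix(stats::runif(450, -1.5, 1.5), ncol = 3)
  tr <- grow_tree(pts, c(0, 0, 2.5), 0.12, 1, 12,
                  cco_config(seed = 3), territory_volume = 27)
  lg <- attr(tr, "growth_log")
  expect_true(all(lg$volume_opt <= lg$volume_naive + 1e-12))
})

test_that("radius scaling propagates max-of-daughters with parent caps", {
  pat <- fix_small_patient()
  syn <- grow_synthetic_trees(pat$tree, pat$mesh, pat$map,
                              cco_config(total_terminals = 24, seed = 1))
  tree <- syn$combined
  leaves <- as.integer(names(syn$outlet_of_synthetic))

  # identity scales leave the tree untouched
  id_scales <- setNames(rep(1, length(leaves)), leaves)
  t1 <- apply_radius_scaling(tree, id_scales)
  expect_equal(t1$segments$radius, tree$segments$radius, tolerance = 1e-14)

  # a parent of daughters scaled 1.2 / 0.9 carries factor 1.2
  two <- leaves[1:2]
  seg <- tree$segments
  sc <- setNames(rep(1, length(leaves)), leaves)
  sc[as.character(two)] <- c(1.2, 0.9)
  t2 <- apply_radius_scaling(tree, sc)
  applied <- attr(t2, "applied_scale")
  par_id <- seg$parent[match(two[1], seg$id)]
  par_row <- match(par_id, seg$id)
  if (seg$origin[par_row] == "synthetic") {
    sib <- tree_children(tree)[[as.character(par_id)]]
    expected <- max(sc[as.character(intersect(sib, two))], 0.9)
    # cap may reduce the applied factor but never below the daughters' max
    expect_lte(applied[[as.character(par_id)]], 1.2 + 1e-12)
  }
  # child radius <= parent radius everywhere after scaling
  seg2 <- t2$segments
  pr <- match(seg2$parent, seg2$id)
  hp <- !is.na(pr)
  expect_true(all(seg2$radius[hp] <= seg2$radius[pr[hp]] + 1e-12))

  # idempotence: rescaling the scaled tree with unit factors is a no-op
  t3 <- apply_radius_scaling(t2, id_scales)
  expect_equal(t3$segments$radius, t2$segments$radius, tolerance = 1e-14)

  expect_error(apply_radius_scaling(tree, setNames(-1, leaves[1])),
               "positive")
})

test_that("uniform radius doubling divides path resistance by 16", {
  df <- data.frame(id = 0:2, parent = c(NA, 0L, 1L),
                   x0 = 0, y0 = 0, z0 = c(3, 2, 1),
                   x1 = 0, y1 = 0, z1 = c(2, 1, 0),
                   radius = c(0.1, 0.08, 0.06), origin = "synthetic",
                   perfuses_lv = TRUE)
  tree <- vessel_tree(df, root = 0L, validate = FALSE)
  r1 <- sum(segment_rcl(tree$segments$length, tree$segments$radius)$R)
  t2 <- apply_radius_scaling(tree, c("2" = 2))
  r2 <- sum(segment_rcl(t2$segments$length, t2$segments$radius)$R)
  expect_equal(r1 / r2, 16, tolerance = 1e-12)
})

test_that("terminal counts divide the stated total across territories", {
  pat <- fix_patient()
  counts <- allocate_terminals(pat$map$territory_volume, 500)
  expect_identical(sum(counts), 500L)
  # proportionality up to rounding
  expect_true(all(abs(counts - 500 * pat$map$territory_volume /
                        sum(pat$map$territory_volume)) <= 1))
})
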