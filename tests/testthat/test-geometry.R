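test_that("the packaged vessel table builds the reference network", {
  net <- full_network()
  v <- net$vessels
  expect_equal(sum(v$kind == "artery"), 15)
  expect_equal(sum(v$kind == "vein"), 12)
  expect_equal(nrow(net$beds), 8)
  expect_equal(net$root_artery, "MPA")
  expect_setequal(net$vein_roots, c("LIV", "LSV", "RIV", "RSV"))

  mpa <- v[v$name == "MPA", ]
  expect_equal(mpa$length_cm, 4.30)
  expect_equal(mpa$radius_cm, 1.350)
  expect_setequal(c(mpa$daughter1, mpa$daughter2), c("LPA", "RPA"))
  expect_true(any(net$beds$artery == "LIA D1" & net$beds$vein == "LIV D1"))
  expect_equal(v$A0_cm2, pi * v$radius_cm^2)
})

test_that("malformed vessel tables are rejected with structural errors", {
  tab <- pulmonary_vessel_table()
  bad <- tab
  bad$daughter1[bad$name == "MPA"] <- "NOPE"
  expect_error(build_proximal_network(bad), "not defined")
  dup <- rbind(tab, tab[1, ])
  expect_error(build_proximal_network(dup), "duplicate")
  neg <- tab
  neg$radius_cm[3] <- -1
  expect_error(build_proximal_network(neg), "positive")
})

test_that("structured-tree radii and lengths follow the two-factor scaling law", {
  tr <- generate_tree(0.5, alpha = 0.88, beta = 0.66, lrr = 25, r_min = 0.01)
  nd <- tr$nodes
  expect_equal(nd$radius_cm[nd$i == 0 & nd$j == 0], 0.5)
  expect_equal(nd$radius_cm[nd$i == 1 & nd$j == 1], 0.88 * 0.66 * 0.5)
  expect_equal(nd$radius_cm[nd$i == 1 & nd$j == 1], 0.29040, tolerance = 1e-10)
  expect_equal(nd$length_cm, nd$radius_cm * 25)
  expect_true(all(nd$radius_cm >= tr$r_min))
  # major-only path depth agrees with brute-force iteration r <- alpha * r
  tr2 <- generate_tree(0.5, alpha = 0.86, beta = 0.66, lrr = 25, r_min = 0.005)
  brute <- 0; r <- 0.5 * 0.86
  while (r >= 0.005) { brute <- brute + 1; r <- r * 0.86 }
  expect_equal(brute, 30)
  expect_equal(max(tr2$nodes$i[tr2$nodes$j == 0]), brute)
})

test_that("degenerate and invalid tree requests behave as specified", {
  tr <- generate_tree(0.05, 0.88, 0.66, 25, r_min = 0.1)
  expect_equal(nrow(tr$nodes), 1)
  expect_true(tr$nodes$terminal)
  expect_error(generate_tree(-1, 0.88, 0.66, 25, 0.01), "positive")
  expect_error(generate_tree(0.5, 0.66, 0.88, 25, 0.01), "beta < alpha")
})

test_that("tree size is monotone in the scaling factors and the radius cutoff", {
  base <- c(alpha = 0.86, beta = 0.65, rmin = 4e-3)
  n_of <- function(alpha, beta, rmin) {
    nrow(generate_tree(0.4, alpha, beta, 30, rmin)$nodes)
  }
  for (a in c(0.80, 0.84, 0.88, 0.92)) {
    for (a2 in c(0.80, 0.84, 0.88, 0.92)) {
      if (a2 > a) expect_gte(n_of(a2, 0.65, 4e-3), n_of(a, 0.65, 4e-3))
    }
  }
  for (b in c(0.60, 0.65, 0.70)) {
    for (b2 in c(0.60, 0.65, 0.70)) {
      if (b2 > b) expect_gte(n_of(0.86, b2, 4e-3), n_of(0.86, b, 4e-3))
    }
  }
  for (r1 in c(1e-3, 3e-3, 1e-2)) {
    for (r2 in c(1e-3, 3e-3, 1e-2)) {
      if (r2 > r1) expect_lte(n_of(0.86, 0.65, r2), n_of(0.86, 0.65, r1))
    }
  }
})

test_that("unique-subtree count bounds the literal branch count", {
  tr <- small_bed()$at
  n_unique <- count_unique_subtrees(tr)
  n_total <- count_total_branches(tr)
  expect_lte(n_unique, n_total)
  expect_gt(n_total, n_unique)          # non-degenerate tree shares subtrees
  # full binary tree of G generations: every (i, j) with i + j <= G occurs
  tr_full <- generate_tree(1, 0.75, 0.7, 20, r_min = 0.33)
  G <- max(tr_full$nodes$i + tr_full$nodes$j)
  expect_equal(count_unique_subtrees(tr_full), (G + 1) * (G + 2) / 2)
  expect_equal(count_total_branches(tr_full), 2^(G + 1) - 1)
  # determinism
  tr_b <- generate_tree(0.1, 0.85, 0.68, 20, 0.028)
  expect_identical(count_unique_subtrees(tr_b), count_unique_subtrees(small_bed()$at))
  # degenerate tree: the two counts coincide
  d <- generate_tree(0.05, 0.88, 0.66, 25, r_min = 0.04)
  expect_equal(count_unique_subtrees(d), count_total_branches(d))
})

test_that("the mirrored venous tree shares topology with scaled geometry", {
  at <- small_bed()$at
  vt <- small_bed()$vt
  expect_equal(vt$nodes[, c("i", "j", "terminal")], at$nodes[, c("i", "j", "terminal")])
  expect_equal(vt$nodes$radius_cm, at$nodes$radius_cm * 0.09 / 0.1)
  expect_equal(vt$nodes$length_cm, vt$nodes$radius_cm * 25)
})
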