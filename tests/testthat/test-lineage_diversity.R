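test_that("regional richness reproduces the hand-computed toy values", {
  tt <- toy_tree()

  # one-hot: root = I, CD = I, AB = IV; at t = 0.5 three lineages trace to I
  expect_equal(regional_richness(tt, toy_onehot("I", "IV", "I"), 0.5),
               c(I = 3, IV = 1))

  # probabilistic states at t = 1: origin + root + CD contribute
  expect_equal(regional_richness(tt, toy_probs(), 1), c(I = 2.0, IV = 1.0))

  # above the root age only the origin lineage remains
  expect_equal(regional_richness(tt, toy_probs(), 4), c(I = 0.7, IV = 0.3))
  expect_equal(sum(regional_richness(tt, toy_probs(), 4)), 1)

  # a node with a missing vector is reported by id
  pm <- unclass(toy_probs())
  pm[7, ] <- NA
  bad <- regiodiv:::.new_state_posterior(pm, c("I", "IV"))
  expect_error(regional_richness(tt, bad, 1), "node 7")
})

test_that("node diversity weights richness by the focal node's probabilities", {
  tt <- toy_tree()
  nd <- node_diversity(tt, toy_probs(), 6)  # AB node, age 1
  expect_equal(nd$diversity, 0.1 * 2.0 + 0.9 * 1.0, tolerance = 1e-12)
  expect_true(nd$processed)  # max p = 0.9 >= 0.70

  # 50/50 node: below threshold, flagged unprocessed
  pm <- unclass(toy_probs())
  pm[6, ] <- c(0.5, 0.5)
  half <- regiodiv:::.new_state_posterior(pm, c("I", "IV"))
  expect_false(node_diversity(tt, half, 6)$processed)

  # one-hot states collapse to integer same-region counts
  nd2 <- node_diversity(tt, toy_onehot("I", "IV", "I"), 7)  # CD node, age 2
  expect_equal(nd2$diversity, 2)  # origin + root, both I

  expect_error(node_diversity(tt, toy_probs(), 2), "tip")
})

test_that("diversity_table orders by age, applies the threshold, keeps rows", {
  tt <- toy_tree()
  tab <- diversity_table(tt, toy_onehot("I", "IV", "I"))
  expect_equal(nrow(tab), 3)
  expect_equal(tab$node, c(5, 7, 6))  # oldest first
  expect_true(all(tab$processed))

  pm <- unclass(toy_onehot("I", "IV", "I"))
  pm[6, ] <- c(0.5, 0.5)  # AB node falls below the threshold
  half <- regiodiv:::.new_state_posterior(pm, c("I", "IV"))
  tab2 <- diversity_table(tt, half)
  expect_equal(nrow(tab2), 3)
  expect_equal(sum(tab2$processed), 2)
  # the blanked node still contributes to other nodes' richness sums:
  # at the root only the origin lineage remains
  expect_equal(tab2$lineage_diversity[tab2$node == 5], 1)

  # written table leaves the unprocessed diversity blank but keeps the row
  f <- tempfile(fileext = ".tsv")
  write_node_table(tab2, f)
  body <- utils::read.table(f, header = TRUE, sep = "\t", comment.char = "#",
                            check.names = FALSE)
  expect_equal(nrow(body), 3)
  expect_true(is.na(body$lineage_diversity[body$node == 6]))
})

test_that("richness grid totals match the lineage-through-time counts", {
  tt <- toy_tree()
  res <- richness_through_time(tt, toy_probs(), c(0, 0.5, 1.5, 2.5, 3.5))
  totals <- tapply(res$grid$richness, res$grid$age, sum)
  expect_equal(as.vector(totals), c(4, 4, 3, 2, 1))

  # grid point exactly at a node age is right-continuous (strictly-older set)
  at2 <- richness_through_time(tt, toy_probs(), 2)$grid
  expect_equal(sum(at2$richness), 2)  # origin + root only

  empty <- richness_through_time(tt, toy_probs(), numeric(0))
  expect_equal(nrow(empty$grid), 0)

  # payload flags the nodes whose top region is the focal one
  res2 <- richness_through_time(tt, toy_probs(), 0, flag_region = "IV")
  expect_equal(res2$nodes$flagged[match(c(5, 6, 7), res2$nodes$node)],
               c(FALSE, TRUE, FALSE))
})

test_that("conservation: summed richness equals independent LTT everywhere", {
  set.seed(31)
  for (rep in 1:6) {
    tt <- random_ultrametric(sample(5:40, 1))
    probs <- random_posterior(tt)
    for (t in c(0, stats::runif(25, 0, tt$ages[tt$root] * 1.2))) {
      expect_equal(sum(regional_richness(tt, probs, t)),
                   ltt_crossing(tt, t), tolerance = 1e-9)
    }
  }
})

test_that("diversity lies in [0, LTT(age)] and richness is monotone in probability mass", {
  set.seed(37)
  tt <- random_ultrametric(25)
  probs <- random_posterior(tt)
  internal <- 26:(25 + tt$phy$Nnode)
  for (v in internal) {
    d <- node_diversity(tt, probs, v)$diversity
    expect_gte(d, 0)
    expect_lte(d, lineage_count(tt, tt$ages[v]) + 1e-12)
  }
  # adding probability mass in a region at an old node never decreases the
  # richness of that region at younger ages
  pm <- unclass(probs)
  v_old <- internal[which.max(tt$ages[internal])]
  pm2 <- pm
  pm2[v_old, ] <- c(1, 0, 0, 0)
  bumped <- regiodiv:::.new_state_posterior(pm2, colnames(probs))
  for (t in stats::runif(10, 0, tt$ages[v_old] * 0.99)) {
    expect_gte(regional_richness(tt, bumped, t)[1] + 1e-12,
               regional_richness(tt, probs, t)[1])
  }
})

test_that("relabeling regions permutes richness vectors identically", {
  set.seed(41)
  tt <- random_ultrametric(12)
  probs <- random_posterior(tt, K = 4)
  perm <- c(3, 1, 4, 2)
  pm <- unclass(probs)[, perm]
  permuted <- regiodiv:::.new_state_posterior(pm, colnames(probs)[perm])
  for (t in stats::runif(5, 0, tt$ages[tt$root])) {
    r1 <- regional_richness(tt, probs, t)
    r2 <- regional_richness(tt, permuted, t)
    expect_equal(unname(r2), unname(r1[perm]), tolerance = 1e-12)
  }
})

test_that("convention switches change the sums the way they claim", {
  tt <- toy_tree()
  probs <- toy_probs()
  # no origin: total drops by exactly one everywhere
  expect_equal(sum(regional_richness(tt, probs, 1, include_origin = FALSE)),
               sum(regional_richness(tt, probs, 1)) - 1)
  # inclusive ties: a grid point at a node age now counts that node
  expect_equal(sum(regional_richness(tt, probs, 2, strict_older = FALSE)),
               sum(regional_richness(tt, probs, 2)) + 1)
})

test_that("multifurcating divergences count degree minus one lineages", {
  tt <- read_time_tree(text = "((A:1,B:1,C:1):1,D:2);")
  pm <- matrix(NA_real_, 6, 2)
  pm[5, ] <- c(1, 0)  # root
  pm[6, ] <- c(0, 1)  # trifurcating node, age 1
  probs <- regiodiv:::.new_state_posterior(pm, c("I", "IV"))
  expect_equal(regional_richness(tt, probs, 0.5), c(I = 2, IV = 2))
  expect_equal(sum(regional_richness(tt, probs, 0.5)), lineage_count(tt, 0.5))
})

test_that("a bare node table gives the same diversity as the tree on binary trees", {
  tt <- simulate_yule(30, 1, seed = 9)
  m <- ctmc_model(rate = 0.1)
  truth <- simulate_dispersal(tt, m, root_region = "I", seed = 9)
  probs <- posteriorize(tt, truth, kappa = 50, seed = 9)
  tab_tree <- diversity_table(tt, probs)
  internal <- 31:(30 + tt$phy$Nnode)
  nt <- data.frame(node = internal, age = tt$ages[internal])
  for (j in seq_along(colnames(probs)))
    nt[[colnames(probs)[j]]] <- probs[internal, j]
  tab_flat <- diversity_from_node_table(nt)
  m1 <- tab_tree[order(tab_tree$node), ]
  m2 <- tab_flat[order(tab_flat$node), ]
  expect_equal(m2$lineage_diversity, m1$lineage_diversity, tolerance = 1e-12)
  expect_equal(m2$processed, m1$processed)
})
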