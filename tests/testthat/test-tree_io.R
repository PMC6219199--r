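test_that("parsing computes node counts and ages from branch lengths", {
  tt <- toy_tree()
  expect_equal(tt$n_tip, 4)
  expect_equal(tt$phy$Nnode, 3)
  ages <- node_ages(tt)
  expect_equal(unname(ages[c("A", "B", "C", "D")]), rep(0, 4))
  expect_equal(unname(ages["5"]), 3)  # root
  expect_equal(unname(ages["6"]), 1)  # AB
  expect_equal(unname(ages["7"]), 2)  # CD

  single <- read_time_tree(text = "(A:1);")
  expect_equal(single$n_tip, 1)
  expect_equal(unname(single$ages[single$root]), 1)

  zero <- read_time_tree(text = "((A:0,B:0):0,C:0);")
  expect_true(all(zero$ages == 0))
})

test_that("malformed input and missing branch lengths are rejected with context", {
  expect_error(read_time_tree(text = "((A:1,B:1):2,(C:2,D:2):1;"),
               "unclosed")
  expect_error(read_time_tree(text = "(A:1,B:1)):2;"), "character")
  expect_error(read_time_tree(text = "((A:1,B):1,C:1);"), "B")
})

test_that("non-ultrametric trees are refused, naming the worst tip", {
  expect_error(read_time_tree(text = "((A:3,B:2.9):1,C:4);", tol = 0.01),
               "B")
  # within tolerance: accepted, tips snapped to age 0
  tt <- read_time_tree(text = "((A:3,B:2.9):1,C:4);", tol = 0.2)
  expect_equal(unname(tt$ages[1:3]), rep(0, 3))
})

test_that("node ages are invariant under child-order permutation", {
  a1 <- node_ages(read_time_tree(text = "((A:1,B:1):2,(C:2,D:2):1);"))
  a2 <- node_ages(read_time_tree(text = "((D:2,C:2):1,(B:1,A:1):2);"))
  expect_equal(a1[c("A", "B", "C", "D")], a2[c("A", "B", "C", "D")])
  expect_equal(sort(unname(a1[5:7])), sort(unname(a2[5:7])))
})

test_that("bracketed node annotations round-trip through write and parse", {
  tx <- paste0("((A:1,B:1)[&posterior=0.98,region.prob={0.25,0.75}]:2,",
               "(C:2,D:2)[&posterior=1]:1)[&posterior=0.5]:0;")
  tt <- read_time_tree(text = tx)
  expect_equal(tt$annotations[["6"]]$posterior, 0.98)
  expect_equal(tt$annotations[["6"]]$region.prob, c(0.25, 0.75))
  expect_equal(sum(tt$annotations[["6"]]$region.prob), 1)

  out <- write_time_tree(tt)
  back <- read_time_tree(text = out)
  expect_equal(back$annotations, tt$annotations)
  expect_equal(back$phy$edge, tt$phy$edge)
  expect_equal(back$phy$tip.label, tt$phy$tip.label)
  expect_equal(back$phy$edge.length, tt$phy$edge.length, tolerance = 1e-9)
})

test_that("branch-attached comments are folded onto the subtending node", {
  tx <- "((A:1,B:1):[&rate=0.5]2,(C:2,D:2)[&posterior=1]:1);"
  tt <- read_time_tree(text = tx)
  expect_equal(tt$annotations[["6"]]$rate, 0.5)
})

test_that("NEXUS trees with translate tables and comments are read", {
  nex <- paste(
    "#NEXUS",
    "Begin trees;",
    "  Translate",
    "    1 A,",
    "    2 B,",
    "    3 C,",
    "    4 D;",
    "tree STATE_1 = [&R] ((1:1,2:1)[&posterior=0.9]:2,(3:2,4:2):1);",
    "End;", sep = "\n")
  tt <- read_time_tree(text = nex)
  expect_setequal(tt$phy$tip.label, c("A", "B", "C", "D"))
  expect_equal(unname(tt$ages[tt$root]), 3)
  expect_equal(tt$annotations[["6"]]$posterior, 0.9)
})

test_that("round-trip preserves topology and durations on simulated trees", {
  tt <- simulate_yule(40, 1, seed = 5)
  back <- read_time_tree(text = write_time_tree(tt))
  expect_equal(back$phy$tip.label, tt$phy$tip.label)
  expect_equal(back$phy$edge, tt$phy$edge)
  expect_equal(back$phy$edge.length, tt$phy$edge.length, tolerance = 1e-9)
})

test_that("attach_state_probabilities matches by node id or clade and normalizes", {
  tt <- toy_tree()
  tab <- data.frame(node = c(5, 6, 7),
                    I = c(0.7, 0.1, 0.6), IV = c(0.3, 0.9, 0.4))
  sp <- attach_state_probabilities(tt, tab, regions = c("I", "IV"))
  expect_equal(sp[5, ], c(I = 0.7, IV = 0.3))

  tab2 <- data.frame(clade = c("A,B,C,D", "A,B", "C,D"),
                     I = c(0.7, 0.1, 0.6), IV = c(0.3, 0.9, 0.4))
  sp2 <- attach_state_probabilities(tt, tab2, regions = c("I", "IV"))
  expect_equal(unclass(sp2), unclass(sp), ignore_attr = TRUE)

  # mild deficit renormalized
  tab3 <- data.frame(node = c(5, 6, 7),
                     I = c(0.5, 0.1, 0.6), IV = c(0.499, 0.9, 0.4))
  sp3 <- attach_state_probabilities(tt, tab3, regions = c("I", "IV"))
  expect_equal(sp3[5, ], c(I = 0.5, IV = 0.499) / 0.999, tolerance = 1e-12)

  # deficit beyond 0.05 refused
  tab4 <- data.frame(node = c(5, 6, 7),
                     I = c(0.5, 0.1, 0.6), IV = c(0.4, 0.9, 0.4))
  expect_error(attach_state_probabilities(tt, tab4, regions = c("I", "IV")),
               "refusing")

  # tips get one-hot vectors from their region assignment
  sp5 <- attach_state_probabilities(
    tt, tab, regions = c("I", "IV"),
    tip_regions = c(A = "IV", B = "IV", C = "I", D = "I"))
  expect_equal(sp5[1, ], c(I = 0, IV = 1))
  expect_equal(sp5[3, ], c(I = 1, IV = 0))

  # unmatched clade and duplicate/missing matches are errors
  bad <- data.frame(clade = c("A,B,C,D", "A,C", "C,D"),
                    I = c(1, 1, 1), IV = c(0, 0, 0))
  expect_error(attach_state_probabilities(tt, bad, regions = c("I", "IV")),
               "A,C")
  dup <- data.frame(node = c(5, 5, 7), I = c(1, 1, 1), IV = c(0, 0, 0))
  expect_error(attach_state_probabilities(tt, dup, regions = c("I", "IV")),
               "more than one")
  part <- data.frame(node = c(5, 7), I = c(1, 1), IV = c(0, 0))
  expect_error(attach_state_probabilities(tt, part, regions = c("I", "IV")),
               "no probability row")
})

test_that("strict-clock rescaling divides durations by the rate", {
  phy <- ape::read.tree(text = "((A:0.0412,B:0.0412):0.0412,C:0.0824);")
  tt <- scale_to_time(phy, 0.0206)
  expect_equal(unname(tt$ages[tt$root]), 4, tolerance = 1e-9)
  e <- which(tt$phy$edge[, 2] == which(tt$phy$tip.label == "A"))
  expect_equal(tt$phy$edge.length[e], 2, tolerance = 1e-9)

  # interval: lower rate gives older ages; 0.025 / rate at both endpoints
  phy2 <- ape::read.tree(text = "(A:0.025,B:0.025);")
  pair <- scale_to_time(phy2, c(0.0125, 0.0206))
  expect_equal(unname(pair$older$ages[3]), 2.0, tolerance = 1e-9)
  expect_equal(unname(pair$younger$ages[3]), 0.025 / 0.0206, tolerance = 1e-6)
  expect_gt(pair$older$ages[3], pair$younger$ages[3])

  # rescaling back recovers substitution lengths
  tt3 <- scale_to_time(phy, 0.0125)
  expect_equal(tt3$phy$edge.length * 0.0125,
               phy$edge.length[match(tt3$phy$edge[, 2], phy$edge[, 2])],
               tolerance = 1e-12)
  expect_error(scale_to_time(phy, 0), "positive")
})

test_that("node tables render estimates to three significant figures", {
  expect_equal(fmt_sig3(c(0.0977, 0.999, 121, 5.8421)),
               c("0.0977", "0.999", "121", "5.84"))

  rec <- data.frame(node = 20L, age_mean = 0.0977, age_lower = 0.0018,
                    age_upper = 0.272, support = 1.00,
                    I = 0.0008, II = 0.0001, III = 0, IV = 0.999,
                    lineage_diversity = 121.04, processed = TRUE)
  attr(rec, "regions") <- c("I", "II", "III", "IV")
  attr(rec, "conventions") <- list(include_origin = TRUE)
  f <- tempfile(fileext = ".tsv")
  write_node_table(rec, f)
  lines <- readLines(f)
  expect_true(any(startsWith(lines, "# include_origin=TRUE")))
  row <- strsplit(lines[length(lines)], "\t")[[1]]
  expect_equal(row[2], "0.0977")
  expect_equal(row[9], "0.999")
  expect_equal(row[10], "121")

  # empty record list -> header-only file
  f2 <- tempfile(fileext = ".tsv")
  write_node_table(rec[0, , drop = FALSE], f2)
  body <- grep("^#", readLines(f2), invert = TRUE, value = TRUE)
  expect_length(body, 1)
})
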