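tri_cells <- function(types = c("A", "A", "B")) {
  cell_table(data.frame(roi_id = "t", cell_id = c("p", "q", "r"),
                        x = c(0, 30, 0), y = c(0, 0, 40),
                        cell_type = types, stringsAsFactors = FALSE))
}

test_that("proximity graph prunes the right triangle as expected", {
  g <- build_proximity_graph(tri_cells(), max_edge_len = 50)
  expect_equal(nrow(g$edges), 3L)  # 30, 40, 50; the 50 um hypotenuse is kept
  expect_setequal(round(g$edges$length_um, 9), c(30, 40, 50))

  g45 <- build_proximity_graph(tri_cells(), max_edge_len = 45)
  expect_equal(nrow(g45$edges), 2L)
  expect_setequal(round(g45$edges$length_um, 9), c(30, 40))
})

test_that("degenerate inputs fall back to complete-graph-then-prune", {
  two <- cell_table(data.frame(roi_id = "d", cell_id = c("a", "b"),
                               x = c(0, 10), y = c(0, 0),
                               cell_type = c("A", "B"), stringsAsFactors = FALSE))
  g <- build_proximity_graph(two, 50)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$length_um, 10)

  col <- cell_table(data.frame(roi_id = "d", cell_id = letters[1:4],
                               x = c(0, 10, 20, 90), y = rep(3, 4),
                               cell_type = c("A", "A", "B", "B"),
                               stringsAsFactors = FALSE))
  gc <- build_proximity_graph(col, 50)
  # all 6 pairwise links considered, those within 50 um kept
  expect_equal(sort(gc$edges$length_um), c(10, 10, 20))

  dup <- cell_table(data.frame(roi_id = "d", cell_id = c("a", "b", "c", "e"),
                               x = c(0, 0, 30, 0), y = c(0, 0, 0, 40),
                               cell_type = c("A", "B", "A", "B"),
                               stringsAsFactors = FALSE))
  expect_message(gd <- build_proximity_graph(dup, 50), "jittered")
  expect_true(gd$jittered)
  expect_gte(nrow(gd$edges), 3L)
})

test_that("edges are classified by type pair and other labels are ignored", {
  g <- build_proximity_graph(tri_cells(), 50)
  cc <- classify_edges(g, "A", "B")
  expect_equal(cc[c("nA", "nB", "eAA", "eAB", "eBB")],
               list(nA = 2L, nB = 1L, eAA = 1L, eAB = 2L, eBB = 0L))

  far <- cell_table(data.frame(roi_id = "f", cell_id = c("a", "b", "c"),
                               x = c(0, 500, 0), y = c(0, 0, 500),
                               cell_type = c("A", "A", "B"),
                               stringsAsFactors = FALSE))
  cf <- classify_edges(build_proximity_graph(far, 50), "A", "B")
  expect_equal(cf$eAA + cf$eBB + cf$eAB, 0L)

  expect_error(classify_edges(g, "A", "A"), "must differ")
  expect_error(classify_edges(g, "A", "Z"), "'Z' absent.*t")
})

test_that("a third cell type leaves two-type counts untouched", {
  ct <- random_roi(40, seed = 11, field = 250, types = c("EPI", "IMM", "MLC"))
  g <- build_proximity_graph(ct, 50)
  cc <- classify_edges(g, "EPI", "IMM")
  bf <- brute_force_classify(g, "EPI", "IMM")
  expect_equal(cc[c("nA", "nB", "eAA", "eBB", "eAB")], bf)
  # equivalently: delete every edge incident to an MLC cell first
  mlc <- which(g$nodes$cell_type == "MLC")
  g2 <- g
  g2$edges <- g$edges[!(g$edges$ia %in% mlc | g$edges$ib %in% mlc), ]
  cc2 <- classify_edges(g2, "EPI", "IMM")
  expect_equal(cc2[c("eAA", "eBB", "eAB")], cc[c("eAA", "eBB", "eAB")])
})

test_that("graph invariants hold over random ROIs", {
  for (seed in 1:10) {
    ct <- random_roi(35, seed = seed, field = 220)
    g <- build_proximity_graph(ct, 50)
    n <- nrow(g$nodes)
    # planar triangulation bound
    expect_lte(nrow(g$edges), 3 * n - 6)
    expect_true(all(g$edges$length_um <= 50))
    expect_false(any(g$edges$ia == g$edges$ib))
    expect_false(any(duplicated(g$edges[, c("ia", "ib")])))
    # two-type ROI: every edge falls in exactly one class
    cc <- classify_edges(g, "EPI", "IMM")
    expect_equal(cc$eAA + cc$eBB + cc$eAB, nrow(g$edges))
    # classification is symmetric in the two labels
    sw <- classify_edges(g, "IMM", "EPI")
    expect_equal(list(sw$nA, sw$nB, sw$eAA, sw$eBB, sw$eAB),
                 list(cc$nB, cc$nA, cc$eBB, cc$eAA, cc$eAB))
    # edge sets shrink monotonically with the cutoff
    key <- function(gg) paste(gg$edges$ia, gg$edges$ib)
    g30 <- build_proximity_graph(ct, 30)
    g40 <- build_proximity_graph(ct, 40)
    expect_true(all(key(g30) %in% key(g40)))
    expect_true(all(key(g40) %in% key(g)))
  }
})

test_that("kept edges satisfy the empty-circumcircle characterization", {
  for (seed in c(3, 17)) {
    ct <- random_roi(25, seed = seed, field = 200)
    g <- build_proximity_graph(ct, 1e6)  # no pruning: the full triangulation
    x <- g$nodes$x; y <- g$nodes$y
    for (k in seq_len(nrow(g$edges))) {
      expect_true(delaunay_edge_oracle(x, y, g$edges$ia[k], g$edges$ib[k]))
    }
    # and non-edges fail it
    key <- paste(g$edges$ia, g$edges$ib)
    non <- 0L
    for (i in 1:24) for (j in (i + 1):25) {
      if (!(paste(i, j) %in% key) && non < 30L) {
        non <- non + 1L
        expect_false(delaunay_edge_oracle(x, y, i, j))
      }
    }
  }
})
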