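test_that("node activity is the per-sample mean of member genes", {
  m <- tiny_expr(rbind(c(1, 5), c(3, 7), c(10, 20)),
                 genes = c("g1", "g2", "g3"))
  one <- fake_node("n1", "g3")
  expect_equal(unname(node_activity(m, list(one))[1L, ]),
               unname(m$values["g3", ]))

  pair <- fake_node("n2", c("g1", "g2"))
  expect_equal(unname(node_activity(m, list(pair))[1L, ]), c(2, 6))
  flipped <- fake_node("n2", c("g2", "g1"))
  expect_equal(node_activity(m, list(flipped)),
               node_activity(m, list(pair)))

  expect_error(node_activity(m, list(fake_node("nx", "absent"))),
               "absent.*nx")
})

test_that("metanode clustering separates planted activity blocks", {
  set.seed(41)
  base1 <- rnorm(60); base2 <- rnorm(60)
  act <- rbind(n1 = base1 + rnorm(60, sd = 0.2),
               n2 = base1 + rnorm(60, sd = 0.2),
               n3 = base2 + rnorm(60, sd = 0.2),
               n4 = base2 + rnorm(60, sd = 0.2))
  cl <- cluster_metanodes(act, cut_height = 0.5)
  expect_equal(length(unique(cl$partition)), 2L)
  expect_equal(cl$partition[["n1"]], cl$partition[["n2"]])
  expect_equal(cl$partition[["n3"]], cl$partition[["n4"]])
  expect_false(cl$partition[["n1"]] == cl$partition[["n3"]])
  expect_true(!is.unsorted(cl$dendrogram$height))

  ident <- rbind(a = base1, b = base1, c = base2)
  cl2 <- cluster_metanodes(ident, cut_height = 0.1)
  merge_h <- cl2$dendrogram$height[1L]
  expect_equal(merge_h, 0, tolerance = 1e-12)

  expect_error(cluster_metanodes(rbind(a = rep(1, 10), b = rnorm(10))),
               "constant")
})

test_that("roles attach to metanodes by marker enrichment", {
  mk <- default_markers()
  bg <- c(mk$luminal, mk$basal, mk$claudin, mk$immune,
          sprintf("F%03d", 1:300))
  nodes <- list(
    fake_node("node_01", c(mk$immune, sprintf("F%03d", 1:10))),
    fake_node("node_02", c(mk$claudin, sprintf("F%03d", 11:40))),
    fake_node("node_03", c(mk$luminal, sprintf("F%03d", 41:50))),
    fake_node("node_04", c(mk$basal, sprintf("F%03d", 51:60))),
    fake_node("node_05", sprintf("F%03d", 61:90)))
  act <- matrix(rnorm(5 * 40), 5,
                dimnames = list(sprintf("node_%02d", 1:5), NULL))
  clustering <- list(partition = setNames(1:5, rownames(act)))
  roles <- assign_roles(clustering, nodes, mk, bg)
  tab <- roles$table
  expect_identical(tab$role[tab$node_id == "node_01"], "immune")
  expect_identical(tab$role[tab$node_id == "node_03"], "luminal")
  expect_identical(tab$role[tab$node_id == "node_04"], "basal")
  expect_identical(tab$role[tab$node_id == "node_05"], "other")
  expect_identical(roles$claudin_node, "node_02")
  expect_setequal(roles$metanode_genes$immune,
                  c(mk$immune, sprintf("F%03d", 1:10)))

  # two metanodes claiming the same role is an error
  nodes2 <- c(nodes, list(fake_node("node_06",
                                    c(mk$immune, sprintf("F%03d", 91:95)))))
  clustering2 <- list(partition = setNames(1:6, sprintf("node_%02d", 1:6)))
  expect_error(assign_roles(clustering2, nodes2, mk, bg), "immune")
})

test_that("metanode activity equals the weighted mean of node activities", {
  set.seed(43)
  m <- tiny_expr(matrix(rnorm(8 * 12), 8))
  n1 <- fake_node("n1", m$gene_ids[1:3])
  n2 <- fake_node("n2", m$gene_ids[4:8])
  act <- node_activity(m, list(n1, n2))
  union_act <- metanode_activity(m, m$gene_ids[1:8])
  expect_equal(union_act, (3 * act["n1", ] + 5 * act["n2", ]) / 8)
})
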