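toy_pdb <- system.file("extdata", "toy_chain_synthetic.pdb",
                       package = "cpmgdisp")

test_that("the packaged toy chain loads with the declared policies", {
  sm <- load_structure(toy_pdb)
  expect_s3_class(sm, "structure_model")
  expect_equal(nrow(sm$residues), 12)
  expect_false(any(sm$atoms$elesy %in% c("H", "D")))
  expect_true(all(is.finite(sm$atoms$x)))
  # glycine has no CB
  expect_false("CB" %in% sm$atoms$elety[sm$atoms$resno == 12])
})

test_that("model selection and alternate locations follow the policy", {
  # two-model file: model 2 shifted by 10 A
  path <- withr::local_tempfile(fileext = ".pdb")
  m1 <- c(pdb_atom(1, "N", "ALA", "A", 1, 0, 0, 0),
          pdb_atom(2, "CA", "ALA", "A", 1, 1.4, 0, 0))
  m2 <- c(pdb_atom(1, "N", "ALA", "A", 1, 10, 0, 0),
          pdb_atom(2, "CA", "ALA", "A", 1, 11.4, 0, 0))
  writeLines(c("MODEL     1", m1, "ENDMDL", "MODEL     2", m2, "ENDMDL",
               "END"), path)
  expect_equal(load_structure(path)$atoms$x, c(0, 1.4))
  expect_equal(load_structure(path, model_index = 2)$atoms$x, c(10, 11.4))
  expect_error(load_structure(path, model_index = 3), "out of range")
  # altloc: the higher-occupancy copy wins
  path2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_atom(1, "CA", "ALA", "A", 1, 0, 0, 0, occ = 0.4,
                        alt = "A"),
               pdb_atom(2, "CA", "ALA", "A", 1, 5, 0, 0, occ = 0.6,
                        alt = "B"),
               "END"), path2)
  sm <- load_structure(path2)
  expect_equal(nrow(sm$atoms), 1)
  expect_equal(sm$atoms$x, 5)
})

test_that("a missing chain is reported with the available ones", {
  expect_error(load_structure(toy_pdb, chain = "B"), "available: A")
  expect_equal(nrow(load_structure(toy_pdb, chain = "A")$residues), 12)
})

test_that("interaction typing follows the declared geometric rules", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_engineered_pdb(path)
  sm <- load_structure(path)
  # alanines with CB atoms 4.0 A apart: hydrophobic
  cl <- classify_interaction(sm, 1, 3)
  expect_identical(cl$types, "hydrophobic")
  # sequence neighbours are covalent regardless of separation
  expect_true("covalent" %in% classify_interaction(sm, 1, 2)$types)
  expect_true("covalent" %in% classify_interaction(sm, 4, 5)$types)
  # backbone O..N at 3.2 A: hydrogen bond
  expect_identical(classify_interaction(sm, 2, 4)$types, "hydrogen_bond")
  # close but nothing stronger: proximal
  expect_identical(classify_interaction(sm, 3, 5)$types, "proximal_6A")
  # beyond 6 A: no edge
  expect_length(classify_interaction(sm, 1, 5)$types, 0)
  expect_gt(classify_interaction(sm, 1, 5)$min_distance, 6)
  expect_error(classify_interaction(sm, 3, 3), "differ")
})

test_that("atoms exactly at and just beyond the 6 A rule split correctly", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_atom(1, "CA", "GLY", "A", 1, 0, 0, 0),
               pdb_atom(2, "CA", "GLY", "A", 5, 6.2, 0, 0),
               pdb_atom(3, "CA", "GLY", "A", 9, 12.2, 0, 0),
               "END"), path)
  sm <- load_structure(path)
  expect_length(classify_interaction(sm, 1, 5)$types, 0)   # 6.2 A: nothing
  expect_identical(classify_interaction(sm, 5, 9)$types, "proximal_6A")
})

test_that("the contact graph matches the hand-computed edge list", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_engineered_pdb(path)
  sm <- load_structure(path)
  cg <- build_contact_graph(sm)
  got <- cg$edges[, c("res_i", "res_j", "type")]
  want <- data.frame(
    res_i = c(1, 1, 2, 2, 3, 3, 4),
    res_j = c(2, 3, 3, 4, 4, 5, 5),
    type = c("covalent", "hydrophobic", "covalent", "hydrogen_bond",
             "covalent", "proximal_6A", "covalent"))
  want <- want[order(want$res_i, want$res_j, want$type), ]
  rownames(want) <- NULL
  expect_equal(got, want)
  # prefiltered and brute-force graphs are identical
  cg_bf <- build_contact_graph(sm, prefilter = FALSE)
  expect_equal(cg$edges, cg_bf$edges)
  # re-classification from coordinates reproduces the stored edges
  for (k in seq_len(nrow(cg$edges))) {
    cl <- classify_interaction(sm, cg$edges$res_i[k], cg$edges$res_j[k])
    expect_true(cg$edges$type[k] %in% cl$types)
    expect_equal(cl$min_distance, cg$edges$distance[k])
  }
})

test_that("node annotations decorate but do not change topology", {
  sm <- load_structure(toy_pdb)
  ann <- c(`3` = "exchanging", `7` = "cluster", `9` = "both")
  cg <- build_contact_graph(sm, annotations = ann)
  cg_perm <- build_contact_graph(sm, annotations = rev(ann))
  cg_none <- build_contact_graph(sm)
  expect_equal(cg$edges, cg_perm$edges)
  expect_equal(cg$edges, cg_none$edges)
  expect_identical(cg$nodes$category[cg$nodes$resno == 7], "cluster")
  expect_identical(cg_none$nodes$category, rep("none", 12))
})

test_that("path finding restricts intermediates to dynamic or cluster nodes", {
  # engineered graph: 1-2-3-4 chain bridged by 1-5-4; only 2, 3 dynamic
  edges <- data.frame(res_i = c(1, 2, 3, 1, 5),
                      res_j = c(2, 3, 4, 5, 4))
  cg <- make_contact_graph(edges)
  out <- find_connecting_paths(cg, cluster_nodes = c(1, 4),
                               dynamic_nodes = c(2, 3))
  expect_equal(out$paths$path, "1-2-3-4")
  expect_equal(out$paths$length, 3L)
  # adjacent cluster pair: direct edge
  out2 <- find_connecting_paths(cg, cluster_nodes = c(1, 2),
                                dynamic_nodes = integer(0))
  expect_equal(out2$paths$path, "1-2")
  expect_equal(out2$paths$length, 1L)
  # no dynamic nodes and no direct edge: unreachable, reported not raised
  out3 <- find_connecting_paths(cg, cluster_nodes = c(1, 4),
                                dynamic_nodes = integer(0))
  expect_equal(nrow(out3$paths), 0)
  expect_equal(out3$unreachable, data.frame(from = 1, to = 4))
  # a node absent from the graph is an error
  expect_error(find_connecting_paths(cg, c(1, 99), c(2, 3)), "99")
})

test_that("shortest qualifying paths agree with exhaustive enumeration", {
  sm <- load_structure(toy_pdb)
  cg <- build_contact_graph(sm)
  adj <- graph_adjacency(cg)
  set.seed(17)
  for (i in 1:12) {
    cluster <- sort(sample(1:12, 2))
    dynamic <- sample(setdiff(1:12, cluster), sample(3:8, 1))
    out <- find_connecting_paths(cg, cluster, dynamic, max_len = 6)
    allowed <- union(cluster, dynamic)
    all_paths <- enumerate_paths(adj, cluster[1], cluster[2], allowed, 6)
    if (length(all_paths) == 0) {
      expect_equal(nrow(out$paths), 0)
      expect_equal(nrow(out$unreachable), 1)
    } else {
      shortest <- min(lengths(all_paths)) - 1
      want <- sort(vapply(
        Filter(function(p) length(p) - 1 == shortest, all_paths),
        paste, character(1), collapse = "-"))
      expect_equal(sort(out$paths$path), want)
      expect_true(all(out$paths$length == shortest))
    }
  }
})

test_that("sphere scripts are deterministic and ordered", {
  empty <- export_sphere_script(setNames(character(0), character(0)))
  expect_length(empty, 4)  # header only
  cat_map <- c(`12` = "two_site_fittable", `3` = "two_site_fittable",
               `7` = "broadened_unfittable")
  s <- export_sphere_script(cat_map)
  purple <- grep("color purple", s, value = TRUE)
  expect_length(purple, 2)
  expect_true(grepl("resi 3 ", purple[1]))   # ascending residue order
  expect_true(grepl("resi 12 ", purple[2]))
  expect_length(grep("color pink", s), 1)
  expect_identical(s, export_sphere_script(cat_map))
})
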