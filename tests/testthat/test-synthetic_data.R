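test_that("planted orthologs and decoys are counted and bounded as requested", {
  sim <- generate_network_pair(n = 40, ortholog_fraction = 1, decoy_rate = 0,
                               seed = 2)
  expect_equal(nrow(sim$labels), 40)
  expect_equal(nrow(sim$homology), 40)
  expect_identical(sim$homology$node_a, sim$labels$node_a)
  expect_true(all(sim$homology$score >= 1))
  # averaged score is exactly the mean of the two directions
  expect_equal(sim$homology$score,
               (sim$homology$score_ab + sim$homology$score_ba) / 2)

  expect_error(generate_network_pair(n = 5), "at least 10")
  expect_error(generate_network_pair(decoy_rate = 2), "lie in")
})

test_that("zero rewiring copies the topology; rewired copies stay simple graphs", {
  sim0 <- generate_network_pair(n = 30, rewire_rate = 0, seed = 3)
  el1 <- igraph::as_edgelist(sim0$g1)
  el2 <- igraph::as_edgelist(sim0$g2)
  expect_identical(sub("^a", "", as.vector(el1)), sub("^b", "", as.vector(el2)))

  sim <- generate_network_pair(n = 30, rewire_rate = 0.5, seed = 3)
  expect_false(igraph::any_multiple(sim$g2))
  expect_false(any(igraph::which_loop(sim$g2)))
  expect_equal(igraph::ecount(sim$g2), igraph::ecount(sim$g1))
})

test_that("identical seeds reproduce the simulation bit for bit; different seeds differ", {
  s1 <- generate_network_pair(seed = 7)
  s2 <- generate_network_pair(seed = 7)
  expect_identical(s1$homology, s2$homology)
  expect_identical(igraph::as_edgelist(s1$g2), igraph::as_edgelist(s2$g2))
  s3 <- generate_network_pair(seed = 8)
  expect_false(identical(s1$homology, s3$homology))
})

test_that("noiseless expression modules are perfectly rank-correlated; one module gives a clique", {
  ep <- generate_expression_pair(n_genes = 12, n_tissues = 8, module_count = 3,
                                 noise_sd = 0, seed = 4)
  g <- build_coexpression_network(ep$expr1, cutoff = 0.8)
  mods <- split(ep$modules$gene1, ep$modules$module)
  for (mod in mods) {
    for (i in seq_along(mod)) {
      for (j in seq_len(i - 1)) {
        expect_true(igraph::are_adjacent(g, mod[i], mod[j]))
      }
    }
  }

  one_mod <- generate_expression_pair(n_genes = 6, n_tissues = 8,
                                      module_count = 1, noise_sd = 0, seed = 5)
  g1 <- build_coexpression_network(one_mod$expr1, cutoff = 0.8)
  expect_equal(igraph::ecount(g1), choose(6, 2))
  expect_true(all(igraph::E(g1)$weight == 1))

  expect_identical(generate_expression_pair(seed = 6)$expr1,
                   generate_expression_pair(seed = 6)$expr1)
  expect_error(generate_expression_pair(n_tissues = 3), "at least 5")
})

test_that("orthologous genes across species are strongly coexpressed with their module partners", {
  ep <- generate_expression_pair(n_genes = 20, n_tissues = 10, module_count = 4,
                                 noise_sd = 0.2, seed = 9)
  # cross-species profiles of the same gene index share a latent profile
  v1 <- as.numeric(ep$expr1[1, -1])
  v2 <- as.numeric(ep$expr2[1, -1])
  expect_gt(abs(spearman_rho(v1, v2)), 0.8)
})

test_that("written study files are valid pipeline inputs", {
  dir <- withr::local_tempdir()
  sim <- generate_network_pair(n = 25, seed = 10)
  ep <- generate_expression_pair(n_genes = 10, n_tissues = 6, seed = 10)
  paths <- write_synthetic_files(sim, dir, expression = ep)
  # isolated nodes are encoded as self-loops, so loading warns by design
  g1 <- suppressWarnings(load_graph(file.path(dir, "network1.tsv"),
                                    species_tag = "A"))
  expect_equal(igraph::ecount(g1), igraph::ecount(sim$g1))
  ab <- parse_blast_tabular(file.path(dir, "blast_ab.tsv"))
  ba <- parse_blast_tabular(file.path(dir, "blast_ba.tsv"))
  P <- suppressMessages(average_bidirectional(ab, ba))
  expect_equal(nrow(P), nrow(sim$homology))
  expect_equal(sort(P$score), sort(round(sim$homology$score_ab, 2) / 2 +
                                     round(sim$homology$score_ba, 2) / 2))
  expr <- read_expression(file.path(dir, "expression1.tsv"))
  expect_identical(dim(expr), dim(ep$expr1))
})
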