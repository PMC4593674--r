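test_that("edge loading merges reciprocal duplicates and applies the cutoff", {
  edges <- data.frame(protein1 = c("A", "B", "A", "C", "C"),
                      protein2 = c("B", "A", "B", "C", "D"),
                      combined_score = c(700, 900, 650, 999, 300))
  g <- interaction_network(edges, min_score = 400)
  expect_equal(igraph::gorder(g), 2)  # C-D below cutoff, C-C self loop
  expect_equal(igraph::gsize(g), 1)
  expect_identical(igraph::E(g)$combined_score, 900)
  expect_identical(igraph::graph_attr(g, "n_self_loops_dropped"), 1L)
  expect_equal(igraph::gsize(interaction_network(edges,
                                                   min_score = 950)), 0)
  expect_error(interaction_network(data.frame(protein1 = "A",
                                              protein2 = "B",
                                              combined_score = 1200)),
               "\\[0, 1000\\]")

  # dedup on random edge lists matches an independent pass, and loading
  # is order-independent
  set.seed(3)
  rnd <- data.frame(protein1 = sample(LETTERS[1:12], 400, TRUE),
                    protein2 = sample(LETTERS[1:12], 400, TRUE),
                    combined_score = sample(0:1000, 400, TRUE))
  g1 <- interaction_network(rnd, min_score = 0)
  g2 <- interaction_network(rnd[sample(400), ], min_score = 0)
  key <- function(g) {
    el <- igraph::as_edgelist(g)
    sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]),
               igraph::E(g)$combined_score))
  }
  expect_identical(key(g1), key(g2))
  # oracle dedup
  rnd2 <- rnd[rnd$protein1 != rnd$protein2, ]
  ok <- paste(pmin(rnd2$protein1, rnd2$protein2),
              pmax(rnd2$protein1, rnd2$protein2))
  oracle <- sort(paste(names(tapply(rnd2$combined_score, ok, max)),
                       tapply(rnd2$combined_score, ok, max)))
  expect_identical(key(g1), oracle)
})

test_that("connectivity summary counts connected focal proteins and hubs", {
  g <- interaction_network(data.frame(protein1 = "A", protein2 = "B",
                                      combined_score = 700))
  cs <- connectivity_summary(g, c("A", "B", "C"))
  expect_identical(cs$n_connected, 2L)
  expect_identical(cs$hubs$protein[1:2], c("A", "B"))  # tie broken A first
  expect_identical(cs$hubs$degree, c(1L, 1L, 0L))
  cs0 <- connectivity_summary(g, "C")
  expect_identical(cs0$n_connected, 0L)

  fx <- make_network_fixture(n_proteins = 40, n_clusters = 4,
                             within_edge_prob = 1, between_edge_prob = 0.02,
                             seed = 8)
  net <- interaction_network(fx$edges, min_score = 0)
  # brute-force recount of degrees >= 1 within the focal induced subgraph
  focal <- fx$truth$membership$protein[fx$truth$membership$cluster == 1]
  el <- fx$edges[fx$edges$protein1 %in% focal & fx$edges$protein2 %in% focal, ]
  touched <- unique(c(el$protein1, el$protein2))
  expect_identical(connectivity_summary(net, focal)$n_connected,
                   length(touched))
})

test_that("category mapping unions labels across a node's GO terms", {
  ann <- data.frame(gene = c("A", "A", "B", "C"),
                    term = c("GO:1", "GO:2", "GO:2", "GO:3"))
  groups <- list(muscle = "GO:1", nervous = c("GO:2"))
  g <- interaction_network(data.frame(protein1 = c("A", "B"),
                                      protein2 = c("B", "C"),
                                      combined_score = c(900, 900)))
  lab <- map_categories(g, ann, groups)
  expect_setequal(lab$A, c("muscle", "nervous"))
  expect_identical(lab$B, "nervous")
  expect_identical(lab$C, character(0))
  expect_error(map_categories(g, ann, list(x = "GO:404")), "absent")

  # random fixture: labels equal a set-union oracle
  fx <- make_network_fixture(seed = 21)
  net <- interaction_network(fx$edges, min_score = 0)
  groups2 <- stats::setNames(as.list(sapply(fx$truth$planted_terms, `[`, 1)),
                             paste0("cat", seq_along(fx$truth$planted_terms)))
  lab2 <- map_categories(net, fx$annotation, groups2)
  for (v in sample(names(lab2), 10)) {
    terms_v <- fx$annotation$term[fx$annotation$gene == v]
    expect_setequal(lab2[[v]],
                    names(groups2)[sapply(groups2,
                                          function(gt) any(terms_v %in% gt))])
  }
})

test_that("category clustering finds planted modules and is calibrated at
           the trivial boundary", {
  fx <- make_network_fixture(n_proteins = 60, n_clusters = 4,
                             within_edge_prob = 0.8,
                             between_edge_prob = 0, seed = 5)
  net <- interaction_network(fx$edges, min_score = 0)
  groups <- stats::setNames(lapply(fx$truth$planted_terms, identity),
                            paste0("cat", 1:4))
  lab <- map_categories(net, fx$annotation, groups)
  res <- category_clustering(net, lab, "cat1", n_permutations = 499,
                             seed = 2)
  expect_lte(res$p_value, 0.05)
  expect_gt(res$observed, 0)
  expect_true(res$p_value > 0 && res$p_value <= 1)

  # all nodes carrying the category: observed fraction 1, p = 1
  lab_all <- stats::setNames(rep(list("cat1"), igraph::gorder(net)),
                             igraph::V(net)$name)
  res_all <- category_clustering(net, lab_all, "cat1",
                                 n_permutations = 199, seed = 3)
  expect_identical(res_all$observed, 1)
  expect_identical(res_all$p_value, 1)
  expect_error(category_clustering(net, lab, "nope", 199), "absent")
})

test_that("Fisher enrichment equals the hypergeometric-sum oracle and
           recovers planted terms", {
  # hand-checkable configuration
  universe <- sprintf("g%03d", 1:100)
  selected <- universe[1:10]
  ann <- data.frame(gene = universe,
                    term = rep("GO:ALL", 100))
  extra <- data.frame(gene = c(universe[1:5], universe[11:15]),
                      term = "GO:HIT")
  res <- fisher_enrichment(selected, universe, rbind(ann, extra))
  hit <- res[res$term == "GO:HIT", ]
  expect_equal(hit$p, oracle_hyper_tail(5, 10, 10, 100), tolerance = 1e-12)
  all_row <- res[res$term == "GO:ALL", ]
  expect_equal(all_row$p, 1)

  # random 2x2 tables against the explicit sum
  set.seed(77)
  for (rep in 1:30) {
    N <- sample(30:120, 1); n <- sample(5:20, 1)
    K <- sample(3:25, 1)
    uni <- sprintf("u%03d", 1:N)
    sel <- sample(uni, n)
    members <- sample(uni, K)
    ann2 <- rbind(data.frame(gene = uni, term = "GO:BG"),
                  data.frame(gene = members, term = "GO:T"))
    r <- fisher_enrichment(sel, uni, ann2)
    k <- length(intersect(members, sel))
    p_exp <- if (k == 0) 1 else oracle_hyper_tail(k, K, n, N)
    expect_equal(r$p[r$term == "GO:T"], p_exp, tolerance = 1e-12)
    expect_equal(r$q, oracle_bh(r$p)[order(r$p, r$term)], tolerance = 1e-12)
  }

  # planted fixture: each cluster's term attains the minimum q for its set
  fx <- make_network_fixture(n_proteins = 60, n_clusters = 4, seed = 13)
  uni2 <- fx$truth$membership$protein
  for (k in 1:2) {
    selk <- uni2[fx$truth$membership$cluster == k]
    rk <- fisher_enrichment(selk, uni2, fx$annotation)
    expect_identical(rk$term[which.min(rk$q)], fx$truth$planted_terms[[k]][1])
  }
  expect_error(fisher_enrichment(character(0), uni2, fx$annotation), "empty")
  expect_error(fisher_enrichment("zzz", uni2, fx$annotation), "subset")
})
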