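test_that("AHU form is invariant under relabeling and separates trees", {
  set.seed(8)
  for (i in 1:20) {
    g <- random_tree(sample(2:15, 1))
    expect_equal(canonical_code(random_relabel(g))$form,
                 canonical_code(g)$form)
  }
  expect_false(canonical_code(make_path(4))$form ==
                 canonical_code(make_star(4))$form)
  expect_false(canonical_code(make_path(5))$form ==
                 canonical_code(make_path(6))$form)
  expect_true(is.na(canonical_code(make_cycle(5))$form))
})

test_that("AHU equality agrees with brute-force isomorphism on small trees", {
  set.seed(14)
  # sample pairs of trees on up to 8 vertices, including equal-size pairs
  for (i in 1:25) {
    n <- sample(4:8, 1)
    g1 <- random_tree(n)
    g2 <- if (i %% 3 == 0) random_relabel(g1) else random_tree(n)
    expect_equal(canonical_code(g1)$form == canonical_code(g2)$form,
                 brute_isomorphic(g1, g2))
  }
})

test_that("labelled forms distinguish label multisets and placements", {
  e <- cbind(c("a", "b"), c("b", "c"))
  g_aab <- glycan_graph(e, labels = c(a = "x", b = "x", c = "y"))
  g_abb <- glycan_graph(e, labels = c(a = "x", b = "y", c = "y"))
  g_bab <- glycan_graph(e, labels = c(a = "x", b = "y", c = "x"))
  expect_false(canonical_code(g_aab, TRUE)$form ==
                 canonical_code(g_abb, TRUE)$form)
  expect_false(canonical_code(g_aab, TRUE)$form ==
                 canonical_code(g_bab, TRUE)$form)
  # label-blind they are all P_3
  expect_equal(canonical_code(g_aab)$form, canonical_code(g_abb)$form)
  # labelled equality is relabeling-invariant too
  g_sw <- glycan_graph(cbind(c("q", "r"), c("r", "s")),
                       labels = c(q = "y", r = "x", s = "x"))
  expect_equal(canonical_code(g_sw, TRUE)$form,
               canonical_code(g_aab, TRUE)$form)
})

test_that("all labelled trees on 7 vertices fall into 11 unlabeled classes", {
  # Pruefer enumeration: 7^5 labelled trees
  seqs <- as.matrix(expand.grid(rep(list(1:7), 5)))
  forms <- character(nrow(seqs))
  for (r in seq_len(nrow(seqs))) {
    g <- glycan_graph(prufer_tree(seqs[r, ], 7L))
    forms[r] <- canonical_code(g)$form
  }
  expect_equal(length(unique(forms)), 11L)
  counts <- count_classes(lapply(seq_len(50), function(r)
    glycan_graph(prufer_tree(seqs[r, ], 7L), accession = paste0("g", r))))
  expect_equal(sum(counts$count), 50L)
})

test_that("count_classes groups relabelings and handles non-trees", {
  set.seed(55)
  base <- random_tree(9)
  reps <- lapply(1:10, function(i) {
    g <- random_relabel(base)
    g$accession <- paste0("copy", i)
    g
  })
  cc <- count_classes(reps)
  expect_equal(nrow(cc), 1L)
  expect_equal(cc$count, 10L)
  expect_equal(nrow(count_classes(list())), 0L)
  mixed <- c(reps[1:2], list(make_cycle(5), make_cycle(6), make_cycle(5)))
  mixed <- lapply(seq_along(mixed), function(i) {
    g <- mixed[[i]]; g$accession <- paste0("m", i); g
  })
  cm <- count_classes(mixed)
  expect_equal(nrow(cm), 3L)  # the tree class, C_5, C_6
  expect_equal(sum(cm$count), 5L)
})

test_that("db_lookup returns the three stepwise verdicts", {
  set.seed(66)
  db <- list(make_path(11), make_caterpillar12(), make_star(5),
             random_tree(8), make_cycle(6))
  db <- lapply(seq_along(db), function(i) {
    g <- db[[i]]; g$accession <- paste0("acc", i); g
  })
  idx <- build_search_index(db)

  # present: an indexed tree under a different labeling of vertex ids
  hit <- db_lookup(idx, random_relabel(db[[2]]))
  expect_true(hit$present)
  expect_equal(hit$accessions, "acc2")

  # absent code: P_50 has a code no indexed graph attains
  miss1 <- db_lookup(idx, make_path(50))
  expect_false(miss1$present)
  expect_equal(miss1$reason, "code_absent")

  # same code (N = 6, D = 10) as P_11 / the caterpillar but different
  # topology: a leaf on u5 (instead of u3, which reproduces the indexed
  # caterpillar) keeps the independence number at 6 and must fall through
  # to NO_ISOMORPH
  q <- glycan_graph(rbind(cbind(paste0("u", 1:10), paste0("u", 2:11)),
                          c("u3", "x")))  # P_11 + leaf on u3
  expect_true(db_lookup(idx, q)$present)  # isomorphic to the caterpillar
  q2 <- glycan_graph(rbind(cbind(paste0("u", 1:10), paste0("u", 2:11)),
                           c("u5", "x")))
  fdq2 <- finite_dimension(q2)
  expect_equal(c(fdq2$N, fdq2$D), c(6L, 10L))
  miss2 <- db_lookup(idx, q2)
  expect_false(miss2$present)
  expect_equal(miss2$reason, "no_isomorph")

  # cyclic queries go through exact isomorphism
  expect_true(db_lookup(idx, make_cycle(6))$present)
  expect_false(db_lookup(idx, make_cycle(8))$present)
})

test_that("index round-trips through JSON", {
  db <- list(make_path(6), make_star(7), make_cycle(5))
  db <- lapply(seq_along(db), function(i) {
    g <- db[[i]]; g$accession <- paste0("acc", i); g
  })
  idx <- build_search_index(db)
  f <- tempfile(fileext = ".json")
  write_search_index(idx, f)
  idx2 <- read_search_index(f)
  unlink(f)
  expect_equal(sort(names(idx2$buckets)), sort(names(idx$buckets)))
  expect_true(db_lookup(idx2, make_star(7))$present)
  expect_true(db_lookup(idx2, make_cycle(5))$present)
  expect_false(db_lookup(idx2, make_cycle(7))$present)
})

test_that("labelled index respects labels at the final comparison step", {
  e <- cbind(c("a", "b", "c"), c("b", "c", "d"))
  g1 <- glycan_graph(e, labels = c(a = "Glc", b = "Gal", c = "Gal",
                                   d = "Glc"), accession = "lab1")
  idx <- build_search_index(list(g1), use_labels = TRUE)
  same <- glycan_graph(e, labels = c(a = "Glc", b = "Gal", c = "Gal",
                                     d = "Glc"))
  diff <- glycan_graph(e, labels = c(a = "Glc", b = "Glc", c = "Gal",
                                     d = "Glc"))
  expect_true(db_lookup(idx, same)$present)
  v <- db_lookup(idx, diff)
  expect_false(v$present)
  expect_equal(v$reason, "no_isomorph")
})
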