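dec <- model_family("DEC")
decj <- model_family("DEC", TRUE)
zero_params <- list(d = 0, e = 0, j = 0)
both_A <- c(t1 = 1L, t2 = 1L)

test_that("two identical single-area tips give lnL = ln(1/3) under frozen rates", {
  # d = e = 0: only a root of {A} can produce two {A} tips; flat prior over
  # the 3 non-null states of the 2-area space
  ll <- prune_likelihood(two_tip_tree, both_A, space2, dec, zero_params)
  expect_equal(ll, log(1 / 3), tolerance = 1e-12)

  # same instance through the brute-force oracle
  bf <- brute_force_likelihood(two_tip_tree, both_A, space2, dec, zero_params)
  expect_equal(bf, log(1 / 3), tolerance = 1e-12)
})

test_that("an unsatisfiable root constraint drives the likelihood to -Inf", {
  cons <- list(list(name = "rootB", mrca_taxa = c("t1", "t2"),
                    required_areas = "B"))
  ll <- prune_likelihood(two_tip_tree, both_A, space2, dec, zero_params,
                         constraints = cons)
  expect_identical(ll, -Inf)
  expect_identical(
    brute_force_likelihood(two_tip_tree, both_A, space2, dec, zero_params,
                           constraints = cons), -Inf)
})

test_that("a constraint already satisfied with probability 1 leaves lnL unchanged", {
  cons <- list(list(name = "rootA", mrca_taxa = c("t1", "t2"),
                    required_areas = "A"))
  ll0 <- prune_likelihood(two_tip_tree, both_A, space2, dec, zero_params)
  ll1 <- prune_likelihood(two_tip_tree, both_A, space2, dec, zero_params,
                          constraints = cons)
  expect_equal(ll1, ll0, tolerance = 1e-10)
})

test_that("node-constraint masking zeroes exactly the states lacking a required area", {
  partials <- matrix(c(0.1, 0.2, 0.3, 0.5), ncol = 1,
                     dimnames = list(space2$labels, "3"))
  cons <- list(list(name = "needA", mrca_taxa = c("t1", "t2"),
                    required_areas = "A"))
  masked <- apply_node_constraints(partials, cons, space2, two_tip_tree)
  expect_equal(as.numeric(masked), c(0, 0.2, 0, 0.5))

  expect_error(constraint_masks(
    list(list(name = "bad", mrca_taxa = c("t1", "zz"), required_areas = "A")),
    space2, two_tip_tree), "unknown tip")
  expect_error(constraint_masks(
    list(list(name = "bad", mrca_taxa = "t1", required_areas = "A")),
    space2, two_tip_tree), "at least 2")
  expect_error(constraint_masks(
    list(list(name = "bad", mrca_taxa = c("t1", "t2"),
              required_areas = character(0))),
    space2, two_tip_tree), "no required areas")
})

test_that("pruning equals brute-force enumeration on random small instances", {
  for (seed in 1:10) {
    inst <- random_instance(seed)
    ll <- prune_likelihood(inst$tree, inst$tips, inst$space, inst$family,
                           inst$params)
    bf <- brute_force_likelihood(inst$tree, inst$tips, inst$space, inst$family,
                                 inst$params)
    expect_equal(ll, bf, tolerance = 1e-10,
                 label = paste("pruning lnL, seed", seed))
  }
})

test_that("likelihood is invariant to swapping a node's children", {
  for (seed in 11:16) {
    inst <- random_instance(seed)
    ll <- prune_likelihood(inst$tree, inst$tips, inst$space, inst$family,
                           inst$params)
    ntip <- length(inst$tree$tip.label)
    rotated <- ape::rotate(inst$tree, ntip + 1L)   # swap the root's children
    ll_rot <- prune_likelihood(rotated, inst$tips, inst$space, inst$family,
                               inst$params)
    expect_equal(ll_rot, ll, tolerance = 1e-10)
  }
})

test_that("adding constraints never increases the likelihood", {
  for (seed in 21:30) {
    inst <- random_instance(seed)
    tipnames <- inst$tree$tip.label
    cons <- list(list(name = "c1", mrca_taxa = tipnames[1:2],
                      required_areas = inst$space$areas[1]))
    ll0 <- prune_likelihood(inst$tree, inst$tips, inst$space, inst$family,
                            inst$params)
    ll1 <- prune_likelihood(inst$tree, inst$tips, inst$space, inst$family,
                            inst$params, constraints = cons)
    expect_lte(ll1, ll0 + 1e-10)
  }
})

test_that("+J at j = 0 collapses to the base model", {
  for (base in c("DEC", "DIVALIKE", "BAYAREALIKE")) {
    for (seed in 31:33) {
      inst <- random_instance(seed, family = model_family(base, FALSE))
      pj <- inst$params; pj$j <- 0
      ll0 <- prune_likelihood(inst$tree, inst$tips, inst$space,
                              model_family(base, FALSE), inst$params)
      llj <- prune_likelihood(inst$tree, inst$tips, inst$space,
                              model_family(base, TRUE), pj)
      expect_equal(llj, ll0, tolerance = 1e-10)
    }
  }
})

test_that("polytomies and inconsistent inputs are rejected", {
  poly <- ape::read.tree(text = "(t1:1,t2:1,t3:1);")
  expect_error(prune_likelihood(poly, c(t1 = 1L, t2 = 1L, t3 = 1L), space2,
                                dec, zero_params), "binary")
  expect_error(prune_likelihood(two_tip_tree, c(t1 = 1L), space2, dec,
                                zero_params), "missing")
  expect_error(prune_likelihood(two_tip_tree, c(t1 = 0L, t2 = 1L), space2,
                                dec, zero_params), "null")
})

test_that("ML fitting recovers boundary behaviour and respects nesting", {
  # no range variation: the likelihood cannot increase with d, so the fitted
  # dispersal rate collapses to the optimizer floor
  tr <- simulate_tree(6, 1, 5)
  tips <- stats::setNames(rep(1L, 6), tr$tip.label)
  f <- fit_ml(tr, tips, space2, dec, seed = 1)
  expect_equal(f$params$d, 1e-12, tolerance = 1e-6)
  expect_identical(f$k, 2L)

  # +J nests the base model: its fitted likelihood cannot be lower
  sim <- simulate_history(simulate_tree(40, 1, 9),
                          sim_config(space3, decj, d = 0.1, e = 0.02, j = 0.3,
                                     seed = 9))
  f0 <- fit_ml(sim$tree, sim$tips, space3, dec, seed = 2)
  fj <- fit_ml(sim$tree, sim$tips, space3, decj, seed = 2)
  expect_gte(fj$lnL, f0$lnL - 1e-6)
  expect_identical(fj$k, 3L)
  expect_true(fj$converged)
})

test_that("marginal ancestral states obey the masking identity", {
  # frozen two-tip case: root marginal is entirely on {A}
  est <- marginal_ancestral_states(two_tip_tree, both_A, space2, dec,
                                   zero_params)
  iA <- state_index(space2, 1L)
  expect_equal(unname(est$probs[1, iA]), 1, tolerance = 1e-12)

  # random instances: two-pass marginals equal the constrain-and-renormalize
  # recomputation, node by node and state by state
  for (seed in 41:43) {
    inst <- random_instance(seed, max_tips = 6L)
    ll <- prune_likelihood(inst$tree, inst$tips, inst$space, inst$family,
                           inst$params)
    est <- marginal_ancestral_states(inst$tree, inst$tips, inst$space,
                                     inst$family, inst$params)
    expect_true(all(abs(rowSums(est$probs) - 1) < 1e-9))
    S <- length(inst$space$states)
    for (v in est$node_ids) {
      for (k in which(inst$space$states != 0L)) {
        masks <- list()
        masks[[as.character(v)]] <- seq_len(S) == k
        llk <- cladorange:::prune_engine(
          inst$tree, inst$tips[inst$tree$tip.label], inst$space, inst$family,
          inst$params, masks)$lnL
        marg <- if (is.finite(llk)) exp(llk - ll) else 0
        expect_equal(unname(est$probs[as.character(v), k]), marg,
                     tolerance = 1e-8)
      }
    }
  }
})

test_that("constrained nodes carry zero marginal mass on disallowed states", {
  fix <- paper_constraint_fixture()
  sim <- simulate_history(
    fix$tree, sim_config(fix$space, decj, d = 0.02, e = 0.002, j = 0.2,
                         seed = 4))
  est <- marginal_ancestral_states(fix$tree, sim$tips, fix$space, decj,
                                   list(d = 0.02, e = 0.002, j = 0.2),
                                   constraints = fix$constraints)
  masks <- constraint_masks(fix$constraints, fix$space, fix$tree)
  for (key in names(masks)) {
    expect_true(all(est$probs[key, !masks[[key]]] == 0))
    expect_equal(sum(est$probs[key, ]), 1, tolerance = 1e-9)
  }
})

test_that("marginals refuse impossible configurations", {
  cons <- list(list(name = "rootB", mrca_taxa = c("t1", "t2"),
                    required_areas = "B"))
  expect_error(
    marginal_ancestral_states(two_tip_tree, both_A, space2, dec, zero_params,
                              constraints = cons), "-Inf")
})

test_that("node signatures identify every internal node by a tip pair", {
  fix <- paper_constraint_fixture()
  sig <- node_signatures(fix$tree)
  expect_identical(nrow(sig), fix$tree$Nnode)
  for (i in seq_len(nrow(sig))) {
    expect_identical(ape::getMRCA(fix$tree, c(sig$tip1[i], sig$tip2[i])),
                     sig$node[i])
  }
})
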