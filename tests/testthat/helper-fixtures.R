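# shared fixtures: tiny state spaces, trees and a seeded random-instance
# generator used by the oracle-equivalence and property tests

space2 <- build_state_space(2, 2, TRUE, c("A", "B"))
space3 <- build_state_space(3, 3, TRUE, c("A", "B", "C"))

two_tip_tree <- ape::read.tree(text = "(t1:1,t2:1);")

all_families <- list(
  model_family("DEC", FALSE), model_family("DEC", TRUE),
  model_family("DIVALIKE", FALSE), model_family("DIVALIKE", TRUE),
  model_family("BAYAREALIKE", FALSE), model_family("BAYAREALIKE", TRUE)
)

# a small random instance: tree, tips, space, family, params; seeded
random_instance <- function(seed, max_tips = 5L, max_areas = 3L,
                            family = NULL) {
  set.seed(seed)
  n_tips <- sample(2:max_tips, 1)
  n_areas <- sample(2:max_areas, 1)
  space <- build_state_space(n_areas, n_areas, TRUE,
                             LETTERS[seq_len(n_areas)])
  if (is.null(family)) family <- all_families[[1 + (seed %% 6)]]
  params <- list(d = stats::runif(1, 0.01, 0.5),
                 e = stats::runif(1, 0.01, 0.3),
                 j = if (family$jump)
                   stats::runif(1, 0.05, 0.8 * family$j_ceiling) else 0)
  tree <- simulate_tree(n_tips, 1, seed + 17)
  nonnull <- space$states[space$states != 0L]
  set.seed(seed + 31)
  tips <- stats::setNames(sample(nonnull, n_tips, replace = TRUE),
                          tree$tip.label)
  list(tree = tree, tips = tips, space = space, family = family,
       params = params)
}

# ancestral_estimate stub from explicit per-node probability rows
fake_estimate <- function(prob_rows, node_ids, space) {
  probs <- do.call(rbind, prob_rows)
  rownames(probs) <- as.character(node_ids)
  colnames(probs) <- space$labels
  structure(list(probs = probs, lnL = NA_real_, node_ids = node_ids,
                 space = space),
            class = "ancestral_estimate")
}
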