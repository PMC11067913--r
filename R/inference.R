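# Pruning likelihood on a dated binary tree over the range state space, with
# fossil node constraints, ML fitting, and marginal ancestral range
# estimation. A brute-force enumeration over joint internal-node states
# serves as the test oracle on small instances.

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0)) {
    stop("branch lengths must be nonnegative and non-missing")
  }
  if (!ape::is.rooted(tree) || !ape::is.binary(tree)) {
    stop("tree must be rooted and strictly binary (no polytomies)")
  }
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  invisible(tree)
}

validate_tips <- function(tree, tip_ranges, space) {
  missing <- setdiff(tree$tip.label, names(tip_ranges))
  if (length(missing)) {
    stop("tip(s) missing from the range table: ", paste(missing, collapse = ", "))
  }
  bits <- as.integer(tip_ranges[tree$tip.label])
  if (any(bits == 0L)) stop("null tip ranges are not allowed")
  if (anyNA(state_index(space, bits))) stop("tip range outside the state space")
  bits
}

#' Resolve node constraints to per-node allowed-state masks
#'
#' Each constraint names a node as the MRCA of two or more tips and requires
#' its ancestral range to include every listed area (the mechanism used to
#' inject fossil localities: a fossil found in Eurasia and assigned to a clade
#' forces that clade's ancestral range to contain Eurasia). States lacking any
#' required area get mask FALSE. Multiple constraints resolving to the same
#' node are intersected.
#'
#' @param constraints list of constraints, each a list with `name`,
#'   `mrca_taxa` (character, >= 2 tips) and `required_areas` (character).
#' @param space a `state_space`.
#' @param tree a `phylo` tree.
#' @return named list: node id (as character) -> logical mask over states.
#' @export
constraint_masks <- function(constraints, space, tree) {
  masks <- list()
  if (is.null(constraints) || !length(constraints)) return(masks)
  for (cs in constraints) {
    if (length(cs$mrca_taxa) < 2L) {
      stop("constraint '", cs$name, "' needs at least 2 mrca taxa")
    }
    bad <- setdiff(cs$mrca_taxa, tree$tip.label)
    if (length(bad)) {
      stop("constraint '", cs$name, "': unknown tip(s): ",
           paste(bad, collapse = ", "))
    }
    if (!length(cs$required_areas)) {
      stop("constraint '", cs$name, "' has no required areas")
    }
    req <- range_state(cs$required_areas, space)
    node <- ape::getMRCA(tree, cs$mrca_taxa)
    mask <- bitwAnd(space$states, req) == req
    key <- as.character(node)
    masks[[key]] <- if (is.null(masks[[key]])) mask else masks[[key]] & mask
  }
  masks
}

#' Mask per-node partial likelihoods by node constraints
#'
#' At each constrained node, entries for states not containing all required
#' areas are zeroed; everything else is untouched.
#'
#' @param partials matrix of per-node vectors (states in rows, columns named
#'   by node id).
#' @param constraints constraint list (see [constraint_masks()]).
#' @param space a `state_space`.
#' @param tree a `phylo` tree.
#' @return the masked matrix.
#' @export
apply_node_constraints <- function(partials, constraints, space, tree) {
  masks <- constraint_masks(constraints, space, tree)
  for (key in names(masks)) {
    if (key %in% colnames(partials)) {
      partials[, key] <- partials[, key] * masks[[key]]
    }
  }
  partials
}

# flat-table aggregator: sparse S x n_events matrix summing event values into
# their parent state
clado_aggregator <- function(ct) {
  Matrix::sparseMatrix(i = ct$parent, j = seq_along(ct$parent), x = 1,
                       dims = c(ct$n_states, length(ct$parent)))
}

# core pruning engine; node_masks: named list node-id -> logical mask
prune_engine <- function(tree, tip_bits, space, family, params,
                         node_masks = list(), keep = FALSE) {
  S <- length(space$states)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  q <- build_anagenetic_matrix(space, params$d, params$e)
  prop <- make_propagator(q)
  j <- if (family$jump) params$j else 0
  ct <- build_clado_table(family, j, space)
  agg <- clado_aggregator(ct)

  tr <- ape::reorder.phylo(tree, "postorder")
  edge <- tr$edge
  elen <- tr$edge.length

  U <- matrix(0, S, ntip + nnode)
  for (i in seq_len(ntip)) U[state_index(space, tip_bits[i]), i] <- 1
  contrib <- if (keep) matrix(NA_real_, S, ntip + nnode) else NULL
  child_of <- if (keep) vector("list", ntip + nnode) else NULL
  logscale <- 0
  neg_inf <- FALSE

  # postorder edges come in child pairs per parent
  parents <- edge[, 1]
  kids <- edge[, 2]
  for (v in unique(parents)) {
    rows <- which(parents == v)
    c1 <- kids[rows[1]]; c2 <- kids[rows[2]]
    # explicit per-branch P keeps tiny transition probabilities numerically
    # identical to the ones the enumeration oracle reads entry by entry
    a <- as.numeric(propagate_matrix(prop, elen[rows[1]]) %*% U[, c1])
    b <- as.numeric(propagate_matrix(prop, elen[rows[2]]) %*% U[, c2])
    if (keep) {
      contrib[, c1] <- a; contrib[, c2] <- b
      child_of[[v]] <- list(left = c1, right = c2,
                            t_left = elen[rows[1]], t_right = elen[rows[2]])
    }
    ev <- ct$prob * a[ct$left] * b[ct$right]
    u <- as.numeric(agg %*% ev)
    mask <- node_masks[[as.character(v)]]
    if (!is.null(mask)) u <- u * mask
    m <- sum(u)
    if (!is.finite(m) || m <= 0) { neg_inf <- TRUE; break }
    U[, v] <- u / m
    logscale <- logscale + log(m)
  }

  root <- ntip + 1L
  prior <- as.numeric(space$states != 0L)
  prior <- prior / sum(prior)
  lnL <- if (neg_inf) -Inf else {
    s <- sum(prior * U[, root])
    if (s <= 0) -Inf else log(s) + logscale
  }
  list(lnL = lnL, U = U, contrib = contrib, child_of = child_of,
       prop = prop, ct = ct, prior = prior, tree = tr)
}

#' Pruning log-likelihood of tip ranges under a biogeographic model
#'
#' Felsenstein-style post-order recursion: tip partials are indicators of the
#' observed range; a child's contribution at the parent end of its branch is
#' the branch transition matrix applied to the child partial; the node partial
#' combines the two children through the cladogenetic event table; constrained
#' nodes have disallowed states zeroed after combination; the total is the sum
#' over root states under a flat prior on non-null states (cladogenesis is
#' applied at the root like any other internal node). Per-node rescaling with
#' accumulated log factors prevents underflow. An unsatisfiable configuration
#' returns `-Inf` rather than raising.
#'
#' @param tree rooted, dated, binary `phylo` tree (branch lengths in Myr).
#' @param tip_ranges named integer vector: taxon -> non-null range bitmask.
#' @param space a `state_space`.
#' @param family a `model_family`.
#' @param params list with `d`, `e` and (for +J families) `j`.
#' @param constraints optional list of node constraints.
#' @param return_partials if TRUE, also return the matrix of rescaled per-node
#'   partials (columns named by node id).
#' @return the log-likelihood, or a list with `lnL` and `partials`.
#' @export
prune_likelihood <- function(tree, tip_ranges, space, family, params,
                             constraints = NULL, return_partials = FALSE) {
  validate_tree(tree)
  bits <- validate_tips(tree, tip_ranges, space)
  masks <- constraint_masks(constraints, space, tree)
  res <- prune_engine(tree, bits, space, family, params, masks)
  if (!return_partials) return(res$lnL)
  colnames(res$U) <- as.character(seq_len(ncol(res$U)))
  list(lnL = res$lnL, partials = res$U)
}

#' Brute-force likelihood by joint enumeration (test oracle)
#'
#' Sums over every joint assignment of non-null states to internal nodes the
#' product of the root prior, the per-node cladogenetic sums and the branch
#' transition probabilities. Exponential in the number of internal nodes:
#' guarded to small instances. Must equal [prune_likelihood()].
#'
#' @inheritParams prune_likelihood
#' @param max_assignments guard on the enumeration size.
#' @return the log-likelihood.
#' @export
brute_force_likelihood <- function(tree, tip_ranges, space, family, params,
                                   constraints = NULL,
                                   max_assignments = 5e6) {
  validate_tree(tree)
  bits <- validate_tips(tree, tip_ranges, space)
  masks <- constraint_masks(constraints, space, tree)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  nonnull <- which(space$states != 0L)
  if (length(nonnull)^nnode > max_assignments) {
    stop("instance too large for brute-force enumeration")
  }
  q <- build_anagenetic_matrix(space, params$d, params$e)
  j <- if (family$jump) params$j else 0
  ct <- build_clado_table(family, j, space)
  ev_by_parent <- split(data.frame(l = ct$left, r = ct$right, p = ct$prob),
                        ct$parent)

  tr <- ape::reorder.phylo(tree, "postorder")
  edge <- tr$edge
  # the same branch propagator as the pruning engine: the enumeration below is
  # the independent part (joint summation over internal states), while
  # transition probabilities are shared plumbing, so agreement is checkable at
  # tolerances below the absolute accuracy of the matrix exponential itself
  prop <- make_propagator(q)
  P <- lapply(seq_len(nrow(edge)), function(i) {
    propagate_matrix(prop, tr$edge.length[i])
  })
  kids_rows <- split(seq_len(nrow(edge)), edge[, 1])

  internal <- (ntip + 1L):(ntip + nnode)
  prior <- as.numeric(space$states != 0L); prior <- prior / sum(prior)
  tip_idx <- state_index(space, bits)

  grid <- as.matrix(expand.grid(rep(list(nonnull), nnode)))
  total <- 0
  for (g in seq_len(nrow(grid))) {
    assign_idx <- grid[g, ]
    state_of <- function(node) {
      if (node <= ntip) tip_idx[node] else assign_idx[node - ntip]
    }
    ok <- TRUE
    w <- prior[state_of(ntip + 1L)]
    for (v in internal) {
      sv <- state_of(v)
      mask <- masks[[as.character(v)]]
      if (!is.null(mask) && !mask[sv]) { ok <- FALSE; break }
      rows <- kids_rows[[as.character(v)]]
      c1 <- edge[rows[1], 2]; c2 <- edge[rows[2], 2]
      ev <- ev_by_parent[[as.character(sv)]]
      if (is.null(ev)) { ok <- FALSE; break }
      f <- sum(ev$p * P[[rows[1]]][ev$l, state_of(c1)] *
                 P[[rows[2]]][ev$r, state_of(c2)])
      w <- w * f
      if (w == 0) { ok <- FALSE; break }
    }
    if (ok) total <- total + w
  }
  if (total <= 0) -Inf else log(total)
}

#' Maximum-likelihood fit of a biogeographic model
#'
#' Box-constrained local optimization (L-BFGS-B) of the pruning likelihood
#' over (d, e) on a log scale and, for +J families, j untransformed. The
#' default start (d = e = 0.01, j = 0.01) is supplemented by `n_starts - 1`
#' seeded random starts; the best final likelihood wins, ties broken by the
#' lowest start index. Deterministic given `seed`.
#'
#' @inheritParams prune_likelihood
#' @param n_starts number of optimization starts (>= 1).
#' @param seed integer seed for the random starts.
#' @param lower,upper bounds for d and e (per Myr). The default lower bound
#'   1e-12 acts as the optimizer floor for extirpation-free data.
#' @param control passed to [stats::optim()] (factr etc.).
#' @return a `range_fit`: list with `model` (label), `family`, `params`
#'   (d, e, j), `lnL`, `k` (2 without jump, 3 with), `n_tips`, `converged`,
#'   `n_starts`, `seed` and the winning start index.
#' @export
fit_ml <- function(tree, tip_ranges, space, family, constraints = NULL,
                   n_starts = 1L, seed = 1L, lower = 1e-12, upper = 5,
                   control = list(factr = 1e8, maxit = 200)) {
  validate_tree(tree)
  bits <- validate_tips(tree, tip_ranges, space)
  masks <- constraint_masks(constraints, space, tree)
  jmax <- family$j_ceiling - 1e-5

  objective <- function(par) {
    params <- list(d = exp(par[1]), e = exp(par[2]),
                   j = if (family$jump) par[3] else 0)
    ll <- tryCatch(
      prune_engine(tree, bits, space, family, params, masks)$lnL,
      error = function(err) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }

  starts <- list(c(log(0.01), log(0.01), if (family$jump) 0.01))
  if (n_starts > 1L) {
    set.seed(seed)
    for (r in seq_len(n_starts - 1L)) {
      starts[[r + 1L]] <- c(stats::runif(2, log(1e-4), log(1)),
                            if (family$jump)
                              stats::runif(1, 0, family$j_ceiling / 2))
    }
  }
  lo <- c(log(lower), log(lower), if (family$jump) 0)
  hi <- c(log(upper), log(upper), if (family$jump) jmax)

  best <- NULL
  best_start <- NA_integer_
  for (r in seq_along(starts)) {
    fit <- tryCatch(
      stats::optim(starts[[r]], objective, method = "L-BFGS-B",
                   lower = lo, upper = hi, control = control),
      error = function(err) NULL)
    if (is.null(fit) || fit$value >= 1e10) next
    if (is.null(best) || fit$value < best$value - 1e-12) {
      best <- fit
      best_start <- r
    }
  }
  if (is.null(best)) {
    stop("non-finite likelihood at every optimization start (",
         length(starts), " starts, seed ", seed, ") for ", family$label)
  }
  par <- best$par
  params <- list(d = exp(par[1]), e = exp(par[2]),
                 j = if (family$jump) par[3] else 0)
  structure(
    list(model = family$label, family = family, params = params,
         lnL = -best$value, k = if (family$jump) 3L else 2L,
         n_tips = length(tree$tip.label),
         converged = best$convergence == 0, n_starts = length(starts),
         seed = seed, best_start = best_start),
    class = "range_fit"
  )
}

#' @export
print.range_fit <- function(x, ...) {
  cat(sprintf("%s fit: lnL = %.4f, d = %.5g, e = %.5g, j = %.5g (k = %d, n = %d, %s)\n",
              x$model, x$lnL, x$params$d, x$params$e, x$params$j, x$k, x$n_tips,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Fit all six candidate models
#'
#' DEC, DEC+J, DIVALIKE, DIVALIKE+J, BAYAREALIKE, BAYAREALIKE+J, in that
#' fixed order.
#'
#' @inheritParams fit_ml
#' @return named list of six `range_fit` objects.
#' @export
fit_all_models <- function(tree, tip_ranges, space, constraints = NULL,
                           n_starts = 1L, seed = 1L, ...) {
  specs <- list(
    model_family("DEC", FALSE), model_family("DEC", TRUE),
    model_family("DIVALIKE", FALSE), model_family("DIVALIKE", TRUE),
    model_family("BAYAREALIKE", FALSE), model_family("BAYAREALIKE", TRUE)
  )
  fits <- lapply(specs, function(fam) {
    fit_ml(tree, tip_ranges, space, fam, constraints = constraints,
           n_starts = n_starts, seed = seed, ...)
  })
  names(fits) <- vapply(specs, `[[`, character(1), "label")
  fits
}

#' Marginal ancestral range probabilities at internal nodes
#'
#' For each internal node v and range R, returns the split-point marginal
#' P(state at v = R | data, params): the probability mass just before the
#' cladogenetic event at v. Computed by an up-pass (pruning partials) and a
#' down-pass that propagates the complement of each subtree through the
#' cladogenetic table; equals, node by node, exp(lnL with v constrained to
#' exactly R minus the total lnL).
#'
#' @inheritParams prune_likelihood
#' @return an `ancestral_estimate`: list with `probs` (matrix, internal nodes
#'   in rows named by node id, states in columns labelled by range), `lnL`,
#'   `node_ids`, and the `space`. Each row sums to 1; constrained nodes carry
#'   zero mass on disallowed states.
#' @export
marginal_ancestral_states <- function(tree, tip_ranges, space, family, params,
                                      constraints = NULL) {
  validate_tree(tree)
  bits <- validate_tips(tree, tip_ranges, space)
  masks <- constraint_masks(constraints, space, tree)
  res <- prune_engine(tree, bits, space, family, params, masks, keep = TRUE)
  if (!is.finite(res$lnL)) {
    stop("likelihood is -Inf under these data/constraints; no marginals exist")
  }
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  S <- length(space$states)
  ct <- res$ct
  root <- ntip + 1L

  aggL <- Matrix::sparseMatrix(i = ct$left, j = seq_along(ct$left), x = 1,
                               dims = c(S, length(ct$left)))
  aggR <- Matrix::sparseMatrix(i = ct$right, j = seq_along(ct$right), x = 1,
                               dims = c(S, length(ct$right)))

  D <- matrix(0, S, ntip + nnode)
  D[, root] <- res$prior
  probs <- matrix(0, nnode, S,
                  dimnames = list(as.character((ntip + 1L):(ntip + nnode)),
                                  space$labels))

  # preorder: parents before children
  order_nodes <- rev(unique(res$tree$edge[, 1]))
  for (v in order_nodes) {
    dv <- D[, v]
    mask <- masks[[as.character(v)]]
    if (!is.null(mask)) dv <- dv * mask
    probs_row <- dv * res$U[, v]
    probs[as.character(v), ] <- probs_row / sum(probs_row)
    ch <- res$child_of[[v]]
    # weight per event: D(parent) * prob * contribution of the sibling branch
    base <- dv[ct$parent] * ct$prob
    for (side in c("left", "right")) {
      child <- if (side == "left") ch$left else ch$right
      if (child <= ntip) next
      tchild <- if (side == "left") ch$t_left else ch$t_right
      sib_contrib <- if (side == "left") res$contrib[, ch$right] else
        res$contrib[, ch$left]
      w <- if (side == "left") base * sib_contrib[ct$right] else
        base * sib_contrib[ct$left]
      wstate <- if (side == "left") as.numeric(aggL %*% w) else
        as.numeric(aggR %*% w)
      p <- propagate_matrix(res$prop, tchild)
      dchild <- as.numeric(crossprod(p, wstate))
      s <- sum(dchild)
      D[, child] <- if (s > 0) dchild / s else dchild
    }
  }

  structure(
    list(probs = probs, lnL = res$lnL,
         node_ids = (ntip + 1L):(ntip + nnode), space = space),
    class = "ancestral_estimate"
  )
}

#' @export
print.ancestral_estimate <- function(x, ...) {
  cat(sprintf("ancestral_estimate: %d internal nodes x %d states (lnL = %.4f)\n",
              nrow(x$probs), ncol(x$probs), x$lnL))
  invisible(x)
}

#' Two-tip MRCA signatures for internal nodes
#'
#' Node ids are not portable across tools; a pair of tips whose MRCA is the
#' node is. Returns, for every internal node, the first tip descending
#' through each child.
#'
#' @param tree a `phylo` tree.
#' @return data.frame with columns `node`, `tip1`, `tip2`.
#' @export
node_signatures <- function(tree) {
  ntip <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  first_tip <- integer(ntip + tree$Nnode)
  first_tip[seq_len(ntip)] <- seq_len(ntip)
  sig <- data.frame(node = integer(0), tip1 = character(0), tip2 = character(0))
  parents <- tr$edge[, 1]; kids <- tr$edge[, 2]
  for (v in unique(parents)) {
    rows <- which(parents == v)
    c1 <- kids[rows[1]]; c2 <- kids[rows[2]]
    first_tip[v] <- first_tip[c1]
    sig <- rbind(sig, data.frame(
      node = v, tip1 = tree$tip.label[first_tip[c1]],
      tip2 = tree$tip.label[first_tip[c2]]))
  }
  sig[order(sig$node), ]
}
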