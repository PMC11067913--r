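# Forward simulation of range evolution: pure-birth trees, exact stochastic
# simulation of the anagenetic CTMC along branches, cladogenetic draws from
# the event table at nodes, full event logs, and fixture bundles.

#' Simulate a pure-birth (Yule) tree with a fixed number of extant tips
#'
#' Thin, seeded wrapper around [ape::rphylo()] with no extinction, so the tree
#' is ultrametric with exactly `n_tips` tips. Deterministic given `seed`.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate per lineage per Myr (> 0).
#' @param seed integer seed.
#' @return a `phylo` tree with tips `t1..tn`.
#' @export
simulate_tree <- function(n_tips, birth_rate, seed) {
  if (n_tips < 2L) stop("n_tips must be >= 2")
  if (birth_rate <= 0) stop("birth_rate must be positive")
  set.seed(as.integer(seed))
  ape::rphylo(n = n_tips, birth = birth_rate, death = 0)
}

#' Simulation configuration
#'
#' @param space a `state_space`.
#' @param family a `model_family`.
#' @param d,e,j anagenetic rates and founder-event weight.
#' @param root_range `"random"` (flat over non-null states) or a specific
#'   non-null bitmask.
#' @param seed integer seed.
#' @param max_rejections how many replicate redraws are allowed when a tip
#'   reaches the null range (an extinct lineage cannot appear among extant
#'   tips, so such replicates are rejected and redrawn under an incremented
#'   sub-seed).
#' @return a `sim_config` list.
#' @export
sim_config <- function(space, family, d, e, j = 0, root_range = "random",
                       seed = 1L, max_rejections = 100L) {
  structure(list(space = space, family = family, d = d, e = e, j = j,
                 root_range = root_range, seed = as.integer(seed),
                 max_rejections = as.integer(max_rejections)),
            class = "sim_config")
}

# per-state anagenetic move tables from the rate matrix
anagenetic_moves <- function(space, d, e) {
  q <- build_anagenetic_matrix(space, d, e)
  S <- nrow(q)
  lapply(seq_len(S), function(i) {
    targets <- which(q[i, ] > 0)
    targets <- targets[targets != i]
    rates <- q[i, targets]
    type <- ifelse(space$size[targets] > space$size[i], "dispersal", "extirpation")
    list(targets = targets, rates = rates, total = sum(rates), type = type)
  })
}

#' Simulate a full biogeographic history on a tree
#'
#' The root range is drawn (or fixed); along every branch the anagenetic CTMC
#' is simulated exactly (exponential waiting times at the state's total rate,
#' event chosen proportional to rates); at every internal node one
#' cladogenetic event is drawn from the event table. Replicates in which any
#' tip reaches the null range (or a null lineage reaches a speciation event)
#' are rejected and redrawn with an incremented sub-seed, up to
#' `max_rejections`. Deterministic given the config seed.
#'
#' @param tree a dated binary `phylo` tree.
#' @param config a `sim_config`.
#' @return a `sim_output`: list with `tree`, `tips` (named bitmask vector),
#'   `true_states` (split-point range bitmask per node number),
#'   `event_log` (data.frame: time from root, node, type, from, to, left,
#'   right), `n_rejections` and `config`.
#' @export
simulate_history <- function(tree, config) {
  validate_tree(tree)
  space <- config$space
  ct <- build_clado_table(config$family, if (config$family$jump) config$j else 0,
                          space)
  moves <- anagenetic_moves(space, config$d, config$e)
  ev_rows <- split(seq_along(ct$parent), ct$parent)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  depth <- ape::node.depth.edgelength(tree)
  nonnull_idx <- which(space$states != 0L)

  for (attempt in 0:config$max_rejections) {
    set.seed(config$seed + attempt * 1000003L)
    states <- integer(ntip + nnode)        # split-point state per node
    log_time <- numeric(0); log_node <- integer(0); log_type <- character(0)
    log_from <- integer(0); log_to <- integer(0)
    log_left <- integer(0); log_right <- integer(0)
    ok <- TRUE

    root <- ntip + 1L
    root_idx <- if (identical(config$root_range, "random")) {
      sample(nonnull_idx, 1L)
    } else {
      state_index(space, config$root_range)
    }
    if (is.na(root_idx) || space$states[root_idx] == 0L) {
      stop("root_range must be a non-null state of the space")
    }
    states[root] <- space$states[root_idx]

    tr <- ape::reorder.phylo(tree, "postorder")
    pre_edges <- rev(seq_len(nrow(tr$edge)))
    # start state at the top of each branch, filled as clado events are drawn
    branch_start <- integer(ntip + nnode)

    draw_clado <- function(node) {
      pstate <- states[node]
      pidx <- state_index(space, pstate)
      if (pstate == 0L) return(NULL)
      rows <- ev_rows[[as.character(pidx)]]
      r <- rows[sample.int(length(rows), 1L, prob = ct$prob[rows])]
      log_time <<- c(log_time, depth[node]); log_node <<- c(log_node, node)
      log_type <<- c(log_type, ct$type[r]); log_from <<- c(log_from, pstate)
      log_to <<- c(log_to, NA_integer_)
      log_left <<- c(log_left, space$states[ct$left[r]])
      log_right <<- c(log_right, space$states[ct$right[r]])
      c(space$states[ct$left[r]], space$states[ct$right[r]])
    }

    daughters <- draw_clado(root)
    if (is.null(daughters)) ok <- FALSE
    if (ok) {
      kids <- tr$edge[tr$edge[, 1] == root, 2]
      branch_start[kids[1]] <- daughters[1]
      branch_start[kids[2]] <- daughters[2]
      for (ei in pre_edges) {
        parent <- tr$edge[ei, 1]; child <- tr$edge[ei, 2]
        st <- branch_start[child]
        t0 <- depth[parent]; t1 <- depth[child]
        tcur <- t0
        while (st != 0L) {
          mv <- moves[[state_index(space, st)]]
          if (mv$total <= 0) break
          wait <- stats::rexp(1L, mv$total)
          if (tcur + wait > t1) break
          tcur <- tcur + wait
          pick <- if (length(mv$targets) == 1L) 1L else
            sample.int(length(mv$targets), 1L, prob = mv$rates)
          newst <- space$states[mv$targets[pick]]
          log_time <- c(log_time, tcur); log_node <- c(log_node, child)
          log_type <- c(log_type, mv$type[pick]); log_from <- c(log_from, st)
          log_to <- c(log_to, newst)
          log_left <- c(log_left, NA_integer_); log_right <- c(log_right, NA_integer_)
          st <- newst
        }
        states[child] <- st
        if (child <= ntip) {
          if (st == 0L) { ok <- FALSE; break }
        } else {
          d2 <- draw_clado(child)
          if (is.null(d2)) { ok <- FALSE; break }
          kids <- tr$edge[tr$edge[, 1] == child, 2]
          branch_start[kids[1]] <- d2[1]
          branch_start[kids[2]] <- d2[2]
        }
      }
    }
    if (ok) {
      tips <- stats::setNames(states[seq_len(ntip)], tree$tip.label)
      log <- data.frame(time = log_time, node = log_node, type = log_type,
                        from = log_from, to = log_to,
                        left = log_left, right = log_right)
      log <- log[order(log$time, log$node), ]
      rownames(log) <- NULL
      return(structure(
        list(tree = tree, tips = tips, true_states = states,
             event_log = log, n_rejections = attempt, config = config),
        class = "sim_output"))
    }
  }
  stop("rejection budget exhausted (", config$max_rejections,
       " redraws); extirpation too high for the tree depth")
}

#' Replay an event log to reconstruct all node and tip states
#'
#' Applies the logged cladogenetic and anagenetic events from the root range
#' down the tree. Used to verify that the log fully determines the simulated
#' history: the replay must reproduce `true_states` exactly.
#'
#' @param sim a `sim_output`.
#' @return integer vector of split-point states per node number.
#' @export
replay_event_log <- function(sim) {
  tree <- sim$tree
  ntip <- length(tree$tip.label)
  states <- integer(ntip + tree$Nnode)
  root <- ntip + 1L
  log <- sim$event_log
  clado <- log[log$type %in% c("sympatry", "subset", "vicariance", "jump"), ]
  ana <- log[log$type %in% c("dispersal", "extirpation"), ]

  root_clado <- clado[clado$node == root, ]
  states[root] <- root_clado$from[1]
  tr <- ape::reorder.phylo(tree, "postorder")
  branch_start <- integer(ntip + tree$Nnode)
  set_kids <- function(node, cl) {
    kids <- tr$edge[tr$edge[, 1] == node, 2]
    branch_start[kids[1]] <<- cl$left[1]
    branch_start[kids[2]] <<- cl$right[1]
  }
  set_kids(root, root_clado)
  for (ei in rev(seq_len(nrow(tr$edge)))) {
    child <- tr$edge[ei, 2]
    st <- branch_start[child]
    bev <- ana[ana$node == child, ]
    if (nrow(bev)) {
      bev <- bev[order(bev$time), ]
      for (r in seq_len(nrow(bev))) {
        stopifnot(bev$from[r] == st)
        st <- bev$to[r]
      }
    }
    states[child] <- st
    if (child > ntip) set_kids(child, clado[clado$node == child, ])
  }
  states
}

#' Read a fixture's true-state table onto a (possibly renumbered) tree
#'
#' Newick round-trips renumber nodes, so the table written by [make_fixture()]
#' keys every node by an MRCA tip pair. This loader re-resolves each row
#' against the supplied tree and returns states in that tree's numbering.
#'
#' @param path the `true_states.tsv` written by [make_fixture()].
#' @param tree the tree to map onto (e.g. re-read from the fixture's Newick).
#' @return integer vector of range bitmasks indexed by the tree's node numbers.
#' @export
read_true_states <- function(path, tree) {
  df <- utils::read.delim(path)
  out <- integer(length(tree$tip.label) + tree$Nnode)
  for (i in seq_len(nrow(df))) {
    node <- if (df$tip1[i] == df$tip2[i]) {
      match(df$tip1[i], tree$tip.label)
    } else {
      ape::getMRCA(tree, c(df$tip1[i], df$tip2[i]))
    }
    if (is.na(node)) stop("cannot resolve node for tips ", df$tip1[i], ", ",
                          df$tip2[i])
    out[node] <- df$bits[i]
  }
  out
}

#' Draw cladogenetic events from an event table (for calibration checks)
#'
#' @param ct a `clado_table`.
#' @param parent_idx parent state index.
#' @param n number of draws.
#' @param seed integer seed.
#' @return integer vector of event row indices into the flat table.
#' @export
sample_clado_events <- function(ct, parent_idx, n, seed = 1L) {
  rows <- which(ct$parent == parent_idx)
  if (!length(rows)) stop("parent state has no cladogenetic events")
  set.seed(as.integer(seed))
  rows[sample.int(length(rows), n, replace = TRUE, prob = ct$prob[rows])]
}

#' Write a simulation fixture bundle to disk
#'
#' Writes the tree (Newick), the geography file, the true split-point states,
#' the event log, and the configuration (including the seed). Re-running with
#' the same config overwrites the same content (idempotent).
#'
#' @param config a `sim_config` plus tree settings: pass `n_tips` and
#'   `birth_rate` to simulate the tree too.
#' @param out_dir output directory (created if needed).
#' @param n_tips,birth_rate pure-birth tree settings.
#' @return (invisibly) named vector of the five file paths.
#' @export
make_fixture <- function(config, out_dir, n_tips = 50L, birth_rate = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tree <- simulate_tree(n_tips, birth_rate, config$seed)
  sim <- simulate_history(tree, config)
  space <- config$space

  paths <- c(tree = file.path(out_dir, "tree.nwk"),
             geography = file.path(out_dir, "geography.txt"),
             states = file.path(out_dir, "true_states.tsv"),
             events = file.path(out_dir, "event_log.tsv"),
             config = file.path(out_dir, "config.txt"))
  ape::write.tree(tree, paths["tree"])
  write_geography(paths["geography"], sim$tips, space)
  # node ids are not portable across Newick round-trips, so every node is also
  # keyed by a tip pair whose MRCA it is (tips: the label twice)
  ntip <- length(tree$tip.label)
  sig <- node_signatures(tree)
  tip1 <- c(tree$tip.label, sig$tip1[order(sig$node)])
  tip2 <- c(tree$tip.label, sig$tip2[order(sig$node)])
  states_df <- data.frame(node = seq_along(sim$true_states),
                          tip1 = tip1, tip2 = tip2,
                          bits = sim$true_states,
                          range = range_label(sim$true_states, space))
  utils::write.table(states_df, paths["states"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$event_log, paths["events"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg <- c(n_tips = n_tips, birth_rate = birth_rate, family = config$family$label,
           d = config$d, e = config$e, j = config$j,
           n_areas = space$n_areas, max_range_size = space$max_range_size,
           areas = paste(space$areas, collapse = ","),
           root_range = paste(config$root_range, collapse = ","),
           seed = config$seed, n_rejections = sim$n_rejections)
  writeLines(paste(names(cfg), cfg, sep = "\t"), paths["config"])
  invisible(paths)
}
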