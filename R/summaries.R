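# Model selection (AICc, Akaike weights, LRT), per-area inclusion
# proportions, most-probable ranges, and dispersal / extirpation / composite
# range-transition counting.

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 lnL + 2k + 2k(k+1)/(n - k - 1)`.
#'
#' @param lnL log-likelihood.
#' @param k number of free parameters.
#' @param n sample size (number of tips).
#' @return the AICc value.
#' @export
aicc <- function(lnL, k, n) {
  if (n <= k + 1) stop("AICc requires n > k + 1")
  -2 * lnL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights from AICc values
#'
#' `w_i = exp(-Delta_i / 2) / sum_m exp(-Delta_m / 2)` with
#' `Delta_i = AICc_i - min(AICc)`. Invariant to adding a constant to every
#' AICc.
#'
#' @param aicc_values numeric vector (at least one finite value).
#' @return weights summing to 1.
#' @export
akaike_weights <- function(aicc_values) {
  if (!length(aicc_values) || !any(is.finite(aicc_values))) {
    stop("need at least one finite AICc value")
  }
  delta <- aicc_values - min(aicc_values, na.rm = TRUE)
  w <- exp(-delta / 2)
  w[!is.finite(w)] <- 0
  w / sum(w)
}

#' Likelihood-ratio test between nested model fits
#'
#' @param lnL_null log-likelihood of the restricted model.
#' @param lnL_alt log-likelihood of the nesting model (must be >= null up to
#'   numerical tolerance).
#' @param df difference in free parameters (>= 1).
#' @return list with `statistic` (= 2 * (lnL_alt - lnL_null)) and `p_value`
#'   (upper tail of the chi-square with `df` degrees of freedom).
#' @export
likelihood_ratio_test <- function(lnL_null, lnL_alt, df = 1L) {
  if (df < 1L) stop("df must be >= 1")
  stat <- 2 * (lnL_alt - lnL_null)
  if (stat < -1e-6) stop("alternative likelihood is below the null beyond tolerance")
  stat <- max(stat, 0)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Model-comparison table (AICc and Akaike weights)
#'
#' One row per fit, in the fixed order DEC, DEC+J, DIVALIKE, DIVALIKE+J,
#' BAYAREALIKE, BAYAREALIKE+J (fits absent from the list are skipped).
#'
#' @param fits list of `range_fit` objects (see [fit_ml()]), or a data.frame
#'   with columns `model`, `lnL`, `k`, `d`, `e`, `j`.
#' @param n sample size; defaults to the common `n_tips` of the fits.
#' @return data.frame with columns model, lnL, k, d, e, j, AICc, weight.
#' @export
model_comparison_table <- function(fits, n = NULL) {
  model_order <- c("DEC", "DEC+J", "DIVALIKE", "DIVALIKE+J",
                   "BAYAREALIKE", "BAYAREALIKE+J")
  if (is.data.frame(fits)) {
    df <- fits
  } else {
    if (!length(fits)) stop("need at least one fit")
    ns <- vapply(fits, `[[`, numeric(1), "n_tips")
    if (length(unique(ns)) > 1L) stop("fits have inconsistent n_tips")
    if (is.null(n)) n <- ns[1]
    df <- do.call(rbind, lapply(fits, function(f) {
      data.frame(model = f$model, lnL = f$lnL, k = f$k,
                 d = f$params$d, e = f$params$e, j = f$params$j)
    }))
  }
  if (is.null(n)) stop("n is required for a data.frame input")
  df <- df[order(match(df$model, model_order)), , drop = FALSE]
  df$AICc <- mapply(aicc, df$lnL, df$k, MoreArgs = list(n = n))
  df$weight <- akaike_weights(df$AICc)
  rownames(df) <- NULL
  df
}

#' Per-area inclusion proportions of ancestral range estimates
#'
#' For each requested node and each area, the summed probability of all range
#' states containing that area. Cells lie in [0, 1] and neither rows nor
#' columns need sum to 1 (a node 70% {Africa}, 25% {Africa+Arabia}, 5%
#' {Arabia} has Africa proportion 0.95 and Arabia proportion 0.30).
#'
#' @param est an `ancestral_estimate` (see [marginal_ancestral_states()]).
#' @param nodes node ids (default: all internal nodes); may be named, in which
#'   case names label the rows.
#' @param space a `state_space` (default: the estimate's own).
#' @return matrix, nodes in rows, areas in columns.
#' @export
area_inclusion_proportions <- function(est, nodes = NULL, space = est$space) {
  if (is.null(nodes)) nodes <- est$node_ids
  keys <- as.character(as.integer(nodes))
  bad <- setdiff(keys, rownames(est$probs))
  if (length(bad)) stop("unknown node(s): ", paste(bad, collapse = ", "))
  area_masks <- vapply(space$areas, ranges_containing, logical(length(space$states)),
                       space = space)
  out <- est$probs[keys, , drop = FALSE] %*% area_masks
  rownames(out) <- if (!is.null(names(nodes))) names(nodes) else keys
  out
}

#' Most probable ancestral range per node
#'
#' Argmax state of each node's marginal vector; exact ties broken by the
#' lowest state index (the canonical state ordering).
#'
#' @param est an `ancestral_estimate`.
#' @return named integer vector: node id -> range bitmask.
#' @export
most_probable_ranges <- function(est) {
  idx <- apply(est$probs, 1, which.max)
  out <- est$space$states[idx]
  names(out) <- rownames(est$probs)
  out
}

#' Assemble a full node-state map (tips + internal nodes)
#'
#' @param tree a `phylo` tree.
#' @param tip_ranges named integer vector of tip range bitmasks.
#' @param mp named integer vector of internal-node ranges (node id -> bitmask),
#'   e.g. from [most_probable_ranges()].
#' @return integer vector indexed by node number (1..Ntip+Nnode).
#' @export
node_state_map <- function(tree, tip_ranges, mp) {
  ntip <- length(tree$tip.label)
  out <- integer(ntip + tree$Nnode)
  out[seq_len(ntip)] <- as.integer(tip_ranges[tree$tip.label])
  out[as.integer(names(mp))] <- as.integer(mp)
  out
}

#' Count dispersal and area-loss events along the tree
#'
#' Compares each parent range with each child range along every branch: an
#' area present in the child but not the parent is one dispersal event,
#' attributed fractionally (weight 1 / |parent range|) to every source area of
#' the parent, so each gained area contributes exactly one unit of total
#' dispersal; an area present in the parent but not the child increments that
#' area's loss count.
#'
#' @param tree a `phylo` tree.
#' @param states integer vector of range bitmasks indexed by node number
#'   (tips and internal nodes), e.g. from [node_state_map()]; all non-null.
#' @param space a `state_space`.
#' @return list with `dispersal` (directed area x area weight matrix, zero
#'   diagonal) and `losses` (named per-area counts).
#' @export
count_events <- function(tree, states, space) {
  if (any(states == 0L)) stop("null ranges are not allowed in event counting")
  n <- space$n_areas
  disp <- matrix(0, n, n, dimnames = list(space$areas, space$areas))
  losses <- stats::setNames(numeric(n), space$areas)
  for (i in seq_len(nrow(tree$edge))) {
    p <- states[tree$edge[i, 1]]
    c <- states[tree$edge[i, 2]]
    gained <- range_area_idx(bitwAnd(c, bitwNot(p)), n)
    lost <- range_area_idx(bitwAnd(p, bitwNot(c)), n)
    src <- range_area_idx(p, n)
    if (length(gained)) {
      for (b in gained) disp[src, b] <- disp[src, b] + 1 / length(src)
    }
    if (length(lost)) losses[lost] <- losses[lost] + 1
  }
  list(dispersal = disp, losses = losses)
}

#' Count composite-label range transitions along the tree
#'
#' Classifies the parent and child range of every branch with
#' [classify_composite()] and counts branches whose labels differ, e.g.
#' Laurasia -> Gondwana.
#'
#' @inheritParams count_events
#' @param scheme a `composite_scheme`.
#' @return label x label count matrix (diagonal zero).
#' @export
count_composite_transitions <- function(tree, states, scheme) {
  if (any(states == 0L)) stop("null ranges are not allowed")
  labs <- c("Laurasia", "Gondwana", "NorthernPangaea", "Pangaea")
  counts <- matrix(0, 4, 4, dimnames = list(labs, labs))
  cls <- classify_composite(states, scheme)
  for (i in seq_len(nrow(tree$edge))) {
    a <- cls[tree$edge[i, 1]]
    b <- cls[tree$edge[i, 2]]
    if (a != b) counts[a, b] <- counts[a, b] + 1
  }
  counts
}

#' Write a dispersal matrix as a (source, target, weight) edge list
#' @param dispersal directed area x area matrix.
#' @param path output TSV path.
#' @export
write_dispersal_edgelist <- function(dispersal, path) {
  idx <- which(dispersal > 0, arr.ind = TRUE)
  df <- data.frame(source = rownames(dispersal)[idx[, 1]],
                   target = colnames(dispersal)[idx[, 2]],
                   weight = dispersal[idx])
  df <- df[order(df$source, df$target), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
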