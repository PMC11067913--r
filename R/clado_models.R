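# Anagenetic rate matrix (dispersal d, extirpation e) and cladogenetic event
# tables for the DEC / DIVALIKE / BAYAREALIKE families, with an optional
# founder-event (jump) weight j.

J_CEILING <- c(DEC = 3, DIVALIKE = 2, BAYAREALIKE = 1)

#' Specify a cladogenetic model family
#'
#' @param family one of "DEC", "DIVALIKE", "BAYAREALIKE".
#' @param jump whether founder-event (jump) speciation is allowed; without it
#'   the weight j is forced to 0.
#' @return a `model_family` object with fields `family`, `jump`, `label`
#'   (e.g. "DEC+J") and `j_ceiling` (3 for DEC, 2 for DIVALIKE, 1 for
#'   BAYAREALIKE).
#' @export
model_family <- function(family = c("DEC", "DIVALIKE", "BAYAREALIKE"),
                         jump = FALSE) {
  family <- match.arg(family)
  structure(
    list(family = family, jump = isTRUE(jump),
         label = paste0(family, if (isTRUE(jump)) "+J" else ""),
         j_ceiling = unname(J_CEILING[family])),
    class = "model_family"
  )
}

#' Anagenetic dispersal/extirpation rate matrix over the state space
#'
#' Builds the generator Q of the continuous-time Markov chain of range change
#' along branches. For a non-null range R: the rate of gaining area b (with
#' the enlarged range still within the size cap) is `d * sum_{a in R} mult[a, b]`;
#' the rate of losing any area a in R is `e` (single-area ranges contract to
#' the null range, which is absorbing). Diagonal entries are minus the row
#' sums, so every row sums to zero.
#'
#' @param space a `state_space`.
#' @param d dispersal rate per source area per target area (events/Myr).
#' @param e per-area extirpation rate (events/Myr).
#' @param mult optional `n_areas x n_areas` nonnegative dispersal multiplier
#'   matrix (diagonal ignored); defaults to all ones.
#' @return square numeric matrix, one row/column per state, dimnames the state
#'   labels.
#' @export
build_anagenetic_matrix <- function(space, d, e, mult = NULL) {
  if (d < 0 || e < 0) stop("d and e must be nonnegative")
  n <- space$n_areas
  if (is.null(mult)) {
    mult <- matrix(1, n, n)
  } else {
    mult <- as.matrix(mult)
    if (!all(dim(mult) == c(n, n))) stop("multiplier matrix must be n_areas x n_areas")
    if (any(mult < 0)) stop("multiplier matrix entries must be nonnegative")
  }
  S <- length(space$states)
  q <- matrix(0, S, S, dimnames = list(space$labels, space$labels))
  for (i in seq_len(S)) {
    R <- space$states[i]
    if (R == 0L) next  # null range is absorbing
    in_idx <- range_area_idx(R, n)
    # expansions
    if (space$size[i] < space$max_range_size) {
      for (b in setdiff(seq_len(n), in_idx)) {
        target <- bitwOr(R, bitwShiftL(1L, b - 1L))
        jdx <- state_index(space, target)
        if (!is.na(jdx)) q[i, jdx] <- q[i, jdx] + d * sum(mult[in_idx, b])
      }
    }
    # contractions (size-1 ranges contract to null, if the null state exists)
    for (a in in_idx) {
      target <- bitwAnd(R, bitwNot(bitwShiftL(1L, a - 1L)))
      jdx <- state_index(space, target)
      if (!is.na(jdx)) q[i, jdx] <- q[i, jdx] + e
    }
    q[i, i] <- -sum(q[i, -i])
  }
  q
}

# --- cladogenetic event enumeration ----------------------------------------

# all nonempty proper subsets of a bitmask (as integer bitmasks)
proper_subsets <- function(bits) {
  # standard subset-enumeration trick: s = (s - 1) & bits walks all submasks
  out <- integer(0)
  s <- bitwAnd(bits - 1L, bits)
  while (s > 0L) {
    out <- c(out, s)
    s <- bitwAnd(s - 1L, bits)
  }
  out
}

#' Enumerate allowed cladogenetic daughter-range pairs for one parent
#'
#' Families differ in which events exist. For a single-area parent all
#' families allow only the sympatric copy (R, R). For widespread parents:
#' DEC allows subset sympatry (one daughter keeps R, the other a single area
#' of R) and narrow vicariance (R splits into a single area and the rest);
#' DIVALIKE allows every ordered disjoint bipartition of R (widespread
#' daughters permitted) and no subset sympatry; BAYAREALIKE allows only the
#' exact copy (R, R). With `jump = TRUE` every parent additionally gets
#' founder events (R, {b}) and ({b}, R) for each area b outside R. Ordered
#' pairs are listed both ways; symmetric self-pairs once.
#'
#' @param parent non-null parent range bitmask.
#' @param family a `model_family`.
#' @param space a `state_space`.
#' @return data.frame with columns `left`, `right` (daughter bitmasks) and
#'   `type` (sympatry, subset, vicariance, jump).
#' @export
enumerate_clado_events <- function(parent, family, space) {
  parent <- as.integer(parent)
  if (parent == 0L) stop("the null range cannot cladogenerate")
  n <- space$n_areas
  sz <- range_size(parent, n)
  left <- integer(0); right <- integer(0); type <- character(0)
  add <- function(l, r, ty) {
    left <<- c(left, l); right <<- c(right, r); type <<- c(type, rep(ty, length(l)))
  }

  if (family$family == "BAYAREALIKE") {
    add(parent, parent, "sympatry")
  } else if (sz == 1L) {
    add(parent, parent, "sympatry")
  } else if (family$family == "DEC") {
    singles <- bitwShiftL(1L, range_area_idx(parent, n) - 1L)
    add(rep(parent, length(singles)), singles, "subset")
    add(singles, rep(parent, length(singles)), "subset")
    vl <- c(singles, bitwAnd(parent, bitwNot(singles)))
    vr <- c(bitwAnd(parent, bitwNot(singles)), singles)
    dup <- duplicated(paste(vl, vr))
    add(vl[!dup], vr[!dup], "vicariance")
  } else { # DIVALIKE
    subs <- proper_subsets(parent)
    add(subs, bitwAnd(parent, bitwNot(subs)), "vicariance")
  }

  if (family$jump) {
    outside <- setdiff(seq_len(n), range_area_idx(parent, n))
    if (length(outside)) {
      singles <- bitwShiftL(1L, outside - 1L)
      add(rep(parent, length(singles)), singles, "jump")
      add(singles, rep(parent, length(singles)), "jump")
    }
  }

  data.frame(left = left, right = right, type = type)
}

#' Build the full cladogenetic event table with founder-event weight j
#'
#' Every enumerated event carries its type's per-event weight and the weights
#' are normalized to probabilities within each parent. Per-event weights:
#' DEC families give sympatry/subset/vicariance events weight (3-j)/3,
#' DIVALIKE gives sympatry/vicariance (2-j)/2, BAYAREALIKE gives the copy
#' 1-j; each individual ordered jump event carries weight j. At j = 0 the
#' table equals the jump-free table event for event (zero-weight jump events
#' are dropped).
#'
#' @param family a `model_family`.
#' @param j founder-event weight, `0 <= j < j_ceiling`; must be 0 when the
#'   family has no jump.
#' @param space a `state_space`.
#' @return a `clado_table`: list with parallel vectors `parent`, `left`,
#'   `right` (state indices into `space$states`), `type`, `prob`, plus the
#'   family, `j` and number of states. Probabilities sum to 1 within every
#'   non-null parent; the null parent has no events.
#' @export
build_clado_table <- function(family, j, space) {
  if (!family$jump && j != 0) stop("j > 0 requires a +J model family")
  if (j < 0 || j >= family$j_ceiling) {
    stop("j must satisfy 0 <= j < ", family$j_ceiling, " for ", family$family)
  }
  base_w <- switch(family$family,
                   DEC = (3 - j) / 3,
                   DIVALIKE = (2 - j) / 2,
                   BAYAREALIKE = 1 - j)
  parent <- integer(0); left <- integer(0); right <- integer(0)
  type <- character(0); prob <- numeric(0)
  for (i in seq_along(space$states)) {
    R <- space$states[i]
    if (R == 0L) next
    ev <- enumerate_clado_events(R, family, space)
    w <- ifelse(ev$type == "jump", j, base_w)
    keep <- w > 0
    ev <- ev[keep, , drop = FALSE]; w <- w[keep]
    if (!nrow(ev)) stop("no cladogenetic event has positive weight for parent ",
                        space$labels[i])
    parent <- c(parent, rep(i, nrow(ev)))
    left <- c(left, state_index(space, ev$left))
    right <- c(right, state_index(space, ev$right))
    type <- c(type, ev$type)
    prob <- c(prob, w / sum(w))
  }
  if (anyNA(left) || anyNA(right)) stop("daughter state outside the state space")
  structure(
    list(family = family, j = j, n_states = length(space$states),
         parent = parent, left = left, right = right, type = type, prob = prob),
    class = "clado_table"
  )
}

#' Events of one parent state from a cladogenetic table
#' @param table a `clado_table`.
#' @param parent_idx state index of the parent.
#' @param space optional `state_space` to add readable labels.
#' @return data.frame of events (left/right indices, type, prob).
#' @export
clado_events <- function(table, parent_idx, space = NULL) {
  sel <- table$parent == parent_idx
  out <- data.frame(left = table$left[sel], right = table$right[sel],
                    type = table$type[sel], prob = table$prob[sel])
  if (!is.null(space)) {
    out$left_label <- space$labels[out$left]
    out$right_label <- space$labels[out$right]
  }
  out
}

#' Write a cladogenetic event table as TSV
#' @param table a `clado_table`.
#' @param space the `state_space` it was built on.
#' @param path output file.
#' @export
write_clado_table <- function(table, space, path) {
  df <- data.frame(parent = space$labels[table$parent],
                   left = space$labels[table$left],
                   right = space$labels[table$right],
                   type = table$type, prob = table$prob)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# --- branch transition probabilities ----------------------------------------

#' Transition probability matrix over one branch
#'
#' Computes `expm(q * t)` for the anagenetic generator. Rows sum to 1 and all
#' entries lie in [0, 1] (numerical tolerance 1e-9).
#'
#' @param q anagenetic rate matrix.
#' @param t branch length (Myr), nonnegative.
#' @return stochastic matrix of the same dimension.
#' @export
branch_transition_matrix <- function(q, t) {
  if (t < 0) stop("branch length must be nonnegative")
  if (t == 0) {
    p <- diag(nrow(q))
    dimnames(p) <- dimnames(q)
    return(p)
  }
  p <- as.matrix(Matrix::expm(q * t))
  p[p < 0 & p > -1e-12] <- 0
  dimnames(p) <- dimnames(q)
  p
}

# Fast repeated-exponential propagator: one eigendecomposition of Q, then
# P(t) = V diag(exp(lambda t)) V^-1 per branch. Falls back to Matrix::expm
# when Q is close to defective (validated against expm at a probe time).
make_propagator <- function(q) {
  prop <- list(q = q, fallback = TRUE)
  dec <- tryCatch({
    eg <- eigen(q)
    vinv <- solve(eg$vectors)
    list(values = eg$values, v = eg$vectors, vinv = vinv)
  }, error = function(e) NULL)
  if (!is.null(dec)) {
    probe <- Re(dec$v %*% (exp(dec$values) * dec$vinv))  # t = 1
    ref <- as.matrix(Matrix::expm(q))
    if (max(abs(probe - ref)) < 1e-9) {
      prop <- list(q = q, fallback = FALSE, values = dec$values,
                   v = dec$v, vinv = dec$vinv)
    }
  }
  prop
}

# P(t) %*% u without forming P
propagate_vec <- function(prop, t, u) {
  if (t == 0) return(u)
  if (prop$fallback) {
    return(as.numeric(branch_transition_matrix(prop$q, t) %*% u))
  }
  out <- Re(prop$v %*% (exp(prop$values * t) * (prop$vinv %*% u)))
  as.numeric(out)
}

propagate_matrix <- function(prop, t, clean = TRUE) {
  if (prop$fallback || t == 0) return(branch_transition_matrix(prop$q, t))
  p <- Re(prop$v %*% (exp(prop$values * t) * prop$vinv))
  if (clean) p[p < 0] <- 0
  p
}
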