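# Range state space: ranges are sets of areas encoded as integer bitmasks,
# bit i (value 2^i) <=> presence in area i (0-based, header column order).

#' Number of areas in a range bitmask
#'
#' @param bits integer vector of range bitmasks.
#' @param n_areas number of areas (bits above this are assumed unset).
#' @return integer vector of range sizes (popcounts).
#' @export
range_size <- function(bits, n_areas = 31L) {
  bits <- as.integer(bits)
  count <- integer(length(bits))
  for (b in seq_len(min(n_areas, 31L)) - 1L) {
    count <- count + bitwAnd(bitwShiftR(bits, b), 1L)
  }
  count
}

#' Area indices contained in a range bitmask
#' @param bits a single range bitmask.
#' @param n_areas number of areas.
#' @return integer vector of 1-based area indices.
#' @export
range_area_idx <- function(bits, n_areas) {
  which(bitwAnd(as.integer(bits), bitwShiftL(1L, seq_len(n_areas) - 1L)) > 0L)
}

#' Build the capped range state space
#'
#' Enumerates all ranges (sets of areas) of size up to `max_range_size` over
#' `n_areas` named areas, optionally including the null (empty) range. States
#' are ordered deterministically: null first, then by range size, then by
#' ascending bitmask value, so indices are stable across runs and suitable for
#' matrix rows/columns and serialized output.
#'
#' With nine areas and a maximum range size of four (null included) the space
#' has 1 + C(9,1) + C(9,2) + C(9,3) + C(9,4) = 256 states.
#'
#' @param n_areas number of areas (1..31).
#' @param max_range_size largest allowed number of areas in a range.
#' @param include_null whether the empty range is a state (it is the absorbing
#'   extinction state of the anagenetic process).
#' @param area_names character vector of unique area names; defaults to
#'   `LETTERS`-style labels.
#' @return an object of class `state_space`: a list with `areas`, `n_areas`,
#'   `max_range_size`, `include_null`, `states` (integer bitmasks in canonical
#'   order), `size` (per-state popcount) and `labels`.
#' @export
build_state_space <- function(n_areas, max_range_size, include_null = TRUE,
                              area_names = NULL) {
  n_areas <- as.integer(n_areas)
  max_range_size <- as.integer(max_range_size)
  if (n_areas < 1L || n_areas > 31L) stop("n_areas must be in 1..31")
  if (max_range_size < 1L || max_range_size > n_areas) {
    stop("max_range_size must be in 1..n_areas")
  }
  if (is.null(area_names)) {
    area_names <- if (n_areas <= 26L) LETTERS[seq_len(n_areas)] else
      paste0("A", seq_len(n_areas))
  }
  area_names <- as.character(area_names)
  if (length(area_names) != n_areas) stop("area_names must have length n_areas")
  if (anyDuplicated(area_names) || any(!nzchar(area_names))) {
    stop("area names must be unique and non-empty")
  }

  all_masks <- seq_len(bitwShiftL(1L, n_areas)) - 1L
  sz <- range_size(all_masks, n_areas)
  keep <- sz >= 1L & sz <= max_range_size
  masks <- all_masks[keep]
  szk <- sz[keep]
  ord <- order(szk, masks)
  masks <- masks[ord]
  szk <- szk[ord]
  if (include_null) {
    masks <- c(0L, masks)
    szk <- c(0L, szk)
  }

  labels <- vapply(masks, function(m) {
    if (m == 0L) "null" else
      paste(area_names[range_area_idx(m, n_areas)], collapse = "+")
  }, character(1))

  structure(
    list(areas = area_names, n_areas = n_areas,
         max_range_size = max_range_size, include_null = include_null,
         states = masks, size = szk, labels = labels),
    class = "state_space"
  )
}

#' @export
print.state_space <- function(x, ...) {
  cat(sprintf("state_space: %d areas (%s), max range size %d, %s null, %d states\n",
              x$n_areas, paste(x$areas, collapse = ", "), x$max_range_size,
              if (x$include_null) "with" else "without", length(x$states)))
  invisible(x)
}

#' Index of a range bitmask in a state space
#' @param space a `state_space`.
#' @param bits integer vector of bitmasks.
#' @return integer indices into `space$states` (NA if absent).
#' @export
state_index <- function(space, bits) match(as.integer(bits), space$states)

#' Encode area names as a range bitmask
#' @param areas character vector of area names (empty vector = null range).
#' @param space a `state_space`.
#' @return a single integer bitmask.
#' @export
range_state <- function(areas, space) {
  if (length(areas) == 0L) return(0L)
  idx <- match(areas, space$areas)
  if (anyNA(idx)) stop("unknown area(s): ", paste(areas[is.na(idx)], collapse = ", "))
  Reduce(bitwOr, bitwShiftL(1L, idx - 1L), 0L)
}

#' Decode a range bitmask to area names
#' @param bits a single range bitmask.
#' @param space a `state_space`.
#' @return character vector of area names.
#' @export
range_areas <- function(bits, space) {
  space$areas[range_area_idx(bits, space$n_areas)]
}

#' Human-readable label for range bitmasks
#' @param bits integer vector of bitmasks.
#' @param space a `state_space`.
#' @return character vector like `"Africa+Eurasia"`, `"null"` for the empty range.
#' @export
range_label <- function(bits, space) {
  vapply(as.integer(bits), function(m) {
    if (m == 0L) "null" else paste(range_areas(m, space), collapse = "+")
  }, character(1))
}

#' The nine-plate squamate area scheme
#'
#' The named preset used throughout the examples: nine tectonic plates, with
#' the composite supercontinent scheme splitting them into Laurasian
#' (Eurasia, Caribbean, North America, Sunda) and Gondwanan (Africa, Arabia,
#' Australia, India, South America) areas, Africa acting as the pivot that
#' defines Northern Pangaea.
#'
#' @return a list with `areas` (in file-column order), `laurasia`, `gondwana`,
#'   `pivot`, `max_range_size` and `labels` (the four composite labels).
#' @export
squamate_scheme <- function() {
  areas <- c("Africa", "Arabia", "Australia", "Caribbean", "Eurasia",
             "India", "NorthAmerica", "SouthAmerica", "Sunda")
  list(
    areas = areas,
    laurasia = c("Eurasia", "Caribbean", "NorthAmerica", "Sunda"),
    gondwana = c("Africa", "Arabia", "Australia", "India", "SouthAmerica"),
    pivot = "Africa",
    max_range_size = 4L,
    labels = c("Laurasia", "Gondwana", "NorthernPangaea", "Pangaea")
  )
}

#' Build a composite supercontinent scheme
#'
#' @param laurasia,gondwana disjoint character vectors covering all areas.
#' @param pivot single area in `gondwana` (ranges whose only Gondwanan member
#'   is the pivot are labelled Northern Pangaea rather than Pangaea).
#' @param space a `state_space` whose areas the scheme must cover.
#' @return an object of class `composite_scheme`.
#' @export
composite_scheme <- function(laurasia, gondwana, pivot, space) {
  if (length(intersect(laurasia, gondwana)) > 0L) {
    stop("laurasia and gondwana must be disjoint")
  }
  if (!setequal(union(laurasia, gondwana), space$areas)) {
    stop("laurasia and gondwana must jointly cover all areas")
  }
  if (length(pivot) != 1L || !(pivot %in% gondwana)) {
    stop("pivot must be a single Gondwanan area")
  }
  structure(
    list(laurasia_bits = range_state(laurasia, space),
         gondwana_bits = range_state(gondwana, space),
         pivot_bits = range_state(pivot, space),
         laurasia = laurasia, gondwana = gondwana, pivot = pivot),
    class = "composite_scheme"
  )
}

#' Classify a range into a composite supercontinent label
#'
#' Labels, in precedence order: subset of the Laurasian areas -> "Laurasia";
#' subset of the Gondwanan areas -> "Gondwana"; Gondwanan part equal to the
#' pivot alone -> "NorthernPangaea"; any other Laurasian+Gondwanan mixture ->
#' "Pangaea". Northern Pangaea is a carve-out of the mixed ranges whose only
#' Gondwanan member is the pivot (Africa in the squamate scheme).
#'
#' @param bits integer vector of non-null range bitmasks.
#' @param scheme a `composite_scheme`.
#' @return character vector of labels.
#' @export
classify_composite <- function(bits, scheme) {
  bits <- as.integer(bits)
  if (any(bits == 0L)) stop("cannot classify the null range")
  gond_part <- bitwAnd(bits, scheme$gondwana_bits)
  laur_part <- bitwAnd(bits, scheme$laurasia_bits)
  out <- rep("Pangaea", length(bits))
  out[gond_part == 0L] <- "Laurasia"
  out[laur_part == 0L] <- "Gondwana"
  out[gond_part == scheme$pivot_bits & laur_part != 0L] <- "NorthernPangaea"
  out
}

#' Enforce the maximum range size on a tip-range table
#'
#' Ranges within the cap pass through unchanged. Over-cap taxa are replaced by
#' their entry in `overrides` (which must itself satisfy the cap); an over-cap
#' taxon with no override is an error naming the taxon. Idempotent.
#'
#' @param tip_ranges named integer vector: taxon -> range bitmask.
#' @param max_size the range-size cap.
#' @param overrides named integer vector of replacement ranges (may be empty).
#' @param n_areas number of areas (for popcounts).
#' @return a new named integer vector satisfying the cap.
#' @export
enforce_range_cap <- function(tip_ranges, max_size, overrides = integer(0),
                              n_areas = 31L) {
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(tip_ranges))
    if (length(unknown)) {
      stop("override(s) for unknown taxon: ", paste(unknown, collapse = ", "))
    }
    if (any(range_size(overrides, n_areas) > max_size)) {
      stop("override ranges must satisfy the cap")
    }
  }
  sz <- range_size(tip_ranges, n_areas)
  over <- names(tip_ranges)[sz > max_size]
  missing_over <- setdiff(over, names(overrides))
  if (length(missing_over)) {
    stop("range exceeds the cap of ", max_size, " with no override for taxon: ",
         paste(missing_over, collapse = ", "))
  }
  out <- tip_ranges
  hit <- intersect(over, names(overrides))
  out[hit] <- overrides[hit]
  out
}

#' Mask of states containing a given area
#'
#' Used for per-area inclusion proportions: the proportion of ancestral-range
#' probability falling on states that contain the area.
#'
#' @param area area name or 1-based index.
#' @param space a `state_space`.
#' @return logical vector over `space$states`; the null range is always FALSE.
#' @export
ranges_containing <- function(area, space) {
  if (is.character(area)) {
    idx <- match(area, space$areas)
    if (is.na(idx)) stop("unknown area: ", area)
  } else {
    idx <- as.integer(area)
    if (idx < 1L || idx > space$n_areas) stop("unknown area index: ", idx)
  }
  bitwAnd(space$states, bitwShiftL(1L, idx - 1L)) > 0L
}
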