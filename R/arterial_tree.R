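#' Arterial tree tables
#'
#' The proximal pulmonary arterial tree (MPA, LPA, RPA and descendants) is
#' represented as a tibble with one row per vessel segment and class
#' `arterial_tree`. Columns:
#'
#' * `id` — opaque segment identifier (character).
#' * `parent_id` — parent segment id, `NA` for the root.
#' * `name` — anatomical label (`"MPA"`, `"LPA"`, `"RPA"`, deeper branches
#'   `"LPA.1"`, `"RPA.2.1"`, ...).
#' * `length_cm`, `diameter_cm` — hydraulic dimensions, both positive; the
#'   lumen is assumed uniform along a segment.
#' * `generation` — 0 for the root, parent's generation + 1 otherwise.
#'
#' Structural invariants (checked by [validate_tree()]): exactly one root,
#' connected and acyclic, at least two leaf segments (the outlets), and no
#' child more than 5% wider than its parent.
#'
#' @name arterial_tree
NULL

new_arterial_tree <- function(df) {
  df <- tibble::as_tibble(df)
  class(df) <- c("arterial_tree", class(df))
  df
}

#' Validate an arterial tree
#'
#' Checks the structural invariants of an [arterial_tree] table and returns it
#' invisibly, or aborts with a message naming the offending field.
#'
#' @param tree An `arterial_tree` tibble (or plain data frame with the same
#'   columns).
#' @param min_outlets Minimum number of leaf segments required. Anatomical
#'   trees need at least 2; internal callers may relax this for degenerate
#'   test networks.
#' @return `tree`, invisibly.
#' @export
validate_tree <- function(tree, min_outlets = 2) {
  required <- c("id", "parent_id", "name", "length_cm", "diameter_cm", "generation")
  missing_cols <- setdiff(required, names(tree))
  if (length(missing_cols) > 0) {
    stop("tree is missing field(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(tree$id)) {
    stop("field `id`: duplicated segment identifiers", call. = FALSE)
  }
  if (any(!is.finite(tree$diameter_cm)) || any(tree$diameter_cm <= 0)) {
    stop("field `diameter_cm`: all diameters must be positive", call. = FALSE)
  }
  if (any(!is.finite(tree$length_cm)) || any(tree$length_cm <= 0)) {
    stop("field `length_cm`: all lengths must be positive", call. = FALSE)
  }
  roots <- tree$id[is.na(tree$parent_id)]
  if (length(roots) != 1) {
    stop(
      "field `parent_id`: expected exactly one root (parent_id NA), found ",
      length(roots),
      call. = FALSE
    )
  }
  non_root <- tree[!is.na(tree$parent_id), ]
  if (nrow(non_root) > 0 && !all(non_root$parent_id %in% tree$id)) {
    stop("field `parent_id`: refers to unknown segment id", call. = FALSE)
  }
  # connectivity/acyclicity: every segment must reach the root by parent links
  parent_of <- stats::setNames(tree$parent_id, tree$id)
  for (id in tree$id) {
    seen <- character(0)
    cur <- id
    while (!is.na(parent_of[[cur]])) {
      if (cur %in% seen) {
        stop("field `parent_id`: cycle detected at segment ", cur, call. = FALSE)
      }
      seen <- c(seen, cur)
      cur <- parent_of[[cur]]
    }
    if (cur != roots) {
      stop("field `parent_id`: segment ", id, " not connected to root", call. = FALSE)
    }
  }
  gen <- stats::setNames(tree$generation, tree$id)
  if (gen[[roots]] != 0) {
    stop("field `generation`: root must have generation 0", call. = FALSE)
  }
  if (nrow(non_root) > 0) {
    bad <- non_root$generation != gen[non_root$parent_id] + 1
    if (any(bad)) {
      stop(
        "field `generation`: must equal parent generation + 1 (segment ",
        non_root$id[which(bad)[1]], ")",
        call. = FALSE
      )
    }
    diam <- stats::setNames(tree$diameter_cm, tree$id)
    too_wide <- non_root$diameter_cm > diam[non_root$parent_id] * 1.05
    if (any(too_wide)) {
      stop(
        "field `diameter_cm`: child wider than parent (segment ",
        non_root$id[which(too_wide)[1]], ")",
        call. = FALSE
      )
    }
  }
  n_out <- length(setdiff(tree$id, tree$parent_id))
  if (n_out < min_outlets) {
    stop("tree must have at least ", min_outlets, " outlet segments", call. = FALSE)
  }
  invisible(tree)
}

root_id <- function(tree) tree$id[is.na(tree$parent_id)]

#' Generate a synthetic proximal pulmonary arterial tree
#'
#' Builds a rooted binary tree of vessel segments whose bifurcations obey a
#' Murray-type diameter power law: at each branch point
#' `D_parent^gamma = D_child1^gamma + D_child2^gamma`. The root is labelled
#' `"MPA"` and its two children `"LPA"` and `"RPA"`, mirroring the proximal
#' pulmonary anatomy the tree stands in for.
#'
#' With `asymmetry = 0` the split is exactly symmetric. With `asymmetry = a`
#' in (0, 1), the larger daughter's share of `D_parent^gamma` is drawn
#' uniformly from `[1/2, 1/2 + a/2]` at every bifurcation (seeded), and which
#' side is larger is randomised, so the tree is irregular but still closes the
#' Murray relation exactly.
#'
#' @param root_diameter Root (MPA) diameter in cm. Must be positive.
#' @param n_generations Number of bifurcation generations (>= 1). The default
#'   3 gives 8 outlets, a typical proximal truncation.
#' @param murray_exponent Diameter power-law exponent `gamma` (> 0). Default
#'   2.25, consistent with the exponent used to apportion outlet resistance;
#'   the classic anatomical value 3.0 is also common.
#' @param asymmetry Bifurcation asymmetry in [0, 1); 0 gives a perfectly
#'   symmetric tree.
#' @param length_to_diameter Segment length as a multiple of its diameter.
#'   Default 3.0, typical proximal pulmonary proportions.
#' @param seed Integer seed controlling the (only) randomness: asymmetric
#'   share draws. The result is deterministic for a fixed seed.
#'
#' @return An [arterial_tree] tibble.
#' @export
#' @examples
#' tree <- generate_tree(3.0, n_generations = 2, seed = 1)
#' outlets(tree)
generate_tree <- function(root_diameter,
                          n_generations = 3,
                          murray_exponent = 2.25,
                          asymmetry = 0,
                          length_to_diameter = 3.0,
                          seed = 1L) {
  if (!is.numeric(root_diameter) || length(root_diameter) != 1 || root_diameter <= 0) {
    stop("`root_diameter` must be a single positive number (cm)", call. = FALSE)
  }
  if (!is.numeric(murray_exponent) || murray_exponent <= 0) {
    stop("`murray_exponent` must be positive", call. = FALSE)
  }
  if (!is.numeric(n_generations) || n_generations < 1) {
    stop("`n_generations` must be >= 1", call. = FALSE)
  }
  if (!is.numeric(asymmetry) || asymmetry < 0 || asymmetry >= 1) {
    stop("`asymmetry` must be in [0, 1)", call. = FALSE)
  }
  if (!is.numeric(length_to_diameter) || length_to_diameter <= 0) {
    stop("`length_to_diameter` must be positive", call. = FALSE)
  }
  n_generations <- as.integer(n_generations)

  withr::with_seed(as.integer(seed), {
    rows <- list(list(
      id = "s1", parent_id = NA_character_, name = "MPA",
      diameter_cm = root_diameter, generation = 0L
    ))
    frontier <- list(list(id = "s1", name = "MPA", diameter = root_diameter, gen = 0L))
    next_id <- 2L
    while (length(frontier) > 0 && frontier[[1]]$gen < n_generations) {
      new_frontier <- list()
      for (node in frontier) {
        share_big <- if (asymmetry > 0) stats::runif(1, 0.5, 0.5 + asymmetry / 2) else 0.5
        big_first <- if (asymmetry > 0) stats::runif(1) < 0.5 else TRUE
        shares <- if (big_first) c(share_big, 1 - share_big) else c(1 - share_big, share_big)
        child_names <- if (node$gen == 0L) {
          c("LPA", "RPA")
        } else {
          paste0(node$name, ".", 1:2)
        }
        for (k in 1:2) {
          d <- node$diameter * shares[k]^(1 / murray_exponent)
          id <- paste0("s", next_id)
          next_id <- next_id + 1L
          rows[[length(rows) + 1L]] <- list(
            id = id, parent_id = node$id, name = child_names[k],
            diameter_cm = d, generation = node$gen + 1L
          )
          new_frontier[[length(new_frontier) + 1L]] <-
            list(id = id, name = child_names[k], diameter = d, gen = node$gen + 1L)
        }
      }
      frontier <- new_frontier
    }
    tree <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
    tree$length_cm <- length_to_diameter * tree$diameter_cm
    tree <- tree[, c("id", "parent_id", "name", "length_cm", "diameter_cm", "generation")]
    validate_tree(new_arterial_tree(tree))
    new_arterial_tree(tree)
  })
}

#' Outlet segments of an arterial tree
#'
#' Returns the leaf segments (the model outlets) in a stable, documented
#' order: depth-first from the root, visiting children sorted by diameter
#' descending, ties broken by id. Windkessel parameter vectors are aligned
#' with this ordering throughout the package.
#'
#' @param tree An [arterial_tree].
#' @return A tibble of leaf segments (subset of `tree` rows) in outlet order.
#' @export
outlets <- function(tree) {
  children_of <- split(tree, tree$parent_id)
  leaf_ids <- character(0)
  visit <- function(id) {
    kids <- children_of[[id]]
    if (is.null(kids) || nrow(kids) == 0) {
      leaf_ids <<- c(leaf_ids, id)
      return(invisible(NULL))
    }
    kids <- kids[order(-kids$diameter_cm, kids$id), ]
    for (k in kids$id) visit(k)
  }
  visit(root_id(tree))
  out <- tree[match(leaf_ids, tree$id), ]
  new_arterial_tree(out)
}

#' Apply disease remodeling to an arterial tree
#'
#' Rescales the tree to a target MPA diameter (all segments scaled
#' proportionally, preserving length-to-diameter ratios) and, for the disease
#' groups, narrows a seeded random subset of outlet segments to mimic distal
#' chronic thromboembolic obstruction.
#'
#' @param tree An [arterial_tree].
#' @param group One of `"CTEPH"`, `"CTEPD"`, `"CONTROL"`. Controls are never
#'   occluded.
#' @param mpa_diameter Target root diameter in cm.
#' @param occlusion_fraction Fraction of outlets to narrow, in [0, 1); the
#'   count is rounded down. Ignored for `"CONTROL"`.
#' @param stenosis_factor Diameter multiplier applied to occluded outlets.
#'   Default 0.5.
#' @param seed Integer seed for the choice of occluded outlets.
#'
#' @return A remodeled [arterial_tree].
#' @export
apply_disease_remodeling <- function(tree, group, mpa_diameter,
                                     occlusion_fraction = 0,
                                     stenosis_factor = 0.5,
                                     seed = 1L) {
  validate_tree(tree)
  group <- match.arg(group, c("CTEPH", "CTEPD", "CONTROL"))
  if (!is.numeric(mpa_diameter) || mpa_diameter <= 0) {
    stop("`mpa_diameter` must be positive (cm)", call. = FALSE)
  }
  if (!is.numeric(occlusion_fraction) || occlusion_fraction < 0 || occlusion_fraction >= 1) {
    stop("`occlusion_fraction` must be in [0, 1)", call. = FALSE)
  }
  if (!is.numeric(stenosis_factor) || stenosis_factor <= 0 || stenosis_factor > 1) {
    stop("`stenosis_factor` must be in (0, 1]", call. = FALSE)
  }
  scale <- mpa_diameter / tree$diameter_cm[is.na(tree$parent_id)]
  out <- tree
  out$diameter_cm <- out$diameter_cm * scale
  out$length_cm <- out$length_cm * scale
  if (group != "CONTROL" && occlusion_fraction > 0) {
    leaf <- outlets(out)
    n_occ <- floor(occlusion_fraction * nrow(leaf))
    if (n_occ >= nrow(leaf)) {
      stop("`occlusion_fraction` would occlude all outlets", call. = FALSE)
    }
    if (n_occ > 0) {
      occ_ids <- withr::with_seed(
        as.integer(seed),
        sample(leaf$id, n_occ)
      )
      idx <- out$id %in% occ_ids
      out$diameter_cm[idx] <- out$diameter_cm[idx] * stenosis_factor
    }
  }
  new_arterial_tree(out)
}

#' Read and write arterial tree files
#'
#' Trees are stored as plain CSV with columns
#' `id, parent_id, name, length_cm, diameter_cm` (units fixed to cm; the root
#' has an empty `parent_id`). Generations are recomputed on read.
#' `write_tree()` followed by `read_tree()` is the identity on valid trees.
#'
#' @param path File path.
#' @param tree An [arterial_tree].
#' @return `read_tree()` returns an [arterial_tree]; `write_tree()` returns
#'   `path` invisibly.
#' @export
read_tree <- function(path) {
  df <- readr::read_csv(path,
    col_types = readr::cols(
      id = readr::col_character(),
      parent_id = readr::col_character(),
      name = readr::col_character(),
      length_cm = readr::col_double(),
      diameter_cm = readr::col_double()
    )
  )
  required <- c("id", "parent_id", "name", "length_cm", "diameter_cm")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("tree file missing field(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  # recompute generations from parent links
  roots <- df$id[is.na(df$parent_id)]
  if (length(roots) != 1) {
    stop(
      "field `parent_id`: expected exactly one root, found ", length(roots),
      call. = FALSE
    )
  }
  gen <- stats::setNames(rep(NA_integer_, nrow(df)), df$id)
  gen[roots] <- 0L
  remaining <- setdiff(df$id, roots)
  while (length(remaining) > 0) {
    parent <- stats::setNames(df$parent_id, df$id)[remaining]
    ready <- remaining[!is.na(gen[parent])]
    if (length(ready) == 0) {
      stop("field `parent_id`: disconnected or cyclic segments: ",
        paste(remaining, collapse = ", "),
        call. = FALSE
      )
    }
    gen[ready] <- gen[parent[match(ready, remaining)]] + 1L
    remaining <- setdiff(remaining, ready)
  }
  df$generation <- as.integer(gen[df$id])
  tree <- new_arterial_tree(df[, c(required, "generation")])
  validate_tree(tree)
  tree
}

#' @rdname read_tree
#' @export
write_tree <- function(tree, path) {
  validate_tree(tree)
  readr::write_csv(
    tree[, c("id", "parent_id", "name", "length_cm", "diameter_cm")],
    path
  )
  invisible(path)
}
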