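#' Convert wet mass to dry mass
#'
#' Applies a species-specific dry:wet weight ratio obtained from wood and
#' leaf subsamples.
#'
#' @param wet_mass Nonnegative numeric (vectorized).
#' @param ratio Dry:wet ratio(s) in (0, 1].
#' @return `wet_mass * ratio`.
#' @export
#' @examples
#' to_dry_mass(10, 0.5)  # 5
to_dry_mass <- function(wet_mass, ratio) {
  if (any(!is.finite(ratio)) || any(ratio <= 0) || any(ratio > 1)) {
    stop("dry:wet `ratio` must lie in (0, 1]", call. = FALSE)
  }
  if (any(wet_mass < 0, na.rm = TRUE)) {
    stop("`wet_mass` must be nonnegative", call. = FALSE)
  }
  wet_mass * ratio
}

#' Aggregate segment masses down the branching topology
#'
#' Computes, for every branch, its own segment mass plus the mass of all
#' branches downstream of it, so that all biomass distal to a branching
#' node is attributed to that node's diameter. The root aggregate is the
#' tree total.
#'
#' @param parent_id Character/integer vector of parent ids; root(s) marked
#'   by `NA` (or `""`).
#' @param branch_id Vector of unique branch ids, same length.
#' @param segment_masses Nonnegative per-branch masses, or a matrix with
#'   one column per mass variable.
#' @return Aggregated masses in the input order (vector or matrix matching
#'   `segment_masses`).
#' @export
#' @examples
#' aggregate_downstream(c(NA, "r", "r"), c("r", "a", "b"), c(5, 3, 2))
#' # 10 3 2
aggregate_downstream <- function(parent_id, branch_id, segment_masses) {
  n <- length(branch_id)
  if (anyDuplicated(branch_id)) {
    stop("`branch_id` values must be unique", call. = FALSE)
  }
  m <- as.matrix(segment_masses)
  if (nrow(m) != n || length(parent_id) != n) {
    stop("`parent_id`, `branch_id` and `segment_masses` must align",
         call. = FALSE)
  }
  parent_id[!is.na(parent_id) & parent_id == ""] <- NA
  pidx <- match(parent_id, branch_id)
  if (any(is.na(pidx) & !is.na(parent_id))) {
    bad <- which(is.na(pidx) & !is.na(parent_id))[1L]
    stop("parent id '", parent_id[bad], "' of branch '", branch_id[bad],
         "' not found", call. = FALSE)
  }
  depth <- node_depths(pidx)
  agg <- m
  for (k in order(depth, decreasing = TRUE)) {
    p <- pidx[k]
    if (!is.na(p)) agg[p, ] <- agg[p, ] + agg[k, ]
  }
  if (is.matrix(segment_masses)) agg else drop(agg)
}

# depth of each node from its root; errors on cycles
node_depths <- function(pidx) {
  n <- length(pidx)
  depth <- rep(NA_integer_, n)
  for (k in seq_len(n)) {
    d <- 0L
    j <- k
    while (!is.na(pidx[j])) {
      j <- pidx[j]
      d <- d + 1L
      if (d > n) stop("cycle detected in branch topology", call. = FALSE)
    }
    depth[k] <- d
  }
  depth
}

# internal constructor for the log-scale observation table consumed by the
# likelihood; Y is the n x 4 log-trait matrix in allom_traits() order
new_allom_obs <- function(species, tree, diameter_cm, Y,
                          report = list()) {
  stopifnot(
    is.factor(species), is.factor(tree),
    length(species) == length(tree),
    length(diameter_cm) == length(tree),
    is.matrix(Y), ncol(Y) == N_TRAITS, nrow(Y) == length(tree),
    all(is.finite(Y)), all(is.finite(diameter_cm)), all(diameter_cm > 0)
  )
  tree <- droplevels(tree)
  species <- droplevels(species)
  # every tree must map to exactly one species
  map <- unique(data.frame(tree = as.integer(tree),
                           species = as.integer(species)))
  if (anyDuplicated(map$tree)) {
    stop("a tree id maps to more than one species", call. = FALSE)
  }
  map <- map[order(map$tree), ]
  df <- data.frame(
    species = species,
    tree = tree,
    diameter_cm = as.numeric(diameter_cm),
    log_length = Y[, 1L],
    log_ag_mass = Y[, 2L],
    log_stem_mass = Y[, 3L],
    log_leaf_mass = Y[, 4L]
  )
  structure(
    df,
    class = c("allom_obs", "data.frame"),
    n_obs = nrow(df),
    n_trees = nlevels(tree),
    n_species = nlevels(species),
    tree_species = map$species,
    report = report
  )
}

#' Build the model's observation table from branch records
#'
#' Turns raw field-style branch records into the log-scale, aggregated,
#' filtered table the likelihood consumes: aggregates wet masses downstream
#' when parent links are present, converts wet to dry mass with
#' species-specific ratios, computes aboveground mass as stem + leaf dry
#' mass per branch, applies the minimum-diameter filter, and natural-log
#' transforms the four traits. Records with a nonpositive trait are dropped
#' with a warning (their count is kept in the preprocessing report).
#'
#' @param records Branch-record `data.frame` with columns species_id,
#'   tree_id, branch_id, parent_id, diameter_cm, length_m, wood_wet_kg,
#'   leaf_wet_kg (see [read_branch_csv()]).
#' @param ratios Named numeric vector of dry:wet ratios, one per species
#'   present in `records`.
#' @param min_diameter Diameter filter in cm (default 2; the boundary is
#'   inclusive: a 2.0 cm branch is retained).
#' @return An object of class `allom_obs`: a `data.frame` of species, tree,
#'   observed diameter and the four log traits, with attributes `n_obs`,
#'   `n_trees`, `n_species`, `tree_species` (species index per tree) and
#'   `report` (rows in/out, drop counts).
#' @export
allom_observations <- function(records, ratios, min_diameter = 2.0) {
  required <- c("species_id", "tree_id", "branch_id", "parent_id",
                "diameter_cm", "length_m", "wood_wet_kg", "leaf_wet_kg")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop("records are missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  species_seen <- unique(records$species_id)
  if (is.null(names(ratios)) || !all(species_seen %in% names(ratios))) {
    stop("`ratios` must be a named vector covering every species id",
         call. = FALSE)
  }
  n_in <- nrow(records)

  # aggregate wet masses downstream per tree when parent links are present
  wood_wet <- records$wood_wet_kg
  leaf_wet <- records$leaf_wet_kg
  has_links <- any(!is.na(records$parent_id) & records$parent_id != "")
  if (has_links) {
    for (tid in unique(records$tree_id)) {
      idx <- which(records$tree_id == tid)
      agg <- aggregate_downstream(
        records$parent_id[idx], records$branch_id[idx],
        cbind(wood_wet[idx], leaf_wet[idx])
      )
      wood_wet[idx] <- agg[, 1L]
      leaf_wet[idx] <- agg[, 2L]
    }
  }

  r <- ratios[records$species_id]
  stem_dry <- to_dry_mass(wood_wet, r)
  leaf_dry <- to_dry_mass(leaf_wet, r)
  ag_dry <- stem_dry + leaf_dry
  length_m <- records$length_m

  keep <- records$diameter_cm >= min_diameter
  n_small <- sum(!keep)

  pos <- length_m > 0 & ag_dry > 0 & stem_dry > 0 & leaf_dry > 0
  n_nonpos <- sum(keep & !pos)
  if (n_nonpos > 0) {
    warning(n_nonpos, " record(s) dropped due to nonpositive trait value(s)",
            call. = FALSE)
  }
  keep <- keep & pos

  Y <- cbind(log(length_m[keep]), log(ag_dry[keep]),
             log(stem_dry[keep]), log(leaf_dry[keep]))
  colnames(Y) <- TRAITS
  report <- list(
    rows_in = n_in,
    rows_out = sum(keep),
    dropped_below_min_diameter = n_small,
    dropped_nonpositive_trait = n_nonpos,
    min_diameter = min_diameter,
    aggregated = has_links
  )
  new_allom_obs(
    species = factor(records$species_id[keep]),
    tree = factor(records$tree_id[keep]),
    diameter_cm = records$diameter_cm[keep],
    Y = Y,
    report = report
  )
}

#' @export
print.allom_obs <- function(x, ...) {
  cat("Allometric observation table: ", attr(x, "n_obs"), " observations, ",
      attr(x, "n_trees"), " trees, ", attr(x, "n_species"), " species\n",
      sep = "")
  rep <- attr(x, "report")
  if (length(rep)) {
    cat("  preprocessing: ", rep$rows_in, " rows in, ", rep$rows_out,
        " out (", rep$dropped_below_min_diameter, " below ",
        rep$min_diameter, " cm, ", rep$dropped_nonpositive_trait,
        " nonpositive)\n", sep = "")
  }
  invisible(x)
}

# n x 4 log-trait matrix from an allom_obs
obs_matrix <- function(data) {
  as.matrix(data[, c("log_length", "log_ag_mass",
                     "log_stem_mass", "log_leaf_mass")])
}
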