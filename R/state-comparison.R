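#' Exchanging-residue set for one state
#'
#' The set-level summary of one ligand state: which residues show
#' conformational exchange, split into the reliably fittable and the
#' exchange-broadened-but-unfittable subsets (disjoint by construction;
#' their union is the exchanging set). The optional `universe` is the set
#' of residues observable (assigned) in that state -- residues outside it
#' carry no evidence either way.
#'
#' @param state_label State name.
#' @param fittable,broadened Integer residue vectors (disjoint).
#' @param universe Observable residues; default: the union of the two
#'   sets (no exclusion information).
#' @return Object of class `state_exchange_set` with `fittable`,
#'   `broadened`, `exchanging`, `universe` (all sorted).
#' @export
state_exchange_set <- function(state_label, fittable, broadened = integer(0),
                               universe = NULL) {
  fittable <- sort(unique(as.integer(fittable)))
  broadened <- sort(unique(as.integer(broadened)))
  if (length(intersect(fittable, broadened))) {
    stop("fittable and broadened sets must be disjoint")
  }
  exchanging <- sort(c(fittable, broadened))
  if (is.null(universe)) universe <- exchanging
  universe <- sort(unique(as.integer(universe)))
  if (!all(exchanging %in% universe)) {
    stop("exchanging residues must lie inside the state's universe")
  }
  structure(list(state_label = state_label, fittable = fittable,
                 broadened = broadened, exchanging = exchanging,
                 universe = universe),
            class = "state_exchange_set")
}

#' Exchange set from a screening result
#'
#' @param screen Output of [screen_residues()].
#' @param state_label State name (default: taken from the screen).
#' @return A `state_exchange_set`; the universe is every screened residue.
#' @export
exchange_set_from_fits <- function(screen, state_label = "state") {
  s <- screen$summary
  state_exchange_set(
    state_label,
    fittable = s$residue[s$classification == "two_site_fittable"],
    broadened = s$residue[s$classification == "broadened_unfittable"],
    universe = s$residue)
}

#' Compare exchanging residues between two states
#'
#' Exact set differences over the common observable universe: residues
#' exchanging only in the reference state, only in the other state, and in
#' both. Residues observable in just one of the two states are excluded
#' from the comparison and listed separately -- absence of an assignment
#' is not evidence of absent motion.
#'
#' @param reference,other `state_exchange_set` objects.
#' @param fittable_only If TRUE compare only the reliably fittable sets;
#'   default compares all exchanging residues (fittable + broadened).
#' @return Object of class `comparison_report`: `reference_only`,
#'   `other_only`, `shared`, `excluded` (residues observable in exactly
#'   one state), state labels. Partition identity
#'   `|reference_only| + |shared| = |reference exchanging on the common
#'   universe|` holds by construction and is asserted.
#' @export
diff_states <- function(reference, other, fittable_only = FALSE) {
  stopifnot(inherits(reference, "state_exchange_set"),
            inherits(other, "state_exchange_set"))
  pick <- function(s) if (fittable_only) s$fittable else s$exchanging
  common <- intersect(reference$universe, other$universe)
  excluded <- sort(c(setdiff(reference$universe, other$universe),
                     setdiff(other$universe, reference$universe)))
  a <- intersect(pick(reference), common)
  b <- intersect(pick(other), common)
  out <- list(reference_label = reference$state_label,
              other_label = other$state_label,
              reference_only = sort(setdiff(a, b)),
              other_only = sort(setdiff(b, a)),
              shared = sort(intersect(a, b)),
              excluded = excluded)
  stopifnot(length(out$reference_only) + length(out$shared) == length(a),
            length(out$other_only) + length(out$shared) == length(b))
  structure(out, class = "comparison_report")
}

#' Overlay an exchange set with a CHESCA cluster list
#'
#' Partitions the union of the exchanging set and a cluster membership
#' list into: residues exchanging but outside the cluster
#' (`exchange_only`), cluster residues without detected exchange
#' (`cluster_only`), and cluster residues that exchange (`both`). The
#' three categories are disjoint and exhaustive over the union.
#'
#' @param exchange A `state_exchange_set`.
#' @param cluster Integer vector of cluster residues.
#' @param fittable_only If TRUE use only the reliably fittable subset as
#'   "exchanging".
#' @return Object of class `cluster_overlay` with the three sets and their
#'   `counts`.
#' @export
overlay_cluster <- function(exchange, cluster, fittable_only = FALSE) {
  stopifnot(inherits(exchange, "state_exchange_set"))
  cluster <- sort(unique(as.integer(cluster)))
  ex <- if (fittable_only) exchange$fittable else exchange$exchanging
  out <- list(state_label = exchange$state_label,
              exchange_only = sort(setdiff(ex, cluster)),
              cluster_only = sort(setdiff(cluster, ex)),
              both = sort(intersect(ex, cluster)))
  out$counts <- lengths(out[c("exchange_only", "cluster_only", "both")])
  stopifnot(sum(out$counts) == length(union(ex, cluster)))
  structure(out, class = "cluster_overlay")
}
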