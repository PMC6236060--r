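#' Load a protein structure for contact analysis
#'
#' Thin wrapper over PDB parsing that applies the policies the contact
#' module assumes: standard `ATOM` records only (no heteroatoms or
#' waters), hydrogens dropped, one model, and for alternate locations the
#' highest-occupancy copy of each atom.
#'
#' @param pdb_path Path to a PDB file.
#' @param chain Chain identifier(s) to keep; default all. A requested
#'   chain that is absent is an error listing the available chains.
#' @param model_index Which model of a multi-model file to use (1-based,
#'   default first).
#' @return Object of class `structure_model`: `atoms` (data frame: chain,
#'   resno, resid, elety, elesy, x, y, z, o) and `residues` (chain, resno,
#'   resid).
#' @export
load_structure <- function(pdb_path, chain = NULL, model_index = 1L) {
  pdb <- bio3d::read.pdb(pdb_path, multi = TRUE, rm.alt = FALSE,
                         verbose = FALSE)
  at <- pdb$atom
  n_models <- nrow(pdb$xyz)
  if (model_index < 1 || model_index > n_models) {
    stop("model_index ", model_index, " out of range: file has ",
         n_models, " model(s)")
  }
  xyz <- pdb$xyz[model_index, ]
  at$x <- xyz[seq(1, length(xyz), 3)]
  at$y <- xyz[seq(2, length(xyz), 3)]
  at$z <- xyz[seq(3, length(xyz), 3)]
  at <- at[at$type == "ATOM", , drop = FALSE]
  elesy <- toupper(trimws(at$elesy))
  guess <- toupper(substr(trimws(at$elety), 1, 1))      # for files without
  elesy[!nzchar(elesy)] <- guess[!nzchar(elesy)]        # an element column
  at$elesy <- elesy
  at <- at[!elesy %in% c("H", "D"), , drop = FALSE]
  if (!is.null(chain)) {
    have <- unique(at$chain)
    if (!all(chain %in% have)) {
      stop("chain(s) ", paste(setdiff(chain, have), collapse = ", "),
           " not present; available: ", paste(have, collapse = ", "))
    }
    at <- at[at$chain %in% chain, , drop = FALSE]
  }
  # alternate locations: keep the highest-occupancy copy of each atom,
  # preserving the file's atom order otherwise
  at$o[is.na(at$o)] <- 1
  key <- paste(at$chain, at$resno, at$elety)
  keep_idx <- vapply(split(seq_len(nrow(at)), key),
                     function(ix) ix[which.max(at$o[ix])], integer(1))
  at <- at[sort(keep_idx), , drop = FALSE]
  if (!all(is.finite(at$x) & is.finite(at$y) & is.finite(at$z))) {
    stop("non-finite coordinates in ", pdb_path)
  }
  at <- at[order(at$chain, at$resno), ]
  rownames(at) <- NULL
  residues <- unique(at[, c("chain", "resno", "resid")])
  if (anyDuplicated(paste(residues$chain, residues$resno))) {
    stop("duplicate residue positions within a chain in ", pdb_path)
  }
  rownames(residues) <- NULL
  structure(list(atoms = at[, c("chain", "resno", "resid", "elety",
                                "elesy", "x", "y", "z", "o")],
                 residues = residues, source = pdb_path),
            class = "structure_model")
}

.backbone_atoms <- c("N", "CA", "C", "O", "OXT")

## atoms of one residue (first matching chain if chain not given)
.residue_atoms <- function(structure, resno, chain = NULL) {
  at <- structure$atoms
  sel <- at$resno == resno
  if (!is.null(chain)) sel <- sel & at$chain == chain
  at[sel, , drop = FALSE]
}

.min_dist <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(Inf)
  dx <- outer(a$x, b$x, "-"); dy <- outer(a$y, b$y, "-")
  dz <- outer(a$z, b$z, "-")
  sqrt(min(dx * dx + dy * dy + dz * dz))
}

#' Classify the interaction between two residues
#'
#' Typed residue-residue contact rules over heavy-atom coordinates:
#' \describe{
#'   \item{covalent}{sequence neighbours (|i - j| = 1) in the same chain,
#'     regardless of distance.}
#'   \item{hydrogen_bond}{any N/O (donor or acceptor, backbone or side
#'     chain) heavy-atom pair within the hydrogen-bond cutoff (3.5 A; no
#'     angle term).}
#'   \item{hydrophobic}{both residues in the hydrophobic set (A, V, L, I,
#'     M, F, W, P, Y) with a side-chain carbon pair within 4.5 A.}
#'   \item{proximal_6A}{any heavy-atom pair within 6.0 A when no stronger
#'     label applies ("side chain motion may lead to contact").}
#' }
#' A pair can carry several of the stronger labels at once; `proximal_6A`
#' is only assigned alone.
#'
#' @param structure A `structure_model`.
#' @param res_i,res_j Residue numbers (distinct).
#' @param chain_i,chain_j Optional chain ids.
#' @param cutoffs Geometric cutoffs, see [disp_config()].
#' @return List with `types` (character vector, possibly empty),
#'   `min_distance` (A, over heavy atoms). Residues lacking coordinates
#'   give empty types with a warning.
#' @export
classify_interaction <- function(structure, res_i, res_j,
                                 chain_i = NULL, chain_j = NULL,
                                 cutoffs = disp_config()$network) {
  stopifnot(inherits(structure, "structure_model"))
  if (res_i == res_j && identical(chain_i, chain_j)) stop("res_i must differ from res_j")
  a <- .residue_atoms(structure, res_i, chain_i)
  b <- .residue_atoms(structure, res_j, chain_j)
  if (!nrow(a) || !nrow(b)) {
    warning("residue ", if (!nrow(a)) res_i else res_j,
            " has no coordinates; no edge assigned")
    return(list(types = character(0), min_distance = Inf))
  }
  md <- .min_dist(a, b)
  types <- character(0)
  if (a$chain[1] == b$chain[1] && abs(res_i - res_j) == 1) {
    types <- c(types, "covalent")
  }
  no_a <- a[a$elesy %in% c("N", "O"), , drop = FALSE]
  no_b <- b[b$elesy %in% c("N", "O"), , drop = FALSE]
  if (.min_dist(no_a, no_b) <= cutoffs$hbond_cutoff) {
    types <- c(types, "hydrogen_bond")
  }
  if (a$resid[1] %in% cutoffs$hydrophobic_residues &&
      b$resid[1] %in% cutoffs$hydrophobic_residues) {
    sc_a <- a[a$elesy == "C" & !a$elety %in% .backbone_atoms, , drop = FALSE]
    sc_b <- b[b$elesy == "C" & !b$elety %in% .backbone_atoms, , drop = FALSE]
    if (.min_dist(sc_a, sc_b) <= cutoffs$hydrophobic_cutoff) {
      types <- c(types, "hydrophobic")
    }
  }
  if (!length(types) && md <= cutoffs$proximity_cutoff) {
    types <- "proximal_6A"
  }
  list(types = types, min_distance = md)
}

#' Build the typed residue contact graph
#'
#' Classifies every residue pair (with a bounding-sphere spatial prefilter
#' unless `prefilter = FALSE`; the prefilter is exact for the cutoffs
#' used) and assembles an undirected graph: one node per residue
#' (annotated with a category, e.g. from the state-comparison stage) and
#' one edge per (pair, interaction type) with the measured heavy-atom
#' minimum distance.
#'
#' @param structure A `structure_model`.
#' @param annotations Optional named character vector mapping residue
#'   number to a category (e.g. "exchanging", "cluster", "both");
#'   unannotated residues get "none".
#' @param cutoffs Geometric cutoffs.
#' @param prefilter Use the spatial prefilter (default) or classify all
#'   pairs.
#' @return Object of class `contact_graph`: `graph` (igraph, vertex
#'   attributes `resno`, `category`; edge attributes `type`, `distance`),
#'   `edges` (data frame res_i, res_j, type, distance) and `nodes`.
#' @export
build_contact_graph <- function(structure, annotations = NULL,
                                cutoffs = disp_config()$network,
                                prefilter = TRUE) {
  stopifnot(inherits(structure, "structure_model"))
  res <- structure$residues
  n <- nrow(res)
  at_by_res <- lapply(seq_len(n), function(i)
    .residue_atoms(structure, res$resno[i], res$chain[i]))
  cand <- if (prefilter && n > 1) {
    cx <- vapply(at_by_res, function(a) mean(a$x), numeric(1))
    cy <- vapply(at_by_res, function(a) mean(a$y), numeric(1))
    cz <- vapply(at_by_res, function(a) mean(a$z), numeric(1))
    rad <- vapply(seq_len(n), function(i) {
      a <- at_by_res[[i]]
      sqrt(max((a$x - cx[i])^2 + (a$y - cy[i])^2 + (a$z - cz[i])^2))
    }, numeric(1))
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    dcent <- sqrt((cx[pairs[, 1]] - cx[pairs[, 2]])^2 +
                  (cy[pairs[, 1]] - cy[pairs[, 2]])^2 +
                  (cz[pairs[, 1]] - cz[pairs[, 2]])^2)
    keep <- dcent <= cutoffs$proximity_cutoff +
      rad[pairs[, 1]] + rad[pairs[, 2]]
    # sequence neighbours are covalent regardless of distance
    adj <- res$chain[pairs[, 1]] == res$chain[pairs[, 2]] &
      abs(res$resno[pairs[, 1]] - res$resno[pairs[, 2]]) == 1
    pairs[keep | adj, , drop = FALSE]
  } else if (n > 1) {
    which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  } else {
    matrix(integer(0), 0, 2)
  }
  edges <- list()
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    cl <- classify_interaction(structure, res$resno[i], res$resno[j],
                               res$chain[i], res$chain[j], cutoffs)
    for (tp in cl$types) {
      edges[[length(edges) + 1L]] <- data.frame(
        res_i = res$resno[i], res_j = res$resno[j],
        chain_i = res$chain[i], chain_j = res$chain[j],
        type = tp, distance = cl$min_distance)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(res_i = integer(), res_j = integer(), chain_i = character(),
               chain_j = character(), type = character(), distance = numeric())
  edges <- edges[order(edges$res_i, edges$res_j, edges$type), ]
  rownames(edges) <- NULL
  category <- rep("none", n)
  if (!is.null(annotations)) {
    hit <- match(as.character(res$resno), names(annotations))
    category[!is.na(hit)] <- annotations[hit[!is.na(hit)]]
  }
  nodes <- data.frame(resno = res$resno, chain = res$chain,
                      resid = res$resid, category = category)
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(edges$res_i),
                   to = as.character(edges$res_j),
                   type = edges$type, distance = edges$distance),
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes$resno),
                          category = nodes$category, resid = nodes$resid))
  structure(list(graph = g, edges = edges, nodes = nodes,
                 cutoffs = cutoffs),
            class = "contact_graph")
}

#' Trace interaction paths between cluster residues
#'
#' For every pair of cluster residues, finds the shortest path(s) through
#' the contact graph whose intermediate nodes are all dynamic (exchanging)
#' residues or other cluster members, up to a maximum path length. Pairs
#' with no such path are reported, not raised.
#'
#' @param cg A `contact_graph`.
#' @param cluster_nodes,dynamic_nodes Integer residue vectors; must exist
#'   in the graph.
#' @param max_len Maximum path length in edges (default 6).
#' @return List with `paths` (data frame: from, to, length, path as
#'   "a-b-c" string; all shortest paths per pair) and `unreachable`
#'   (data frame of pairs without a qualifying path).
#' @export
find_connecting_paths <- function(cg, cluster_nodes, dynamic_nodes,
                                  max_len = disp_config()$network$max_path_len) {
  stopifnot(inherits(cg, "contact_graph"))
  g <- igraph::simplify(cg$graph, remove.multiple = TRUE,
                        remove.loops = TRUE)
  cluster_nodes <- sort(unique(as.integer(cluster_nodes)))
  dynamic_nodes <- sort(unique(as.integer(dynamic_nodes)))
  have <- as.integer(igraph::V(g)$name)
  missing <- setdiff(cluster_nodes, have)
  if (length(missing)) {
    stop("cluster node(s) not in graph: ", paste(missing, collapse = ", "))
  }
  allowed <- as.character(intersect(union(cluster_nodes, dynamic_nodes), have))
  sub <- igraph::induced_subgraph(g, allowed)
  pairs <- if (length(cluster_nodes) >= 2) {
    combn(cluster_nodes, 2)
  } else matrix(integer(0), 2, 0)
  paths <- list(); unreachable <- list()
  for (k in seq_len(ncol(pairs))) {
    a <- as.character(pairs[1, k]); b <- as.character(pairs[2, k])
    d <- igraph::distances(sub, a, b)[1, 1]
    if (is.finite(d) && d <= max_len) {
      sp <- igraph::all_shortest_paths(sub, a, b)$res
      for (p in sp) {
        ids <- as.integer(igraph::V(sub)$name[p])
        paths[[length(paths) + 1L]] <- data.frame(
          from = pairs[1, k], to = pairs[2, k], length = length(ids) - 1L,
          path = paste(ids, collapse = "-"))
      }
    } else {
      unreachable[[length(unreachable) + 1L]] <- data.frame(
        from = pairs[1, k], to = pairs[2, k])
    }
  }
  empty_paths <- data.frame(from = integer(), to = integer(),
                            length = integer(), path = character())
  out_paths <- if (length(paths)) do.call(rbind, paths) else empty_paths
  out_paths <- out_paths[order(out_paths$from, out_paths$to, out_paths$path), ]
  rownames(out_paths) <- NULL
  list(paths = out_paths,
       unreachable = if (length(unreachable)) do.call(rbind, unreachable)
                     else data.frame(from = integer(), to = integer()))
}

#' Export a sphere-rendering script
#'
#' Deterministic PyMOL command text painting residue categories as
#' coloured CA spheres, mirroring the usual dispersion-figure conventions
#' (purple/pink for fittable/broadened, blue/red for state differences,
#' yellow/blue/green for cluster overlays). Residues are emitted in
#' ascending order within each category; categories in the palette's
#' order.
#'
#' @param category_map Named character vector: names are residue numbers,
#'   values are categories.
#' @param palette Named character vector mapping category to colour.
#' @param object Structure object name used in the selections.
#' @return Character vector of script lines.
#' @export
export_sphere_script <- function(category_map,
                                 palette = c(two_site_fittable = "purple",
                                             broadened_unfittable = "pink"),
                                 object = "structure") {
  lines <- c("# residue category sphere rendering",
             sprintf("hide everything, %s", object),
             sprintf("show cartoon, %s", object),
             "set sphere_scale, 0.7")
  for (cat in names(palette)) {
    resn <- sort(as.integer(names(category_map)[category_map == cat]))
    for (r in resn) {
      lines <- c(lines,
                 sprintf("show spheres, %s and resi %d and name CA", object, r),
                 sprintf("color %s, %s and resi %d and name CA",
                         palette[[cat]], object, r))
    }
  }
  lines
}
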