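# in-code fixtures shared across test files

# dispersion rows for one residue from the closed form + optional noise
make_curves <- function(residue = 1L, k_ex = 273, p_a = 0.944,
                        delta_delta = 2.5, r2_0 = c(`600` = 14, `850` = 16),
                        noise = 0, seed = NULL,
                        nu = default_nu_grid(), sigma = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(names(r2_0), function(f) {
    fc <- field_context(as.numeric(f))
    ideal <- if (delta_delta == 0 || p_a == 1) {
      rep(r2_0[[f]], length(nu))
    } else {
      carver_richards_r2eff(
        exchange_parameters(k_ex, p_a, delta_delta, r2_0[[f]]),
        1 / (2 * nu), fc)
    }
    s <- if (is.null(sigma)) pmax(0.02 * ideal, 0.3) else rep(sigma, length(nu))
    data.frame(state = "test", field_mhz = as.numeric(f), residue = residue,
               nu_cpmg_hz = nu, r2_eff = ideal + rnorm(length(nu), 0, noise),
               sigma = s)
  })
  do.call(rbind, rows)
}

# fixed-format PDB ATOM record
pdb_atom <- function(serial, name, resn, chain, resno, x, y, z,
                     occ = 1.00, alt = " ", elem = substr(name, 1, 1)) {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %4s%s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, nm, alt, resn, chain, resno, x, y, z, occ, 0.0, elem)
}

# one residue's atoms on a planar template anchored at (ox, oy):
# N(ox-1.2, oy+0.3), CA(ox, oy), C(ox+1.2, oy+0.6), O(ox+1.3, oy+1.8),
# optional CB(ox, oy+cby)
pdb_residue_lines <- function(serial0, resn, resno, ox, oy, cb = TRUE,
                              cby = -1) {
  at <- list(c("N", ox - 1.2, oy + 0.3), c("CA", ox, oy),
             c("C", ox + 1.2, oy + 0.6), c("O", ox + 1.3, oy + 1.8))
  if (cb) at <- c(at, list(c("CB", ox, oy + cby)))
  vapply(seq_along(at), function(i) {
    a <- at[[i]]
    pdb_atom(serial0 + i, a[1], resn, "A", resno,
             as.numeric(a[2]), as.numeric(a[3]), 0)
  }, character(1))
}

# engineered 5-residue structure with a hand-computed edge list:
#   covalent: every sequence-neighbour pair (1-2, 2-3, 3-4, 4-5),
#             placed far apart so no other label applies to them
#   1-3 hydrophobic: ALA/ALA, CB pair (0,-1) vs (0,-5) = 4.0 A
#   2-4 hydrogen bond: O2 (10.3, 1.8) to N4 (10.3, -1.4) = 3.2 A
#   3-5 proximal: closest heavy pair CA3 (0,-6) to O5 (1.3,-10.4) = 4.59 A,
#                 no N/O pair within 3.5, LYS not hydrophobic
#   1-4, 1-5, 2-5: all heavy-atom pairs beyond 6 A
write_engineered_pdb <- function(path) {
  lines <- c(
    pdb_residue_lines(0,  "ALA", 1, 0,    0,    cby = -1),
    pdb_residue_lines(10, "SER", 2, 9,    0),
    pdb_residue_lines(20, "ALA", 3, 0,   -6,    cby = 1),
    pdb_residue_lines(30, "GLY", 4, 11.5, -1.7, cb = FALSE),
    pdb_residue_lines(40, "LYS", 5, 0,   -12.2, cby = -1))
  writeLines(c(lines, "TER", "END"), path)
  path
}

# wrap an abstract residue-level edge list as a contact_graph for
# path-logic tests
make_contact_graph <- function(edges, nodes = sort(unique(c(edges$res_i,
                                                            edges$res_j)))) {
  if (!"type" %in% names(edges)) edges$type <- "proximal_6A"
  if (!"distance" %in% names(edges)) edges$distance <- 5
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$res_i),
               to = as.character(edges$res_j),
               type = edges$type, distance = edges$distance),
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes), category = "none",
                          resid = "ALA"))
  structure(list(graph = g, edges = edges,
                 nodes = data.frame(resno = nodes, chain = "A",
                                    resid = "ALA", category = "none"),
                 cutoffs = disp_config()$network),
            class = "contact_graph")
}

# exhaustive simple-path enumeration oracle (independent of igraph):
# all simple paths from a to b over an adjacency list, intermediates
# restricted to `allowed`, at most max_len edges
enumerate_paths <- function(adj, a, b, allowed, max_len) {
  out <- list()
  walk <- function(node, path) {
    if (length(path) - 1 > max_len) return()
    if (node == b) {
      out[[length(out) + 1L]] <<- path
      return()
    }
    for (nb in adj[[as.character(node)]]) {
      if (nb %in% path) next
      if (nb != b && !(nb %in% allowed)) next
      walk(nb, c(path, nb))
    }
  }
  walk(a, a)
  out
}

# adjacency list of a contact_graph (undirected, simplified)
graph_adjacency <- function(cg) {
  e <- unique(cg$edges[, c("res_i", "res_j")])
  nodes <- sort(unique(c(e$res_i, e$res_j, cg$nodes$resno)))
  adj <- setNames(lapply(nodes, function(n) {
    sort(unique(c(e$res_j[e$res_i == n], e$res_i[e$res_j == n])))
  }), nodes)
  adj
}
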