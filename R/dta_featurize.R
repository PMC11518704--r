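# Molecule-graph and protein-sequence featurization.
#
# SMILES parsing is delegated to ChemmineR/ChemmineOB (OpenBabel). From the
# resulting connection table each heavy atom is described by the standard
# 74-dimensional integer vector used by graph-based molecular encoders:
# eight blocks covering atom type, degree, implicit hydrogen count, formal
# charge, radical electrons, hybridization, aromaticity and total hydrogen
# count, one-hot within blocks.

.atom_symbols <- c(
  "C", "N", "O", "S", "F", "Si", "P", "Cl", "Br", "Mg", "Na", "Ca", "Fe",
  "As", "Al", "I", "B", "V", "K", "Tl", "Yb", "Sb", "Sn", "Ag", "Pd", "Co",
  "Se", "Ti", "Zn", "H", "Li", "Ge", "Cu", "Au", "Ni", "Cd", "In", "Mn",
  "Zr", "Cr", "Pt", "Hg", "other"
)  # 43 entries

.default_valence <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1,
                      Br = 1, I = 1, B = 3, Si = 4)

#' Amino-acid alphabet used by the protein encoder
#'
#' The 20 proteinogenic amino acids plus the auxiliary symbols B, Z
#' (ambiguity codes) and X (unknown), 23 symbols in total; unrecognised
#' letters map to X.
#' @return Character vector of length 23.
#' @export
protein_alphabet <- function() {
  c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "B", "Z", "X")
}

# Parse one molecule's connection table out of an SDFset element.
.connection_table <- function(sdf_item) {
  ab <- ChemmineR::atomblock(sdf_item)
  bb <- ChemmineR::bondblock(sdf_item)
  syms <- sub("_.*$", "", rownames(ab))
  n <- length(syms)
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0) {
    data.frame(a = integer(0), b = integer(0), order = integer(0))
  } else {
    data.frame(a = as.integer(bb[, 1]), b = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  }
  charges <- integer(n)
  txt <- ChemmineR::sdf2str(sdf_item)
  chg <- grep("^M  CHG", txt, value = TRUE)
  for (line in chg) {
    v <- as.integer(strsplit(trimws(sub("^M  CHG", "", line)), "\\s+")[[1]])
    k <- v[1]
    for (j in seq_len(k)) charges[v[2 * j]] <- v[2 * j + 1]
  }
  list(symbols = syms, bonds = bonds, charges = charges)
}

# Aromatic-ring perception on a kekulized connection table: a ring of size
# 5 or 6 counts as aromatic when every ring carbon takes part in a double
# bond within the ring (heteroatoms N/O/S are exempt, covering furan-,
# pyrrole- and thiophene-type rings). SDF bond order 4 (aromatic) is also
# honoured when a writer emits it.
.aromatic_atoms <- function(ct) {
  n <- length(ct$symbols)
  arom <- logical(n)
  if (!nrow(ct$bonds)) return(arom)
  g <- igraph::graph_from_edgelist(cbind(ct$bonds$a, ct$bonds$b),
                                   directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  bond_key <- paste(pmin(ct$bonds$a, ct$bonds$b),
                    pmax(ct$bonds$a, ct$bonds$b))
  border <- stats::setNames(ct$bonds$order, bond_key)
  for (e in seq_len(nrow(ct$bonds))) {
    a <- ct$bonds$a[e]; b <- ct$bonds$b[e]
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(a, b)))
    sp <- suppressWarnings(igraph::shortest_paths(g2, from = a, to = b)$vpath[[1]])
    if (!length(sp)) next
    ring <- as.integer(sp)
    if (!(length(ring) %in% c(5L, 6L))) next
    ring_pairs <- paste(pmin(ring, c(ring[-1], ring[1])),
                        pmax(ring, c(ring[-1], ring[1])))
    orders <- border[ring_pairs]
    ok <- vapply(seq_along(ring), function(i) {
      at <- ring[i]
      if (ct$symbols[at] %in% c("N", "O", "S")) return(TRUE)
      touching <- orders[c(i, if (i == 1) length(ring) else i - 1)]
      any(touching %in% c(2L, 4L))
    }, logical(1))
    if (all(ok) || all(orders == 4L)) arom[ring] <- TRUE
  }
  arom
}

.one_hot <- function(value, levels) {
  v <- numeric(length(levels))
  i <- match(value, levels)
  if (is.na(i)) i <- length(levels)
  v[i] <- 1
  v
}

.atom_features <- function(ct) {
  n <- length(ct$symbols)
  deg <- tabulate(c(ct$bonds$a, ct$bonds$b), nbins = n)
  bosum <- numeric(n)
  has_double <- logical(n); has_triple <- logical(n); n_double <- integer(n)
  for (e in seq_len(nrow(ct$bonds))) {
    a <- ct$bonds$a[e]; b <- ct$bonds$b[e]; o <- ct$bonds$order[e]
    oo <- if (o == 4L) 1.5 else o
    bosum[c(a, b)] <- bosum[c(a, b)] + oo
    if (o == 2L) { has_double[c(a, b)] <- TRUE; n_double[c(a, b)] <- n_double[c(a, b)] + 1L }
    if (o == 3L) has_triple[c(a, b)] <- TRUE
  }
  arom <- .aromatic_atoms(ct)
  feats <- matrix(0, nrow = n, ncol = 74)
  for (i in seq_len(n)) {
    sym <- ct$symbols[i]
    val <- if (sym %in% names(.default_valence)) .default_valence[[sym]] else 0
    val <- val + if (sym %in% c("N", "O", "S", "P")) ct$charges[i] else 0
    imp_h <- max(0, round(val - bosum[i]))
    hyb <- if (arom[i]) "SP2"
           else if (has_triple[i] || n_double[i] >= 2L) "SP"
           else if (has_double[i]) "SP2"
           else "SP3"
    feats[i, ] <- c(
      .one_hot(sym, .atom_symbols),                       # 43: atom type
      .one_hot(as.character(min(deg[i], 10L)), as.character(0:10)),  # 11: degree
      .one_hot(as.character(min(imp_h, 6L)), as.character(0:6)),     # 7: implicit H
      ct$charges[i],                                      # 1: formal charge
      0,                                                  # 1: radical electrons
      .one_hot(hyb, c("SP", "SP2", "SP3", "SP3D", "SP3D2")),  # 5
      as.numeric(arom[i]),                                # 1: aromatic
      .one_hot(as.character(min(imp_h, 4L)), as.character(0:4))      # 5: total H
    )
  }
  feats
}

#' Featurize molecules from SMILES into graph objects
#'
#' Converts each SMILES string to a 2D molecular graph with one node per
#' heavy atom (74-dimensional feature vectors, see the file header) and an
#' undirected adjacency over bonds. Molecules with more than `theta_d` heavy
#' atoms are truncated with a warning, mirroring the protein-length
#' convention. The symmetrically normalized adjacency with self-loops used
#' by the graph-convolution encoder is precomputed.
#'
#' @param smiles Character vector of SMILES strings.
#' @param theta_d Node-count cap (default 290).
#' @return List of `mol_graph` objects: `smiles`, `n_real`, `features`
#'   (`n x 74`), `adj_norm` (`n x n`). Unparseable input is an error.
#' @export
featurize_molecule <- function(smiles, theta_d = 290) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  if (any(!nzchar(trimws(smiles)))) stop("empty SMILES string")
  sdf <- ChemmineR::smiles2sdf(stats::setNames(smiles, paste0("m", seq_along(smiles))))
  if (length(sdf) != length(smiles)) stop("SMILES conversion failed for some input")
  out <- vector("list", length(smiles))
  for (i in seq_along(smiles)) {
    ct <- .connection_table(sdf[[i]])
    n <- length(ct$symbols)
    if (n < 1) stop("unparseable SMILES: ", smiles[i])
    if (n > theta_d) {
      warning("molecule with ", n, " atoms truncated to theta_d = ", theta_d)
      keep <- seq_len(theta_d)
      ct$symbols <- ct$symbols[keep]
      ct$charges <- ct$charges[keep]
      ct$bonds <- ct$bonds[ct$bonds$a <= theta_d & ct$bonds$b <= theta_d, , drop = FALSE]
      n <- theta_d
    }
    A <- matrix(0, n, n)
    if (nrow(ct$bonds)) {
      A[cbind(ct$bonds$a, ct$bonds$b)] <- 1
      A[cbind(ct$bonds$b, ct$bonds$a)] <- 1
    }
    Ahat <- A + diag(n)
    dinv <- 1 / sqrt(rowSums(Ahat))
    out[[i]] <- structure(
      list(smiles = smiles[i], n_real = n,
           features = .atom_features(ct),
           adj_norm = Ahat * outer(dinv, dinv)),
      class = "mol_graph"
    )
  }
  out
}

#' Pad a molecule graph with virtual nodes
#'
#' Appends all-zero feature rows and disconnected adjacency rows up to
#' `theta_d` nodes. The encoder masks virtual nodes, so padding never
#' changes the model output; this helper exists to express (and test) that
#' contract.
#'
#' @param graph A `mol_graph`.
#' @param theta_d Target node count.
#' @return A `mol_graph` with `theta_d` rows and unchanged `n_real`.
#' @export
pad_graph <- function(graph, theta_d) {
  n <- nrow(graph$features)
  stopifnot(theta_d >= n)
  if (theta_d == n) return(graph)
  feats <- rbind(graph$features, matrix(0, theta_d - n, ncol(graph$features)))
  adj <- matrix(0, theta_d, theta_d)
  adj[seq_len(n), seq_len(n)] <- graph$adj_norm
  graph$features <- feats
  graph$adj_norm <- adj
  graph
}

#' Encode a protein sequence as alphabet indices
#'
#' Sequences longer than `theta_p` are truncated; shorter sequences are used
#' at their effective length (zero padding beyond it is masked by the
#' encoder, so it cannot affect the output).
#'
#' @param sequence Amino-acid string.
#' @param theta_p Maximum sequence length (default 1200).
#' @return Integer vector of indices into [protein_alphabet()].
#' @export
encode_protein <- function(sequence, theta_p = 1200) {
  stopifnot(is.character(sequence), length(sequence) == 1, nzchar(sequence))
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (length(chars) > theta_p) chars <- chars[seq_len(theta_p)]
  idx <- match(chars, protein_alphabet())
  idx[is.na(idx)] <- length(protein_alphabet())  # unknown -> X
  idx
}
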